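# Internal helpers shared across modules.

#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats pchisq pnorm rnorm runif rbinom rmultinom cor.test sd
#'   p.adjust phyper setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

# round half away from zero (base::round is round-half-even); reproduces the
# printed fold changes of SAGE reports
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

DNA_BASES_CHR <- c("A", "C", "G", "T")

# n random DNA strings of length len (vectorized)
randomDNA <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES_CHR, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# reverse complement of plain character vectors
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministically remove every CATG occurrence (used for 3' tails so the
# anchoring-enzyme site of a transcript stays the intended one)
scrubCATG <- function(x) {
  while (any(grepl("CATG", x, fixed = TRUE)))
    x <- gsub("CATG", "CTTG", x, fixed = TRUE)
  x
}

# the five library roles of the two-time-point calcium-challenge design
sageRoles <- function() c("C2h", "LowCa2h", "C12h", "HighCa12h", "LowCa12h")

# resolve a role->library-name mapping against a set of library names
resolveRoles <- function(roles, libs) {
  need <- sageRoles()
  if (is.null(roles)) roles <- setNames(need, need)
  if (!all(need %in% names(roles)))
    stop("role mapping must name all of: ", paste(need, collapse = ", "))
  roles <- roles[need]
  missing <- setdiff(unname(roles), libs)
  if (length(missing))
    stop("libraries not present in the count matrix: ",
         paste(missing, collapse = ", "))
  roles
}
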