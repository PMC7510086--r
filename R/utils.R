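#' @importFrom stats runif sd setNames
#' @importFrom utils write.table read.delim head
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Complement of a character vector of single bases (keeps N and gap).
complement_chars <- function(ch) {
  out <- COMPLEMENT[ch]
  out[is.na(out)] <- "N"
  unname(out)
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Does observed base `base` satisfy IUPAC pattern character `pat`?
# Ambiguous observed bases (N in the subject) never satisfy a specific
# requirement; they only count as a match when the pattern itself is N?
# No: an N in the subject is unknown, so it fails every pattern character.
iupac_match <- function(base, pat) {
  allowed <- IUPAC_SETS[[pat]]
  if (is.null(allowed)) stop("invalid IUPAC character: ", pat)
  base %in% allowed
}

is_dna <- function(x, allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  grepl(paste0("^[", alphabet, "]+$"), x)
}

# Run code with a private RNG stream seeded at `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n), the
#' convention behind "mean +/- s.e.m." error bars. Returns `NA` for a single
#' value.
#'
#' @param x numeric vector of replicate values.
#' @return standard error of the mean.
#' @export
sem <- function(x) {
  n <- length(x)
  if (n < 1) stop("sem() needs at least one value")
  if (n == 1) return(NA_real_)
  stats::sd(x) / sqrt(n)
}
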