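#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Hamming distance between equal-length DNA strings
#'
#' @param a,b character vectors of equal-length strings; `b` may be length 1
#'   (recycled against `a`).
#' @return integer vector of per-pair mismatch counts.
#' @examples
#' hamming("ACGT", "ACGA")
#' @export
hamming <- function(a, b) {
  if (length(b) == 1L) b <- rep_len(b, length(a))
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  if (any(nchar(a) != nchar(b))) {
    stop("hamming(): strings must have equal length", call. = FALSE)
  }
  ma <- strsplit(a, "", fixed = TRUE)
  mb <- strsplit(b, "", fixed = TRUE)
  mapply(function(x, y) sum(x != y), ma, mb, USE.NAMES = FALSE)
}

# Mismatch counts of many equal-length strings against one pattern.
# Vectorised via a char matrix; strings must all share nchar(pattern).
.mismatches_to <- function(strings, pattern) {
  n <- length(strings)
  if (n == 0L) return(integer(0))
  w <- nchar(pattern)
  m <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
              nrow = w)
  p <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  as.integer(colSums(m != p))
}

# Deterministic sub-seed derivation: fold an operation tag into the scenario
# seed so every stochastic stage is independently reproducible. Kept below
# 2^31 - 1 (R integers are 32-bit).
sub_seed <- function(seed, tag) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stochastic rounding: E[result] == x exactly, result integer-valued.
stochastic_round <- function(x) {
  f <- floor(x)
  frac <- x - f
  f + (stats::runif(length(x)) < frac)
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_ALPHABET, width, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
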