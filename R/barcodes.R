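# Barcode / index design.
#
# Construct barcodes are 4 nt and matched exactly during counting, so the
# packaged code keeps all pairs at Hamming distance >= 2 (a single
# substitution can never convert one valid barcode into another). Sample
# indices are 6 nt; a minimum pairwise distance of 3 lets one substitution be
# corrected unambiguously when the caller allows index mismatches.

all_kmers <- function(width, alphabet = DNA_ALPHABET) {
  grid <- do.call(expand.grid, rep(list(alphabet), width))
  apply(as.matrix(grid)[, rev(seq_len(width)), drop = FALSE], 1, paste,
        collapse = "")
}

# Words whose letter-value sum is 0 mod 4: a distance->=2 code of size 4^(w-1)
# (any single substitution changes the sum mod 4).
.parity_code <- function(width) {
  kmers <- all_kmers(width)
  vals <- vapply(strsplit(kmers, "", fixed = TRUE), function(ch) {
    sum(match(ch, DNA_ALPHABET) - 1L)
  }, integer(1))
  kmers[vals %% 4L == 0L]
}

# Greedy maximal code at pairwise Hamming >= min_dist over a shuffled
# candidate pool.
.greedy_code <- function(candidates, min_dist, n_needed) {
  chosen <- character(0)
  chosen_mat <- NULL
  width <- nchar(candidates[1L])
  for (cand in candidates) {
    if (length(chosen) >= n_needed) break
    v <- strsplit(cand, "", fixed = TRUE)[[1L]]
    if (is.null(chosen_mat) ||
        all(colSums(chosen_mat != v) >= min_dist)) {
      chosen <- c(chosen, cand)
      chosen_mat <- cbind(chosen_mat, matrix(v, nrow = width))
    }
  }
  chosen
}

#' Design a set of DNA codewords at a minimum pairwise Hamming distance
#'
#' @param n number of codewords required.
#' @param width word length in nucleotides.
#' @param min_hamming minimum pairwise Hamming distance.
#' @param seed integer seed; the set is deterministic given the seed.
#' @return character vector of `n` distinct words, pairwise Hamming distance
#'   at least `min_hamming`.
#' @details For `min_hamming = 2` the candidates are drawn from a parity code
#'   of size `4^(width-1)`, so capacity is exact (64 words for 4-mers). For
#'   larger distances a greedy packing over all `4^width` words is used and a
#'   capacity error is raised if it cannot seat `n` words.
#' @export
design_code <- function(n, width, min_hamming, seed = 0L) {
  stopifnot(n >= 1, width >= 1, min_hamming >= 1)
  pool <- if (min_hamming == 2L) .parity_code(width) else all_kmers(width)
  if (min_hamming <= 1L) {
    cap <- length(pool)
    if (n > cap) stop(sprintf(
      "capacity error: %d words requested but only %d %d-mers exist",
      n, cap, width), call. = FALSE)
    return(with_seed(seed, sample(pool, n)))
  }
  shuffled <- with_seed(seed, sample(pool))
  code <- .greedy_code(shuffled, min_hamming, n)
  if (length(code) < n) {
    stop(sprintf(paste0(
      "capacity error: %d words requested at min Hamming %d ",
      "but only %d could be packed from %d-mers"),
      n, min_hamming, length(code), width), call. = FALSE)
  }
  code
}

#' Assign synthetic barcodes to a manifest lacking them
#'
#' The real 4-nt barcode sequences of the library are not public; this
#' generates a deterministic collision-free stand-in set so that exact-match
#' counting is well defined.
#'
#' @param m a `pathscreen_manifest` (barcode column may be empty or absent).
#' @param min_hamming minimum pairwise Hamming distance between barcodes
#'   (default 2: no two barcodes are single-substitution neighbours).
#' @param seed integer seed making the assignment reproducible.
#' @return the manifest with the `barcode` column filled in.
#' @export
assign_barcodes <- function(m, min_hamming = 2L, seed = 0L) {
  df <- as.data.frame(m)
  n <- nrow(df)
  if (n == 0L) stop("assign_barcodes(): empty manifest", call. = FALSE)
  df$barcode <- design_code(n, width = 4L, min_hamming = min_hamming,
                            seed = seed)
  new_manifest(df, version = attr(m, "version") %||% "unversioned")
}

#' Design sample indices for a sequencing pool
#'
#' @param n number of samples.
#' @param min_hamming minimum pairwise distance (default 3, allowing
#'   unambiguous single-error correction).
#' @param seed integer seed.
#' @return character vector of 6-nt indices.
#' @export
assign_indices <- function(n, min_hamming = 3L, seed = 0L) {
  design_code(n, width = 6L, min_hamming = min_hamming, seed = seed)
}
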