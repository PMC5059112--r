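# Fixed single-end read layout: each sequencing read is exactly 27 nt,
# laid out as [0,4) construct barcode, [4,21) constant linker ending in the
# ORF start codon ATG, [21,27) sample index (0-based, half-open).

# Default linker: 14 nt of vector/Kozak context followed by ATG. The true
# linker sequence is not public; any fixed 17-mer ending in ATG satisfies
# the layout contract because linker matching is against this same constant.
DEFAULT_LINKER <- "TAGCGGCCGCCACCATG"

#' Describe the fixed 27-nt read layout
#'
#' @param linker_seq the 17-nt constant linker; must end in `ATG` (the ORF
#'   start codon sits immediately downstream of the barcode region).
#' @return a `read_layout` list with fields `barcode_len`, `linker_seq`,
#'   `index_len`, `total_len` (always 4 + 17 + 6 = 27).
#' @export
read_layout <- function(linker_seq = DEFAULT_LINKER) {
  if (nchar(linker_seq) != 17L || grepl("[^ACGT]", linker_seq)) {
    stop("linker_seq must be a 17-nt A/C/G/T string", call. = FALSE)
  }
  if (!endsWith(linker_seq, "ATG")) {
    stop("linker_seq must end in the ATG start codon", call. = FALSE)
  }
  structure(list(barcode_len = 4L, linker_seq = linker_seq, index_len = 6L,
                 total_len = 4L + 17L + 6L),
            class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  cat(sprintf("<read_layout> %d nt = %d (barcode) + %d (linker %s) + %d (index)\n",
              x$total_len, x$barcode_len, nchar(x$linker_seq), x$linker_seq,
              x$index_len))
  invisible(x)
}
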