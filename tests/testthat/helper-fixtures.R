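# Shared fixtures, built in code at test time.

# A small manifest: n activating constructs over ceiling(n/2) pathways plus
# two negative controls, with deterministic barcodes.
tiny_manifest <- function(n = 6, seed = 11) {
  ids <- sprintf("ACT%02d", seq_len(n))
  pw <- sprintf("Pathway%02d", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)])
  df <- data.frame(
    construct_id = c(ids, "CTRL_A", "CTRL_B"),
    pathway = c(pw, "", ""),
    protein = c(ids, "HcRed", "luciferase"),
    activation_strategy = "synthetic",
    variant_note = "",
    validation_assay = "",
    barcode = "",
    role = c(rep("pathway_activator", n), "negative_control",
             "negative_control"),
    stringsAsFactors = FALSE)
  m <- pathscreen:::new_manifest(df, version = "tiny")
  assign_barcodes(m, min_hamming = 2L, seed = seed)
}

# A small, fast scenario over the tiny manifest's scale; any
# screen_scenario() argument can be overridden.
tiny_scenario <- function(..., seed = 7) {
  args <- list(n_cells = 20000L, moi = 0.3, days = 7L, capacity = 2e4,
               read_depth = 5000L, error_rate = 0, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(screen_scenario, args)
}

# Build an exact read for (construct, sample index) under a layout.
make_read <- function(barcode, index, layout = read_layout()) {
  paste0(barcode, layout$linker_seq, index)
}

# Independent brute-force counting oracle: assigns each read by direct
# substring comparison against every (barcode, index) pair; mirrors the
# documented layout but shares no code with count_barcodes().
naive_count_oracle <- function(seqs, layout, samplesheet, manifest,
                               max_linker_mm = 2L, max_index_mm = 0L) {
  ids <- as.data.frame(manifest)$construct_id
  bcs <- as.data.frame(manifest)$barcode
  counts <- matrix(0L, nrow = length(ids), ncol = nrow(samplesheet),
                   dimnames = list(ids, samplesheet$sample_id))
  mm <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (s in seqs) {
    if (nchar(s) < layout$total_len) next
    s <- substr(s, 1, layout$total_len)
    idx <- substr(s, 22, 27)
    d <- vapply(samplesheet$index_seq, function(x) mm(idx, x), integer(1))
    if (min(d) > max_index_mm || sum(d == min(d)) > 1) next
    si <- which.min(d)
    if (mm(substr(s, 5, 21), layout$linker_seq) > max_linker_mm) next
    ci <- which(bcs == substr(s, 1, 4))
    if (length(ci) != 1) next
    counts[ci, si] <- counts[ci, si] + 1L
  }
  counts
}

# Deterministic mean-field expectation of construct frequencies after
# `days` of growth at one dose: iterate the expected-count recurrence
# (passaging rescales all genotypes equally, so frequencies only depend on
# the growth factors).
mean_field_freqs <- function(pop, scenario, arm, manifest) {
  gi <- if (identical(arm, "vehicle")) 0 else scenario$doses[[arm]]
  keys <- names(pop$counts)
  rho <- pathscreen:::genotype_rho(keys, scenario$effects, arm)
  factor <- 2 ^ (scenario$baseline_growth * (1 - gi * rho))
  n <- pop$counts * factor ^ scenario$days
  final <- pathscreen:::new_cell_population(n)
  ab <- construct_abundance(final, manifest)
  ab / sum(ab)
}
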