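# Screen simulator: infection, selection arms, sequencing, full screens.

test_that("Poisson infection matches the conditional single-integration closed form", {
  m <- tiny_manifest(10)
  lambda <- 0.3
  n <- 200000L
  pop <- simulate_infection(n, lambda, m, seed = 1)
  keys <- names(pop$counts)
  n_single <- sum(pop$counts[!grepl("+", keys, fixed = TRUE)])
  total <- population_size(pop)
  # survivors are Poisson(lambda) conditioned on k >= 1
  p_expected <- lambda * exp(-lambda) / (1 - exp(-lambda))
  phat <- n_single / total
  se <- sqrt(p_expected * (1 - p_expected) / total)
  expect_lt(abs(phat - p_expected), 3.29 * se)  # 99.9% band
  # survival rate itself matches 1 - exp(-lambda)
  expect_lt(abs(total / n - (1 - exp(-lambda))), 0.005)
})

test_that("infection oracle: closed form agrees with direct per-cell draws", {
  # brute-force oracle at small n: literal per-cell Poisson + uniform draws
  set.seed(99)
  n <- 50000L
  lambda <- 0.3
  k <- rpois(n, lambda)
  oracle_frac <- sum(k == 1) / sum(k >= 1)
  closed <- lambda * exp(-lambda) / (1 - exp(-lambda))
  expect_lt(abs(oracle_frac - closed), 0.01)
})

test_that("low-MOI limit: all survivors carry exactly one construct", {
  m <- tiny_manifest(4)
  pop <- simulate_infection(50000L, 1e-4, m, seed = 2)
  expect_false(any(grepl("+", names(pop$counts), fixed = TRUE)))
})

test_that("equal-representation library gives uniform per-construct abundance", {
  m <- default_manifest()
  pop <- simulate_infection(500000L, 0.3, m, seed = 3)
  ab <- construct_abundance(pop, m)
  chi <- stats::chisq.test(ab)
  expect_gt(chi$p.value, 0.001)
})

test_that("infection is deterministic per seed and validates arguments", {
  m <- tiny_manifest(4)
  p1 <- simulate_infection(10000L, 0.3, m, seed = 5)
  p2 <- simulate_infection(10000L, 0.3, m, seed = 5)
  expect_identical(p1$counts, p2$counts)
  expect_error(simulate_infection(0L, 0.3, m), "n_cells")
  expect_error(simulate_infection(100L, 0, m), "moi")
})

test_that("simulate_arm: days = 0 is the identity, unknown dose errors", {
  m <- tiny_manifest(4)
  sc <- tiny_scenario(days = 0L)
  pop <- simulate_infection(5000L, 0.3, m, seed = 1)
  expect_identical(simulate_arm(pop, sc, "vehicle", seed = 1)$counts,
                   pop$counts)
  expect_error(simulate_arm(pop, sc, "nonsense", seed = 1), "unknown dose")
})

test_that("no resistance heterogeneity: drug and vehicle compositions agree", {
  m <- tiny_manifest(6)
  sc <- tiny_scenario(days = 10L)
  pop <- simulate_infection(20000L, 0.3, m, seed = 4)
  veh <- simulate_arm(pop, sc, "vehicle", seed = 10)
  drug <- simulate_arm(pop, sc, "1.5uM", seed = 11)  # all rho = 1
  fv <- construct_abundance(veh, m); fv <- fv / sum(fv)
  fd <- construct_abundance(drug, m); fd <- fd / sum(fd)
  expect_lt(max(abs(fv - fd)), 0.05)
})

test_that("a fully resistant construct overtakes the drug arm but not vehicle", {
  m <- tiny_manifest(6)
  sc <- tiny_scenario(days = 21L,
                      effects = list(ACT01 = list("1.5uM" = 0)))
  pop <- simulate_infection(50000L, 0.3, m, seed = 5)
  f0 <- construct_abundance(pop, m); f0 <- f0 / sum(f0)
  drug <- simulate_arm(pop, sc, "1.5uM", seed = 12)
  veh <- simulate_arm(pop, sc, "vehicle", seed = 13)
  fd <- construct_abundance(drug, m); fd <- fd / sum(fd)
  fv <- construct_abundance(veh, m); fv <- fv / sum(fv)
  expect_gt(fd[["ACT01"]], fv[["ACT01"]] * 5)
  expect_lt(abs(fv[["ACT01"]] - f0[["ACT01"]]), 0.05)
})

test_that("mean-field oracle: simulated frequencies match the deterministic recurrence", {
  m <- tiny_manifest(6)
  sc <- tiny_scenario(days = 14L, capacity = 1e5,
                      effects = list(ACT02 = list("750nM" = 0.2)))
  pop <- simulate_infection(100000L, 0.3, m, seed = 6)
  expected <- mean_field_freqs(pop, sc, "750nM", m)
  sim <- simulate_arm(pop, sc, "750nM", seed = 14)
  fs <- construct_abundance(sim, m); fs <- fs / sum(fs)
  expect_lt(max(abs(fs - expected)), 0.03)
})

test_that("sequencing reads are 27 nt, round-trip losslessly at zero error", {
  m <- tiny_manifest(6)
  layout <- read_layout()
  pop <- simulate_infection(5000L, 0.3, m, seed = 7)
  idx <- assign_indices(1, seed = 1)
  seqs <- simulate_sequencing(pop, idx, layout, m, depth = 2000L,
                              error_rate = 0, seed = 8, sample_id = "s1")
  expect_length(seqs, 2000L)
  expect_true(all(nchar(seqs) == 27L))
  sheet <- data.frame(sample_id = "s1", index_seq = idx)
  res <- pathscreen:::.parse_reads(unname(seqs), layout, sheet, m)
  expect_true(all(is.na(res$reject)))
  expect_true(all(res$sample_id == "s1"))
  # per-construct read tallies equal the multinomial template draw exactly
  expect_equal(sort(unique(res$construct_id)) %in%
                 as.data.frame(m)$construct_id, rep(TRUE,
                 length(unique(res$construct_id))))
})

test_that("single-genotype population yields only that barcode", {
  m <- tiny_manifest(4)
  pop <- pathscreen:::new_cell_population(c(ACT03 = 100))
  seqs <- simulate_sequencing(pop, "AAAAAA", read_layout(), m, depth = 500L,
                              error_rate = 0, seed = 9)
  bc <- as.data.frame(m)$barcode[as.data.frame(m)$construct_id == "ACT03"]
  expect_true(all(substr(seqs, 1, 4) == bc))
})

test_that("substitution error rate matches the closed-form per-read error fraction", {
  m <- tiny_manifest(4)
  pop <- simulate_infection(5000L, 0.3, m, seed = 10)
  eps <- 0.01
  depth <- 100000L
  seqs <- simulate_sequencing(pop, "ACACAC", read_layout(), m, depth = depth,
                              error_rate = eps, seed = 11)
  clean <- paste0(as.data.frame(m)$barcode, read_layout()$linker_seq,
                  "ACACAC")
  frac_mut <- mean(!(seqs %in% clean))
  p <- 1 - (1 - eps)^27  # ~0.237
  se <- sqrt(p * (1 - p) / depth)
  expect_lt(abs(frac_mut - p), 4 * se)
})

test_that("sequencing rejects bad arguments", {
  m <- tiny_manifest(4)
  pop <- simulate_infection(1000L, 0.3, m, seed = 1)
  expect_error(simulate_sequencing(pop, "AAAA", read_layout(), m, 100L),
               "layout error")
  expect_error(simulate_sequencing(pop, "AAAAAA", read_layout(), m, 0L),
               "depth")
})

test_that("generate_screen produces 7 populations, samplesheet, truth table", {
  m <- tiny_manifest(6)
  sc <- tiny_scenario(days = 3L, read_depth = 500L)
  run <- generate_screen(sc, m)
  expect_length(run$populations, 7L)
  expect_named(run$populations,
               c("t0", "drug_150nM", "drug_750nM", "drug_1.5uM",
                 "veh_150nM", "veh_750nM", "veh_1.5uM"))
  expect_equal(nrow(run$samplesheet), 7L * sc$n_tech_reps)
  expect_equal(anyDuplicated(run$samplesheet$index_seq), 0L)
  # each drug sample has a matching vehicle arm at the same dose
  drug_doses <- unique(run$samplesheet$dose_label[run$samplesheet$arm == "drug"])
  veh_doses <- unique(run$samplesheet$dose_label[run$samplesheet$arm == "vehicle"])
  expect_setequal(drug_doses, veh_doses)
  # truth table covers every construct x dose with planted rho (default 1)
  expect_equal(nrow(run$truth), 8L * 3L)
  expect_true(all(run$truth$rho == 1))
  expect_error(generate_screen(tiny_scenario(read_depth = 0L), m),
               "read_depth")
})

test_that("a fixed seed reproduces a byte-identical screen", {
  m <- tiny_manifest(4)
  sc <- tiny_scenario(days = 2L, read_depth = 300L, error_rate = 0.01,
                      seed = 21)
  r1 <- generate_screen(sc, m)
  r2 <- generate_screen(sc, m)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$samplesheet, r2$samplesheet)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_screen(r1, d1); write_screen(r2, d2)
  f1 <- file.path(d1, "t0_r1.fastq"); f2 <- file.path(d2, "t0_r1.fastq")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("written FASTQ is standard: an independent parser reads it back", {
  skip_if_not_installed("Biostrings")
  m <- tiny_manifest(4)
  pop <- simulate_infection(2000L, 0.3, m, seed = 3)
  seqs <- simulate_sequencing(pop, "GTGTGT", read_layout(), m, depth = 200L,
                              error_rate = 0, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(seqs, tmp)
  parsed <- Biostrings::readDNAStringSet(tmp, format = "fastq")
  expect_equal(length(parsed), 200L)
  expect_identical(as.character(unname(parsed)), unname(seqs))
})

test_that("growth without drug preserves expected construct frequencies", {
  m <- tiny_manifest(8)
  sc <- tiny_scenario(days = 10L, capacity = 5e4)
  pop <- simulate_infection(50000L, 0.3, m, seed = 30)
  f0 <- construct_abundance(pop, m); f0 <- f0 / sum(f0)
  drift <- replicate(5, {
    v <- simulate_arm(pop, sc, "vehicle", seed = sample.int(1e6, 1))
    fa <- construct_abundance(v, m)
    fa / sum(fa)
  })
  expect_lt(max(abs(rowMeans(drift) - f0)), 0.02)
})
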