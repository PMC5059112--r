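# Demultiplexing and barcode counting.

demux_fixture <- function(n = 6) {
  m <- tiny_manifest(n)
  layout <- read_layout()
  sheet <- data.frame(sample_id = c("s1", "s2"),
                      index_seq = assign_indices(2, min_hamming = 3L,
                                                 seed = 3),
                      stringsAsFactors = FALSE)
  list(m = m, layout = layout, sheet = sheet,
       bc = setNames(as.data.frame(m)$barcode,
                     as.data.frame(m)$construct_id))
}

test_that("parse_read slices and assigns the documented layout", {
  fx <- demux_fixture()
  r <- make_read(fx$bc[["ACT01"]], fx$sheet$index_seq[1], fx$layout)
  out <- parse_read(r, fx$layout, fx$sheet, fx$m)
  expect_equal(out$sample_id, "s1")
  expect_equal(out$construct_id, "ACT01")

  # two linker substitutions over a tolerance of one -> bad_linker
  # (linker starts "TA...", so writing "CC" changes exactly two bases)
  r2 <- r
  substr(r2, 5, 6) <- "CC"
  out2 <- parse_read(r2, fx$layout, fx$sheet, fx$m, max_linker_mm = 1L)
  expect_equal(out2$reject, "bad_linker")
  # but tolerated at the default of two
  out2b <- parse_read(r2, fx$layout, fx$sheet, fx$m)
  expect_equal(out2b$construct_id, "ACT01")

  # short read -> bad_length; long read truncated then parsed
  expect_equal(parse_read(substr(r, 1, 26), fx$layout, fx$sheet, fx$m)$reject,
               "bad_length")
  expect_equal(parse_read(paste0(r, "GGGG"), fx$layout, fx$sheet,
                          fx$m)$construct_id, "ACT01")

  # unknown index -> bad_index; unknown barcode -> bad_barcode
  bad_idx <- paste0(substr(r, 1, 21), "NNNNNN")
  expect_equal(parse_read(bad_idx, fx$layout, fx$sheet, fx$m)$reject,
               "bad_index")
  absent <- setdiff(pathscreen:::all_kmers(4L), unname(fx$bc))[1]
  r3 <- make_read(absent, fx$sheet$index_seq[2], fx$layout)
  out3 <- parse_read(r3, fx$layout, fx$sheet, fx$m)
  expect_equal(out3$reject, "bad_barcode")
  expect_equal(out3$sample_id, "s2")
})

test_that("index mismatch tolerance recovers all single errors at distance >= 3", {
  fx <- demux_fixture()
  r <- make_read(fx$bc[["ACT02"]], fx$sheet$index_seq[2], fx$layout)
  # exhaustive single-substitution enumeration over the index region
  for (pos in 22:27) {
    for (nt in c("A", "C", "G", "T")) {
      if (substr(r, pos, pos) == nt) next
      rr <- r
      substr(rr, pos, pos) <- nt
      # default exact matching rejects ...
      expect_equal(parse_read(rr, fx$layout, fx$sheet, fx$m)$reject,
                   "bad_index")
      # ... one allowed mismatch recovers the sample uniquely
      out <- parse_read(rr, fx$layout, fx$sheet, fx$m, max_index_mm = 1L)
      expect_equal(out$sample_id, "s2")
      expect_equal(out$construct_id, "ACT02")
    }
  }
})

test_that("tied index matches are rejected as bad_index", {
  fx <- demux_fixture()
  sheet <- data.frame(sample_id = c("x", "y"),
                      index_seq = c("AAAAAA", "AAAATT"))
  # one mismatch from both indices
  r <- make_read(fx$bc[["ACT01"]], "AAAAAT", fx$layout)
  out <- parse_read(r, fx$layout, sheet, fx$m, max_index_mm = 1L)
  expect_equal(out$reject, "bad_index")
})

test_that("count_barcodes conserves reads and matches per-read parsing", {
  fx <- demux_fixture()
  set.seed(42)
  n_ok <- 300
  cids <- sample(names(fx$bc), n_ok, replace = TRUE)
  sids <- sample(1:2, n_ok, replace = TRUE)
  seqs <- make_read(fx$bc[cids], fx$sheet$index_seq[sids], fx$layout)
  # adulterate: 10 short, 10 bad barcode, 10 unknown index
  seqs <- c(seqs, substr(seqs[1:10], 1, 20),
            make_read(rep("NNNN", 10), fx$sheet$index_seq[1], fx$layout),
            make_read(fx$bc[["ACT01"]], rep("NNNNNN", 10), fx$layout))
  ct <- count_barcodes(seqs, fx$layout, fx$sheet, fx$m)
  expect_equal(ct$total_reads, length(seqs))
  expect_equal(sum(ct$counts) + sum(ct$unassigned$count), length(seqs))
  expect_equal(sum(ct$counts), n_ok)
  expect_equal(unname(ct$counts["ACT01", "s1"]),
               sum(cids == "ACT01" & sids == 1))
  reasons <- tapply(ct$unassigned$count, ct$unassigned$reason, sum)
  expect_equal(as.numeric(reasons[c("bad_length", "bad_barcode",
                                    "bad_index")]),
               c(10, 10, 10))
  # bad_index / bad_length tallies land under unknown_index
  expect_true(all(ct$unassigned$sample[ct$unassigned$reason %in%
                    c("bad_index", "bad_length")] == "unknown_index"))

  # permuting read order never changes the table
  ct2 <- count_barcodes(sample(seqs), fx$layout, fx$sheet, fx$m)
  expect_identical(ct$counts, ct2$counts)
})

test_that("count_barcodes equals the naive substring-matching oracle", {
  fx <- demux_fixture(8)
  m <- fx$m
  sc <- tiny_scenario(read_depth = 2500L, error_rate = 0.02, days = 2L)
  pop <- simulate_infection(8000L, 0.3, m, seed = 17)
  seqs <- c(simulate_sequencing(pop, fx$sheet$index_seq[1], fx$layout, m,
                                2500L, 0.02, seed = 18, sample_id = "s1"),
            simulate_sequencing(pop, fx$sheet$index_seq[2], fx$layout, m,
                                2500L, 0.02, seed = 19, sample_id = "s2"))
  ct <- count_barcodes(unname(seqs), fx$layout, fx$sheet, m)
  oracle <- naive_count_oracle(unname(seqs), fx$layout, fx$sheet, m)
  expect_identical(unclass(ct$counts), unclass(oracle))
  expect_equal(sum(ct$counts) + sum(ct$unassigned$count), 5000)
})

test_that("FASTQ streaming: files, gzip, chunk boundaries, empty input", {
  fx <- demux_fixture()
  seqs <- make_read(fx$bc[c("ACT01", "ACT02", "ACT03")],
                    fx$sheet$index_seq[c(1, 2, 1)], fx$layout)
  names(seqs) <- paste0("r", 1:3)
  plain <- withr::local_tempfile(fileext = ".fastq")
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(seqs, plain)
  write_fastq(seqs, gz)
  ct_mem <- count_barcodes(unname(seqs), fx$layout, fx$sheet, fx$m)
  ct_pl <- count_barcodes(plain, fx$layout, fx$sheet, fx$m)
  ct_gz <- count_barcodes(gz, fx$layout, fx$sheet, fx$m)
  # tiny chunks exercise the streaming path across record boundaries
  ct_ch <- count_barcodes(plain, fx$layout, fx$sheet, fx$m, chunk_size = 2L)
  expect_identical(ct_pl$counts, ct_mem$counts)
  expect_identical(ct_gz$counts, ct_mem$counts)
  expect_identical(ct_ch$counts, ct_mem$counts)
  # multiple files accumulate
  ct_two <- count_barcodes(c(plain, plain), fx$layout, fx$sheet, fx$m)
  expect_equal(ct_two$total_reads, 6)

  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  ct_e <- count_barcodes(empty, fx$layout, fx$sheet, fx$m)
  expect_equal(ct_e$total_reads, 0)
  expect_true(all(ct_e$counts == 0))

  expect_error(count_barcodes("no_such.fastq", fx$layout, fx$sheet, fx$m),
               "not found")
})

test_that("malformed FASTQ errors name the offending record", {
  fx <- demux_fixture()
  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
  expect_error(count_barcodes(bad, fx$layout, fx$sheet, fx$m),
               "truncated record")
  bad2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("r1", "ACGT", "+", "IIII"), bad2)
  expect_error(count_barcodes(bad2, fx$layout, fx$sheet, fx$m),
               "record 1")
})

test_that("count tables round-trip through write_counts/read_counts", {
  fx <- demux_fixture()
  seqs <- c(make_read(fx$bc[c("ACT01", "ACT01", "ACT04")],
                      fx$sheet$index_seq[c(1, 1, 2)], fx$layout),
            "TTTT")  # bad_length
  ct <- count_barcodes(seqs, fx$layout, fx$sheet, fx$m)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_counts(ct, tmp)
  expect_true(file.exists(paste0(tmp, ".qc.json")))
  ct2 <- read_counts(tmp)
  expect_equal(unclass(ct2$counts), unclass(ct$counts))
  expect_equal(sum(ct2$unassigned$count), sum(ct$unassigned$count))
  expect_equal(ct2$total_reads, ct$total_reads)
})
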