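# Streaming FASTQ demultiplexing and barcode counting against the fixed
# 27-nt read layout. Rejections are data, not errors: every read is either
# assigned to a (sample, construct) pair or tallied under a rejection
# reason, and assigned + rejected always equals the number of input reads.

REJECT_REASONS <- c("bad_length", "bad_index", "bad_linker", "bad_barcode")

#' Parse a single read against the fixed layout
#'
#' Slices the read as barcode [0,4), linker [4,21), index [21,27) (0-based,
#' half-open). The index must match one sample-sheet index uniquely within
#' `max_index_mm` mismatches (ties reject as `bad_index`); the linker must
#' be within `max_linker_mm` of the layout's constant; the barcode must
#' match a manifest barcode exactly (4-nt barcodes at pairwise distance 2
#' cannot support error correction). Reads longer than 27 nt are truncated
#' to 27; shorter reads are rejected `bad_length`.
#'
#' @param seq one read sequence.
#' @param layout a [read_layout()].
#' @param samplesheet data.frame with `sample_id` and `index_seq`.
#' @param manifest the library manifest.
#' @param max_linker_mm maximum linker mismatches tolerated (default 2).
#' @param max_index_mm maximum index mismatches tolerated (default 0).
#' @return a list: either `list(sample_id =, construct_id =)` or
#'   `list(reject = reason, sample_id = <NA or sample>)`.
#' @export
parse_read <- function(seq, layout, samplesheet, manifest,
                       max_linker_mm = 2L, max_index_mm = 0L) {
  res <- .parse_reads(seq, layout, samplesheet, manifest, max_linker_mm,
                      max_index_mm)
  if (is.na(res$reject[1L])) {
    list(sample_id = res$sample_id[1L], construct_id = res$construct_id[1L])
  } else {
    list(reject = res$reject[1L],
         sample_id = res$sample_id[1L])
  }
}

# Vectorised parser over a batch of reads. Returns a data.frame with
# sample_id, construct_id, reject (NA when assigned). Matching is done on
# the unique barcode/linker/index strings in the batch, so cost scales with
# distinct error patterns rather than reads.
.parse_reads <- function(seqs, layout, samplesheet, manifest,
                         max_linker_mm = 2L, max_index_mm = 0L) {
  n <- length(seqs)
  sample_id <- rep(NA_character_, n)
  construct_id <- rep(NA_character_, n)
  reject <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(sample_id, construct_id, reject,
                      stringsAsFactors = FALSE))
  }
  len <- nchar(seqs)
  short <- len < layout$total_len
  reject[short] <- "bad_length"
  ok <- !short
  seqs[ok] <- substr(seqs[ok], 1L, layout$total_len)

  bc_end <- layout$barcode_len
  lk_end <- layout$barcode_len + nchar(layout$linker_seq)
  barcode <- substr(seqs, 1L, bc_end)
  linker <- substr(seqs, bc_end + 1L, lk_end)
  index <- substr(seqs, lk_end + 1L, layout$total_len)

  # index -> sample, unique best match within max_index_mm
  sheet_idx <- samplesheet$index_seq
  u_index <- unique(index[ok])
  if (max_index_mm <= 0L) {
    u_match <- match(u_index, sheet_idx)
  } else {
    dmat <- vapply(sheet_idx, function(si) .mismatches_to(u_index, si),
                   integer(length(u_index)))
    dmat <- matrix(dmat, nrow = length(u_index))
    u_match <- apply(dmat, 1L, function(d) {
      best <- min(d)
      if (best > max_index_mm || sum(d == best) > 1L) NA_integer_
      else which.min(d)
    })
  }
  idx_of <- u_match[match(index, u_index)]
  sample_id[ok] <- samplesheet$sample_id[idx_of[ok]]
  bad_idx <- ok & is.na(sample_id)
  reject[bad_idx] <- "bad_index"
  ok <- ok & !bad_idx

  # linker within max_linker_mm of the constant
  u_linker <- unique(linker[ok])
  u_lmm <- .mismatches_to(u_linker, layout$linker_seq)
  lmm <- u_lmm[match(linker, u_linker)]
  bad_lk <- ok & lmm > max_linker_mm
  reject[bad_lk] <- "bad_linker"
  ok <- ok & !bad_lk

  # barcode exact
  bc_match <- match(barcode, as.data.frame(manifest)$barcode)
  construct_id[ok] <- as.data.frame(manifest)$construct_id[bc_match[ok]]
  bad_bc <- ok & is.na(construct_id)
  reject[bad_bc] <- "bad_barcode"

  construct_id[!is.na(reject)] <- NA_character_
  data.frame(sample_id, construct_id, reject, stringsAsFactors = FALSE)
}

new_count_table <- function(counts, unassigned, total_reads) {
  structure(list(counts = counts, unassigned = unassigned,
                 total_reads = total_reads),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d constructs x %d samples, %g reads (%g assigned, %g rejected)\n",
              nrow(x$counts), ncol(x$counts), x$total_reads,
              sum(x$counts), sum(x$unassigned$count)))
  invisible(x)
}

#' Count barcode reads into a per-sample, per-construct table
#'
#' Streams FASTQ files (plain or gzip) in fixed-size chunks — memory is
#' independent of file size — and tallies [parse_read()] assignments.
#' Conservation holds by construction: assigned plus rejected reads equal
#' the number of input records.
#'
#' @param fastq a character vector of FASTQ paths, or a (possibly named)
#'   list/vector of read sequences for in-memory counting.
#' @param layout a [read_layout()].
#' @param samplesheet data.frame with `sample_id` and `index_seq`.
#' @param manifest the library manifest.
#' @param max_linker_mm,max_index_mm mismatch tolerances (defaults 2 and 0).
#' @param chunk_size reads per streamed chunk.
#' @return a `count_table`: `counts` (constructs x samples integer matrix),
#'   `unassigned` (data.frame sample, reason, count — reads whose index
#'   could not be resolved are tallied under `"unknown_index"`), and
#'   `total_reads`.
#' @export
count_barcodes <- function(fastq, layout, samplesheet, manifest,
                           max_linker_mm = 2L, max_index_mm = 0L,
                           chunk_size = 100000L) {
  ids <- as.data.frame(manifest)$construct_id
  samples <- samplesheet$sample_id
  counts <- matrix(0L, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
  un_keys <- c(samples, "unknown_index")
  unassigned <- matrix(0, nrow = length(un_keys),
                       ncol = length(REJECT_REASONS),
                       dimnames = list(un_keys, REJECT_REASONS))
  total_reads <- 0

  tally <- function(seqs) {
    res <- .parse_reads(seqs, layout, samplesheet, manifest,
                        max_linker_mm, max_index_mm)
    total_reads <<- total_reads + nrow(res)
    asg <- is.na(res$reject)
    if (any(asg)) {
      tab <- table(factor(res$construct_id[asg], levels = ids),
                   factor(res$sample_id[asg], levels = samples))
      counts <<- counts + as.matrix(unclass(tab))
    }
    if (any(!asg)) {
      key <- ifelse(is.na(res$sample_id[!asg]), "unknown_index",
                    res$sample_id[!asg])
      tab <- table(factor(key, levels = un_keys),
                   factor(res$reject[!asg], levels = REJECT_REASONS))
      unassigned <<- unassigned + as.matrix(unclass(tab))
    }
  }

  looks_like_path <- is.character(fastq) && length(fastq) > 0 &&
    all(grepl("\\.(fastq|fq)(\\.gz)?$", fastq))
  if (looks_like_path && !all(file.exists(fastq))) {
    stop("FASTQ file not found: ",
         paste(fastq[!file.exists(fastq)], collapse = ", "), call. = FALSE)
  }
  if (looks_like_path) {
    for (path in fastq) {
      con <- if (grepl("\\.gz$", path)) gzfile(path, "rt")
             else file(path, "rt")
      record_no <- 0L
      repeat {
        lines <- readLines(con, n = 4L * chunk_size)
        if (length(lines) == 0L) break
        if (length(lines) %% 4L != 0L) {
          close(con)
          stop(sprintf(
            "malformed FASTQ %s: truncated record %d",
            path, record_no + length(lines) %/% 4L + 1L), call. = FALSE)
        }
        heads <- lines[seq(1L, length(lines), by = 4L)]
        if (any(!startsWith(heads, "@"))) {
          bad <- which(!startsWith(heads, "@"))[1L]
          close(con)
          stop(sprintf("malformed FASTQ %s: record %d does not start with '@'",
                       path, record_no + bad), call. = FALSE)
        }
        tally(lines[seq(2L, length(lines), by = 4L)])
        record_no <- record_no + length(lines) %/% 4L
      }
      close(con)
    }
  } else {
    # in-memory sequences (one vector or a list of vectors)
    seqs <- unlist(fastq, use.names = FALSE)
    if (is.null(seqs)) seqs <- character(0)
    start <- 1L
    while (start <= length(seqs)) {
      end <- min(start + chunk_size - 1L, length(seqs))
      tally(seqs[start:end])
      start <- end + 1L
    }
  }

  un_df <- data.frame(
    sample = rep(rownames(unassigned), ncol(unassigned)),
    reason = rep(colnames(unassigned), each = nrow(unassigned)),
    count = as.vector(unassigned), stringsAsFactors = FALSE)
  un_df <- un_df[un_df$count > 0, , drop = FALSE]
  rownames(un_df) <- NULL
  new_count_table(counts, un_df, total_reads)
}

#' Write a count table (TSV + QC JSON)
#'
#' @param ct a `count_table`.
#' @param path output TSV path (constructs x samples; an `unassigned` block
#'   of rejection tallies is appended below the construct rows). A QC JSON
#'   sidecar `<path>.qc.json` records per-sample totals and the rejection
#'   breakdown.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ct, path) {
  df <- data.frame(construct_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(ct$unassigned)) {
    un <- ct$unassigned
    block <- data.frame(construct_id = paste0("__unassigned:", un$reason,
                                              ":", un$sample),
                        stringsAsFactors = FALSE)
    for (s in colnames(ct$counts)) block[[s]] <- 0
    # the owning sample is encoded in the row id; park the tally in the
    # first data column so the row sums recover it on read-back
    if (ncol(ct$counts) > 0) block[[colnames(ct$counts)[1L]]] <- un$count
    utils::write.table(block, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
  }
  qc <- list(total_reads = ct$total_reads,
             assigned = sum(ct$counts),
             per_sample_assigned = as.list(colSums(ct$counts)),
             rejections = if (nrow(ct$unassigned)) ct$unassigned else
               data.frame(sample = character(0), reason = character(0),
                          count = numeric(0)))
  jsonlite::write_json(qc, paste0(path, ".qc.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a count table written by [write_counts()]
#'
#' @param path the TSV path.
#' @return a `count_table` (the QC sidecar is not required).
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = NULL,
                          quote = "")
  is_un <- startsWith(df$construct_id, "__unassigned:")
  un_rows <- df[is_un, , drop = FALSE]
  df <- df[!is_un, , drop = FALSE]
  counts <- as.matrix(df[, -1, drop = FALSE])
  mode(counts) <- "integer"
  rownames(counts) <- df$construct_id
  unassigned <- data.frame(sample = character(0), reason = character(0),
                           count = numeric(0))
  if (nrow(un_rows)) {
    parts <- strsplit(sub("^__unassigned:", "", un_rows$construct_id), ":",
                      fixed = TRUE)
    unassigned <- data.frame(
      sample = vapply(parts, function(p) paste(p[-1], collapse = ":"),
                      character(1)),
      reason = vapply(parts, `[[`, character(1), 1L),
      count = rowSums(as.matrix(un_rows[, -1, drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  new_count_table(counts, unassigned, sum(counts) + sum(unassigned$count))
}
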