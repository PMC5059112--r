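# Fractional representation and vehicle-normalized enrichment.
#
# The read count of each construct is divided by the sample's total
# assigned reads (its fractional representation); fractions are averaged
# over technical then biological replicates; drug-arm fractions are
# divided by the vehicle reference to give per-dose enrichment ratios.

#' Fractional representation of each construct in each sample
#'
#' `f(s, c) = count(s, c) / sum_c' count(s, c')`. Samples with zero
#' assigned reads are excluded (with a warning) and recorded in the
#' `excluded` attribute.
#'
#' @param ct a `count_table`, or a plain constructs x samples count matrix.
#' @return a `fraction_table`: constructs x samples matrix of fractions,
#'   each retained column summing to 1.
#' @export
fractional_representation <- function(ct) {
  counts <- if (inherits(ct, "count_table")) ct$counts else as.matrix(ct)
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning("excluding zero-read sample(s): ",
            paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  f <- sweep(counts[, !zero, drop = FALSE], 2L, totals[!zero], `/`)
  structure(f, class = c("fraction_table", class(f)),
            excluded = colnames(counts)[zero])
}

#' Average fractions over technical then biological replicates
#'
#' Arithmetic mean over technical replicates within each biological
#' replicate, then over biological replicates — in that fixed order. A
#' geometric-mean variant is available behind `geometric = TRUE`.
#'
#' @param f a `fraction_table` (columns are sample_ids).
#' @param samplesheet data.frame with sample_id, arm, dose_label, tech_rep,
#'   bio_rep.
#' @param geometric use geometric instead of arithmetic means.
#' @return a `fraction_table` whose columns are replicate groups keyed
#'   `"<arm>:<dose_label>"`.
#' @export
average_replicates <- function(f, samplesheet, geometric = FALSE) {
  sheet <- samplesheet[samplesheet$sample_id %in% colnames(f), , drop = FALSE]
  if (nrow(sheet) == 0L) {
    stop("configuration error: no sample-sheet rows match the fraction table",
         call. = FALSE)
  }
  mean_fun <- if (geometric) function(m) exp(rowMeans(log(m)))
              else rowMeans
  group <- paste(sheet$arm, sheet$dose_label, sep = ":")
  cols <- lapply(split(seq_len(nrow(sheet)), group), function(rows) {
    sub <- sheet[rows, , drop = FALSE]
    # technical first ...
    bio_means <- vapply(split(sub$sample_id, sub$bio_rep), function(sids) {
      mean_fun(f[, sids, drop = FALSE])
    }, numeric(nrow(f)))
    # ... then biological
    mean_fun(matrix(bio_means, nrow = nrow(f)))
  })
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(f)
  structure(out, class = c("fraction_table", class(out)),
            excluded = attr(f, "excluded"))
}

#' Normalize drug-arm fractions to the vehicle reference
#'
#' `e(d, c) = (f_drug(d, c) + alpha) / (f_vehicle(c) + alpha)`: the
#' pseudocount is applied symmetrically so vehicle-vs-itself is exactly 1,
#' and keeps ratios finite when a construct drops out of an arm.
#'
#' @param f_drug constructs x doses matrix of drug-arm fractions.
#' @param f_vehicle named vector (or 1-column matrix) of vehicle-reference
#'   fractions over the same constructs.
#' @param alpha pseudocount on the fraction scale (default 1e-6, small
#'   relative to the ~1/39 abundance of any library member).
#' @return an `enrichment_table`: constructs x doses matrix of ratios, with
#'   the pseudocount recorded in the `alpha` attribute.
#' @export
normalize_to_vehicle <- function(f_drug, f_vehicle, alpha = 1e-6) {
  f_drug <- as.matrix(f_drug)
  f_vehicle <- drop(as.matrix(f_vehicle))
  if (!setequal(rownames(f_drug), names(f_vehicle))) {
    only <- c(setdiff(rownames(f_drug), names(f_vehicle)),
              setdiff(names(f_vehicle), rownames(f_drug)))
    stop("schema error: constructs present in only one table: ",
         paste(only, collapse = ", "), call. = FALSE)
  }
  f_vehicle <- f_vehicle[rownames(f_drug)]
  e <- sweep(f_drug + alpha, 1L, f_vehicle + alpha, `/`)
  structure(e, class = c("enrichment_table", class(e)), alpha = alpha)
}

#' Squared Pearson correlation between two replicate fraction vectors
#'
#' @param fa,fb paired fractions over the same constructs (length >= 3).
#' @return r^2, or `NA` if either vector has zero variance.
#' @export
replicate_concordance <- function(fa, fb) {
  if (length(fa) != length(fb) || length(fa) < 3L) {
    stop("replicate_concordance() needs >= 3 paired fractions",
         call. = FALSE)
  }
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) return(NA_real_)
  stats::cor(fa, fb)^2
}

#' Full enrichment chain: counts to per-dose enrichment ratios
#'
#' Fractional representation, replicate averaging (technical then
#' biological), pooling of all vehicle wells into a single averaged vehicle
#' reference, and vehicle normalization. t0 samples, if present, are
#' ignored.
#'
#' @param ct a `count_table`.
#' @param samplesheet the screen's sample sheet.
#' @param alpha pseudocount for [normalize_to_vehicle()].
#' @param geometric passed to [average_replicates()].
#' @return an `enrichment_table` (constructs x dose labels), with the
#'   averaged fraction tables in attributes `f_drug` and `f_vehicle`.
#' @export
compute_enrichment <- function(ct, samplesheet, alpha = 1e-6,
                               geometric = FALSE) {
  f <- fractional_representation(ct)
  sheet <- samplesheet[samplesheet$arm %in% c("drug", "vehicle"), ,
                       drop = FALSE]
  if (!any(sheet$arm == "drug")) {
    stop("configuration error: no drug arms in sample sheet", call. = FALSE)
  }
  if (!any(sheet$arm == "vehicle")) {
    stop("configuration error: no vehicle arms in sample sheet",
         call. = FALSE)
  }
  avg <- average_replicates(f, sheet, geometric = geometric)
  is_veh <- startsWith(colnames(avg), "vehicle:")
  f_vehicle <- rowMeans(avg[, is_veh, drop = FALSE])
  f_drug <- avg[, !is_veh, drop = FALSE]
  colnames(f_drug) <- sub("^drug:", "", colnames(f_drug))
  e <- normalize_to_vehicle(f_drug, f_vehicle, alpha = alpha)
  attr(e, "f_drug") <- f_drug
  attr(e, "f_vehicle") <- f_vehicle
  e
}

#' Write an enrichment table with its JSON sidecar
#'
#' @param e an `enrichment_table`.
#' @param path output TSV (constructs x doses). A sidecar
#'   `<path>.meta.json` records the pseudocount and averaging order.
#' @param excluded samples excluded upstream, recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(e, path, excluded = character(0)) {
  df <- data.frame(construct_id = rownames(e), unclass(e),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(alpha = attr(e, "alpha"),
               averaging = "technical then biological arithmetic mean",
               excluded_samples = excluded)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
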