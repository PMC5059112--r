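# Pathway-level hit calling: a pathway scores when at least one of its
# activating constructs is enriched more than 50% above the
# negative-control baseline at two or more drug concentrations.

#' Per-dose negative-control baseline
#'
#' Arithmetic mean of the vehicle-normalized enrichment of the
#' negative-control constructs (by default HcRed and luciferase; the
#' MEK1-DD spike-in is flagged positive_control and excluded).
#'
#' @param e an `enrichment_table` (constructs x doses).
#' @param manifest the library manifest.
#' @param control_ids override the control set (defaults to all
#'   `negative_control` records).
#' @return named numeric vector of per-dose baselines (strictly positive).
#' @export
control_baseline <- function(e, manifest, control_ids = NULL) {
  if (is.null(control_ids)) {
    control_ids <- manifest_controls(manifest, "negative_control")
  }
  control_ids <- intersect(control_ids, rownames(e))
  if (length(control_ids) == 0L) {
    stop("configuration error: no negative-control constructs available ",
         "for the baseline", call. = FALSE)
  }
  b <- colMeans(e[control_ids, , drop = FALSE])
  if (any(b <= 0)) {
    stop("control baseline must be strictly positive", call. = FALSE)
  }
  b
}

#' Enrichment relative to the control baseline
#'
#' @param e an `enrichment_table`.
#' @param baseline per-dose baseline from [control_baseline()].
#' @return constructs x doses matrix of `e(d, c) / baseline(d)`.
#' @export
relative_enrichment <- function(e, baseline) {
  if (!all(colnames(e) %in% names(baseline))) {
    stop("baseline is missing dose(s): ",
         paste(setdiff(colnames(e), names(baseline)), collapse = ", "),
         call. = FALSE)
  }
  sweep(unclass(e), 2L, baseline[colnames(e)], `/`)
}

#' Call pathway-level resistance hits
#'
#' A construct supports its pathway when its relative enrichment exceeds
#' `threshold` (strictly) at `min_doses` or more doses — by default more
#' than 50% above controls at two or more drug concentrations, the level at
#' which screen hits were found to validate reliably in follow-up
#' dose-response assays. A pathway is called when at least one of its
#' activating constructs supports it. Control constructs never support
#' hits. Missing (NA) relative enrichment fails that dose.
#'
#' @param rel constructs x doses relative-enrichment matrix.
#' @param manifest the library manifest (pathway membership and roles).
#' @param threshold relative-enrichment cutoff (default 1.5, i.e. >50%
#'   above controls; strict inequality).
#' @param min_doses minimum number of passing doses per construct
#'   (default 2).
#' @param per_construct if `TRUE` (default) the same construct must pass at
#'   `min_doses` doses; if `FALSE`, doses passed by any construct of the
#'   pathway are pooled (sensitivity-analysis variant).
#' @return a `hit_report` data.frame: pathway, called, supporting_constructs
#'   (comma-separated), n_doses_passed, max_relative_enrichment; the
#'   per-construct pass matrix and parameters are carried as attributes.
#' @export
call_hits <- function(rel, manifest, threshold = 1.5, min_doses = 2L,
                      per_construct = TRUE) {
  if (min_doses > ncol(rel)) {
    stop(sprintf(
      "configuration error: min_doses = %d but only %d dose(s) present",
      min_doses, ncol(rel)), call. = FALSE)
  }
  df <- as.data.frame(manifest)
  act <- df[df$role == "pathway_activator", , drop = FALSE]
  act <- act[act$construct_id %in% rownames(rel), , drop = FALSE]
  rel_act <- rel[act$construct_id, , drop = FALSE]
  pass <- !is.na(rel_act) & rel_act > threshold
  n_pass <- rowSums(pass)

  pathways <- unique(act$pathway)
  rows <- lapply(pathways, function(pw) {
    members <- act$construct_id[act$pathway == pw]
    if (per_construct) {
      supporting <- members[n_pass[members] >= min_doses]
      called <- length(supporting) > 0L
      doses_passed <- if (called) max(n_pass[supporting]) else
        max(n_pass[members])
    } else {
      pooled <- colSums(pass[members, , drop = FALSE]) > 0L
      called <- sum(pooled) >= min_doses
      supporting <- members[n_pass[members] > 0L]
      if (!called) supporting <- character(0)
      doses_passed <- sum(pooled)
    }
    data.frame(
      pathway = pw, called = called,
      supporting_constructs = paste(supporting, collapse = ","),
      n_doses_passed = doses_passed,
      max_relative_enrichment = max(rel_act[members, , drop = FALSE],
                                    na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report <- report[order(-report$called, -report$max_relative_enrichment), ]
  rownames(report) <- NULL
  structure(report, class = c("hit_report", "data.frame"),
            threshold = threshold, min_doses = min_doses,
            per_construct = per_construct, pass_matrix = pass,
            relative_enrichment = rel_act)
}

#' Pathways called as hits
#' @param report a `hit_report`.
#' @return character vector of called pathway names.
#' @export
hit_pathways <- function(report) report$pathway[report$called]

#' @export
print.hit_report <- function(x, ...) {
  n_hit <- sum(x$called)
  cat(sprintf("<hit_report> %d/%d pathways called (threshold %.2f, >= %d doses)\n",
              n_hit, nrow(x), attr(x, "threshold"), attr(x, "min_doses")))
  if (n_hit > 0) {
    hits <- as.data.frame(x)[x$called, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      cat(sprintf("  %-28s via %s (max rel. enrichment %.2f)\n",
                  hits$pathway[i], hits$supporting_constructs[i],
                  hits$max_relative_enrichment[i]))
    }
  }
  invisible(x)
}

#' Plot relative enrichment by construct and dose
#'
#' Grouped bar chart of relative enrichment (constructs on the x axis, one
#' bar per dose), with the hit threshold drawn as a horizontal line — the
#' conventional display of a pathway-activation screen readout.
#'
#' @param x a `hit_report`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix that was plotted.
#' @export
plot.hit_report <- function(x, ...) {
  rel <- attr(x, "relative_enrichment")
  ord <- order(-apply(rel, 1L, max))
  m <- t(rel[ord, , drop = FALSE])
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = rownames(m),
                    ylab = "enrichment relative to controls",
                    cex.names = 0.6, ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2)
  invisible(m)
}

#' Write a hit report (TSV + markdown summary)
#'
#' @param report a `hit_report`.
#' @param path output TSV path; a human-readable `<path>.md` summary and a
#'   per-dose relative-enrichment table `<path>.rel.tsv` are written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_hits <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rel <- attr(report, "relative_enrichment")
  rel_df <- data.frame(construct_id = rownames(rel), rel,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(rel_df, paste0(path, ".rel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- c("# Pathway hit report", "",
          sprintf("Threshold: relative enrichment > %.2f at >= %d doses",
                  attr(report, "threshold"), attr(report, "min_doses")), "",
          sprintf("Called pathways: %s",
                  if (any(report$called))
                    paste(hit_pathways(report), collapse = ", ")
                  else "none"), "",
          "| pathway | called | supporting constructs | max rel. enrichment |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %s | %.3f |", report$pathway,
                  ifelse(report$called, "yes", "no"),
                  ifelse(nzchar(report$supporting_constructs),
                         report$supporting_constructs, "-"),
                  report$max_relative_enrichment))
  writeLines(md, paste0(path, ".md"))
  invisible(path)
}
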