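# The library manifest: one row per barcoded construct, mapping construct ->
# signaling pathway -> 4-nt barcode, with the activation strategy and the
# functional-validation assay carried as annotations. The packaged default
# reproduces the published 36-construct / 17-pathway pathway-activation
# library plus three control constructs (HcRed and luciferase as inert
# negative controls; a MEK1-DD spike-in flagged as positive control).

MANIFEST_COLUMNS <- c("construct_id", "pathway", "protein",
                      "activation_strategy", "variant_note",
                      "validation_assay", "barcode", "role")

MANIFEST_ROLES <- c("pathway_activator", "negative_control",
                    "positive_control")

new_manifest <- function(df, version = "unversioned") {
  rownames(df) <- NULL
  structure(df, class = c("pathscreen_manifest", "data.frame"),
            version = version)
}

#' Validate a library manifest
#'
#' Checks the structural invariants every manifest must satisfy: documented
#' columns, unique construct ids, 4-nt A/C/G/T barcodes, pairwise-distinct
#' barcodes at Hamming distance >= 2, known roles, and a non-empty pathway
#' for every pathway-activating construct.
#'
#' @param m a `pathscreen_manifest`.
#' @param require_barcodes if `FALSE`, empty barcodes are tolerated (a
#'   manifest awaiting [assign_barcodes()]).
#' @param min_hamming minimum pairwise barcode distance enforced.
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_manifest <- function(m, require_barcodes = TRUE, min_hamming = 2L) {
  df <- as.data.frame(m)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$construct_id)) {
    dup <- unique(df$construct_id[duplicated(df$construct_id)])
    stop("duplicate construct_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(df$role), MANIFEST_ROLES)
  if (length(bad_role)) {
    stop("unknown role value(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  act <- df[df$role == "pathway_activator", , drop = FALSE]
  if (any(is.na(act$pathway) | !nzchar(act$pathway))) {
    stop("pathway must be non-empty for pathway_activator records",
         call. = FALSE)
  }
  bc <- df$barcode
  has_bc <- !is.na(bc) & nzchar(bc)
  if (require_barcodes && !all(has_bc)) {
    stop("manifest has records without barcodes; run assign_barcodes()",
         call. = FALSE)
  }
  bc <- bc[has_bc]
  if (length(bc)) {
    if (any(nchar(bc) != 4L) || any(grepl("[^ACGT]", bc))) {
      bad <- bc[nchar(bc) != 4L | grepl("[^ACGT]", bc)]
      stop("barcodes must be 4 nt over A/C/G/T; offending: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(bc)) {
      dup <- unique(bc[duplicated(bc)])
      ids <- df$construct_id[has_bc][bc %in% dup]
      stop("duplicate barcode(s) ", paste(dup, collapse = ", "),
           " shared by constructs: ", paste(ids, collapse = ", "),
           call. = FALSE)
    }
    if (length(bc) > 1L) {
      mat <- matrix(unlist(strsplit(bc, "", fixed = TRUE)), nrow = 4L)
      for (i in seq_len(length(bc) - 1L)) {
        d <- colSums(mat[, (i + 1L):length(bc), drop = FALSE] != mat[, i])
        if (any(d < min_hamming)) {
          j <- i + which(d < min_hamming)[1L]
          stop(sprintf(
            "barcodes %s (%s) and %s (%s) are at Hamming distance %d < %d",
            bc[i], df$construct_id[has_bc][i], bc[j],
            df$construct_id[has_bc][j], d[which(d < min_hamming)[1L]],
            min_hamming), call. = FALSE)
        }
      }
    }
  }
  invisible(m)
}

#' Load a library manifest from a TSV file
#'
#' The file is tab-separated with a header row naming the documented columns
#' (`construct_id`, `pathway`, `protein`, `activation_strategy`,
#' `variant_note`, `validation_assay`, `barcode`, `role`), UTF-8 encoded;
#' lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @param require_barcodes validate that all records carry barcodes.
#' @return a validated `pathscreen_manifest`.
#' @seealso [default_manifest()] for the packaged library.
#' @export
load_manifest <- function(path, require_barcodes = TRUE) {
  if (!file.exists(path)) {
    stop("manifest file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = "character", na.strings = NULL,
                      fileEncoding = "UTF-8", quote = ""),
    error = function(e) {
      stop("parse error reading manifest ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  n_fields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                  quote = "")
  if (length(unique(n_fields)) > 1L) {
    bad <- which(n_fields != n_fields[1L])[1L]
    stop(sprintf("parse error in manifest %s: line %d has %d fields, expected %d",
                 path, bad, n_fields[bad], n_fields[1L]), call. = FALSE)
  }
  m <- new_manifest(df, version = basename(path))
  validate_manifest(m, require_barcodes = require_barcodes)
  m
}

#' Write a manifest to TSV
#'
#' Inverse of [load_manifest()]: a load -> write -> load round trip
#' reproduces the manifest field for field.
#'
#' @param m a `pathscreen_manifest`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged pathway-activation library manifest
#'
#' 36 pathway-activating constructs covering 17 canonical oncogenic signaling
#' pathways, plus HcRed and luciferase negative controls and a MEK1-DD
#' positive-control spike-in (39 records in all). Barcodes are synthetic
#' (the real sequences are unpublished), generated by
#' `assign_barcodes(min_hamming = 2, seed = 0)` and frozen in the packaged
#' file.
#'
#' @return a validated `pathscreen_manifest`.
#' @export
default_manifest <- function() {
  path <- system.file("extdata", "pathway_library.tsv",
                      package = "pathscreen", mustWork = TRUE)
  load_manifest(path)
}

#' Summarize a library manifest
#'
#' @param object a `pathscreen_manifest`.
#' @param ... unused.
#' @return a list with exact tallies: `n_constructs`, `n_activators`,
#'   `n_pathways` (distinct pathways among activators), `n_validated`
#'   (records with a non-empty validation assay), `n_negative_controls`,
#'   `n_positive_controls`.
#' @export
summary.pathscreen_manifest <- function(object, ...) {
  df <- as.data.frame(object)
  act <- df[df$role == "pathway_activator", , drop = FALSE]
  out <- list(
    n_constructs = nrow(df),
    n_activators = nrow(act),
    n_pathways = length(unique(act$pathway)),
    n_validated = sum(!is.na(df$validation_assay) &
                        nzchar(df$validation_assay)),
    n_negative_controls = sum(df$role == "negative_control"),
    n_positive_controls = sum(df$role == "positive_control")
  )
  class(out) <- "summary.pathscreen_manifest"
  out
}

#' @export
print.summary.pathscreen_manifest <- function(x, ...) {
  cat("Pathway-activation library manifest\n")
  cat(sprintf("  constructs:         %d\n", x$n_constructs))
  cat(sprintf("  pathway activators: %d across %d pathways\n",
              x$n_activators, x$n_pathways))
  cat(sprintf("  functionally validated records: %d\n", x$n_validated))
  cat(sprintf("  controls: %d negative, %d positive\n",
              x$n_negative_controls, x$n_positive_controls))
  invisible(x)
}

#' @export
print.pathscreen_manifest <- function(x, ...) {
  cat(sprintf("<pathscreen_manifest> %d constructs (version %s)\n",
              nrow(x), attr(x, "version") %||% "unversioned"))
  print.data.frame(utils::head(as.data.frame(x)[, c("construct_id", "pathway",
                                                    "barcode", "role")], 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# Construct ids by role, used for control baselines and template draws.
manifest_controls <- function(m, role = "negative_control") {
  df <- as.data.frame(m)
  df$construct_id[df$role %in% role]
}
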