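# Screen scenarios: the full parameterization of one simulated pooled
# positive-selection screen, from infection through sequencing.

#' Parameterize a simulated pooled screen
#'
#' A scenario describes one screen: how many cells are exposed to virus and
#' at what multiplicity of infection, which drug doses are run (as nominal
#' population growth-inhibition fractions), how long selection lasts, how
#' passaging bottlenecks the populations, which constructs carry planted
#' resistance effects, and how deeply each sample is sequenced.
#'
#' @param n_cells cells exposed to virus (default 5e5, one well).
#' @param moi mean lentiviral integrations per cell; integration counts are
#'   Poisson with this rate. Default 0.3, at which ~86% of transduced cells
#'   carry a single construct.
#' @param doses named numeric vector: names are dose labels, values the
#'   nominal growth-inhibition fractions in [0,1]. Default three doses
#'   spanning GI20-GI80.
#' @param days treatment duration in days (default 21, i.e. 3 weeks).
#' @param split_fraction carry-over fraction at each passage (default 0.1,
#'   a 1:10 split).
#' @param capacity cell count at which a population is passaged
#'   (default 2e5, a confluent well).
#' @param effects resistance map: a list `construct_id -> (dose label ->
#'   rho)` where rho in [0,1] multiplies the growth inhibition experienced
#'   by cells carrying that construct (rho = 1 fully sensitive, rho = 0
#'   fully resistant). Missing entries default to 1. See
#'   [planted_effects()].
#' @param baseline_growth net divisions per day of uninhibited cells
#'   (default 1).
#' @param read_depth reads sequenced per sample (default 1e5).
#' @param error_rate per-base substitution probability in sequencing
#'   (default 1e-3).
#' @param n_tech_reps technical sequencing replicates per sample (default 2:
#'   each population is amplified with two distinct index primers).
#' @param layout the [read_layout()].
#' @param seed master integer seed; every stochastic stage derives its own
#'   sub-seed from it, so arms are independently reproducible.
#' @return a validated `screen_scenario` list.
#' @export
screen_scenario <- function(n_cells = 5e5L,
                            moi = 0.3,
                            doses = c("150nM" = 0.2, "750nM" = 0.5,
                                      "1.5uM" = 0.8),
                            days = 21L,
                            split_fraction = 0.1,
                            capacity = 2e5,
                            effects = list(),
                            baseline_growth = 1,
                            read_depth = 1e5L,
                            error_rate = 1e-3,
                            n_tech_reps = 2L,
                            layout = read_layout(),
                            seed = 0L) {
  if (moi <= 0) stop("moi must be > 0", call. = FALSE)
  if (n_cells <= 0) stop("n_cells must be > 0", call. = FALSE)
  if (is.null(names(doses)) || any(!nzchar(names(doses)))) {
    stop("doses must be a named vector of GI fractions", call. = FALSE)
  }
  if (any(doses < 0 | doses > 1)) {
    stop("growth-inhibition fractions must lie in [0,1]", call. = FALSE)
  }
  if (split_fraction <= 0 || split_fraction > 1) {
    stop("split_fraction must lie in (0,1]", call. = FALSE)
  }
  if (days < 0) stop("days must be >= 0", call. = FALSE)
  if (read_depth < 0) stop("read_depth must be >= 0", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must lie in [0,1)", call. = FALSE)
  }
  for (cid in names(effects)) {
    rho <- unlist(effects[[cid]])
    if (any(rho < 0 | rho > 1)) {
      stop("resistance factors rho must lie in [0,1] (construct ", cid, ")",
           call. = FALSE)
    }
  }
  structure(list(
    n_cells = as.integer(n_cells), moi = moi, doses = doses,
    days = as.integer(days), split_fraction = split_fraction,
    capacity = capacity, effects = effects,
    baseline_growth = baseline_growth,
    read_depth = as.integer(read_depth), error_rate = error_rate,
    n_tech_reps = as.integer(n_tech_reps), layout = layout,
    seed = as.integer(seed)
  ), class = "screen_scenario")
}

#' @export
print.screen_scenario <- function(x, ...) {
  cat("<screen_scenario>\n")
  cat(sprintf("  %d cells at MOI %.2f, %d days, 1:%.0f splits at %g cells\n",
              x$n_cells, x$moi, x$days, 1 / x$split_fraction, x$capacity))
  cat(sprintf("  doses: %s\n",
              paste(sprintf("%s (GI %d%%)", names(x$doses),
                            round(100 * x$doses)), collapse = ", ")))
  cat(sprintf("  depth %d reads/sample, error rate %g, %d tech reps, seed %d\n",
              x$read_depth, x$error_rate, x$n_tech_reps, x$seed))
  n_eff <- sum(vapply(x$effects, function(e) any(unlist(e) < 1), logical(1)))
  cat(sprintf("  planted resistance effects: %d construct(s)\n", n_eff))
  invisible(x)
}

#' Build a planted-resistance effects map
#'
#' Gives each named construct the same resistance factor at every dose of
#' the scenario (or at a stated subset of doses).
#'
#' @param construct_ids constructs to make resistant.
#' @param rho resistance factor in [0,1] (0 = fully resistant).
#' @param dose_labels dose labels affected.
#' @return an effects list suitable for [screen_scenario()].
#' @export
planted_effects <- function(construct_ids, rho = 0.1,
                            dose_labels = c("150nM", "750nM", "1.5uM")) {
  stats::setNames(lapply(construct_ids, function(cid) {
    stats::setNames(as.list(rep(rho, length(dose_labels))), dose_labels)
  }), construct_ids)
}

#' Bundled screen scenario presets
#'
#' `"uacc62-mek"` encodes the design of a MEK-inhibitor screen in a
#' BRAF-mutant melanoma line: MOI 0.3, 5e5 cells, three doses labelled
#' 150 nM / 750 nM / 1.5 uM at GI 0.2 / 0.5 / 0.8, 21 days with 1:10
#' splits, and no planted effects. `"planted-5"` is the same design with
#' one construct in each of five pathways made strongly resistant
#' (rho = 0.1 at all doses): the parameter-recovery benchmark.
#'
#' @param name preset name.
#' @param seed master seed for the returned scenario.
#' @param ... overrides passed on to [screen_scenario()].
#' @return a `screen_scenario`.
#' @export
scenario_preset <- function(name = c("uacc62-mek", "planted-5"), seed = 0L,
                            ...) {
  name <- match.arg(name)
  args <- list(seed = seed, ...)
  if (name == "planted-5" && is.null(args$effects)) {
    args$effects <- planted_effects(PLANTED5_CONSTRUCTS, rho = 0.1)
  }
  do.call(screen_scenario, args)
}

# One activating construct in each of five pathways (Ras-MAPK, PI3K,
# NF-kB, Notch, estrogen receptor) -- the pathway families observed to
# drive MEK-inhibitor resistance in the melanoma screen.
PLANTED5_CONSTRUCTS <- c("KRAS_G12V", "AKT1_myr", "IKKB_EE",
                         "NOTCH1_ICD", "ESR1_Y537S")
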