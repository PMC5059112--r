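# Synthetic pooled screens with a known truth table: Poisson infection,
# positive selection under drug, passage bottlenecks, and multinomial
# sequencing of barcode reads.

# A cell population is a tally of genotypes. A genotype is the multiset of
# constructs a cell carries (singleton for most cells at low MOI), keyed as
# the construct ids joined by "+" in sorted order so that e.g. "A+B" and
# "B+A" collapse.
new_cell_population <- function(counts) {
  counts <- counts[counts > 0]
  structure(list(counts = counts), class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  total <- sum(x$counts)
  cat(sprintf("<cell_population> %g cells, %d genotypes\n",
              total, length(x$counts)))
  invisible(x)
}

#' Total cells in a population
#' @param pop a `cell_population`.
#' @return numeric cell count.
#' @export
population_size <- function(pop) sum(pop$counts)

# genotype key -> character vector of carried construct ids (with
# multiplicity: a double integrant of the same construct appears twice)
genotype_constructs <- function(keys) strsplit(keys, "+", fixed = TRUE)

#' Per-construct abundance of a population
#'
#' Counts each cell once per carried copy of a construct (a cell with two
#' integrations contributes two).
#'
#' @param pop a `cell_population`.
#' @param manifest the library manifest fixing the construct universe.
#' @return named numeric vector over `manifest` construct ids.
#' @export
construct_abundance <- function(pop, manifest) {
  ids <- as.data.frame(manifest)$construct_id
  out <- stats::setNames(numeric(length(ids)), ids)
  if (length(pop$counts) == 0L) return(out)
  parts <- genotype_constructs(names(pop$counts))
  lens <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  wt <- rep(pop$counts, lens)
  tab <- tapply(wt, flat, sum)
  out[names(tab)] <- tab
  out
}

#' Simulate lentiviral infection and puromycin selection
#'
#' Each of `n_cells` cells receives a Poisson(`moi`) number of integrations;
#' cells with zero integrations do not survive selection and are dropped.
#' Each integration carries a construct drawn uniformly from the manifest
#' (the pooled library is titered for approximately equal representation).
#'
#' @param n_cells cells exposed to virus.
#' @param moi Poisson rate of integrations per cell; must be positive.
#' @param manifest a validated library manifest.
#' @param seed integer seed; the population is deterministic given it.
#' @return a `cell_population` of surviving (transduced) cells.
#' @export
simulate_infection <- function(n_cells, moi, manifest, seed = 0L) {
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  if (moi <= 0) stop("moi must be positive", call. = FALSE)
  ids <- as.data.frame(manifest)$construct_id
  k_ids <- length(ids)
  with_seed(seed, {
    k <- stats::rpois(n_cells, moi)
    k <- k[k > 0L]
    counts <- new.env(parent = emptyenv())
    # single integrants: one multinomial tabulation
    n1 <- sum(k == 1L)
    singles <- stats::setNames(
      tabulate(sample.int(k_ids, n1, replace = TRUE), nbins = k_ids), ids)
    # double integrants: vectorised sorted pairs
    n2 <- sum(k == 2L)
    keys2 <- character(0)
    if (n2 > 0L) {
      i <- sample.int(k_ids, n2, replace = TRUE)
      j <- sample.int(k_ids, n2, replace = TRUE)
      keys2 <- paste(ids[pmin(i, j)], ids[pmax(i, j)], sep = "+")
    }
    # higher multiplets are rare at low MOI; keys are canonicalised by
    # manifest index order (locale-independent, consistent with the pairs)
    keysk <- vapply(k[k >= 3L], function(ki) {
      paste(ids[sort(sample.int(k_ids, ki, replace = TRUE))], collapse = "+")
    }, character(1))
    multi <- table(c(keys2, keysk))
    all_counts <- c(singles[singles > 0L],
                    stats::setNames(as.numeric(multi), names(multi)))
    tot <- tapply(all_counts, names(all_counts), sum)
    tot <- stats::setNames(as.numeric(tot), names(tot))
    # fix the genotype order independently of the session locale so that
    # downstream RNG consumption is reproducible everywhere
    tot <- tot[order(names(tot), method = "radix")]
    new_cell_population(tot)
  })
}

# rho (resistance factor) of each genotype at one dose: the strongest
# (minimum) factor among carried constructs; constructs absent from the
# effects map are fully sensitive (rho = 1).
genotype_rho <- function(keys, effects, dose_label) {
  if (length(keys) == 0L) return(numeric(0))
  rho_of <- function(cid) {
    e <- effects[[cid]]
    if (is.null(e)) return(1)
    r <- e[[dose_label]]
    if (is.null(r)) 1 else as.numeric(r)
  }
  vapply(genotype_constructs(keys), function(cs) {
    min(vapply(unique(cs), rho_of, numeric(1)))
  }, numeric(1))
}

#' Simulate one treatment arm
#'
#' Daily multiplicative growth under drug: a genotype carrying resistance
#' factor rho at growth inhibition GI grows at
#' `baseline_growth * (1 - GI * rho)` net divisions/day (vehicle: GI = 0),
#' with stochastic rounding of cell counts. Whenever the population exceeds
#' `capacity` it is passaged: a multinomial subsample retaining
#' `split_fraction` of the cells.
#'
#' @param pop starting `cell_population` (the arm's share of the infected
#'   pool).
#' @param scenario a [screen_scenario()].
#' @param arm `"vehicle"` or one of the scenario's dose labels.
#' @param seed integer seed.
#' @return the `cell_population` after `scenario$days` days.
#' @export
simulate_arm <- function(pop, scenario, arm, seed = 0L) {
  if (length(pop$counts) == 0L) stop("empty population", call. = FALSE)
  if (identical(arm, "vehicle")) {
    gi <- 0
  } else if (arm %in% names(scenario$doses)) {
    gi <- unname(scenario$doses[[arm]])
  } else {
    stop("unknown dose label: ", arm, call. = FALSE)
  }
  keys <- names(pop$counts)
  rho <- if (gi > 0) genotype_rho(keys, scenario$effects, arm)
         else rep(1, length(keys))
  rate <- scenario$baseline_growth * (1 - gi * rho)
  factor <- 2 ^ rate
  counts <- pop$counts
  with_seed(seed, {
    for (day in seq_len(scenario$days)) {
      counts <- stochastic_round(counts * factor)
      total <- sum(counts)
      if (total > scenario$capacity) {
        keep <- round(total * scenario$split_fraction)
        counts <- as.numeric(stats::rmultinom(1, keep, counts))
        names(counts) <- keys
      }
    }
  })
  new_cell_population(counts)
}

#' Simulate barcode sequencing of a population
#'
#' Templates are drawn multinomially over integrations (a cell with k
#' constructs contributes k templates). Each read is the construct barcode,
#' the constant linker, and the sample's index, with i.i.d. substitution
#' errors at `error_rate` per base.
#'
#' @param pop a `cell_population`.
#' @param index_seq the sample's 6-nt index.
#' @param layout the [read_layout()].
#' @param manifest the library manifest (source of barcodes).
#' @param depth number of reads to emit.
#' @param error_rate per-base substitution probability in [0,1).
#' @param seed integer seed.
#' @param sample_id read-name prefix.
#' @return character vector of `depth` read sequences, named by read id.
#' @export
simulate_sequencing <- function(pop, index_seq, layout, manifest, depth,
                                error_rate = 0, seed = 0L,
                                sample_id = "sample") {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must lie in [0,1)", call. = FALSE)
  }
  if (nchar(index_seq) != layout$index_len) {
    stop(sprintf("layout error: sample index %s is %d nt, layout expects %d",
                 index_seq, nchar(index_seq), layout$index_len),
         call. = FALSE)
  }
  df <- as.data.frame(manifest)
  templates <- construct_abundance(pop, manifest)
  if (sum(templates) == 0) stop("population carries no constructs",
                                call. = FALSE)
  with_seed(seed, {
    per_construct <- as.numeric(stats::rmultinom(1, depth, templates))
    base <- paste0(df$barcode, layout$linker_seq, index_seq)
    seqs <- rep(base, per_construct)
    # substitution errors: draw the per-read error count, then mutate only
    # the affected reads (cheap at realistic error rates)
    if (error_rate > 0) {
      n_err <- stats::rbinom(depth, layout$total_len, error_rate)
      hit <- which(n_err > 0L)
      for (r in hit) {
        pos <- sample.int(layout$total_len, n_err[r])
        ch <- strsplit(seqs[r], "", fixed = TRUE)[[1L]]
        for (p in pos) {
          ch[p] <- sample(setdiff(DNA_ALPHABET, ch[p]), 1L)
        }
        seqs[r] <- paste(ch, collapse = "")
      }
    }
    names(seqs) <- sprintf("%s:read%d", sample_id, seq_len(depth))
    seqs
  })
}

#' Write reads to a FASTQ file
#'
#' Four-line records with a constant Phred+33 quality of "I" (Q40) at every
#' base; quality is not modelled. Paths ending in `.gz` are gzip-compressed.
#'
#' @param seqs named character vector of read sequences (names become read
#'   ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(seqs)) {
    qual <- vapply(nchar(seqs), function(w) strrep("I", w), character(1))
    rec <- paste0("@", names(seqs), "\n", seqs, "\n+\n", qual)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Generate a complete synthetic screen
#'
#' Reproduces the screen design end to end: infect, select, split the
#' surviving pool into 7 equal populations (one frozen t0 pool, three drug
#' doses, three paired vehicle wells), grow each arm, and sequence every
#' population with `n_tech_reps` index primers. Returns everything the
#' deconvolution pipeline needs plus the truth table of planted effects.
#'
#' @param scenario a [screen_scenario()].
#' @param manifest a validated library manifest.
#' @param out_dir optional directory; when given, FASTQ files, the sample
#'   sheet, the truth table, and a scenario echo are written there.
#' @return a `screen_run` list: `samplesheet` (sample_id, index_seq, arm,
#'   dose_label, tech_rep, bio_rep), `reads` (named list sample_id ->
#'   sequences), `truth` (construct_id, dose_label, rho), `populations`
#'   (named list of `cell_population`s including `t0`), `fastq_paths` (when
#'   written), and the `scenario` and `manifest` used.
#' @export
generate_screen <- function(scenario, manifest, out_dir = NULL) {
  validate_manifest(manifest)
  if (scenario$read_depth <= 0) {
    stop("read_depth must be positive to sequence the screen", call. = FALSE)
  }
  seed <- scenario$seed
  pool <- simulate_infection(scenario$n_cells, scenario$moi, manifest,
                             seed = sub_seed(seed, "infection"))

  # split the surviving pool into 7 equal populations
  dose_labels <- names(scenario$doses)
  arm_names <- c("t0", paste0("drug_", dose_labels),
                 paste0("veh_", dose_labels))
  n_arms <- length(arm_names)
  split_counts <- with_seed(sub_seed(seed, "split7"), {
    vapply(pool$counts, function(n) {
      as.numeric(stats::rmultinom(1, n, rep(1, n_arms)))
    }, numeric(n_arms))
  })
  rownames(split_counts) <- arm_names
  populations <- lapply(arm_names, function(a) {
    new_cell_population(stats::setNames(split_counts[a, ],
                                        names(pool$counts)))
  })
  names(populations) <- arm_names

  # selection: t0 stays frozen, drug arms see their dose, vehicle arms GI=0
  for (d in dose_labels) {
    populations[[paste0("drug_", d)]] <-
      simulate_arm(populations[[paste0("drug_", d)]], scenario, d,
                   seed = sub_seed(seed, paste0("arm_drug_", d)))
    populations[[paste0("veh_", d)]] <-
      simulate_arm(populations[[paste0("veh_", d)]], scenario, "vehicle",
                   seed = sub_seed(seed, paste0("arm_veh_", d)))
  }

  # sample sheet: every population x technical replicate gets its own index
  arm_of <- function(a) {
    if (a == "t0") "t0" else if (startsWith(a, "drug_")) "drug" else "vehicle"
  }
  dose_of <- function(a) if (a == "t0") "" else sub("^(drug|veh)_", "", a)
  sheet <- do.call(rbind, lapply(arm_names, function(a) {
    data.frame(
      sample_id = sprintf("%s_r%d", a, seq_len(scenario$n_tech_reps)),
      arm = arm_of(a), dose_label = dose_of(a),
      tech_rep = seq_len(scenario$n_tech_reps), bio_rep = 1L,
      stringsAsFactors = FALSE)
  }))
  sheet$index_seq <- assign_indices(nrow(sheet), min_hamming = 3L,
                                    seed = sub_seed(seed, "indices"))
  sheet <- sheet[, c("sample_id", "index_seq", "arm", "dose_label",
                     "tech_rep", "bio_rep")]

  # sequencing
  pop_of_sample <- sub("_r[0-9]+$", "", sheet$sample_id)
  reads <- lapply(seq_len(nrow(sheet)), function(i) {
    simulate_sequencing(populations[[pop_of_sample[i]]],
                        sheet$index_seq[i], scenario$layout, manifest,
                        depth = scenario$read_depth,
                        error_rate = scenario$error_rate,
                        seed = sub_seed(seed, paste0("seq_",
                                                     sheet$sample_id[i])),
                        sample_id = sheet$sample_id[i])
  })
  names(reads) <- sheet$sample_id

  # truth table of planted effects
  ids <- as.data.frame(manifest)$construct_id
  truth <- expand.grid(construct_id = ids, dose_label = dose_labels,
                       stringsAsFactors = FALSE)
  truth$rho <- mapply(function(cid, d) {
    e <- scenario$effects[[cid]]
    if (is.null(e) || is.null(e[[d]])) 1 else as.numeric(e[[d]])
  }, truth$construct_id, truth$dose_label)

  run <- structure(list(samplesheet = sheet, reads = reads, truth = truth,
                        populations = populations, scenario = scenario,
                        manifest = manifest, fastq_paths = NULL),
                   class = "screen_run")
  if (!is.null(out_dir)) run <- write_screen(run, out_dir)
  run
}

#' Write a generated screen to disk
#'
#' @param run a `screen_run` from [generate_screen()].
#' @param out_dir output directory (created if absent).
#' @return the run, with `fastq_paths` filled in.
#' @export
write_screen <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(run$reads), function(sid) {
    p <- file.path(out_dir, paste0(sid, ".fastq"))
    write_fastq(run$reads[[sid]], p)
    p
  }, character(1))
  utils::write.table(run$samplesheet, file.path(out_dir, "samplesheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- run$scenario
  echo <- list(n_cells = sc$n_cells, moi = sc$moi,
               doses = as.list(sc$doses), days = sc$days,
               split_fraction = sc$split_fraction, capacity = sc$capacity,
               baseline_growth = sc$baseline_growth,
               read_depth = sc$read_depth, error_rate = sc$error_rate,
               n_tech_reps = sc$n_tech_reps, seed = sc$seed,
               effects = sc$effects)
  yaml::write_yaml(echo, file.path(out_dir, "scenario.yaml"))
  run$fastq_paths <- paths
  run
}

#' Read a sample sheet TSV
#'
#' @param path TSV with columns sample_id, index_seq, arm, dose_label,
#'   tech_rep, bio_rep.
#' @return a data.frame.
#' @export
load_samplesheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = NULL,
                          quote = "")
  need <- c("sample_id", "index_seq", "arm", "dose_label", "tech_rep",
            "bio_rep")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("samplesheet is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$tech_rep <- as.integer(df$tech_rep)
  df$bio_rep <- as.integer(df$bio_rep)
  if (anyDuplicated(df$index_seq)) {
    stop("sample indices must be pairwise distinct within a pool",
         call. = FALSE)
  }
  df
}
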