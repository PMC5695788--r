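#' Configure a subsampling experiment
#'
#' @param scenario A [scenario_spec()].
#' @param full_n Full-cohort size (default 10000).
#' @param n_grid Subsample sizes (default 10, 20, ..., 150).
#' @param n_reps Repetitions per sample size (default 2000); must be even
#'   so repetitions pair up for the Dice replication metric.
#' @param threshold A [threshold_spec()] (default uncorrected p < .01).
#' @param truth_mode Truth definition passed to [truth_set()].
#' @param master_seed Master RNG seed; all per-stage seeds derive from it.
#' @param fresh_cohort_per_rep When `TRUE`, draw an independent cohort of
#'   size n for every repetition instead of subsampling one full cohort
#'   (sensitivity check; default `FALSE`, the full-sample design).
#' @param output_dir Directory for CSV/NIfTI/YAML outputs, or `NULL` to
#'   skip writing.
#' @param verbose Log per-stage progress (default `TRUE`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scenario = scenario_spec("WD"),
                              full_n = 10000L,
                              n_grid = seq(10L, 150L, by = 10L),
                              n_reps = 2000L,
                              threshold = threshold_spec("uncorrected", 0.01),
                              truth_mode = "designed_any",
                              master_seed = 1L,
                              fresh_cohort_per_rep = FALSE,
                              output_dir = NULL,
                              verbose = TRUE) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(threshold, "threshold_spec"))
  full_n <- check_count(full_n, "full_n", lower = 4L)
  n_reps <- check_count(n_reps, "n_reps", lower = 2L)
  if (n_reps %% 2L != 0L) {
    stop_invalid("`n_reps` must be even (repetitions pair up for Dice)")
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 4L) || max(n_grid) > full_n) {
    stop_invalid("`n_grid` must lie within [4, full_n]")
  }
  truth_mode <- match.arg(truth_mode,
                          c("designed_any", "designed_band",
                            "fullsample_sig"))
  structure(
    list(scenario = scenario, full_n = full_n, n_grid = n_grid,
         n_reps = n_reps, threshold = threshold, truth_mode = truth_mode,
         master_seed = as.integer(master_seed),
         fresh_cohort_per_rep = isTRUE(fresh_cohort_per_rep),
         output_dir = output_dir, verbose = isTRUE(verbose)),
    class = "experiment_config"
  )
}

log_info <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Run the full subsampling experiment
#'
#' Builds the scenario's effect field, generates one full cohort, then
#' for each sample size in `n_grid` draws `n_reps` random subsamples,
#' computes the voxel-wise correlation map, thresholds it, and records
#' the outcome metrics: average power, at-least-one power, mean
#' significant |r|, percent significant voxels, and the Dice overlap of
#' consecutive repetition pairs (reps 1-2, 3-4, ...). Per-size curves
#' summarize each metric by its mean and 2.5/97.5 percentiles across
#' repetitions.
#'
#' Per-repetition subsample seeds are derived deterministically from
#' `master_seed`, so a rerun with the same configuration reproduces every
#' output byte for byte.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a `results_bundle`: list with `records` (one row
#'   per repetition), `curves` (per-size summaries), `field`, `truth`,
#'   `config`, and `paths` of any files written. When
#'   `config$output_dir` is set, writes `records.csv` and `curves.csv`
#'   (tidy long format), effect-field and truth-mask NIfTI volumes, and
#'   `config_echo.yaml`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  vb <- config$verbose
  log_info(vb, "[scenario] building %s effect field", config$scenario$kind)
  field <- make_effect_field(config$scenario)
  log_info(vb, "[cohort] generating full cohort n = %d", config$full_n)
  cohort <- if (config$fresh_cohort_per_rep) NULL else {
    generate_cohort(field, config$full_n, seed = config$master_seed)
  }
  truth <- if (config$truth_mode == "fullsample_sig") {
    if (is.null(cohort)) {
      stop_invalid("truth_mode 'fullsample_sig' requires a full cohort")
    }
    truth_set(field, "fullsample_sig",
              full_sig = threshold(correlate(cohort), config$threshold))
  } else {
    truth_set(field, config$truth_mode)
  }
  records <- experiment_records(config, field, cohort, truth)
  curves <- summarize_records(records)
  bundle <- structure(
    list(records = records, curves = curves, field = field, truth = truth,
         config = config, paths = character()),
    class = "results_bundle"
  )
  if (!is.null(config$output_dir)) {
    bundle$paths <- write_results_bundle(bundle, config$output_dir)
  }
  invisible(bundle)
}

experiment_records <- function(config, field, cohort, truth) {
  scen <- config$scenario$kind
  out <- vector("list", length(config$n_grid))
  for (si in seq_along(config$n_grid)) {
    n_sub <- config$n_grid[si]
    t0 <- proc.time()[["elapsed"]]
    avg <- alo <- msr <- pct <- dice_prev <- rep(NA_real_, config$n_reps)
    prev_sig <- NULL
    for (rep_i in seq_len(config$n_reps)) {
      seed_i <- config$master_seed + si * 100000L + rep_i
      if (config$fresh_cohort_per_rep) {
        co <- generate_cohort(field, n_sub, seed = seed_i)
        sm <- correlate(co)
      } else {
        idx <- draw_subsample(cohort, n_sub, seed = seed_i)
        sm <- correlate(cohort, idx)
      }
      sig <- threshold(sm, config$threshold)
      avg[rep_i] <- average_power(sig, truth)
      alo[rep_i] <- as.numeric(at_least_one(sig, truth))
      msr[rep_i] <- mean_significant_effect(sm, sig)
      pct[rep_i] <- percent_significant(sig)
      if (rep_i %% 2L == 0L) {
        dice_prev[rep_i] <- dice(prev_sig, sig)
      }
      prev_sig <- sig
    }
    out[[si]] <- data.frame(
      scenario = scen, n_sub = n_sub, rep = seq_len(config$n_reps),
      avg_power = avg, alo = alo, mean_sig_abs_r = msr, pct_sig = pct,
      dice_prev = dice_prev
    )
    log_info(config$verbose, "[size %3d] %d reps in %.1fs", n_sub,
             config$n_reps, proc.time()[["elapsed"]] - t0)
  }
  do.call(rbind, out)
}

#' Summarize per-repetition records into metric curves
#'
#' For each scenario, sample size, and metric: the mean over defined
#' repetitions, the 2.5 and 97.5 percentiles of the sampling
#' distribution, and the count of defined values (the mean significant
#' effect size is undefined in repetitions with no significant voxel,
#' and Dice only on even repetitions).
#'
#' @param records The `records` data frame of [run_experiment()].
#' @return Data frame with columns scenario, n_sub, metric, mean, lo95,
#'   hi95, n_defined.
#' @export
summarize_records <- function(records) {
  metrics <- c("avg_power", "alo", "mean_sig_abs_r", "pct_sig", "dice_prev")
  keys <- unique(records[c("scenario", "n_sub")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$scenario == keys$scenario[i] &
                     records$n_sub == keys$n_sub[i], ]
    do.call(rbind, lapply(metrics, function(m) {
      v <- sub[[m]][!is.na(sub[[m]])]
      data.frame(
        scenario = keys$scenario[i], n_sub = keys$n_sub[i], metric = m,
        mean = if (length(v)) mean(v) else NA_real_,
        lo95 = if (length(v)) unname(stats::quantile(v, 0.025)) else NA_real_,
        hi95 = if (length(v)) unname(stats::quantile(v, 0.975)) else NA_real_,
        n_defined = length(v)
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bivariate sampling demonstration
#'
#' Single-variable analogue of the voxel experiment: one pair of
#' variables with population correlation `rho` in a large full sample,
#' from which repeated subsamples of increasing size are drawn. Each
#' subsample's correlation, p-value, and significance flag are recorded,
#' illustrating how the range of estimates shrinks and the proportion
#' significant grows with sample size.
#'
#' @param rho Population correlation (default 0.3).
#' @param full_n Full-sample size (default 10000).
#' @param n_grid Subsample sizes (default 10, 20, ..., 150).
#' @param reps_per_size Subsamples per size (default 30).
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed RNG seed.
#' @return List with `full_r` (the full-sample correlation), `records`
#'   (size, rep, r, p, significant), and `summary` (per size: proportion
#'   significant, min/max/mean r).
#' @export
bivariate_demo <- function(rho = 0.3, full_n = 10000L,
                           n_grid = seq(10L, 150L, by = 10L),
                           reps_per_size = 30L, alpha = 0.05, seed = 1L) {
  check_scalar_number(rho, "rho", -1, 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  full_n <- check_count(full_n, "full_n", lower = 10L)
  reps_per_size <- check_count(reps_per_size, "reps_per_size", lower = 1L)
  check_scalar_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
                      strict_upper = TRUE)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (any(n_grid < 4L) || max(n_grid) > full_n) {
    stop_invalid("`n_grid` must lie within [4, full_n]")
  }
  with_seed(seed, {
    y <- stats::rnorm(full_n)
    x <- rho * y + sqrt(1 - rho^2) * stats::rnorm(full_n)
    full_r <- stats::cor(x, y)
    rows <- list()
    for (n_sub in n_grid) {
      for (rep_i in seq_len(reps_per_size)) {
        idx <- sample.int(full_n, n_sub)
        ct <- stats::cor.test(x[idx], y[idx])
        rows[[length(rows) + 1L]] <- data.frame(
          n_sub = n_sub, rep = rep_i,
          r = unname(ct$estimate), p = ct$p.value,
          significant = ct$p.value < alpha
        )
      }
    }
    records <- do.call(rbind, rows)
    summary <- do.call(rbind, lapply(split(records, records$n_sub), function(s) {
      data.frame(n_sub = s$n_sub[1L],
                 prop_significant = mean(s$significant),
                 min_r = min(s$r), max_r = max(s$r), mean_r = mean(s$r))
    }))
    rownames(summary) <- NULL
    list(full_r = full_r, records = records, summary = summary)
  })
}
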