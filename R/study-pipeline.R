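#' Outcome-neutral occupancy quality check
#'
#' Per participant, the difference `d_i` between the mean occupancy of the
#' two high-occupancy states and the mean occupancy of the remaining states;
#' reports `mean(d)` with a normal-approximation 95% confidence interval
#' `mean(d) +/- 1.96 sd(d)/sqrt(n)`. A correct state estimation should give a
#' clearly positive separation.
#'
#' @param fo Occupancy matrix from [fractional_occupancy()].
#' @param top Indices of the high-occupancy states; defaults to the top two
#'   by cohort mean via [select_high_occupancy()].
#' @return List of class `quality_check`: `estimate`, `conf.low`,
#'   `conf.high`, `n` (all on the proportion scale).
#' @export
quality_check <- function(fo, top = NULL) {
  stop_if(!is.matrix(fo) || ncol(fo) < 3L, "`fo` must be a matrix with k >= 3")
  stop_if(nrow(fo) < 2L, "at least two participants required")
  if (is.null(top)) top <- select_high_occupancy(fo)$top
  d <- rowMeans(fo[, top, drop = FALSE]) - rowMeans(fo[, -top, drop = FALSE])
  se <- stats::sd(d) / sqrt(length(d))
  q <- stats::qnorm(0.975)
  structure(list(estimate = mean(d), conf.low = mean(d) - q * se,
                 conf.high = mean(d) + q * se, n = length(d)),
            class = "quality_check")
}

#' @export
print.quality_check <- function(x, ...) {
  cat(sprintf(
    "High- vs low-occupancy separation: %.1f pp (95%% CI %.1f-%.1f), n = %d\n",
    100 * x$estimate, 100 * x$conf.low, 100 * x$conf.high, x$n))
  invisible(x)
}

# Assemble the analysis frame: fo_high + WMH transform + covariates,
# complete cases only. `fo_high` may come from the phenotype table itself or
# be supplied (e.g. from a clustering-derived occupancy table).
analysis_frame <- function(data, wmh_col, fo_high = NULL, vars) {
  stop_if(!wmh_col %in% names(data), "column `", wmh_col, "` not found")
  if (!is.null(fo_high)) {
    stop_if(length(fo_high) != nrow(data),
            "`fo_high` must have one value per participant")
    data$fo_high <- as.numeric(fo_high)
  }
  stop_if(is.null(data$fo_high), "no `fo_high` available")
  tw <- transform_wmh(data[[wmh_col]])
  data$log_wmh <- tw$log_wmh
  data$wmh_zero <- tw$wmh_zero
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  list(data = data[cc, , drop = FALSE], n_excluded = sum(!cc))
}

# Build the model formula, including the zero indicator only when zeros and
# non-zeros coexist (it is constant, hence collinear, otherwise).
wmh_formula <- function(lhs, data, covars) {
  zeros <- sum(data$wmh_zero)
  terms <- c("log_wmh",
             if (zeros > 0 && zeros < nrow(data)) "wmh_zero", covars)
  stats::as.formula(paste(lhs, "~", paste(terms, collapse = " + ")))
}

#' Primary analysis: occupancy on WMH burden
#'
#' Fits the fixed-dispersion beta regression
#' `fo_high ~ log_wmh (+ wmh_zero) + age + sex` on complete cases and reports
#' the odds ratio per interquartile ratio of the analyzed sample's non-zero
#' WMH volumes.
#'
#' @param cohort A `cap_cohort` or a phenotype `data.frame` with columns
#'   `fo_high` (or see `fo_high` argument), the WMH column, `age`, `sex`.
#' @param fo_high Optional numeric vector overriding the `fo_high` column
#'   (e.g. occupancies from a clustering run).
#' @param wmh_col Which WMH component to analyze (default `"wmh_total_ml"`).
#' @param alpha Nominal significance level for the reported flag.
#' @param shrink_boundary Passed to [beta_reg()]: opt-in shrinkage for
#'   occupancies lying exactly on the (0, 1) boundary (possible in very small
#'   or very noisy samples); boundary values are an error by default.
#' @return Object of class `primary_result`: `fit` (a `beta_fit`), `effect`
#'   (odds ratio per IQR, a `cap_effect`), `iqr` (q1, q3, ratio), `n`,
#'   `n_excluded`, `significant`.
#' @export
run_primary <- function(cohort, fo_high = NULL, wmh_col = "wmh_total_ml",
                        alpha = 0.05, shrink_boundary = FALSE) {
  data <- if (inherits(cohort, "cap_cohort")) cohort$phenotype else cohort
  af <- analysis_frame(data, wmh_col, fo_high,
                       vars = c("fo_high", wmh_col, "age", "sex"))
  stop_if(nrow(af$data) < 10L, "fewer than 10 complete cases")
  fml <- wmh_formula("fo_high", af$data, c("age", "sex"))
  fit <- beta_reg(fml, af$data, shrink_boundary = shrink_boundary)
  nz <- af$data[[wmh_col]][af$data[[wmh_col]] > 0]
  q <- stats::quantile(nz, c(0.25, 0.75), names = FALSE)
  eff <- effect_per_iqr(fit, q[1], q[2])
  structure(list(fit = fit, effect = eff,
                 iqr = c(q1 = q[1], q3 = q[2], ratio = q[2] / q[1]),
                 n = fit$n, n_excluded = af$n_excluded,
                 significant = eff$p < alpha, alpha = alpha),
            class = "primary_result")
}

#' Secondary analysis: TMT-B on occupancy
#'
#' Fits the Gamma GLM (log link)
#' `tmt_b_s ~ fo_high + log_wmh (+ wmh_zero) + age + sex + education_years`
#' on complete cases and reports the multiplier per 5 percentage points of
#' occupancy.
#'
#' @inheritParams run_primary
#' @param k_pp Percentage-point step for the reported multiplier (default 5).
#' @return Object of class `secondary_result` mirroring [run_primary()].
#' @export
run_secondary <- function(cohort, fo_high = NULL, wmh_col = "wmh_total_ml",
                          alpha = 0.05, k_pp = 5) {
  data <- if (inherits(cohort, "cap_cohort")) cohort$phenotype else cohort
  af <- analysis_frame(data, wmh_col, fo_high,
                       vars = c("tmt_b_s", "fo_high", wmh_col, "age", "sex",
                                "education_years"))
  stop_if(nrow(af$data) < 10L, "fewer than 10 complete cases")
  fml <- wmh_formula("tmt_b_s", af$data,
                     c("fo_high", "age", "sex", "education_years"))
  fit <- gamma_reg(fml, af$data)
  eff <- effect_per_k_pp(fit, k_pp = k_pp)
  structure(list(fit = fit, effect = eff, n = fit$n,
                 n_excluded = af$n_excluded,
                 significant = eff$p < alpha, alpha = alpha, k_pp = k_pp),
            class = "secondary_result")
}

#' @export
print.primary_result <- function(x, ...) {
  cat("Primary analysis: high-state occupancy ~ WMH burden\n")
  cat(sprintf("  n = %d complete cases (%d excluded), IQR ratio %.2f\n",
              x$n, x$n_excluded, x$iqr["ratio"]))
  cat("  OR "); print(x$effect)
  invisible(x)
}

#' @export
print.secondary_result <- function(x, ...) {
  cat("Secondary analysis: TMT-B ~ high-state occupancy\n")
  cat(sprintf("  n = %d complete cases (%d excluded)\n", x$n, x$n_excluded))
  cat("  multiplier "); print(x$effect)
  invisible(x)
}

# ---- multiverse --------------------------------------------------------

#' Parcellations and confound-regression variants of the multiverse
#'
#' `parcellations()` lists the nine brain parcellations (name and parcel
#' count) and `confound_variants()` the nine named confound-regression
#' strategies of the robustness grid. In this package the strategies are
#' labeled perturbations of the synthetic generator (noise scaling, volume
#' censoring emulating scrubbing, a shared global component), not
#' re-implementations of the original de-noising software.
#'
#' @return A `data.frame` (`parcellations`) or named list of perturbation
#'   settings (`confound_variants`).
#' @export
parcellations <- function() {
  data.frame(
    parcellation = c("desikan-killiany", "aal", "harvard-oxford", "glasser360",
                     "gordon333", "power264", "schaefer100", "schaefer200",
                     "schaefer400"),
    n_parcels = c(86L, 116L, 112L, 360L, 333L, 264L, 100L, 200L, 400L),
    stringsAsFactors = FALSE)
}

#' @rdname parcellations
#' @export
confound_variants <- function() {
  list(
    "24p"          = list(noise_mult = 1.3, censor_frac = 0, global_sd = 0.15),
    "24p+gsr"      = list(noise_mult = 1.3, censor_frac = 0, global_sd = 0),
    "36p"          = list(noise_mult = 1.0, censor_frac = 0, global_sd = 0),
    "36p+spike"    = list(noise_mult = 1.0, censor_frac = 0.03, global_sd = 0),
    "36p+despike"  = list(noise_mult = 0.9, censor_frac = 0, global_sd = 0),
    "36p+scrub"    = list(noise_mult = 1.0, censor_frac = 0.08, global_sd = 0),
    "acompcor"     = list(noise_mult = 1.1, censor_frac = 0, global_sd = 0.1),
    "tcompcor"     = list(noise_mult = 1.2, censor_frac = 0, global_sd = 0.1),
    "aroma"        = list(noise_mult = 1.5, censor_frac = 0, global_sd = 0.25))
}

#' Scenario grid of the multiverse analysis
#'
#' Full factorial grid of confound variant x parcellation x WMH component:
#' 9 x 9 x 3 = 243 scenarios with the default components, or 9 x 9 = 81 when
#' restricted to the total volume only.
#'
#' @param variants Character vector of confound-variant names.
#' @param parcellation_table As from [parcellations()].
#' @param wmh_components Subset of `c("total", "periventricular", "deep")`.
#' @return `data.frame` with one row per scenario.
#' @export
multiverse_grid <- function(variants = names(confound_variants()),
                            parcellation_table = parcellations(),
                            wmh_components = c("total", "periventricular",
                                               "deep")) {
  stop_if(!all(wmh_components %in% c("total", "periventricular", "deep")),
          "unknown WMH component")
  g <- expand.grid(confound_variant = variants,
                   parcellation = parcellation_table$parcellation,
                   wmh_component = wmh_components,
                   stringsAsFactors = FALSE)
  g$n_parcels <- parcellation_table$n_parcels[
    match(g$parcellation, parcellation_table$parcellation)]
  g
}

# Apply a confound variant to a cohort's BOLD data (volume censoring and
# shared global component); censoring also shortens the label sequences, so
# occupancies are computed over retained volumes only.
apply_variant_processing <- function(bold, sequences, variant) {
  n <- length(bold)
  for (i in seq_len(n)) {
    ti <- ncol(bold[[i]])
    if (variant$censor_frac > 0) {
      keep <- sort(sample.int(ti, max(2L, round((1 - variant$censor_frac) * ti))))
      bold[[i]] <- bold[[i]][, keep, drop = FALSE]
      sequences[[i]] <- sequences[[i]][keep]
      ti <- length(keep)
    }
    if (variant$global_sd > 0) {
      g <- stats::rnorm(ti, 0, variant$global_sd)
      bold[[i]] <- bold[[i]] + matrix(g, nrow(bold[[i]]), ti, byrow = TRUE)
    }
  }
  list(bold = bold, sequences = sequences)
}

#' Run the multiverse robustness grid
#'
#' For every scenario of the grid, simulates a cohort under the scenario's
#' confound variant and parcellation, estimates brain states by CAP
#' clustering, computes occupancies, and re-runs the primary (and optionally
#' secondary) analysis against the scenario's WMH component. Each row records
#' the effect estimate, 95% CI, p-value, a nominal-significance flag and the
#' direction; scenario failures are recorded, not fatal. No multiplicity
#' correction is applied: the grid describes robustness, it does not test.
#'
#' @param config Base [generator_config()]; the scenario overrides
#'   `n_parcels` and the noise level.
#' @param grid Scenario grid from [multiverse_grid()].
#' @param seed Master seed; each cell runs on a derived child seed.
#' @param n_restarts,kmeans_max_iter Clustering effort per cell.
#' @param include_secondary Also fit the TMT-B model per cell.
#' @param shrink_boundary Passed to the per-cell primary fit (see
#'   [run_primary()]).
#' @param verbose Print progress.
#' @return `data.frame` of class `multiverse_result`, one row per scenario.
#' @export
run_multiverse <- function(config, grid = multiverse_grid(), seed = 1,
                           n_restarts = 3, kmeans_max_iter = 50,
                           include_secondary = FALSE, shrink_boundary = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  variants <- confound_variants()
  stop_if(!all(grid$confound_variant %in% names(variants)),
          "unknown confound variant in grid")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sc <- grid[i, ]
    cell_seed <- child_seed(seed, i)
    rows[[i]] <- tryCatch(
      run_multiverse_cell(config, sc, variants[[sc$confound_variant]],
                          cell_seed, n_restarts, kmeans_max_iter,
                          include_secondary, shrink_boundary),
      error = function(e) data.frame(or_per_iqr = NA_real_,
                                     conf.low = NA_real_, conf.high = NA_real_,
                                     p = NA_real_, nominal_significant = NA,
                                     direction = NA_integer_,
                                     error = conditionMessage(e),
                                     stringsAsFactors = FALSE))
    if (verbose) {
      message(sprintf("[%d/%d] %s / %s / %s", i, nrow(grid),
                      sc$confound_variant, sc$parcellation, sc$wmh_component))
    }
  }
  out <- cbind(grid, do.call(rbind, rows))
  class(out) <- c("multiverse_result", "data.frame")
  attr(out, "seed") <- seed
  out
}

run_multiverse_cell <- function(config, scenario, variant, cell_seed,
                                n_restarts, kmeans_max_iter,
                                include_secondary, shrink_boundary = FALSE) {
  cfg <- config
  cfg$seed <- cell_seed
  cfg$n_parcels <- scenario$n_parcels
  cfg$network_labels <- default_network_labels(scenario$n_parcels)
  cfg$noise_sd <- config$noise_sd * variant$noise_mult
  cohort <- simulate_cohort(cfg, include_bold = TRUE)
  proc <- with_seed(child_seed(cell_seed, 1L),
                    apply_variant_processing(cohort$bold, cohort$sequences,
                                             variant))
  model <- estimate_brain_states(proc$bold, k = cfg$k_states,
                                 n_restarts = n_restarts,
                                 max_iter = kmeans_max_iter,
                                 seed = child_seed(cell_seed, 2L))
  fo <- fractional_occupancy(model)
  fo <- fo[cohort$phenotype$id, , drop = FALSE]
  sel <- select_high_occupancy(fo)
  wmh_col <- switch(scenario$wmh_component, total = "wmh_total_ml",
                    periventricular = "wmh_peri_ml", deep = "wmh_deep_ml")
  pri <- run_primary(cohort$phenotype, fo_high = sel$fo_high,
                     wmh_col = wmh_col, shrink_boundary = shrink_boundary)
  out <- data.frame(or_per_iqr = pri$effect$estimate,
                    conf.low = pri$effect$conf.low,
                    conf.high = pri$effect$conf.high,
                    p = pri$effect$p,
                    nominal_significant = pri$effect$p < 0.05,
                    direction = sign(log(pri$effect$estimate)),
                    error = NA_character_, stringsAsFactors = FALSE)
  if (include_secondary) {
    sec <- run_secondary(cohort$phenotype, fo_high = sel$fo_high,
                         wmh_col = wmh_col)
    out$tmt_multiplier_per_5pp <- sec$effect$estimate
    out$tmt_p <- sec$effect$p
  }
  out
}

#' @export
summary.multiverse_result <- function(object, ...) {
  ok <- !is.na(object$p)
  sig_neg <- sum(ok & object$nominal_significant & object$direction < 0)
  sig_pos <- sum(ok & object$nominal_significant & object$direction > 0)
  out <- list(n_scenarios = nrow(object), n_failed = sum(!ok),
              significant_negative = sig_neg, significant_positive = sig_pos)
  class(out) <- "summary.multiverse_result"
  out
}

#' @export
print.summary.multiverse_result <- function(x, ...) {
  cat(sprintf(
    "Multiverse: %d scenarios (%d failed); %d significant negative, %d significant positive\n",
    x$n_scenarios, x$n_failed, x$significant_negative, x$significant_positive))
  invisible(x)
}

#' @export
plot.multiverse_result <- function(x, ...) {
  ok <- !is.na(x$p)
  est <- x$or_per_iqr[ok]
  sig <- x$nominal_significant[ok]
  idx <- order(est)
  cols <- ifelse(sig[idx], "black", "grey70")
  graphics::plot(seq_along(est), est[idx], pch = 16, col = cols, log = "y",
                 xlab = "scenario (ordered by estimate)",
                 ylab = "OR per IQR of WMH volume", ...)
  graphics::segments(seq_along(est), x$conf.low[ok][idx],
                     seq_along(est), x$conf.high[ok][idx], col = cols)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

# ---- bootstrap power curve --------------------------------------------

#' Bootstrap power curve for the primary analysis
#'
#' For each target sample size, draws `n_reps` bootstrap resamples (with
#' replacement) of that size from the reference cohort, re-runs the primary
#' regression on each, and records the proportion of resamples rejecting the
#' null at level `alpha`. Each (size, replicate) pair runs on a derived child
#' seed, so the curve is reproducible and order-independent. Resamples with
#' degenerate WMH (all values identical) are recorded as non-rejections with
#' a warning.
#'
#' @param cohort Reference phenotype `data.frame` (or `cap_cohort`) with
#'   `fo_high`, WMH, `age`, `sex`.
#' @param sample_sizes Integer vector of target sizes.
#' @param n_reps Bootstrap replicates per size.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @param power_target Reported "smallest n achieving" threshold.
#' @param wmh_col WMH component column.
#' @return `data.frame` of class `power_curve` with columns `n`, `power`,
#'   `n_reps`; attributes `alpha`, `seed`, `smallest_n` (smallest size with
#'   power >= `power_target`, `NA` if none).
#' @export
power_bootstrap <- function(cohort, sample_sizes, n_reps = 1000, alpha = 0.05,
                            seed = 1, power_target = 0.8,
                            wmh_col = "wmh_total_ml") {
  data <- if (inherits(cohort, "cap_cohort")) cohort$phenotype else cohort
  stop_if(!all(c("fo_high", wmh_col, "age", "sex") %in% names(data)),
          "cohort lacks primary-analysis variables")
  stop_if(!is_count(n_reps), "`n_reps` must be a positive integer")
  data <- data[stats::complete.cases(
    data[, c("fo_high", wmh_col, "age", "sex")]), , drop = FALSE]
  power <- numeric(length(sample_sizes))
  for (j in seq_along(sample_sizes)) {
    nn <- sample_sizes[j]
    rej <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      rep_seed <- child_seed(seed, j * 100000L + r)
      boot <- with_seed(rep_seed,
                        data[sample.int(nrow(data), nn, replace = TRUE), ,
                             drop = FALSE])
      if (length(unique(boot[[wmh_col]])) < 2L) {
        warning("degenerate WMH resample at n = ", nn,
                "; recorded as non-rejection")
        rej[r] <- FALSE
        next
      }
      rej[r] <- tryCatch(
        run_primary(boot, wmh_col = wmh_col, alpha = alpha)$significant,
        error = function(e) FALSE)
    }
    power[j] <- mean(rej)
  }
  out <- data.frame(n = sample_sizes, power = power, n_reps = n_reps)
  class(out) <- c("power_curve", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  hit <- which(power >= power_target)
  attr(out, "smallest_n") <- if (length(hit)) sample_sizes[min(hit)] else NA
  out
}

#' @export
plot.power_curve <- function(x, ...) {
  graphics::plot(x$n, x$power, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "sample size", ylab = "estimated power", ...)
  graphics::abline(h = attr(x, "alpha"), lty = 3)
  invisible(x)
}

# ---- tabular I/O -------------------------------------------------------

#' Write / read pipeline tables as TSV
#'
#' Phenotype, occupancy, centroid and scenario tables are exchanged as plain
#' tab-separated text.
#'
#' @param x A `data.frame` (or matrix with row names for occupancies).
#' @param path Output file.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` a
#'   `data.frame`.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) x <- data.frame(id = rownames(x), x,
                                    stringsAsFactors = FALSE, row.names = NULL)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
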