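#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic-cohort generator. The defaults are
#' calibrated once, analytically, to the population targets the analysis
#' assumes: total WMH volume is zero-inflated log-normal with median 1.05 mL
#' and interquartile ratio Q3/Q1 = 5.06 (about 0.5% exact zeros); five brain
#' states have mean fractional occupancies near 25/24/18.5/17/15.3%; the
#' latent high-state occupancy is linked to log WMH volume on the logit scale
#' with an odds ratio of 0.95 per interquartile ratio; and Trail Making Test
#' part B times follow a Gamma law whose log-mean decreases by a factor 0.98
#' per 5 percentage points of high-state occupancy.
#'
#' @param n_participants Number of participants to simulate.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param n_parcels Number of cortical parcels for simulated BOLD data.
#' @param network_labels Character vector of length `n_parcels` assigning each
#'   parcel to one of the seven canonical large-scale networks; defaults to
#'   contiguous, nearly equal blocks (see [default_network_labels()]).
#' @param k_states Number of discrete brain states (default 5).
#' @param target_mean_fo Probability vector of length `k_states` giving the
#'   population mean fractional occupancy of each state. Must sum to 1. States
#'   1 and 2 are the high-occupancy (default-mode-related) states.
#' @param activation_amplitude Centroid activation height, in signal units.
#' @param noise_sd Standard deviation of i.i.d. Gaussian parcel noise added to
#'   each BOLD volume, in signal units.
#' @param volumes_range Integer `[min, max]`: retained volumes per participant
#'   are drawn uniformly from this range.
#' @param wmh_logmean,wmh_logsd Mean and SD of log WMH volume (log-mL) for the
#'   non-zero component. Defaults give median 1.05 mL and Q3/Q1 = 5.06.
#' @param zero_wmh_prob Probability of an exactly-zero WMH volume.
#' @param or_per_iqr Generative odds ratio on the high-state occupancy per
#'   interquartile ratio of WMH volume (default 0.95; 1 = null).
#' @param beta_dispersion Precision `phi` of the Beta law for the latent
#'   per-participant high-state occupancy. The default (80) yields a realized
#'   occupancy IQR near 20.8--28.0% once multinomial label noise is added.
#' @param tmt_multiplier_per_5pp Multiplicative effect on expected TMT-B time
#'   per +5 percentage points of high-state occupancy (default 0.98; 1 = null).
#' @param gamma_shape Shape of the Gamma law for TMT-B times.
#' @param covariate_effects Named list of logit-scale effects entering the
#'   occupancy link: `age` (per year), `sex_female`, `education` (per year),
#'   `wmh_zero` (zero-volume indicator).
#' @param tmt_effects Named list of log-scale nuisance effects entering the
#'   TMT-B mean: `age`, `sex_female`, `education`, `wmh` (per log-mL),
#'   `wmh_zero`.
#' @param persistence Temporal persistence `rho` in `[0, 1)` of the state
#'   sequence. Labels follow a Markov chain whose transition matrix mixes a
#'   jump to the stationary draw (weight `1 - rho`) with staying in the
#'   current state (weight `rho`), so the stationary law is exactly the
#'   participant's occupancy vector `p_i`; `rho = 0` (default) gives i.i.d.
#'   labels. Exposed as a forward-compatibility hook: occupancy-based analyses
#'   are invariant to `rho` in expectation.
#' @param missing_tmt_prob Probability that a participant's TMT-B value is
#'   missing (`NA`), for exercising complete-case handling.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
generator_config <- function(n_participants = 1651,
                             seed = NULL,
                             n_parcels = 100,
                             network_labels = NULL,
                             k_states = 5,
                             target_mean_fo = c(0.248, 0.240, 0.184, 0.168, 0.152) / 0.992,
                             activation_amplitude = 1,
                             noise_sd = 0.5,
                             volumes_range = c(100L, 125L),
                             wmh_logmean = log(1.05),
                             wmh_logsd = log(5.06) / (2 * qnorm(0.75)),
                             zero_wmh_prob = 9 / 1651,
                             or_per_iqr = 0.95,
                             beta_dispersion = 80,
                             tmt_multiplier_per_5pp = 0.98,
                             gamma_shape = 8,
                             covariate_effects = list(age = log(1.04) / 10,
                                                      sex_female = log(1.12),
                                                      education = 0,
                                                      wmh_zero = log(0.93)),
                             tmt_effects = list(age = log(1.18) / 10,
                                                sex_female = log(0.99),
                                                education = log(0.97),
                                                wmh = log(1.01) / log(5.06),
                                                wmh_zero = log(0.97)),
                             persistence = 0,
                             missing_tmt_prob = 0) {
  stop_if(!is_count(n_participants), "`n_participants` must be a positive integer")
  stop_if(!is_count(n_parcels) || n_parcels < 7,
          "`n_parcels` must be an integer >= 7 (one parcel per network at least)")
  stop_if(!is_count(k_states) || k_states < 2, "`k_states` must be an integer >= 2")
  stop_if(length(target_mean_fo) != k_states,
          "`target_mean_fo` must have length `k_states`")
  stop_if(any(target_mean_fo <= 0), "`target_mean_fo` entries must be > 0")
  stop_if(abs(sum(target_mean_fo) - 1) > 1e-12, "`target_mean_fo` must sum to 1")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")
  stop_if(activation_amplitude <= 0, "`activation_amplitude` must be > 0")
  stop_if(length(volumes_range) != 2L || any(volumes_range < 1) ||
            volumes_range[1] > volumes_range[2] ||
            any(volumes_range != round(volumes_range)),
          "`volumes_range` must be an increasing pair of positive integers")
  stop_if(wmh_logsd < 0, "`wmh_logsd` must be >= 0")
  stop_if(zero_wmh_prob < 0 || zero_wmh_prob > 1, "`zero_wmh_prob` must be in [0, 1]")
  stop_if(or_per_iqr <= 0, "`or_per_iqr` must be > 0")
  stop_if(beta_dispersion <= 0, "`beta_dispersion` must be > 0")
  stop_if(tmt_multiplier_per_5pp <= 0, "`tmt_multiplier_per_5pp` must be > 0")
  stop_if(gamma_shape <= 0, "`gamma_shape` must be > 0")
  stop_if(persistence < 0 || persistence >= 1, "`persistence` must be in [0, 1)")
  stop_if(missing_tmt_prob < 0 || missing_tmt_prob >= 1,
          "`missing_tmt_prob` must be in [0, 1)")
  if (is.null(network_labels)) {
    network_labels <- default_network_labels(n_parcels)
  }
  stop_if(length(network_labels) != n_parcels,
          "`network_labels` must have one entry per parcel")

  structure(list(
    n_participants = as.integer(n_participants), seed = seed,
    n_parcels = as.integer(n_parcels), network_labels = network_labels,
    k_states = as.integer(k_states), target_mean_fo = target_mean_fo,
    activation_amplitude = activation_amplitude, noise_sd = noise_sd,
    volumes_range = as.integer(volumes_range),
    wmh_logmean = wmh_logmean, wmh_logsd = wmh_logsd,
    zero_wmh_prob = zero_wmh_prob, or_per_iqr = or_per_iqr,
    beta_dispersion = beta_dispersion,
    tmt_multiplier_per_5pp = tmt_multiplier_per_5pp, gamma_shape = gamma_shape,
    covariate_effects = covariate_effects, tmt_effects = tmt_effects,
    persistence = persistence, missing_tmt_prob = missing_tmt_prob
  ), class = "generator_config")
}

#' Seven canonical network labels in contiguous blocks
#'
#' Assigns each of `n_parcels` parcels to one of the seven canonical
#' large-scale cortical networks in contiguous, nearly equal blocks. Used as
#' the default parcel-to-network map of the generator.
#'
#' @param n_parcels Number of parcels (>= 7).
#' @return Character vector of length `n_parcels`.
#' @export
default_network_labels <- function(n_parcels) {
  stop_if(!is_count(n_parcels) || n_parcels < 7, "`n_parcels` must be >= 7")
  nets <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
  nets[as.integer(cut(seq_len(n_parcels), breaks = 7))]
}

# Networks activated by each state: state 1 = default-mode activation (DMN+),
# state 2 = default-mode suppression (DMN-), remaining states activate other
# networks in a fixed cycle.
state_network_map <- function(k_states) {
  others <- c("Vis", "SomMot", "Cont", "DorsAttn", "SalVentAttn", "Limbic")
  c("Default", "Default", rep_len(others, max(k_states - 2L, 0L)))[seq_len(k_states)]
}

#' True state centroid patterns of the generator
#'
#' Returns the planted `k x n_parcels` centroid matrix: state 1 activates the
#' default-mode parcels (+amplitude), state 2 suppresses them (-amplitude),
#' and the remaining states activate other networks.
#'
#' @param config A [generator_config()].
#' @return Numeric matrix `k_states x n_parcels`.
#' @export
state_centroids <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  k <- config$k_states
  nets <- state_network_map(k)
  cent <- matrix(0, k, config$n_parcels)
  for (s in seq_len(k)) {
    sgn <- if (s == 2L) -1 else 1
    cent[s, config$network_labels == nets[s]] <- sgn * config$activation_amplitude
  }
  rownames(cent) <- paste0("state_", seq_len(k))
  cent
}

#' Generate demographic covariates
#'
#' Draws age, sex and years of education with marginals matched to the study
#' population's medians and interquartile ranges (age median 66, IQR 59--72;
#' 57% male; education median 13 years). Continuous covariates are sampled
#' from quartile-matching piecewise-uniform histograms and rounded; only
#' medians and IQRs are targeted, not higher moments.
#'
#' @param config A [generator_config()].
#' @param n Number of rows; defaults to `config$n_participants`.
#' @return `data.frame` with columns `id`, `age`, `sex` (factor male/female),
#'   `education_years`.
#' @export
gen_covariates <- function(config, n = config$n_participants) {
  stopifnot(inherits(config, "generator_config"))
  stop_if(!is_count(n), "`n` must be a positive integer")
  with_seed(config$seed, {
    age <- round(r_quartile_hist(n, c(45, 59, 66, 72, 85)))
    sex <- factor(ifelse(stats::runif(n) < 711 / 1651, "female", "male"),
                  levels = c("male", "female"))
    edu <- round(r_quartile_hist(n, c(8, 12, 13, 16, 20)))
    data.frame(id = sprintf("sub-%05d", seq_len(n)),
               age = age, sex = sex, education_years = edu,
               stringsAsFactors = FALSE)
  })
}

# Piecewise-uniform sampler whose population quartiles are the interior knots.
r_quartile_hist <- function(n, knots) {
  bin <- sample.int(4L, n, replace = TRUE)
  stats::runif(n, knots[bin], knots[bin + 1L])
}

#' Generate WMH volumes
#'
#' Total white-matter-hyperintensity volumes in mL: exactly zero with
#' probability `zero_wmh_prob`, otherwise log-normal.
#'
#' @param config A [generator_config()].
#' @param n Number of draws; defaults to `config$n_participants`.
#' @return Numeric vector of volumes (mL).
#' @export
gen_wmh <- function(config, n = config$n_participants) {
  stopifnot(inherits(config, "generator_config"))
  stop_if(config$wmh_logsd < 0, "`wmh_logsd` must be >= 0")
  with_seed(config$seed, {
    v <- stats::rlnorm(n, config$wmh_logmean, config$wmh_logsd)
    v[stats::runif(n) < config$zero_wmh_prob] <- 0
    v
  })
}

# Split a total WMH volume into periventricular and deep components.
# Deep fraction ~ Beta(1.2, 7) with an extra point mass at zero, loosely
# matching the study's deep/total volume ratio and deep-zero frequency.
split_wmh <- function(total) {
  n <- length(total)
  frac <- stats::rbeta(n, 1.2, 7)
  frac[stats::runif(n) < 0.2] <- 0
  deep <- total * frac
  data.frame(wmh_peri_ml = total - deep, wmh_deep_ml = deep)
}

# Logit-scale regression coefficients of the generative occupancy link.
# The slope on log WMH is chosen so the odds ratio per (theoretical)
# interquartile ratio of the non-zero volume distribution equals or_per_iqr.
occupancy_link_coef <- function(config) {
  iqr_ratio <- exp(2 * qnorm(0.75) * config$wmh_logsd)
  b_w <- if (config$wmh_logsd > 0) log(config$or_per_iqr) / log(iqr_ratio) else 0
  eff <- config$covariate_effects
  fo_target <- sum(config$target_mean_fo[1:2]) / 2
  # Centering constants keep the cohort mean occupancy at its target under
  # the default covariate marginals.
  b0 <- stats::qlogis(fo_target) - b_w * config$wmh_logmean -
    eff$age * 66 - eff$sex_female * (711 / 1651) - eff$education * 13
  c(intercept = b0, log_wmh = b_w, wmh_zero = eff$wmh_zero,
    age = eff$age, sex_female = eff$sex_female, education = eff$education)
}

#' Generate state-label sequences with a WMH-linked occupancy
#'
#' Draws, for each participant, (i) a latent high-state occupancy
#' `FO_high ~ Beta(mu * phi, (1 - mu) * phi)` whose logit mean is an affine
#' function of log WMH volume (slope calibrated to `or_per_iqr`), the
#' zero-volume indicator and the demographic covariates, and (ii) a label
#' sequence over `k` states of random length `T_i` in `volumes_range`.
#' `FO_high` is the *average* occupancy of states 1 and 2, so each of the two
#' high states receives probability `FO_high` and the remaining mass
#' `1 - 2 * FO_high` is split over the low states in proportion to
#' `target_mean_fo[3:k]`.
#'
#' @param config A [generator_config()].
#' @param wmh Numeric vector of WMH volumes (mL), as from [gen_wmh()].
#' @param covariates Covariate table, as from [gen_covariates()].
#' @return List with elements `labels` (list of integer vectors in `1..k`),
#'   `n_volumes`, `fo_true` (latent high-state occupancy), `mu` (its
#'   conditional mean), and `coef` (the true link coefficients).
#' @export
gen_state_sequences <- function(config, wmh, covariates) {
  stopifnot(inherits(config, "generator_config"))
  n <- length(wmh)
  stop_if(nrow(covariates) != n, "`wmh` and `covariates` sizes differ")
  with_seed(config$seed, {
    draw <- draw_true_occupancy(config, wmh, covariates)
    tt <- sample(config$volumes_range[1]:config$volumes_range[2], n, replace = TRUE)
    labels <- vector("list", n)
    for (i in seq_len(n)) {
      labels[[i]] <- draw_labels(state_probs(config, draw$fo[i]), tt[i],
                                 config$persistence)
    }
    list(labels = labels, n_volumes = tt, fo_true = draw$fo, mu = draw$mu,
         coef = draw$coef)
  })
}

# Latent per-participant high-state occupancy and its conditional mean.
draw_true_occupancy <- function(config, wmh, covariates) {
  tw <- transform_wmh(wmh)
  cf <- occupancy_link_coef(config)
  eta <- cf["intercept"] + cf["log_wmh"] * tw$log_wmh + cf["wmh_zero"] * tw$wmh_zero +
    cf["age"] * covariates$age + cf["sex_female"] * (covariates$sex == "female") +
    cf["education"] * covariates$education_years
  stop_if(any(!is.finite(eta)), "overflow in the occupancy link")
  mu <- stats::plogis(eta)
  phi <- config$beta_dispersion
  fo <- stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
  # FO_high is the mean of two state occupancies, so 2 * FO_high must stay
  # below 1; with mu ~ 0.25 a violation is astronomically rare.
  bad <- which(fo >= 0.5 | fo <= 0)
  while (length(bad)) {
    fo[bad] <- stats::rbeta(length(bad), mu[bad] * phi, (1 - mu[bad]) * phi)
    bad <- bad[fo[bad] >= 0.5 | fo[bad] <= 0]
  }
  list(fo = fo, mu = mu, coef = cf)
}

state_probs <- function(config, fo_high) {
  k <- config$k_states
  low <- config$target_mean_fo[3:k]
  c(fo_high, fo_high, (1 - 2 * fo_high) * low / sum(low))
}

draw_labels <- function(prob, t_i, persistence = 0) {
  k <- length(prob)
  if (persistence == 0) {
    return(sample.int(k, t_i, replace = TRUE, prob = prob))
  }
  lab <- integer(t_i)
  lab[1] <- sample.int(k, 1L, prob = prob)
  for (t in 2:t_i) {
    lab[t] <- if (stats::runif(1) < persistence) lab[t - 1L] else
      sample.int(k, 1L, prob = prob)
  }
  lab
}

#' Generate one participant's parcel-level BOLD series
#'
#' Each retained volume equals the planted centroid of its state label plus
#' i.i.d. Gaussian parcel noise.
#'
#' @param config A [generator_config()].
#' @param label_sequence Integer vector of state labels in `1..k_states`.
#' @param centroids Optional centroid matrix, defaults to
#'   [state_centroids()] of `config`.
#' @return Numeric matrix `n_parcels x length(label_sequence)` (a parcel
#'   time-series with volumes as columns).
#' @export
gen_bold <- function(config, label_sequence, centroids = state_centroids(config)) {
  stopifnot(inherits(config, "generator_config"))
  stop_if(ncol(centroids) != config$n_parcels, "`n_parcels` mismatch with centroids")
  stop_if(any(label_sequence < 1 | label_sequence > nrow(centroids)),
          "labels outside 1..k")
  with_seed(config$seed, {
    x <- t(centroids[label_sequence, , drop = FALSE])
    if (config$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), 0, config$noise_sd), nrow(x), ncol(x))
    }
    x
  })
}

#' Generate Trail Making Test B completion times
#'
#' `E[TMT_i] = exp(c0 + 20 * log(m5) * FO_high_i + nuisance)` where `m5` is the
#' multiplier per 5 percentage points of occupancy (the factor 20 converts
#' "per 5 pp" to "per unit proportion"), and `TMT_i` is Gamma with shape
#' `gamma_shape` around that mean. The intercept is centred so the median time
#' is near 83 s under the default covariate marginals.
#'
#' @param config A [generator_config()].
#' @param fo_high True high-state occupancy (proportion), per participant.
#' @param covariates Covariate table from [gen_covariates()].
#' @param wmh WMH volumes (mL).
#' @return Numeric vector of TMT-B times in seconds (with `NA`s when
#'   `missing_tmt_prob > 0`).
#' @export
gen_tmt <- function(config, fo_high, covariates, wmh) {
  stopifnot(inherits(config, "generator_config"))
  n <- length(fo_high)
  stop_if(length(wmh) != n || nrow(covariates) != n, "input sizes differ")
  with_seed(config$seed, {
    tw <- transform_wmh(wmh)
    eff <- config$tmt_effects
    b_fo <- 20 * log(config$tmt_multiplier_per_5pp)
    fo_target <- sum(config$target_mean_fo[1:2]) / 2
    c0 <- log(83) - b_fo * fo_target - eff$age * 66 - eff$sex_female * (711 / 1651) -
      eff$education * 13 - eff$wmh * config$wmh_logmean
    eta <- c0 + b_fo * fo_high + eff$age * covariates$age +
      eff$sex_female * (covariates$sex == "female") +
      eff$education * covariates$education_years +
      eff$wmh * tw$log_wmh + eff$wmh_zero * tw$wmh_zero
    stop_if(any(!is.finite(eta)), "non-positive or non-finite TMT mean")
    y <- stats::rgamma(n, shape = config$gamma_shape,
                       rate = config$gamma_shape / exp(eta))
    if (config$missing_tmt_prob > 0) {
      y[stats::runif(n) < config$missing_tmt_prob] <- NA_real_
    }
    y
  })
}

#' Generate a bounded cognitive score
#'
#' Binomial score (e.g. a 0--30 screening instrument) with logit-linear
#' success probability in the high-state occupancy; the effect is specified as
#' an odds ratio per 20 percentage points of occupancy.
#'
#' @param config A [generator_config()].
#' @param fo_high True high-state occupancy (proportion), per participant.
#' @param max_score Number of items (binomial size).
#' @param or_per_20pp Odds ratio on item success per +20 pp occupancy.
#' @param base_prob Success probability at the cohort-target occupancy.
#' @return Integer vector of scores in `0..max_score`.
#' @export
gen_bounded_score <- function(config, fo_high, max_score = 30,
                              or_per_20pp = 1.19, base_prob = 0.9) {
  stopifnot(inherits(config, "generator_config"))
  stop_if(!is_count(max_score), "`max_score` must be a positive integer")
  fo_target <- sum(config$target_mean_fo[1:2]) / 2
  p <- stats::plogis(stats::qlogis(base_prob) +
                       log(or_per_20pp) / 0.20 * (fo_high - fo_target))
  with_seed(config$seed, stats::rbinom(length(fo_high), max_score, p))
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generative chain: covariates, WMH volumes (with a
#' periventricular/deep split), latent occupancies, state-label sequences,
#' realized fractional occupancies, TMT-B times, and (optionally) parcel-level
#' BOLD series. All stages draw from child streams of `config$seed`, so the
#' same configuration reproduces the same cohort bit for bit.
#'
#' @param config A [generator_config()].
#' @param include_bold Generate BOLD matrices (memory-heavy; default `FALSE`).
#' @param include_sequences Keep the per-participant label sequences. When
#'   `FALSE` (and `persistence == 0`), state counts are drawn directly from
#'   the equivalent multinomial, which is much faster for regression-scale
#'   simulation.
#' @return Object of class `cap_cohort`: a list with `phenotype` (data frame
#'   incl. realized `fo_1..fo_k` and `fo_high`), `occupancy` (matrix),
#'   `sequences`, `bold`, `truth` (latent occupancies, link coefficients,
#'   centroids) and `config`.
#' @export
simulate_cohort <- function(config = generator_config(),
                            include_bold = FALSE,
                            include_sequences = include_bold) {
  stopifnot(inherits(config, "generator_config"))
  stop_if(include_bold && !include_sequences,
          "BOLD generation requires label sequences")
  n <- config$n_participants
  k <- config$k_states
  seeds <- lapply(1:6, function(i) child_seed(config$seed, i))

  cov <- gen_covariates(sub_cfg(config, seeds[[1]]))
  wmh <- gen_wmh(sub_cfg(config, seeds[[2]]))
  pd <- with_seed(seeds[[3]], split_wmh(wmh))

  sequences <- NULL
  if (include_sequences) {
    seqs <- gen_state_sequences(sub_cfg(config, seeds[[4]]), wmh, cov)
    counts <- t(vapply(seqs$labels, function(l) tabulate(l, nbins = k),
                       integer(k)))
    sequences <- seqs$labels
    tt <- seqs$n_volumes
    fo_true <- seqs$fo_true
    true_coef <- seqs$coef
  } else {
    fast <- with_seed(seeds[[4]], {
      draw <- draw_true_occupancy(config, wmh, cov)
      tt <- sample(config$volumes_range[1]:config$volumes_range[2], n,
                   replace = TRUE)
      counts <- matrix(0L, n, k)
      for (i in seq_len(n)) {
        counts[i, ] <- stats::rmultinom(1, tt[i], state_probs(config, draw$fo[i]))
      }
      list(draw = draw, tt = tt, counts = counts)
    })
    counts <- fast$counts
    tt <- fast$tt
    fo_true <- fast$draw$fo
    true_coef <- fast$draw$coef
  }

  occupancy <- counts / tt
  colnames(occupancy) <- paste0("fo_", seq_len(k))
  rownames(occupancy) <- cov$id
  fo_high <- rowMeans(occupancy[, 1:2, drop = FALSE])

  tmt <- gen_tmt(sub_cfg(config, seeds[[5]]), fo_true, cov, wmh)

  bold <- NULL
  if (include_bold) {
    cent <- state_centroids(config)
    bold <- with_seed(seeds[[6]], lapply(sequences, function(l)
      gen_bold(sub_cfg(config, NULL), l, cent)))
    names(bold) <- cov$id
  }

  phenotype <- cbind(cov,
                     data.frame(wmh_total_ml = wmh,
                                wmh_peri_ml = pd$wmh_peri_ml,
                                wmh_deep_ml = pd$wmh_deep_ml,
                                tmt_b_s = tmt,
                                n_volumes = tt,
                                fo_high = fo_high),
                     as.data.frame(occupancy))
  structure(list(phenotype = phenotype, occupancy = occupancy,
                 sequences = sequences, bold = bold,
                 truth = list(fo_high = fo_true, coef = true_coef,
                              centroids = state_centroids(config)),
                 config = config),
            class = "cap_cohort")
}

sub_cfg <- function(config, seed) {
  config$seed <- seed
  config
}

#' @export
print.cap_cohort <- function(x, ...) {
  cat("Synthetic brain-state cohort\n")
  cat(sprintf("  participants: %d   states: %d   parcels: %d\n",
              x$config$n_participants, x$config$k_states, x$config$n_parcels))
  cat(sprintf("  WMH median %.2f mL (%.1f%% zero)   BOLD: %s\n",
              stats::median(x$phenotype$wmh_total_ml),
              100 * mean(x$phenotype$wmh_total_ml == 0),
              if (is.null(x$bold)) "not generated" else "generated"))
  invisible(x)
}

#' Generate synthetic lesion and ventricle masks
#'
#' Builds a 3-D fixture for the WMH quantification tools: a central
#' ellipsoidal "ventricle" blob and ellipsoid-packed lesion clusters of known
#' voxel counts, together with exact ground truth (per-lesion voxel counts,
#' distances to the nearest ventricle voxel, and the resulting total /
#' periventricular / deep volumes after cluster-size filtering).
#'
#' @param shape Integer triple: grid dimensions.
#' @param voxel_spacing Positive numeric triple: voxel spacing in mm.
#' @param lesion_spec `data.frame` with columns `x`, `y`, `z` (centre voxel
#'   indices) and `n_voxels` (cluster size); may have zero rows.
#' @param seed Unused placeholder for interface symmetry (construction is
#'   deterministic); kept for future stochastic placement.
#' @param ventricle_radius_mm Radius of the central ventricle blob (mm).
#' @param min_voxels,cutoff_mm Ground-truth filtering and partition settings.
#' @return List with `lesions` and `ventricles` (binary arrays), `spacing`,
#'   and `truth` (per-lesion table plus `total_ml`, `peri_ml`, `deep_ml`).
#' @export
gen_masks <- function(shape = c(32L, 32L, 32L),
                      voxel_spacing = c(1, 1, 1),
                      lesion_spec = data.frame(x = integer(), y = integer(),
                                               z = integer(), n_voxels = integer()),
                      seed = NULL,
                      ventricle_radius_mm = 4,
                      min_voxels = 30, cutoff_mm = 10) {
  stop_if(length(shape) != 3L || any(shape < 4), "`shape` must be 3 dims >= 4")
  stop_if(length(voxel_spacing) != 3L || any(voxel_spacing <= 0),
          "`voxel_spacing` must be positive (mm)")
  shape <- as.integer(shape)
  centre <- (shape + 1) / 2

  grid <- as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                                z = seq_len(shape[3])))
  mm <- sweep(grid, 2, voxel_spacing, `*`)
  cen_mm <- centre * voxel_spacing
  vent <- array(0L, shape)
  vent[sqrt(colSums((t(mm) - cen_mm)^2)) <= ventricle_radius_mm] <- 1L
  stop_if(sum(vent) == 0, "ventricle blob empty; enlarge `ventricle_radius_mm`")

  lesions <- array(0L, shape)
  rows <- vector("list", nrow(lesion_spec))
  for (j in seq_len(nrow(lesion_spec))) {
    ls <- lesion_spec[j, ]
    stop_if(ls$n_voxels < 1, "lesion `n_voxels` must be >= 1")
    d2 <- colSums((t(mm) - c(ls$x, ls$y, ls$z) * voxel_spacing)^2)
    pick <- order(d2, seq_along(d2))[seq_len(ls$n_voxels)]
    vox <- grid[pick, , drop = FALSE]
    stop_if(any(vox == 1L) || any(sweep(vox, 2, shape, `==`)),
            "lesion ", j, " overlaps the image boundary")
    lesions[pick] <- 1L
    # exact voxel-centre distance to the nearest ventricle voxel centre
    vmm <- mm[vent == 1L, , drop = FALSE]
    dmin <- apply(mm[pick, , drop = FALSE], 1, function(p)
      sqrt(min(colSums((t(vmm) - p)^2))))
    rows[[j]] <- data.frame(lesion = j, n_voxels = ls$n_voxels,
                            sub_threshold = ls$n_voxels < min_voxels,
                            n_peri = sum(dmin <= cutoff_mm),
                            n_deep = sum(dmin > cutoff_mm))
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lesion = integer(), n_voxels = integer(),
               sub_threshold = logical(), n_peri = integer(), n_deep = integer())
  vx_ml <- prod(voxel_spacing) / 1000
  kept <- truth[!truth$sub_threshold, , drop = FALSE]
  truth_vol <- list(total_ml = sum(kept$n_voxels) * vx_ml,
                    peri_ml = sum(kept$n_peri) * vx_ml,
                    deep_ml = sum(kept$n_deep) * vx_ml)
  list(lesions = lesions, ventricles = vent, spacing = voxel_spacing,
       truth = c(list(lesion_table = truth), truth_vol))
}
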