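test_that("covariate marginals hit the population targets", {
  cfg <- generator_config(seed = 101)
  cov <- gen_covariates(cfg)
  expect_equal(nrow(cov), 1651L)
  expect_lt(abs(median(cov$age) - 66), 2)
  expect_lt(abs(quantile(cov$age, 0.25) - 59), 3)
  expect_lt(abs(quantile(cov$age, 0.75) - 72), 3)
  expect_lt(abs(mean(cov$sex == "male") - 0.57), 0.04)
  expect_lt(abs(median(cov$education_years) - 13), 1.01)

  one <- gen_covariates(generator_config(seed = 5), n = 1)
  expect_equal(nrow(one), 1L)
  expect_true(is.finite(one$age) && one$sex %in% c("male", "female"))

  cfg2 <- generator_config(n_participants = 10000, seed = 77)
  expect_identical(gen_covariates(cfg2), gen_covariates(cfg2))
  expect_error(generator_config(n_participants = 0), "positive integer")
})

test_that("WMH volumes are zero-inflated log-normal with the study's spread", {
  cfg <- generator_config(n_participants = 1e5, seed = 11)
  v <- gen_wmh(cfg)
  nz <- v[v > 0]
  q <- quantile(nz, c(0.25, 0.5, 0.75), names = FALSE)
  expect_lt(abs(q[3] / q[1] - 5.06), 0.3)
  expect_lt(abs(q[2] - 1.05), 0.1)
  expect_lt(abs(mean(v == 0) - 9 / 1651), 0.003)

  all0 <- gen_wmh(generator_config(n_participants = 50, seed = 1,
                                   zero_wmh_prob = 1))
  expect_true(all(all0 == 0))

  const <- gen_wmh(generator_config(n_participants = 50, seed = 1,
                                    wmh_logsd = 0, zero_wmh_prob = 0))
  expect_true(all(abs(const - exp(log(1.05))) < 1e-12))
  expect_error(generator_config(wmh_logsd = -1), ">= 0")
})

test_that("non-zero WMH volumes pass a log-normality check at n = 1e4", {
  cfg <- generator_config(n_participants = 12000, seed = 19)
  v <- gen_wmh(cfg)
  lv <- log(v[v > 0])[1:10000]
  ks <- suppressWarnings(ks.test(lv, "pnorm", mean(lv), sd(lv)))
  expect_gt(ks$p.value, 0.01)
})

test_that("state sequences have the null-link mean and valid structure", {
  cfg <- generator_config(n_participants = 2000, seed = 23, or_per_iqr = 1,
                          covariate_effects = list(age = 0, sex_female = 0,
                                                   education = 0, wmh_zero = 0))
  cov <- gen_covariates(cfg)
  wmh <- gen_wmh(cfg)
  seqs <- gen_state_sequences(cfg, wmh, cov)
  fo_target <- sum(cfg$target_mean_fo[1:2]) / 2
  expect_lt(abs(mean(seqs$fo_true) - fo_target),
            3 * sd(seqs$fo_true) / sqrt(2000))
  expect_true(all(seqs$n_volumes >= 100 & seqs$n_volumes <= 125))
  expect_true(all(unlist(seqs$labels) %in% 1:5))
  expect_true(all(lengths(seqs$labels) == seqs$n_volumes))
})

test_that("realized mean occupancy matches the target profile", {
  co <- simulate_cohort(generator_config(n_participants = 2000, seed = 31),
                        include_sequences = FALSE)
  m <- colMeans(co$occupancy)
  se <- apply(co$occupancy, 2, sd) / sqrt(nrow(co$occupancy))
  # the two high states are exchangeable under the label law (each receives
  # probability FO_high), so their generative means are both the average of
  # the first two targets; the low states keep their individual targets
  tgt <- co$config$target_mean_fo
  implied <- c(rep(mean(tgt[1:2]), 2), tgt[3:5])
  expect_true(all(abs(m - implied) < 3 * se + 1e-4))
  expect_true(all(abs(rowSums(co$occupancy) - 1) < 1e-12))
})

test_that("beta regression refit recovers the planted WMH-occupancy link", {
  co <- simulate_cohort(generator_config(n_participants = 5000, seed = 37),
                        include_sequences = FALSE)
  fit <- run_primary(co)$fit
  b_true <- unname(co$truth$coef["log_wmh"])
  expect_equal(b_true, log(0.95) / log(5.06), tolerance = 1e-10)
  expect_lt(abs(coef(fit)["log_wmh"] - b_true), 2 * fit$se["log_wmh"])
})

test_that("Gamma GLM refit recovers the planted TMT multiplier", {
  co <- simulate_cohort(generator_config(n_participants = 5000, seed = 41),
                        include_sequences = FALSE)
  sec <- run_secondary(co)
  b_true <- 20 * log(0.98)
  expect_lt(abs(coef(sec$fit)["fo_high"] - b_true),
            2.5 * sec$fit$se["fo_high"])
  expect_true(sec$effect$conf.low <= 0.98 && 0.98 <= sec$effect$conf.high)
})

test_that("TMT generator degenerates correctly at null and low noise", {
  cfg <- generator_config(n_participants = 3000, seed = 43,
                          tmt_multiplier_per_5pp = 1,
                          tmt_effects = list(age = 0, sex_female = 0,
                                             education = 0, wmh = 0,
                                             wmh_zero = 0))
  cov <- gen_covariates(cfg)
  wmh <- gen_wmh(cfg)
  fo <- runif(3000, 0.15, 0.35)
  y <- gen_tmt(cfg, fo, cov, wmh)
  sl <- summary(lm(log(y) ~ fo))$coefficients["fo", ]
  expect_lt(abs(sl["Estimate"]), 2.5 * sl["Std. Error"])

  cfg2 <- generator_config(n_participants = 500, seed = 44, gamma_shape = 1e6)
  y2 <- gen_tmt(cfg2, rep(0.25, 500), gen_covariates(cfg2),
                gen_wmh(cfg2))
  expect_lt(sd(y2) / mean(y2), 0.35)  # only covariate spread remains
})

test_that("BOLD volumes equal centroids at zero noise and are reproducible", {
  cfg <- generator_config(n_participants = 2, seed = 3, n_parcels = 21,
                          noise_sd = 0)
  labs <- c(1L, 2L, 5L, 3L)
  x <- gen_bold(cfg, labs)
  expect_identical(dim(x), c(21L, 4L))
  expect_equal(x, t(state_centroids(cfg)[labs, ]), ignore_attr = TRUE)

  cfg$noise_sd <- 0.5
  expect_identical(gen_bold(cfg, labs), gen_bold(cfg, labs))
  bad_cent <- matrix(0, 5, 10)
  expect_error(gen_bold(cfg, labs, centroids = bad_cent), "mismatch")
})

test_that("simulated cohorts are bit-identical under a fixed seed", {
  cfg <- generator_config(n_participants = 25, seed = 99, n_parcels = 30,
                          volumes_range = c(20L, 25L))
  a <- simulate_cohort(cfg, include_bold = TRUE)
  b <- simulate_cohort(cfg, include_bold = TRUE)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$bold, b$bold)
})

test_that("markov persistence keeps the occupancy law but adds dwell", {
  cfg <- generator_config(n_participants = 300, seed = 55, persistence = 0.4,
                          volumes_range = c(120L, 125L))
  co <- simulate_cohort(cfg, include_sequences = TRUE, include_bold = FALSE)
  m <- colMeans(co$occupancy)
  expect_true(all(abs(m - cfg$target_mean_fo) < 0.02))
  runs <- mean(unlist(lapply(co$sequences, function(l) rle(l)$lengths)))
  expect_gt(runs, 1.5)  # longer dwells than the iid baseline (~1.3)
})

test_that("gen_masks records exact ground truth", {
  mk <- gen_masks(shape = c(40, 40, 40),
                  lesion_spec = data.frame(x = 20, y = 20, z = 30,
                                           n_voxels = 100))
  expect_false(mk$truth$lesion_table$sub_threshold)
  expect_equal(mk$truth$peri_ml, 0.1)
  expect_equal(mk$truth$deep_ml, 0)

  sub <- gen_masks(shape = c(32, 32, 32),
                   lesion_spec = data.frame(x = 8, y = 8, z = 26,
                                            n_voxels = 29))
  expect_true(sub$truth$lesion_table$sub_threshold)
  expect_equal(sub$truth$total_ml, 0)

  none <- gen_masks(shape = c(16, 16, 16))
  expect_equal(sum(none$lesions), 0)
  expect_error(gen_masks(shape = c(16, 16, 16),
                         lesion_spec = data.frame(x = 1, y = 8, z = 8,
                                                  n_voxels = 50)),
               "boundary")
})
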