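# build a scaled_profiles-like tibble directly for unit tests
manual_profile <- function(zbar_wt, zbar_ko = zbar_wt,
                           sem = 0, times = c(0, 1, 3, 5)) {
  dplyr::bind_rows(
    tibble::tibble(feature = "f", genotype = "WT", time_days = times,
                   zbar = zbar_wt, sem = sem, n = 10L,
                   direction = "increase", flat = FALSE),
    tibble::tibble(feature = "f", genotype = "KO", time_days = times,
                   zbar = zbar_ko, sem = sem, n = 10L,
                   direction = "increase", flat = FALSE))
}

test_that("min-max scaling and orientation follow the documented rules", {
  z <- toy_features(
    cbind(up = c(0.1, 0.9, 0.5, 0.2, 0.1, 0.9, 0.5, 0.2),
          down = c(0.9, 0.1, 0.5, 0.8, 0.9, 0.1, 0.5, 0.8)),
    genotype = rep(c("WT", "KO"), each = 4),
    time = rep(c(0, 1, 3, 5), 2))
  prof <- scale_profiles(z)
  up <- prof[prof$feature == "up" & prof$genotype == "WT", ]
  expect_equal(up$zbar[order(up$time_days)], c(0, 1, 0.5, 0.125))
  expect_equal(unique(up$direction), "increase")
  down <- prof[prof$feature == "down" & prof$genotype == "WT", ]
  # maximal deviation is downward: profile flipped before indexing
  expect_equal(unique(down$direction), "decrease")
  expect_equal(down$zbar[order(down$time_days)], c(0, 1, 0.5, 0.125))
})

test_that("scaled SEM is the raw SEM divided by the profile range", {
  set.seed(17)
  vals <- rnorm(40, mean = rep(c(0, 3, 2, 1), each = 10), sd = 0.5)
  z <- toy_features(cbind(f = vals),
                    genotype = rep("WT", 40),
                    time = rep(c(0, 1, 3, 5), each = 10))
  z$genotype <- rep(c("WT", "KO"), 20)  # both genotypes present, same values
  prof <- scale_profiles(z)
  raw_means <- tapply(vals, list(z$genotype, z$time_days), mean)
  rng <- max(raw_means) - min(raw_means)
  raw_sem <- tapply(vals[z$genotype == "WT"],
                    z$time_days[z$genotype == "WT"],
                    function(v) sd(v) / length(v))
  got <- prof[prof$genotype == "WT", ]
  expect_equal(got$sem[order(got$time_days)],
               as.numeric(raw_sem) / rng, tolerance = 1e-12)
})

test_that("flat profiles are flagged and excluded", {
  z <- toy_features(cbind(flat = rep(1, 8), ok = c(1:4, 1:4)),
                    genotype = rep(c("WT", "KO"), each = 4),
                    time = rep(c(0, 1, 3, 5), 2))
  prof <- scale_profiles(z)
  expect_true(all(prof$flat[prof$feature == "flat"]))
  est <- estimate_adaptation(prof)
  expect_false("flat" %in% est$feature)
})

test_that("the adaptation index follows its closed form", {
  expect_equal(adaptation_index(c(0, 1, 0.5, 0), c(0, 1, 3, 5)), 1)
  expect_equal(adaptation_index(c(0, 1, 1, 1), c(0, 1, 3, 5)), 0)
  expect_equal(adaptation_index(c(0, 1, 0.5, 0.25), c(0, 1, 3, 5)), 0.75)
  expect_error(adaptation_index(c(0.5, 0.5), c(0, 5)), "peak")
})

test_that("propagated variance matches the partial derivatives", {
  expect_equal(adaptation_variance(0, 1, 0.5, sem_peak = 0, sem_final = 0), 0)
  # dA/dz_final = -1 when the excursion is unit-sized
  expect_equal(adaptation_variance(0, 1, 0.5, sem_peak = 0, sem_final = 0.1),
               0.01)
})

test_that("propagated variance agrees with Monte-Carlo error propagation", {
  set.seed(18)
  cases <- list(c(z0 = 0, zp = 1, zf = 0.3, sp = 0.05, sf = 0.08),
                c(z0 = 0.1, zp = 0.9, zf = 0.25, sp = 0.1, sf = 0.06),
                c(z0 = 0, zp = 0.8, zf = 0.6, sp = 0.04, sf = 0.12))
  for (cs in cases) {
    n_mc <- 1e5
    zp <- rnorm(n_mc, cs["zp"], cs["sp"])
    zf <- rnorm(n_mc, cs["zf"], cs["sf"])
    a_mc <- 1 - (zf - cs["z0"]) / (zp - cs["z0"])
    v_mc <- var(a_mc)
    v_an <- adaptation_variance(cs["z0"], cs["zp"], cs["zf"],
                                sem_peak = cs["sp"], sem_final = cs["sf"])
    expect_equal(unname(v_an), v_mc, tolerance = 0.05)
  }
})

test_that("the index is invariant to affine rescaling of the raw profile", {
  set.seed(19)
  for (i in 1:10) {
    base <- c(0, runif(3))
    a <- runif(1, 0.5, 3)
    b <- runif(1, -2, 2)
    expect_equal(adaptation_index(base, c(0, 1, 3, 5)),
                 adaptation_index((a * base + b - b) / a, c(0, 1, 3, 5)))
  }
  # scale_profiles removes affine transformations before indexing
  vals <- rep(c(0, 3, 2, 1), each = 6) + rnorm(24, 0, 0.1)
  z1 <- toy_features(cbind(f = vals), genotype = rep(c("WT", "KO"), 12),
                     time = rep(c(0, 1, 3, 5), each = 6))
  z2 <- z1
  z2$f <- 5 * z2$f - 2
  e1 <- estimate_adaptation(scale_profiles(z1))
  e2 <- estimate_adaptation(scale_profiles(z2))
  expect_equal(e1$A, e2$A, tolerance = 1e-10)
})

test_that("eligibility applies all five thresholds and direction matching", {
  expect_true(eligible_for_comparison(0.8, 0.9, "increase", "increase"))
  expect_false(eligible_for_comparison(0.4, 0.9, "increase", "increase"))
  expect_false(eligible_for_comparison(1.3, 0.9, "increase", "increase"))
  expect_false(eligible_for_comparison(0.8, -0.3, "increase", "increase"))
  expect_false(eligible_for_comparison(0.8, 0.9, "increase", "decrease"))
})

test_that("equal indices give a null comparison; p matches the t CDF", {
  prof <- manual_profile(c(0, 1, 0.5, 0.2), sem = 0.05)
  est <- estimate_adaptation(prof)
  cmp <- compare_adaptation(est)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p, 1)
  # asymmetric case: two-tailed p equals numeric integration of the density
  prof2 <- manual_profile(c(0, 1, 0.5, 0.3), c(0, 1, 0.4, 0.05), sem = 0.05)
  cmp2 <- compare_adaptation(estimate_adaptation(prof2))
  p_quad <- 2 * stats::integrate(function(x) stats::dt(x, cmp2$df),
                                 abs(cmp2$statistic), Inf)$value
  expect_equal(cmp2$p, p_quad, tolerance = 1e-6)
  # vanishing uncertainty with a real difference drives p to zero
  prof3 <- manual_profile(c(0, 1, 0.5, 0.3), c(0, 1, 0.4, 0.05), sem = 1e-9)
  expect_lt(compare_adaptation(estimate_adaptation(prof3))$p, 1e-12)
})

test_that("feature-set dynamics give a valid ANOVA and calibrated post-hocs", {
  set.seed(20)
  # identical groups: post-hoc p-values all near 1 under the Sidak family
  n <- 240
  z0 <- toy_features(cbind(f1 = rnorm(n), f2 = rnorm(n)),
                     genotype = rep(c("WT", "KO"), n / 2),
                     time = rep(c(0, 1, 3, 5), each = n / 4))
  fs <- tibble::tibble(feature = c("f1", "f2"), feature_set = "fs1")
  res0 <- featureset_dynamics(z0, fs)
  expect_gt(min(res0$posthoc$p), 0.05)
  expect_gt(stats::median(res0$posthoc$p), 0.5)
  expect_equal(nrow(res0$anova), 4)  # genotype, time, interaction, residuals

  # balanced two-factor design with known cell means: F matches the
  # textbook decomposition computed directly
  g <- rep(c("WT", "KO"), n / 2)
  tm <- rep(c(0, 1, 3, 5), each = n / 4)
  mu <- 0.8 * (g == "KO") + 0.5 * tm
  y <- mu + rnorm(n, 0, 0.4)
  z1 <- toy_features(cbind(f1 = y), genotype = g, time = tm)
  res1 <- featureset_dynamics(z1, tibble::tibble(feature = "f1",
                                                 feature_set = "fs1"))
  fit <- stats::aov(y ~ g * factor(tm))
  an <- stats::anova(fit)
  got <- res1$anova[res1$anova$feature_set == "fs1", ]
  expect_equal(got$statistic[1:3], an$`F value`[1:3], tolerance = 1e-8)
})

test_that("the planted soma-size effect yields a significant interaction", {
  z <- default_zscores()
  dict <- feature_dictionary(z)
  res <- featureset_dynamics(z, dict[, c("feature", "feature_set")])
  inter <- res$anova[res$anova$term == "genotype:time", ]
  expect_lt(inter$p[inter$feature_set == "fs2"], 0.001)
})

test_that("knockout adaptation dominates on the default synthetic data", {
  z <- default_zscores()
  est <- dplyr::left_join(
    estimate_adaptation(scale_profiles(z)),
    feature_dictionary(z)[, c("feature", "feature_set")], by = "feature")
  cmp <- compare_adaptation(est)
  el <- cmp[cmp$eligible & cmp$feature_set == "fs2", ]
  expect_gt(nrow(el), 0)
  # majority of eligible soma-size features: stronger knockout adaptation
  expect_gt(mean(el$A_KO > el$A_WT & el$q < 0.05), 0.5)
})
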