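test_that("steady-state degradation matches closed-form special cases", {
  # a species with no regulators: P_ss = 1, gamma_ss = 1/0.1 - 1 = 9
  sp <- tibble::tibble(species = c("A", "B"), k = 4,
                       lps_responsive = TRUE, gamma = 1, c_ss = 0.1)
  lone <- cytokine_network(
    species = sp,
    edges = tibble::tibble(source = "A", target = "B", sign = "+",
                           K = 0.1, n = 1))
  gss <- derive_steady_degradation(lone)
  expect_equal(unname(gss["A"]), 9)
  # one activator at half-max (C_ss = K, n = 1): P_ss = 0.5, gamma_ss = 4
  expect_equal(unname(gss["B"]), 0.5 / 0.1 - 1)
})

test_that("derived rates make the resting state an exact fixed point", {
  net <- cytokine_network()
  gss <- derive_steady_degradation(net)
  state <- c(setNames(net$species$c_ss, net$species$species),
             setNames(rep(0.1, net$n_stages),
                      paste0("TGFb_env_", seq_len(net$n_stages))))
  d <- network_derivatives(net, state, lps = 0, gamma_ss = gss)
  expect_lt(max(abs(d)), 1e-12)
})

test_that("too-weak production is flagged as a configuration error", {
  net <- cytokine_network()
  # a strong constant inhibitor at baseline starves TNF production
  net$edges$K[net$edges$target == "TNF" & net$edges$source == "IL10"] <- 0.001
  expect_error(derive_steady_degradation(net), "TNF")
})

test_that("Hill factors and the derivative agree with an independent oracle", {
  expect_equal(morphodyn:::hill_activation(0.5, 0.5, 1.5), 0.5)
  expect_equal(morphodyn:::hill_inhibition(0.5, 0.5, 2), 0.5)
  net <- cytokine_network()
  gss <- derive_steady_degradation(net)
  # independently coded scalar right-hand side for the default topology
  oracle <- function(y, lps) {
    hact <- function(C, K, n) C^n / (C^n + K^n)
    hinh <- function(C, K, n) K^n / (C^n + K^n)
    lf <- function(k) 1 + k * lps / (lps + 1)
    with(as.list(y), {
      c(TNF = lf(4) * hinh(IL10, 1, 2) * hinh(TGFb, 1, 2) *
          hinh(IL6, 1, 2) - 0.1 * TNF - gss[["TNF"]] * 0.1,
        IL1b = lf(4) * hact(TNF, 0.5, 1.5) * hinh(IL10, 0.5, 1.5) *
          hinh(TGFb_env_3, 0.5, 1.5) - 0.1 * IL1b - gss[["IL1b"]] * 0.1,
        IL6 = lf(4) * hact(TNF, 0.5, 1.5) * hinh(IL10, 0.5, 1.5) *
          hinh(TGFb_env_3, 0.5, 1.5) - 0.1 * IL6 - gss[["IL6"]] * 0.1,
        TGFb = 1 - 0.1 * TGFb - gss[["TGFb"]] * 0.1,
        IL10 = lf(4) * hact(TNF, 0.5, 1.5) - 0.1 * IL10 -
          gss[["IL10"]] * 0.1,
        CCL5 = lf(4) * hact(TNF, 0.5, 1.5) - 0.1 * CCL5 -
          gss[["CCL5"]] * 0.1,
        TGFb_env_1 = (IL10 - TGFb_env_1) / 6,
        TGFb_env_2 = (TGFb_env_1 - TGFb_env_2) / 6,
        TGFb_env_3 = (TGFb_env_2 - TGFb_env_3) / 6)
    })
  }
  # same near-zero attenuation of negative derivatives as the model
  soften <- function(d, y) ifelse(d < 0, d * y / (y + 1e-4), d)
  set.seed(22)
  for (i in 1:5) {
    y <- setNames(runif(9, 0.05, 1.5),
                  c(net$species$species, paste0("TGFb_env_", 1:3)))
    for (lps in c(0, 1.7)) {
      expect_equal(unname(network_derivatives(net, y, lps, gss)),
                   unname(soften(oracle(y, lps), y)), tolerance = 1e-12)
    }
  }
})

test_that("without stimulation every species stays at its resting level", {
  net <- cytokine_network()
  tr <- simulate_cytokines(net, lps_stimulus(0), t_end = 720)
  expect_lt(max(abs(tr$conc - 0.1)), 1e-6)
})

test_that("a transient stimulus produces rise, decay, and a cascade delay", {
  net <- cytokine_network()
  tr <- simulate_cytokines(net, lps_stimulus(1), t_end = 120)
  tnf <- tr[tr$species == "TNF", ]
  peak_idx <- which.max(tnf$conc)
  expect_gt(max(tnf$conc), 0.3)                      # clear response
  expect_lt(peak_idx, nrow(tnf))                     # then decays
  expect_lt(tnf$conc[nrow(tnf)], max(tnf$conc) / 2)
  # environment TGFb output peaks after microglial IL10 (cascade delay)
  t_peak <- function(spec) {
    s <- tr[tr$species == spec, ]
    s$time_h[which.max(s$conc)]
  }
  expect_gt(t_peak(paste0("TGFb_env_", net$n_stages)), t_peak("IL10"))
  expect_true(all(tr$conc >= 0))
})

test_that("cascade output delay grows with the number of stages", {
  peaks <- vapply(1:4, function(ns) {
    net <- cytokine_network(n_stages = ns)
    tr <- simulate_cytokines(net, lps_stimulus(1), t_end = 120)
    s <- tr[tr$species == paste0("TGFb_env_", ns), ]
    s$time_h[which.max(s$conc)]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("halving the reporting step leaves the trajectory unchanged", {
  net <- cytokine_network()
  a <- simulate_cytokines(net, lps_stimulus(1), t_end = 48, dt = 1)
  b <- simulate_cytokines(net, lps_stimulus(1), t_end = 48, dt = 0.5)
  shared <- a$time_h
  b_sub <- b[b$time_h %in% shared, ]
  expect_equal(a$conc, b_sub$conc, tolerance = 1e-5)
})

test_that("knockout removes the node and re-derives a valid steady state", {
  net <- cytokine_network()
  ko <- knockout(net, "IL10")
  expect_false("IL10" %in% ko$species$species)
  expect_false(any(ko$edges$source == "IL10" | ko$edges$target == "IL10"))
  expect_error(knockout(net, "IL99"), "unknown")
  # knockout network rests at its own steady state
  tr0 <- simulate_cytokines(ko, lps_stimulus(0), t_end = 240)
  mg <- tr0[tr0$species %in% ko$species$species, ]
  expect_lt(max(abs(mg$conc - 0.1)), 1e-6)
  # double knockout is order-independent
  ab <- knockout(knockout(net, "IL10"), "CCL5")
  ba <- knockout(knockout(net, "CCL5"), "IL10")
  expect_identical(ab$species, ba$species)
  expect_identical(ab$edges, ba$edges)
})

test_that("removing a species with no outgoing edges is a topological no-op", {
  net <- cytokine_network()
  ko <- knockout(net, "CCL5")  # CCL5 regulates nothing
  tr_full <- simulate_cytokines(net, lps_stimulus(1), t_end = 48)
  tr_ko <- simulate_cytokines(ko, lps_stimulus(1), t_end = 48)
  for (s in ko$species$species) {
    expect_equal(tr_ko$conc[tr_ko$species == s],
                 tr_full$conc[tr_full$species == s], tolerance = 1e-7)
  }
})

test_that("the trajectory adaptation index follows the recovery formula", {
  mk <- function(conc) {
    structure(tibble::tibble(time_h = seq_along(conc) - 1,
                             time_days = (seq_along(conc) - 1) / 24,
                             species = "TNF", conc = conc),
              class = c("cytokine_trajectory", "tbl_df", "tbl", "data.frame"))
  }
  expect_equal(trajectory_adaptation(mk(c(0.1, 1.1, 0.5, 0.1))), 1)
  expect_equal(trajectory_adaptation(mk(c(0.1, 0.6, 1.1))), 0)
  expect_equal(trajectory_adaptation(mk(c(0.1, 1.1, 0.35))), 0.75)
  expect_warning(a <- trajectory_adaptation(mk(rep(0.1, 4))), "excursion")
  expect_true(is.na(a))
})

test_that("knockout amplifies the peak and enhances low-dose adaptation", {
  net <- cytokine_network()
  dr <- dose_response(net, doses = 10^seq(-2, 2, length.out = 8))
  w <- tidyr::pivot_wider(dr, names_from = "variant",
                          values_from = c("peak", "adaptation"))
  expect_true(all(w$peak_ko >= w$peak_wt))
  low <- w[w$dose <= stats::quantile(w$dose, 0.25), ]
  expect_true(all(low$adaptation_ko >= low$adaptation_wt))
})

test_that("network constructors validate their inputs", {
  expect_error(cytokine_network(k_lps = -1), "positive")
  bad_edges <- default_edges()
  bad_edges$source[1] <- "Ghost"
  expect_error(cytokine_network(edges = bad_edges), "Ghost")
  expect_error(lps_stimulus(-1), "magnitude")
})
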