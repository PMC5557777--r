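#' Two-compartment cytokine network model
#'
#' Builds the microglia + CNS-environment cytokine network. Six microglial
#' species (TNFa, IL1b, IL6, TGFb, IL10, CCL5) follow Hill-kinetic
#' production with an LPS input multiplier, activation and inhibition
#' products over incoming edges, a concentration-dependent degradation
#' `gamma * C` and a constant degradation `gamma_ss * C_ss` chosen so
#' every species is exactly at steady state (`C_ss = 0.1`) without
#' stimulation. A first-order cascade of `n_stages` stages couples
#' microglial IL10 to CNS-environment TGFb, which feeds back as an
#' inhibitor of microglial IL1b and IL6.
#'
#' The default topology: LPS drives every microglial species except TGFb;
#' TNFa activates IL1b, IL6, IL10 and CCL5; IL10 inhibits TNFa, IL1b and
#' IL6; microglial TGFb and IL6 inhibit TNFa; environment TGFb inhibits
#' IL1b and IL6. Inhibitors of TNFa use weak-near-baseline kernels
#' (`K = 1`, `n = 2`) so baseline tone is slight and feedback engages only
#' when the inhibitor is stimulated; the IL6-TNFa edge is the secondary
#' negative feedback whose disinhibition in the IL10 knockout accelerates
#' TNFa recovery. All parameters are data, not code, and can be replaced.
#'
#' @param species Tibble with columns `species`, `k` (maximal LPS
#'   production gain), `lps_responsive`, `gamma` (1/h), `c_ss`.
#' @param edges Tibble with columns `source`, `target`, `sign` (`"+"` or
#'   `"-"`), `K`, `n`. Use source `"TGFb_env"` for the cascade output.
#' @param k_lps Half-saturation of the LPS input (arbitrary units).
#' @param n_stages,tau_a,k_a,gamma_a Cascade stage count, time constant
#'   (h), activation and degradation rates.
#' @param cascade_source,cascade_targets Microglial species driving the
#'   cascade and the cascade output's inhibition targets.
#' @return A `cytokine_network` object.
#' @examples
#' net <- cytokine_network()
#' derive_steady_degradation(net)
#' @export
cytokine_network <- function(species = default_species(),
                             edges = default_edges(),
                             k_lps = 1,
                             n_stages = 3, tau_a = 6, k_a = 1, gamma_a = 1,
                             cascade_source = "IL10",
                             cascade_targets = c("IL1b", "IL6")) {
  stopifnot(all(c("species", "k", "lps_responsive", "gamma", "c_ss") %in%
                  names(species)),
            all(c("source", "target", "sign", "K", "n") %in% names(edges)))
  if (any(species$k < 0) || any(species$gamma <= 0) || any(species$c_ss <= 0) ||
      any(edges$K <= 0) || any(edges$n <= 0) || k_lps <= 0 ||
      n_stages < 1 || tau_a <= 0 || k_a <= 0 || gamma_a <= 0) {
    abort("all rates, thresholds and cooperativities must be positive")
  }
  bad <- setdiff(c(edges$source, edges$target), c(species$species, "TGFb_env"))
  if (length(bad) > 0) {
    abort(paste0("edges refer to unknown species: ", paste(bad, collapse = ", ")))
  }
  if (!all(edges$sign %in% c("+", "-"))) abort("edge sign must be '+' or '-'")
  structure(list(species = species, edges = edges, k_lps = k_lps,
                 n_stages = as.integer(n_stages), tau_a = tau_a, k_a = k_a,
                 gamma_a = gamma_a, cascade_source = cascade_source,
                 cascade_targets = cascade_targets),
            class = "cytokine_network")
}

#' @rdname cytokine_network
#' @export
default_species <- function() {
  tibble(species = c("TNF", "IL1b", "IL6", "TGFb", "IL10", "CCL5"),
         k = 4, lps_responsive = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
         gamma = 0.1, c_ss = 0.1)
}

#' @rdname cytokine_network
#' @export
default_edges <- function() {
  dplyr::bind_rows(
    tibble(source = "TNF", target = c("IL1b", "IL6", "IL10", "CCL5"),
           sign = "+", K = 0.5, n = 1.5),
    tibble(source = "IL10", target = "TNF", sign = "-", K = 1, n = 2),
    tibble(source = "IL10", target = c("IL1b", "IL6"), sign = "-",
           K = 0.5, n = 1.5),
    tibble(source = "TGFb", target = "TNF", sign = "-", K = 1, n = 2),
    tibble(source = "IL6", target = "TNF", sign = "-", K = 1, n = 2),
    tibble(source = "TGFb_env", target = c("IL1b", "IL6"), sign = "-",
           K = 0.5, n = 1.5)
  )
}

#' @export
print.cytokine_network <- function(x, ...) {
  cat(sprintf("<cytokine_network> %d species, %d edges, %d-stage TGFb cascade\n",
              nrow(x$species), nrow(x$edges), x$n_stages))
  invisible(x)
}

#' @method tidy cytokine_network
#' @export
tidy.cytokine_network <- function(x, ...) as_tibble(x$edges)

hill_activation <- function(C, K, n) C^n / (C^n + K^n)
hill_inhibition <- function(C, K, n) K^n / (C^n + K^n)

# production term of Eqs.-style kinetics at given concentrations (no LPS
# factor); conc named vector, at_value = cascade output concentration
production_terms <- function(network, conc, at_value) {
  sp <- network$species$species
  out <- vapply(sp, function(x) {
    e <- network$edges[network$edges$target == x, , drop = FALSE]
    p <- 1
    for (i in seq_len(nrow(e))) {
      src <- e$source[i]
      Cs <- unname(if (src == "TGFb_env") at_value else conc[[src]])
      p <- p * if (e$sign[i] == "+") hill_activation(Cs, e$K[i], e$n[i]) else
        hill_inhibition(Cs, e$K[i], e$n[i])
    }
    p
  }, numeric(1))
  setNames(unname(out), sp)
}

cascade_steady <- function(network) {
  if (network$cascade_source %in% network$species$species) {
    src_ss <- network$species$c_ss[network$species$species ==
                                     network$cascade_source]
    stage1 <- network$k_a * src_ss / network$gamma_a
    (network$k_a / network$gamma_a)^(seq_len(network$n_stages) - 1) * stage1
  } else {
    rep(0, network$n_stages)   # knocked-out source: cascade rests at zero
  }
}

#' Steady-state-preserving constant degradation rates
#'
#' `gamma_ss = P_ss / C_ss - gamma` per species, where `P_ss` is the
#' production product evaluated at the resting state with no LPS; this
#' makes `dC/dt = 0` exactly at `C = C_ss`.
#'
#' @param network A [cytokine_network()].
#' @return Named numeric vector of `gamma_ss` values.
#' @export
derive_steady_degradation <- function(network) {
  css <- setNames(network$species$c_ss, network$species$species)
  at_ss <- cascade_steady(network)
  p_ss <- production_terms(network, as.list(css),
                           at_ss[network$n_stages])
  g_ss <- p_ss / css - setNames(network$species$gamma,
                                network$species$species)
  if (any(g_ss < 0)) {
    abort(paste0("steady-state production too weak for: ",
                 paste(names(g_ss)[g_ss < 0], collapse = ", "),
                 " (gamma_ss would be negative)"))
  }
  g_ss
}

#' Time derivatives of the network state
#'
#' Right-hand side of the model: microglial species follow Hill-kinetic
#' production scaled by `1 + k * LPS/(LPS + K_LPS)` for LPS-responsive
#' species, minus `gamma * C + gamma_ss * C_ss`; cascade stages follow the
#' first-order chain from microglial IL10 to environment TGFb. Negative
#' excursions are prevented by attenuating negative derivatives near zero
#' (`C/(C + 1e-4)` smoothing).
#'
#' @param network A [cytokine_network()].
#' @param state Named state vector: species then cascade stages
#'   `TGFb_env_1..n`.
#' @param lps Current LPS level.
#' @param gamma_ss Precomputed [derive_steady_degradation()] (recomputed
#'   when omitted).
#' @return Named derivative vector.
#' @export
network_derivatives <- function(network, state, lps = 0, gamma_ss = NULL) {
  if (any(!is.finite(state))) abort("non-finite state")
  gamma_ss <- gamma_ss %||% derive_steady_degradation(network)
  sp <- network$species$species
  stages <- paste0("TGFb_env_", seq_len(network$n_stages))
  y <- pmax(state[c(sp, stages)], 0)
  lfac <- 1 + network$species$k * lps / (lps + network$k_lps)
  lfac[!network$species$lps_responsive] <- 1
  P <- production_terms(network, as.list(y[sp]), y[stages[network$n_stages]])
  d_sp <- lfac * P - network$species$gamma * y[sp] -
    gamma_ss * network$species$c_ss
  src <- if (network$cascade_source %in% sp) {
    unname(y[network$cascade_source])
  } else 0
  d_a <- numeric(network$n_stages)
  d_a[1] <- (network$k_a * src - network$gamma_a * y[stages[1]]) /
    network$tau_a
  if (network$n_stages > 1) {
    for (i in 2:network$n_stages) {
      d_a[i] <- (network$k_a * y[stages[i - 1]] -
                   network$gamma_a * y[stages[i]]) / network$tau_a
    }
  }
  d <- c(unname(d_sp), d_a)
  yy <- unname(y)
  neg <- d < 0
  d[neg] <- d[neg] * yy[neg] / (yy[neg] + 1e-4)
  setNames(d, c(sp, stages))
}

# precompiled right-hand side with integer-indexed edges; numerically
# identical to network_derivatives but without per-call name lookups
compile_rhs <- function(network, gamma_ss) {
  sp <- network$species$species
  n_sp <- length(sp)
  n_st <- network$n_stages
  src <- match(network$edges$source, sp)           # NA = cascade output
  src[network$edges$source == "TGFb_env"] <- n_sp + n_st
  tgt <- match(network$edges$target, sp)
  act <- network$edges$sign == "+"
  K <- network$edges$K
  nn <- network$edges$n
  gam <- network$species$gamma
  gss_css <- unname(gamma_ss) * network$species$c_ss
  kx <- network$species$k
  resp <- network$species$lps_responsive
  k_lps <- network$k_lps
  casc_src <- match(network$cascade_source, sp)    # NA when knocked out
  tau <- network$tau_a
  k_a <- network$k_a
  g_a <- network$gamma_a
  function(t, y, parms) {
    y <- pmax(y, 0)
    lfac <- rep(1, n_sp)
    if (parms$lps > 0) {
      lfac[resp] <- 1 + kx[resp] * parms$lps / (parms$lps + k_lps)
    }
    P <- rep(1, n_sp)
    cn <- y[src]^nn
    kn <- K^nn
    f <- ifelse(act, cn / (cn + kn), kn / (cn + kn))
    for (e in seq_along(tgt)) P[tgt[e]] <- P[tgt[e]] * f[e]
    d_sp <- lfac * P - gam * y[seq_len(n_sp)] - gss_css
    src_val <- if (is.na(casc_src)) 0 else y[casc_src]
    a <- y[n_sp + seq_len(n_st)]
    d_a <- (k_a * c(src_val, a[-n_st]) - g_a * a) / tau
    d <- c(d_sp, d_a)
    neg <- d < 0
    d[neg] <- d[neg] * y[neg] / (y[neg] + 1e-4)
    list(d)
  }
}

#' Transient LPS stimulus
#'
#' @param magnitude LPS level during the stimulus (arbitrary units).
#' @param onset,duration Stimulus window in hours (defaults: onset 0,
#'   duration 16 h).
#' @return An `lps_stimulus` list.
#' @export
lps_stimulus <- function(magnitude, onset = 0, duration = 16) {
  if (magnitude < 0) abort("magnitude must be >= 0")
  if (duration <= 0) abort("duration must be positive")
  structure(list(magnitude = magnitude, onset = onset, duration = duration),
            class = "lps_stimulus")
}

#' Simulate the cytokine network
#'
#' Integrates the model with a stiff-capable solver, splitting the time
#' axis at the stimulus on/off switches so the discontinuous input is
#' handled exactly. Both compartments start at their resting state.
#'
#' @param network A [cytokine_network()].
#' @param stimulus An [lps_stimulus()].
#' @param t_end Simulation horizon in hours (must exceed the stimulus
#'   end).
#' @param dt Reporting grid step (h).
#' @param rtol,atol Solver tolerances.
#' @return A `cytokine_trajectory` tibble: `time_h`, `time_days`,
#'   `species`, `conc` (cascade stages are reported as `TGFb_env_i`).
#' @examples
#' net <- cytokine_network()
#' tr <- simulate_cytokines(net, lps_stimulus(1), t_end = 48)
#' @export
simulate_cytokines <- function(network, stimulus = lps_stimulus(1),
                               t_end = 120, dt = 0.5,
                               rtol = 1e-8, atol = 1e-10) {
  if (t_end <= stimulus$onset + stimulus$duration) {
    abort("t_end must exceed the stimulus end")
  }
  gamma_ss <- derive_steady_degradation(network)
  sp <- network$species$species
  stages <- paste0("TGFb_env_", seq_len(network$n_stages))
  y0 <- c(setNames(network$species$c_ss, sp),
          setNames(cascade_steady(network), stages))

  breaks <- sort(unique(c(0, stimulus$onset,
                          stimulus$onset + stimulus$duration, t_end)))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]
  segs <- purrr::map2(breaks[-length(breaks)], breaks[-1], c)

  rhs <- compile_rhs(network, gamma_ss)
  pieces <- list()
  y <- y0
  for (seg in segs) {
    lps_now <- if (seg[1] >= stimulus$onset &&
                   seg[2] <= stimulus$onset + stimulus$duration) {
      stimulus$magnitude
    } else 0
    times <- unique(c(seq(seg[1], seg[2], by = dt), seg[2]))
    sol <- deSolve::ode(y, times, rhs, parms = list(lps = lps_now),
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      abort(paste0("integration failed in segment [", seg[1], ", ", seg[2],
                   "] h; solver state ", attr(sol, "istate")[1]))
    }
    y <- pmax(sol[nrow(sol), -1], 0)
    names(y) <- names(y0)
    pieces[[length(pieces) + 1]] <-
      if (length(pieces) == 0) sol else sol[-1, , drop = FALSE]
  }
  wide <- as.data.frame(do.call(rbind, pieces))
  names(wide) <- c("time_h", names(y0))
  out <- wide |>
    tidyr::pivot_longer(-"time_h", names_to = "species",
                        values_to = "conc") |>
    dplyr::mutate(conc = pmax(.data$conc, 0),
                  time_days = .data$time_h / 24) |>
    dplyr::select("time_h", "time_days", "species", "conc")
  attr(out, "stimulus") <- stimulus
  class(out) <- c("cytokine_trajectory", class(out))
  out
}

#' Remove a species from the network (genetic knockout)
#'
#' Deletes the node and all incident edges; the remaining species'
#' constant degradation rates are re-derived at simulation time so the
#' knockout network has its own exact steady state. Knocking out the
#' cascade source leaves the cascade resting at zero.
#'
#' @param network A [cytokine_network()].
#' @param species Species name to remove.
#' @return The reduced `cytokine_network`.
#' @examples
#' ko <- knockout(cytokine_network(), "IL10")
#' @export
knockout <- function(network, species) {
  if (!species %in% network$species$species) {
    abort(paste0("unknown species: ", species))
  }
  network$species <- network$species[network$species$species != species, ]
  network$edges <- network$edges[network$edges$source != species &
                                   network$edges$target != species, ]
  network
}

#' Adaptation index of a simulated trajectory
#'
#' Applies the recovery index to a species' simulated curve:
#' `A = 1 - (C_final - C_0) / (C_peak - C_0)` with the peak taken as the
#' largest absolute excursion from baseline. Returns `NA` with a warning
#' when there is no excursion.
#'
#' @param trajectory A `cytokine_trajectory`.
#' @param species Species to index (default `"TNF"`).
#' @param tol Minimal excursion treated as a response.
#' @return The adaptation index (scalar).
#' @export
trajectory_adaptation <- function(trajectory, species = "TNF", tol = 1e-9) {
  tr <- trajectory[trajectory$species == species, ]
  if (nrow(tr) == 0) abort(paste0("species not in trajectory: ", species))
  conc <- tr$conc[order(tr$time_h)]
  c0 <- conc[1]
  cf <- conc[length(conc)]
  ip <- which.max(abs(conc - c0))
  cp <- conc[ip]
  if (abs(cp - c0) < tol) {
    warn("no excursion from baseline; adaptation undefined")
    return(NA_real_)
  }
  1 - (cf - c0) / (cp - c0)
}

#' LPS dose-response of peak and adaptation
#'
#' Simulates the wild-type and knockout networks over a dose grid and
#' tabulates the peak TNFa response and its adaptation index per dose.
#'
#' @param network A [cytokine_network()] (the wild type).
#' @param doses Positive, sorted LPS magnitudes.
#' @param variants Which variants to run (`"wt"`, `"ko"`).
#' @param ko_species Species removed in the knockout variant.
#' @param species Readout species.
#' @param t_end,dt Passed to [simulate_cytokines()].
#' @param stimulus_duration Stimulus duration (h).
#' @return Tibble: `dose`, `variant`, `peak`, `adaptation`.
#' @export
dose_response <- function(network, doses = 10^seq(-2, 2, length.out = 12),
                          variants = c("wt", "ko"), ko_species = "IL10",
                          species = "TNF", t_end = 120, dt = 0.5,
                          stimulus_duration = 16) {
  if (any(doses <= 0) || is.unsorted(doses)) {
    abort("doses must be positive and sorted")
  }
  nets <- list(wt = network)
  if ("ko" %in% variants) nets$ko <- knockout(network, ko_species)
  purrr::map(intersect(c("wt", "ko"), variants), function(v) {
    purrr::map(doses, function(dose) {
      tr <- simulate_cytokines(nets[[v]],
                               lps_stimulus(dose,
                                            duration = stimulus_duration),
                               t_end = t_end, dt = dt)
      trs <- tr[tr$species == species, ]
      tibble(dose = dose, variant = v, peak = max(trs$conc),
             adaptation = trajectory_adaptation(tr, species))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
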