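# Boltzmann sampling of the surrogate system under each FEP mapping potential:
# Metropolis Monte Carlo on the reaction coordinate with explicit bath modes
# (Gibbs-resampled each sweep), replicate and seed management, and a stepwise
# heating protocol standing in for the MD equilibration of the original
# simulation protocol.  Seeds are derived from the master seed by a pure
# counter mapping (no hashing): each (variant, temperature, replicate,
# window) slot owns one counter value, and the 64-bit stream seed is
# master * 2^32 + counter.

.SEED_CAP <- list(variant = 16L, t = 16L, rep = 256L, window = 512L)

# Counter for one sampling slot.  Within a replicate, window slots 0..255
# hold FEP windows and slots 256..511 the equilibration ladder stages.
.seed_counter <- function(variant_idx, t_idx, rep_idx, window_idx) {
  cap <- .SEED_CAP
  stopifnot(variant_idx < cap$variant, t_idx < cap$t,
            rep_idx < cap$rep, window_idx < cap$window)
  ((variant_idx * cap$t + t_idx) * cap$rep + rep_idx) * cap$window + window_idx
}

.sysdef <- function(sys) {
  nb <- length(sys$bath)
  list(k1 = sys$k1, x1 = sys$x1, e1 = sys$e1,
       k2 = sys$k2, x2 = sys$x2, e2p = sys$e2p,
       h12 = sys$evb$coupling_h12, x_switch = sys$x_switch,
       strain_height = sys$strain_height, strain_width = sys$strain_width,
       bath_k_reactant = vapply(sys$bath, `[[`, numeric(1), "k_reactant"),
       bath_k_ts = vapply(sys$bath, `[[`, numeric(1), "k_ts"),
       bath_width = vapply(sys$bath, `[[`, numeric(1), "width"))
}

.call_sampler <- function(sys, lam, temperature, n_steps, burn_in, stride,
                          master, counter, x0, q0, step0 = -1, tune = TRUE,
                          store_bath = FALSE) {
  .mc_sample_window(.sysdef(sys), lam, temperature,
                    as.integer(n_steps), as.integer(burn_in),
                    as.integer(stride),
                    as.integer(master %% 2^31), as.integer(counter %% 2^31),
                    x0, as.numeric(q0), step0, tune, store_bath)
}

#' Equilibrate a surrogate system by stepwise heating
#'
#' Mirrors the original protocol of heating the solvated system from 1 K to
#' the target temperature in the tetrahedral-intermediate state: short
#' Metropolis runs on the lambda = 1 mapping potential over a temperature
#' ladder, starting from the product-side minimum.
#'
#' @param sys A [surrogate_system()].
#' @param t_final Target temperature, K.
#' @param ladder Increasing temperature ladder starting at or below 10 K and
#'   ending at `t_final`; default geometric from 1 K in 25 stages.
#' @param steps_per_stage Monte Carlo steps per ladder stage.
#' @param seed Integer seed (or a list with `master` and `counter`).
#' @return An `mc_state`: list with `x`, `q`, `temperature`, `step_size`.
#' @export
equilibrate <- function(sys, t_final = 295, ladder = NULL,
                        steps_per_stage = 200, seed = 1) {
  if (is.null(ladder)) ladder <- exp(seq(log(1), log(t_final), length.out = 25))
  if (ladder[1] > 10 || any(diff(ladder) < 0) ||
      abs(ladder[length(ladder)] - t_final) > 1e-9)
    stop_coldevb("ladder must be nondecreasing, start <= 10 K and end at t_final",
                 "coldevb_config_error")
  sd <- .as_seed(seed)
  st <- .free_energy_stationary(sys, t_final)
  x <- st$x_product
  q <- rep(0, length(sys$bath))
  step <- -1
  if (steps_per_stage > 0) {
    for (i in seq_along(ladder)) {
      out <- .call_sampler(sys, lam = 1, temperature = ladder[i],
                           n_steps = steps_per_stage + 1, burn_in = 0,
                           stride = steps_per_stage + 1,
                           master = sd$master, counter = sd$counter + i - 1,
                           x0 = x, q0 = q, step0 = step, tune = TRUE)
      x <- out$x_final; q <- out$q_final; step <- out$step_size
    }
  }
  structure(list(x = x, q = q, temperature = t_final, step_size = step),
            class = "mc_state")
}

.as_seed <- function(seed) {
  if (is.list(seed)) list(master = seed$master, counter = seed$counter %||% 0)
  else list(master = seed, counter = 0)
}

#' Sample one FEP window
#'
#' Metropolis Monte Carlo targeting the density proportional to
#' \eqn{\exp(-\epsilon_m/RT)} (bath modes included), with step size tuned to
#' 30-50% acceptance during burn-in and frozen for production. Retained
#' frames are thinned by `stride`.
#'
#' @param sys A [surrogate_system()].
#' @param window One row of [make_windows()] (or a list with `index`,
#'   `lambda`).
#' @param temperature Kelvin.
#' @param n_steps Total Monte Carlo steps (burn-in plus production).
#' @param seed Integer seed, or list with `master`/`counter` components.
#' @param start Optional `mc_state` to start from; defaults to the reactant
#'   minimum for lambda < 0.5 and the product minimum otherwise.
#' @param stride Thinning stride for retained frames.
#' @param burn_in_fraction Fraction of steps discarded and used for tuning.
#' @param store_bath Also record bath coordinates in the frame table?
#' @return A `window_trajectory`: window metadata plus a frame matrix with
#'   columns `step`, `x`, `eps1`, `eps2_shifted`, `gap`, `eg`, `eps_m`.
#' @export
sample_window <- function(sys, window, temperature, n_steps = 1e4, seed = 1,
                          start = NULL, stride = 10, burn_in_fraction = 0.1,
                          store_bath = FALSE) {
  if (n_steps < 1) stop_coldevb("n_steps must be >= 1", "coldevb_config_error")
  if (temperature <= 0)
    stop_coldevb("temperature must be positive", "coldevb_config_error")
  lam <- window$lambda
  sd <- .as_seed(seed)
  if (is.null(start)) {
    st <- .free_energy_stationary(sys, temperature)
    start <- list(x = if (lam < 0.5) st$x_reactant else st$x_product,
                  q = rep(0, length(sys$bath)), step_size = -1)
  }
  burn <- max(1L, as.integer(round(n_steps * burn_in_fraction)))
  out <- .call_sampler(sys, lam, temperature, n_steps, burn, stride,
                       sd$master, sd$counter,
                       x0 = start$x, q0 = start$q,
                       step0 = start$step_size %||% -1,
                       tune = TRUE, store_bath = store_bath)
  if (!is.na(out$acceptance) && out$acceptance == 0)
    stop_coldevb(sprintf("sampler accepted no moves in window %s", window$index),
                 "coldevb_sampler_failure")
  colnames(out$frames) <- c("step", "x", "eps1", "eps2_shifted", "gap", "eg",
                            "eps_m",
                            if (store_bath) paste0("q", seq_along(sys$bath)))
  structure(list(window = list(index = window$index, lambda = lam),
                 temperature = temperature, seed = sd,
                 frames = out$frames, acceptance = out$acceptance,
                 final_state = structure(list(x = out$x_final, q = out$q_final,
                                              temperature = temperature,
                                              step_size = out$step_size),
                                         class = "mc_state")),
            class = "window_trajectory")
}

#' Run all FEP windows of one replicate
#'
#' Windows are sampled in ascending lambda; each window starts from the
#' previous window's final state, and the first from the equilibrated
#' (stepwise-heated, product-state) configuration.
#'
#' @inheritParams sample_window
#' @param windows Data frame from [make_windows()].
#' @param n_steps_per_window Monte Carlo steps per window.
#' @param seed Integer master seed or list with `master`/`counter`; window
#'   seeds are consecutive counter values.
#' @param equilibrate_first Run the heating protocol before the first window?
#' @return A `replicate_run`: list of window trajectories plus provenance.
#' @export
run_replicate <- function(sys, temperature, windows = make_windows(),
                          n_steps_per_window = 1e4, seed = 1,
                          stride = 10, burn_in_fraction = 0.1,
                          equilibrate_first = TRUE, store_bath = FALSE) {
  if (any(diff(windows$lambda) <= 0))
    stop_coldevb("windows must be in ascending lambda order", "coldevb_config_error")
  if (nrow(windows) > 256)
    stop_coldevb("at most 256 windows are supported by the seed scheme",
                 "coldevb_config_error")
  sd <- .as_seed(seed)
  state <- if (equilibrate_first)
    equilibrate(sys, t_final = temperature,
                seed = list(master = sd$master, counter = sd$counter + 256L))
  else NULL
  trajs <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    trajs[[i]] <- tryCatch(
      sample_window(sys, w, temperature, n_steps = n_steps_per_window,
                    seed = list(master = sd$master, counter = sd$counter + i - 1),
                    start = state, stride = stride,
                    burn_in_fraction = burn_in_fraction,
                    store_bath = store_bath),
      error = function(e) stop_coldevb(
        sprintf("window %d (lambda=%.3f): %s", w$index, w$lambda,
                conditionMessage(e)), "coldevb_sampler_failure"))
    state <- trajs[[i]]$final_state
  }
  structure(list(label = sys$label, temperature = temperature,
                 seed = sd, windows = windows, trajectories = trajs,
                 provenance = list(n_steps_per_window = n_steps_per_window,
                                   stride = stride,
                                   burn_in_fraction = burn_in_fraction)),
            class = "replicate_run")
}

#' Run replicates over a temperature series
#'
#' Defaults mirror the study protocol: five temperatures (285, 290, 295, 300,
#' 305 K) and 50 replicates per temperature, each replicate seeded
#' deterministically from the master seed via the counter scheme.
#'
#' @inheritParams run_replicate
#' @param temperatures Distinct temperatures, K.
#' @param n_replicates Replicates per temperature.
#' @param master_seed Integer master seed.
#' @param variant_index Counter slot distinguishing variants sharing one
#'   master seed.
#' @param reduce Optional function applied to each `replicate_run`
#'   immediately (e.g. barrier extraction); its value is stored instead of
#'   the full run, keeping memory bounded.
#' @return List with one element per temperature (each a list of replicate
#'   results) plus attribute `seed_table` documenting the counter mapping.
#' @export
run_temperature_series <- function(sys, temperatures = c(285, 290, 295, 300, 305),
                                   n_replicates = 50, master_seed = 1,
                                   windows = make_windows(),
                                   n_steps_per_window = 1e4,
                                   variant_index = 0, reduce = NULL, ...) {
  if (anyDuplicated(temperatures))
    stop_coldevb("temperatures must be distinct", "coldevb_config_error")
  out <- vector("list", length(temperatures))
  names(out) <- as.character(temperatures)
  seed_tab <- list()
  for (ti in seq_along(temperatures)) {
    runs <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      counter <- .seed_counter(variant_index, ti - 1L, r - 1L, 0L)
      seed_tab[[length(seed_tab) + 1L]] <-
        data.frame(variant_index = variant_index,
                   temperature = temperatures[ti], replicate = r,
                   counter = counter)
      run <- run_replicate(sys, temperatures[ti], windows = windows,
                           n_steps_per_window = n_steps_per_window,
                           seed = list(master = master_seed, counter = counter),
                           ...)
      runs[[r]] <- if (is.null(reduce)) run else reduce(run)
    }
    out[[ti]] <- runs
  }
  attr(out, "seed_table") <- do.call(rbind, seed_tab)
  attr(out, "master_seed") <- master_seed
  out
}
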