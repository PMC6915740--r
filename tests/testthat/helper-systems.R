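# Shared fixtures: small surrogate systems and fake trajectory objects built
# in code.

# Bath-free copy of a system (keeps diabats, strain and switching centre).
strip_bath <- function(sys) {
  surrogate_system(label = paste0(sys$label, "_bare"), evb = sys$evb,
                   k1 = sys$k1, x1 = sys$x1, e1 = sys$e1,
                   k2 = sys$k2, x2 = sys$x2, e2_raw = sys$e2_raw,
                   bath = list(), x_switch = sys$x_switch,
                   strain_height = sys$strain_height,
                   strain_width = sys$strain_width)
}

# Hand-built window trajectory with given frame columns.
fake_window <- function(gap, eps_m = 0, eg = eps_m, lambda = 0,
                        temperature = 295.15) {
  n <- length(gap)
  fr <- matrix(0, n, 7,
               dimnames = list(NULL, c("step", "x", "eps1", "eps2_shifted",
                                       "gap", "eg", "eps_m")))
  if (n > 0) {
    fr[, "step"] <- seq_len(n); fr[, "x"] <- seq_len(n)
    fr[, "eps1"] <- rep_len(eps_m, n)
    fr[, "eps2_shifted"] <- rep_len(eps_m, n) - gap
    fr[, "gap"] <- gap
    fr[, "eg"] <- rep_len(eg, n); fr[, "eps_m"] <- rep_len(eps_m, n)
  }
  structure(list(window = list(index = 0L, lambda = lambda),
                 temperature = temperature, seed = list(master = 0, counter = 0),
                 frames = fr, acceptance = 1,
                 final_state = NULL),
            class = "window_trajectory")
}

fake_replicate <- function(trajs, label = "fake") {
  structure(list(label = label, temperature = trajs[[1]]$temperature,
                 seed = list(master = 0, counter = 0),
                 windows = NULL, trajectories = trajs),
            class = "replicate_run")
}

# Published wildtype activation parameters, used repeatedly.
wt_spe_params <- function() activation_parameters("WT SPE", dh = 4.6, tds = -13.4)
wt_ppe_params <- function() activation_parameters("WT PPE", dh = 17.2, tds = -2.0)
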