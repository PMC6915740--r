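# FEP accumulation across mapping windows (Zwanzig exponential averages) and
# the EVB umbrella correction that turns window samples into a free-energy
# profile along the energy-gap coordinate, plus barrier extraction and
# replicate aggregation.

logmeanexp <- function(v) {
  m <- max(v)
  m + log(mean(exp(v - m)))
}

#' Free-energy profile container
#'
#' Binned \eqn{\Delta G(X)} along the energy-gap coordinate, normalised so
#' the reactant minimum is zero, with extracted activation and reaction free
#' energies.
#'
#' @param x_gap Bin centres of the energy gap X, kcal/mol (ascending).
#' @param dg Free energy per bin, kcal/mol; `NA` marks unsupported bins.
#' @param count Raw sample count per bin (`NA` for analytic profiles).
#' @param temperature Kelvin.
#' @param label Variant label.
#' @param kind `"sampled"` or `"analytic"`.
#' @param x_coord Optional underlying reaction-coordinate values (analytic
#'   profiles only).
#' @param normalize Shift the profile so the reactant minimum is zero?
#' @return An object of class `fe_profile` with fields `dg_act`, `dg_rxn`,
#'   `reactant`, `ts`, `product` filled by [extract_barrier()].
#' @export
fe_profile <- function(x_gap, dg, count = rep(NA_real_, length(x_gap)),
                       temperature = NA_real_, label = "system",
                       kind = "sampled", x_coord = NULL, normalize = TRUE) {
  if (is.unsorted(x_gap))
    stop_coldevb("x_gap must be ascending", "coldevb_config_error")
  p <- structure(list(x_gap = x_gap, dg = dg, count = count,
                      temperature = temperature, label = label, kind = kind,
                      x_coord = x_coord,
                      dg_act = NA_real_, dg_rxn = NA_real_,
                      reactant = NULL, ts = NULL, product = NULL),
                 class = "fe_profile")
  b <- tryCatch(extract_barrier(p, annotate = FALSE),
                coldevb_no_barrier = function(e) NULL)
  if (is.null(b)) {
    # flat or monotone profile: no barrier to annotate
    if (normalize) p$dg <- p$dg - min(p$dg, na.rm = TRUE)
    return(p)
  }
  p$dg_act <- b$dg_act; p$dg_rxn <- b$dg_rxn
  p$reactant <- b$reactant; p$ts <- b$ts; p$product <- b$product
  if (normalize) {
    p$dg <- p$dg - b$reactant$dg
    p$reactant$dg <- 0
    p$ts$dg <- p$ts$dg - b$reactant$dg
    p$product$dg <- p$product$dg - b$reactant$dg
  }
  p
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf(
    "Free-energy profile (%s) '%s' at %.2f K: dG_act = %.2f, dG_rxn = %.2f kcal/mol\n",
    x$kind, x$label, x$temperature, x$dg_act, x$dg_rxn))
  invisible(x)
}

#' Zwanzig free-energy increment between adjacent windows
#'
#' \deqn{\delta G(\lambda_m \to \lambda_{m+1}) =
#'   -RT \ln \langle e^{-(\epsilon_{m+1}-\epsilon_m)/RT} \rangle_m,}
#' where the perturbation reduces to \eqn{-\Delta\lambda \, X} on the
#' energy-gap coordinate. Stabilised with the log-sum-exp trick.
#'
#' @param traj A `window_trajectory` from [sample_window()].
#' @param lam_next Target lambda of the neighbouring window.
#' @return Free-energy increment, kcal/mol.
#' @export
zwanzig_increment <- function(traj, lam_next) {
  if (lam_next < 0 || lam_next > 1)
    stop_coldevb("lam_next must lie in [0, 1]", "coldevb_range_error")
  fr <- traj$frames
  if (is.null(fr) || nrow(fr) == 0)
    stop_coldevb("window trajectory has no frames", "coldevb_invalid_value")
  rt <- R_KCAL * traj$temperature
  dlam <- lam_next - traj$window$lambda
  du <- -dlam * fr[, "gap"]
  -rt * logmeanexp(-du / rt)
}

#' Cumulative FEP free energies over all windows
#'
#' Forward Zwanzig increments accumulated from \eqn{\lambda_0 = 0}
#' (optionally averaged with the backward estimate).
#'
#' @param rep A `replicate_run` from [run_replicate()].
#' @param direction `"forward"` (default) or `"both"`.
#' @return Numeric vector \eqn{\Delta G(\lambda_m)}, zero for the first
#'   window.
#' @export
fep_free_energies <- function(rep, direction = c("forward", "both")) {
  direction <- match.arg(direction)
  trajs <- rep$trajectories
  lam <- vapply(trajs, function(t) t$window$lambda, numeric(1))
  m <- length(trajs)
  fwd <- numeric(m)
  for (i in seq_len(m - 1))
    fwd[i + 1] <- fwd[i] + zwanzig_increment(trajs[[i]], lam[i + 1])
  if (direction == "forward") return(fwd)
  bwd <- numeric(m)
  for (i in seq_len(m - 1))
    bwd[i + 1] <- bwd[i] - zwanzig_increment(trajs[[i + 1]], lam[i])
  (fwd + bwd) / 2
}

#' EVB umbrella free-energy profile along the energy gap
#'
#' Combines the FEP window free energies with the per-bin umbrella
#' correction
#' \deqn{\Delta G(X_b) = \Delta G(\lambda_m)
#'   - RT \ln \langle \delta_b(X) e^{-(E_g-\epsilon_m)/RT} \rangle_m,}
#' estimated in every window that samples the bin with at least `min_count`
#' frames and combined across windows by sample-count weighting. Unsupported
#' bins are left `NA`, never interpolated.
#'
#' @param rep A `replicate_run`.
#' @param n_bins Number of bins over the pooled X range (>= 10).
#' @param min_count Minimum raw frames per (window, bin) for that window to
#'   contribute to the bin.
#' @param trim Quantile range of pooled X used for binning.
#' @param direction Passed to [fep_free_energies()].
#' @return An [fe_profile] (`kind = "sampled"`).
#' @export
umbrella_profile <- function(rep, n_bins = 100, min_count = 10,
                             trim = c(0.005, 0.995),
                             direction = "forward") {
  if (n_bins < 10)
    stop_coldevb("n_bins must be >= 10", "coldevb_config_error")
  trajs <- rep$trajectories
  rt <- R_KCAL * rep$temperature
  dg_lam <- fep_free_energies(rep, direction = direction)

  pooled <- unlist(lapply(trajs, function(t) t$frames[, "gap"]))
  rng <- quantile(pooled, trim, names = FALSE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  est <- matrix(NA_real_, length(trajs), n_bins)
  wt <- matrix(0, length(trajs), n_bins)
  for (m in seq_along(trajs)) {
    fr <- trajs[[m]]$frames
    idx <- findInterval(fr[, "gap"], edges, rightmost.closed = TRUE)
    keep <- idx >= 1 & idx <= n_bins
    v <- -(fr[, "eg"] - fr[, "eps_m"]) / rt
    n_tot <- nrow(fr)
    sp <- split(v[keep], idx[keep])
    for (nm in names(sp)) {
      vb <- sp[[nm]]
      if (length(vb) < min_count) next
      b <- as.integer(nm)
      est[m, b] <- dg_lam[m] - rt * (logmeanexp(vb) + log(length(vb) / n_tot))
      wt[m, b] <- length(vb)
    }
  }
  dg <- rep(NA_real_, n_bins)
  cnt <- colSums(wt)
  for (b in which(cnt > 0)) {
    ok <- !is.na(est[, b])
    dg[b] <- sum(est[ok, b] * wt[ok, b]) / sum(wt[ok, b])
  }

  sup <- which(!is.na(dg))
  if (length(sup) >= 3) {
    gaps <- setdiff(seq(min(sup), max(sup)), sup)
    if (length(gaps) > 0) {
      gap_x <- centers[gaps[ceiling(length(gaps) / 2)]]
      mean_gap <- vapply(trajs, function(t) mean(t$frames[, "gap"]), numeric(1))
      lam_near <- trajs[[which.min(abs(mean_gap - gap_x))]]$window$lambda
      stop_coldevb(sprintf(
        "barrier unresolved: no bin support near X = %.1f; densify windows near lambda = %.2f",
        gap_x, lam_near), "coldevb_unresolved_barrier")
    }
  }
  keep <- !is.na(dg)
  fe_profile(x_gap = centers[keep], dg = dg[keep], count = cnt[keep],
             temperature = rep$temperature, label = rep$label,
             kind = "sampled")
}

#' Extract activation and reaction free energies from a profile
#'
#' The transition state is the highest interior maximum lying between the
#' outermost minima; the reactant minimum is the lowest bin below it in X and
#' the product (tetrahedral-intermediate) minimum the lowest bin above it.
#'
#' @param profile An [fe_profile], or a plain numeric vector of bin free
#'   energies at ascending X (then `x_gap` may be given).
#' @param x_gap Bin centres when `profile` is a numeric vector.
#' @param annotate Internal; return the full annotation list.
#' @return List with `dg_act`, `dg_rxn` and the three stationary bins.
#' @export
extract_barrier <- function(profile, x_gap = NULL, annotate = TRUE) {
  if (is.numeric(profile)) {
    g <- profile
    x <- if (is.null(x_gap)) seq_along(g) else x_gap
  } else {
    g <- profile$dg
    x <- profile$x_gap
  }
  ok <- !is.na(g)
  g <- g[ok]; x <- x[ok]
  n <- length(g)
  if (n < 3)
    stop_coldevb("profile needs at least 3 supported bins", "coldevb_no_barrier")
  interior <- 2:(n - 1)
  is_cand <- vapply(interior, function(j)
    min(g[1:(j - 1)]) < g[j] && min(g[(j + 1):n]) < g[j], logical(1))
  if (!any(is_cand))
    stop_coldevb("profile is monotone: no barrier", "coldevb_no_barrier")
  cand <- interior[is_cand]
  j <- cand[which.max(g[cand])]
  ir <- which.min(g[1:(j - 1)])
  ip <- j + which.min(g[(j + 1):n])
  out <- list(
    dg_act = g[j] - g[ir],
    dg_rxn = g[ip] - g[ir],
    reactant = list(x_gap = x[ir], dg = g[ir]),
    ts = list(x_gap = x[j], dg = g[j]),
    product = list(x_gap = x[ip], dg = g[ip]))
  if (!annotate) return(out)
  out[c("dg_act", "dg_rxn", "reactant", "ts", "product")]
}

#' Aggregate activation free energies over replicates
#'
#' Barriers are extracted per replicate first and then averaged, preserving
#' the replicate dispersion needed for the convergence rule and the
#' bootstrap.
#'
#' @param profiles List of [fe_profile] objects sharing one temperature, or a
#'   numeric vector of per-replicate barriers.
#' @return List with `mean`, `sem`, `values`, `temperature`, `n`.
#' @export
aggregate_replicates <- function(profiles) {
  if (is.numeric(profiles)) {
    vals <- profiles
    temp <- NA_real_
  } else {
    temp <- unique(vapply(profiles, function(p) p$temperature, numeric(1)))
    if (length(temp) != 1)
      stop_coldevb("profiles mix temperatures", "coldevb_aggregation_error")
    vals <- vapply(profiles, function(p) p$dg_act, numeric(1))
  }
  n <- length(vals)
  list(mean = mean(vals), sem = if (n > 1) sd(vals) / sqrt(n) else 0,
       values = vals, temperature = temp, n = n)
}
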