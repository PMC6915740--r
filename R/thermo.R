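# Arrhenius decomposition of activation free energies into enthalpic and
# entropic components, Eyring transition-state-theory rates, replicate-batch
# convergence, variant comparison arithmetic and bootstrap uncertainties.
#
# The Arrhenius plot used throughout is dG/T versus 1/T, whose slope is the
# activation enthalpy and whose intercept is minus the activation entropy
# (dG = dH - T dS with dH, dS taken constant over the fitted range).

#' Activation parameters of an enzyme variant
#'
#' Container for \eqn{\Delta G^\ddagger(T_{ref})}, \eqn{\Delta H^\ddagger}
#' and \eqn{\Delta S^\ddagger}; constructed directly from an
#' (\eqn{\Delta H^\ddagger}, \eqn{T\Delta S^\ddagger}) pair (e.g. a row of a
#' published table) or returned by [arrhenius_fit()].
#'
#' @param label Variant label.
#' @param dh Activation enthalpy, kcal/mol.
#' @param tds Entropic component \eqn{T_{ref}\Delta S^\ddagger}, kcal/mol.
#' @param t_ref Reference temperature, K; 295.15 K is 22 degrees C.
#' @param r_squared,replicates,ci Optional fit metadata.
#' @return An object of class `activation_parameters`; its `dg` element is
#'   `dh - tds`, exact by construction.
#' @examples
#' wt_spe <- activation_parameters("WT SPE", dh = 4.6, tds = -13.4)
#' wt_spe$dg   # 18.0
#' @export
activation_parameters <- function(label, dh, tds, t_ref = 295.15,
                                  r_squared = NA_real_,
                                  replicates = NA_integer_, ci = NULL) {
  if (t_ref <= 0) stop_coldevb("t_ref must be positive", "coldevb_config_error")
  structure(list(label = label, t_ref = t_ref,
                 dg = dh - tds, dh = dh, ds = tds / t_ref, tds = tds,
                 r_squared = r_squared, replicates = replicates, ci = ci),
            class = "activation_parameters")
}

#' @export
print.activation_parameters <- function(x, ...) {
  cat(sprintf(
    "%s: dG_act(%.2f K) = %.2f, dH_act = %.2f, TdS_act = %.2f kcal/mol%s\n",
    x$label, x$t_ref, x$dg, x$dh, x$tds,
    if (is.finite(x$r_squared)) sprintf(" (R^2 = %.3f)", x$r_squared) else ""))
  invisible(x)
}

#' Arrhenius fit of activation free energies
#'
#' Ordinary least squares of \eqn{\Delta G^\ddagger/T} on \eqn{1/T}; the
#' slope is \eqn{\Delta H^\ddagger} and the intercept
#' \eqn{-\Delta S^\ddagger}. Inverse-variance weighting by the supplied
#' standard errors is available behind `weighted = TRUE`.
#'
#' @param temperature Temperatures, K (at least 3 distinct values).
#' @param dg Mean activation free energies at those temperatures, kcal/mol.
#' @param sem Optional standard errors of `dg`.
#' @param t_ref Reference temperature for reporting, K.
#' @param label Variant label.
#' @param weighted Use weights `1/sem^2`?
#' @return An [activation_parameters()] object with `r_squared` filled in.
#' @examples
#' t <- c(285, 290, 295, 300, 305)
#' dg <- 4.6 - t * (-13.4 / 295.15)
#' arrhenius_fit(t, dg)   # recovers dH = 4.6, TdS = -13.4, R^2 = 1
#' @export
arrhenius_fit <- function(temperature, dg, sem = NULL, t_ref = 295.15,
                          label = "variant", weighted = FALSE) {
  if (length(unique(temperature)) < 3)
    stop_coldevb("need at least 3 distinct temperatures", "coldevb_fit_error")
  if (length(temperature) != length(dg))
    stop_coldevb("temperature and dg lengths differ", "coldevb_fit_error")
  x <- 1 / temperature
  y <- dg / temperature
  w <- if (weighted && !is.null(sem)) (temperature / sem)^2 else NULL
  fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
  dh <- unname(coef(fit)[2])
  ds <- -unname(coef(fit)[1])
  # R^2 computed directly (summary.lm warns on exact fits)
  wts <- if (is.null(w)) rep(1, length(y)) else w
  rss <- sum(wts * fit$residuals^2)
  tss <- sum(wts * (y - sum(wts * y) / sum(wts))^2)
  r2 <- if (tss <= .Machine$double.eps * sum(wts * y^2)) 1 else 1 - rss / tss
  activation_parameters(label, dh = dh, tds = t_ref * ds, t_ref = t_ref,
                        r_squared = r2,
                        replicates = NA_integer_)
}

#' Replicate-batch convergence of the Arrhenius fit
#'
#' Implements the study's convergence rule: start with `start` replicate
#' barriers per temperature, refit after each batch of `batch` additional
#' replicates per temperature, and stop at the first fit whose regression
#' coefficient exceeds `threshold` (default 0.8).
#'
#' @param runner Function `runner(temperature)` returning one new replicate
#'   activation free energy (kcal/mol) each call.
#' @param temperatures Temperatures, K.
#' @param threshold R-squared bound to reach.
#' @param batch Replicates added per temperature per round.
#' @param start Initial replicates per temperature.
#' @param cap Maximum replicates per temperature.
#' @param t_ref,label Passed to [arrhenius_fit()].
#' @return An [activation_parameters()] with `replicates` set to the count
#'   per temperature used, plus attributes `r2_history` and `barriers` (the
#'   per-temperature replicate values).
#' @export
converge_activation <- function(runner, temperatures = c(285, 290, 295, 300, 305),
                                threshold = 0.8, batch = 10, start = 50,
                                cap = 200, t_ref = 295.15, label = "variant") {
  barriers <- lapply(temperatures, function(t)
    vapply(seq_len(start), function(i) runner(t), numeric(1)))
  names(barriers) <- as.character(temperatures)
  n <- start
  r2_history <- numeric(0)
  repeat {
    means <- vapply(barriers, mean, numeric(1))
    fit <- arrhenius_fit(temperatures, means, t_ref = t_ref, label = label)
    r2_history <- c(r2_history, fit$r_squared)
    if (fit$r_squared > threshold) {
      fit$replicates <- n
      attr(fit, "r2_history") <- r2_history
      attr(fit, "barriers") <- barriers
      return(fit)
    }
    if (n + batch > cap)
      stop(errorCondition(
        sprintf("Arrhenius fit not converged at cap = %d replicates (R^2 trajectory: %s)",
                cap, paste(sprintf("%.3f", r2_history), collapse = ", ")),
        r2_history = r2_history,
        class = c("coldevb_nonconvergence", "coldevb_error")))
    for (t in seq_along(temperatures))
      barriers[[t]] <- c(barriers[[t]],
                         vapply(seq_len(batch),
                                function(i) runner(temperatures[t]), numeric(1)))
    n <- n + batch
  }
}

#' Activation free energy at an arbitrary temperature
#'
#' \eqn{\Delta G^\ddagger(T) = \Delta H^\ddagger - T\Delta S^\ddagger} with
#' the enthalpy and entropy held constant.
#'
#' @param p An [activation_parameters()] object.
#' @param temperature Kelvin.
#' @return kcal/mol. Vectorised over `temperature`.
#' @export
delta_g_at <- function(p, temperature) {
  stopifnot(inherits(p, "activation_parameters"))
  if (any(temperature <= 0))
    stop_coldevb("temperature must be positive", "coldevb_config_error")
  p$dh - temperature * p$ds
}

#' Eyring transition-state-theory rate constant
#'
#' \deqn{k = \frac{k_B T}{h} e^{-\Delta G^\ddagger / RT}}
#' with unit transmission coefficient.
#'
#' @param dg Activation free energy, kcal/mol.
#' @param temperature Kelvin.
#' @return Rate constant, s^-1. Vectorised.
#' @examples
#' tst_rate(18.0, 295.15)   # ~0.289 s^-1, i.e. 28.9 in units of x100 s^-1
#' @export
tst_rate <- function(dg, temperature) {
  if (any(temperature <= 0))
    stop_coldevb("temperature must be positive", "coldevb_config_error")
  KB_OVER_H * temperature * exp(-dg / (R_KCAL * temperature))
}

#' Rate table at several temperatures
#'
#' Evaluates [delta_g_at()] then [tst_rate()] per variant; the printed-unit
#' column `k_x100` is the rate in s^-1 multiplied by 100, matching the
#' published table's "x100 s^-1" convention.
#'
#' @param params List of [activation_parameters()].
#' @param temps_celsius Temperatures in degrees C (default 4, 22, 39).
#' @return Data frame with columns `variant`, `temperature_c`,
#'   `temperature_k`, `dg`, `k_s`, `k_x100`.
#' @export
rate_table <- function(params, temps_celsius = c(4, 22, 39)) {
  if (inherits(params, "activation_parameters")) params <- list(params)
  rows <- list()
  for (p in params) for (tc in temps_celsius) {
    tk <- tc + 273.15
    dg <- delta_g_at(p, tk)
    k <- tst_rate(dg, tk)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = p$label, temperature_c = tc, temperature_k = tk,
      dg = dg, k_s = k, k_x100 = 100 * k)
  }
  if (length(rows) == 0)
    return(data.frame(variant = character(), temperature_c = numeric(),
                      temperature_k = numeric(), dg = numeric(),
                      k_s = numeric(), k_x100 = numeric()))
  do.call(rbind, rows)
}

#' Compare a variant against a reference variant
#'
#' Reports the activation-parameter differences and, per temperature, the
#' TST rate ratio and percent of reference activity.
#'
#' @param wt Reference [activation_parameters()].
#' @param mut Variant [activation_parameters()].
#' @param temps_celsius Temperatures in degrees C.
#' @return List with `ddg`, `ddh`, `d_tds` (mut minus wt, kcal/mol at the
#'   shared `t_ref`) and a data frame `rates` with `ratio` (mut/wt) and
#'   `percent` per temperature.
#' @export
compare_variants <- function(wt, mut, temps_celsius = c(4, 22, 39)) {
  stopifnot(inherits(wt, "activation_parameters"),
            inherits(mut, "activation_parameters"))
  if (abs(wt$t_ref - mut$t_ref) > 1e-9)
    stop_coldevb("variants have different reference temperatures",
                 "coldevb_config_error")
  tk <- temps_celsius + 273.15
  kw <- tst_rate(delta_g_at(wt, tk), tk)
  km <- tst_rate(delta_g_at(mut, tk), tk)
  list(ddg = mut$dg - wt$dg, ddh = mut$dh - wt$dh, d_tds = mut$tds - wt$tds,
       rates = data.frame(temperature_c = temps_celsius,
                          k_wt = kw, k_mut = km,
                          ratio = km / kw, percent = 100 * km / kw))
}

#' Activity ratios from a table of rate constants
#'
#' The published-results arithmetic: mutant/wildtype rate ratios and percent
#' activities computed directly from tabulated rate constants (one row per
#' variant and temperature).
#'
#' @param rates Data frame with columns `mutation`, `temperature_c` and a
#'   rate column (`k_x100` or `k_s`).
#' @param reference Mutation label of the reference variant (default "WT").
#' @return The input with added `ratio` and `percent` columns relative to the
#'   reference at the same temperature.
#' @export
activity_ratios <- function(rates, reference = "WT") {
  kcol <- if ("k_x100" %in% names(rates)) "k_x100" else "k_s"
  by <- intersect(c("temperature_c", "enzyme"), names(rates))
  ref <- rates[rates$mutation == reference, c(by, kcol)]
  if (nrow(ref) == 0)
    stop_coldevb("reference variant not found in rate table", "coldevb_config_error")
  names(ref)[names(ref) == kcol] <- ".k_ref"
  out <- merge(rates, ref, by = by, sort = FALSE)
  out$ratio <- out[[kcol]] / out$.k_ref
  out$percent <- 100 * out$ratio
  out$.k_ref <- NULL
  out[order(match(out$mutation, unique(rates$mutation)), out$temperature_c), ]
}

#' Bootstrap confidence intervals for the Arrhenius decomposition
#'
#' Percentile bootstrap over replicate resampling within each temperature:
#' replicate barriers are resampled with replacement per temperature, the
#' per-temperature means refit, and the spread of the refitted
#' \eqn{\Delta H^\ddagger} and \eqn{T\Delta S^\ddagger} reported.
#'
#' @param barriers Named list (names = temperatures, K) of per-replicate
#'   activation free energies.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed (deterministic output).
#' @param t_ref Reference temperature, K.
#' @param level Confidence level.
#' @return List with `dh_half_width`, `tds_half_width`, `dh_ci`, `tds_ci`,
#'   `n_boot`.
#' @export
bootstrap_ci <- function(barriers, n_boot = 1000, seed = 1, t_ref = 295.15,
                         level = 0.95) {
  temps <- as.numeric(names(barriers))
  if (any(is.na(temps)))
    stop_coldevb("barriers must be a list named by temperature", "coldevb_config_error")
  if (any(vapply(barriers, length, integer(1)) < 2))
    stop_coldevb("need at least 2 replicates per temperature", "coldevb_config_error")
  a <- (1 - level) / 2
  with_local_seed(seed, {
    dh <- numeric(n_boot); tds <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      means <- vapply(barriers, function(v) mean(sample(v, replace = TRUE)),
                      numeric(1))
      fit <- arrhenius_fit(temps, means, t_ref = t_ref)
      dh[b] <- fit$dh; tds[b] <- fit$tds
    }
    dh_ci <- quantile(dh, c(a, 1 - a), names = FALSE)
    tds_ci <- quantile(tds, c(a, 1 - a), names = FALSE)
    list(dh_half_width = diff(dh_ci) / 2, tds_half_width = diff(tds_ci) / 2,
         dh_ci = dh_ci, tds_ci = tds_ci, n_boot = n_boot)
  })
}

# ---------------------------------------------------------------------------
# Published reference tables (activation parameters at 22 C and TST rate
# constants) for the salmon (SPE) and porcine (PPE) pancreatic elastases and
# their surface-loop mutants; inputs to the results arithmetic.

#' Published activation parameters for elastase variants
#'
#' Calculated thermodynamic activation parameters (kcal/mol) at 22 degrees C
#' for peptide-bond hydrolysis by salmon (SPE) and porcine (PPE) pancreatic
#' elastase wildtypes and surface-loop mutants, as reported in the literature.
#'
#' @return Data frame with columns `enzyme`, `mutation`, `dg`, `dh`, `tds`.
#' @export
elastase_activation_params <- function() {
  tab <- .preset_targets()
  dg <- c(18.0, 18.5, 17.7, 18.2, 18.3, 18.8, 18.8, 18.0,
          19.2, 18.5, 19.4, 19.1, 19.5, 19.8, 19.4, 19.4)
  data.frame(enzyme = tab$enzyme, mutation = tab$mutation,
             dg = dg, dh = tab$dh, tds = tab$tds)
}

#' Published TST rate constants for elastase variants
#'
#' Calculated catalytic rate constants in printed units of x100 s^-1 at 4,
#' 22 and 39 degrees C, assuming constant activation enthalpies and
#' entropies.
#'
#' @return Long-format data frame with columns `enzyme`, `mutation`,
#'   `temperature_c`, `k_x100`.
#' @export
elastase_rate_constants <- function() {
  spe <- rbind(
    c(15.9, 28.9, 47.7), c(2.9, 11.4, 36.0), c(11.3, 43.7, 136.2),
    c(3.7, 19.3, 77.7), c(4.0, 16.2, 51.8), c(3.6, 6.5, 10.7),
    c(0.8, 6.0, 32.0), c(6.6, 25.3, 78.0))
  ppe <- rbind(
    c(0.4, 2.8, 15.1), c(1.5, 10.0, 48.3), c(0.4, 2.5, 11.5),
    c(1.0, 4.0, 13.2), c(0.5, 2.0, 7.0), c(0.2, 1.1, 4.4),
    c(0.9, 2.1, 4.2), c(0.6, 2.3, 7.2))
  tab <- .preset_targets()
  k <- rbind(spe, ppe)
  data.frame(enzyme = rep(tab$enzyme, each = 3),
             mutation = rep(tab$mutation, each = 3),
             temperature_c = rep(c(4, 22, 39), nrow(tab)),
             k_x100 = as.numeric(t(k)))
}
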