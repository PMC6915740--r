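test_that("Arrhenius fit recovers exact linear input", {
  t <- c(285, 290, 295, 300, 305)
  ds <- -13.4 / 295.15
  fit <- arrhenius_fit(t, 4.6 - t * ds)
  expect_equal(fit$dh, 4.6, tolerance = 1e-9)
  expect_equal(fit$tds, -13.4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$dg, 18.0, tolerance = 1e-9)

  # zero entropy: constant barrier, slope equals the barrier
  fit0 <- arrhenius_fit(t, rep(7, 5))
  expect_equal(fit0$dh, 7, tolerance = 1e-9)
  expect_equal(fit0$tds, 0, tolerance = 1e-9)

  expect_error(arrhenius_fit(c(290, 290, 290), c(1, 2, 3)),
               class = "coldevb_fit_error")
})

test_that("Arrhenius fit is unbiased under Gaussian noise", {
  t <- c(285, 290, 295, 300, 305)
  ds <- -13.4 / 295.15
  truth <- 4.6 - t * ds
  set.seed(2024)
  dh <- replicate(1000, arrhenius_fit(t, truth + rnorm(5, 0, 0.05))$dh)
  expect_lt(abs(mean(dh) - 4.6), 0.05)
})

test_that("fitted parameters satisfy dG = dH - T dS to machine precision", {
  set.seed(8)
  for (i in 1:5) {
    fit <- arrhenius_fit(c(285, 290, 295, 300, 305),
                         rnorm(5, 18, 1), t_ref = 295.15)
    expect_lt(abs(fit$dg - (fit$dh - 295.15 * fit$ds)), 1e-9)
    expect_lt(abs(delta_g_at(fit, 295.15) - fit$dg), 1e-9)
  }
})

test_that("published wildtype rows reproduce their activation free energies", {
  expect_equal(delta_g_at(wt_spe_params(), 295.15), 18.0)
  expect_equal(delta_g_at(wt_ppe_params(), 295.15), 19.2)
  p0 <- activation_parameters("noS", dh = 9, tds = 0)
  expect_equal(delta_g_at(p0, 273.15), 9)
  expect_equal(delta_g_at(p0, 312.15), 9)
})

test_that("Eyring rates match the closed form and its inversion", {
  expect_equal(tst_rate(0, 295.15), KB_OVER_H * 295.15)
  expect_equal(tst_rate(0, 295.15), 6.150e12, tolerance = 1e-4)
  expect_equal(100 * tst_rate(18.0, 295.15), 28.9, tolerance = 0.002)
  t <- 310
  dg1 <- R_KCAL * t * log(KB_OVER_H * t)
  expect_equal(tst_rate(dg1, t), 1, tolerance = 1e-12)
})

test_that("rate tables reproduce the published convention", {
  rt <- rate_table(list(wt_spe_params()), c(4, 22, 39))
  expect_equal(round(rt$k_x100[rt$temperature_c == 22], 1), 28.9)
  # positive activation enthalpy: rate increases with temperature
  expect_true(all(diff(rt$k_s) > 0))
  expect_equal(nrow(rate_table(list())), 0)
})

test_that("variant comparison reports the published differences", {
  cmp <- compare_variants(wt_spe_params(), wt_ppe_params())
  expect_equal(cmp$ddg, 1.2, tolerance = 1e-9)
  expect_equal(cmp$ddh, 12.6, tolerance = 1e-9)
  expect_gt(cmp$ddh, 10)
  same <- compare_variants(wt_spe_params(), wt_spe_params())
  expect_equal(same$rates$ratio, rep(1, 3))
  expect_equal(same$ddg, 0)
  # bookkeeping: ddG(T) = ddH - T ddS at any temperature, exactly
  t <- c(277.15, 295.15, 312.15)
  dd <- delta_g_at(wt_ppe_params(), t) - delta_g_at(wt_spe_params(), t)
  expect_equal(dd, cmp$ddh - t * (cmp$d_tds / 295.15), tolerance = 1e-12)
  expect_error(compare_variants(wt_spe_params(),
                                activation_parameters("x", 5, -1, t_ref = 300)),
               class = "coldevb_config_error")
})

test_that("published rate ratios and percent activities are reproduced", {
  k <- elastase_rate_constants()
  spe <- activity_ratios(k[k$enzyme == "SPE", ])
  triple <- spe[spe$mutation == "R63L/W65F/V88I", ]
  expect_equal(triple$percent[triple$temperature_c == 4], 71, tolerance = 0.002)
  expect_equal(triple$ratio[triple$temperature_c == 22], 1.5, tolerance = 0.01)
  expect_equal(triple$ratio[triple$temperature_c == 39], 2.9, tolerance = 0.02)
  ppe <- activity_ratios(k[k$enzyme == "PPE", ])
  y93 <- ppe[ppe$mutation == "Y93G/A99G" & ppe$temperature_c == 4, ]
  expect_equal(y93$ratio, 2.5)
})

test_that("replicate-batch convergence stops at the first passing fit", {
  t <- c(285, 290, 295, 300, 305)
  ds <- -13.4 / 295.15
  truth <- function(temp) 4.6 - temp * ds

  # noiseless runner converges at the starting count with R^2 = 1
  fit <- converge_activation(function(temp) truth(temp),
                             temperatures = t, start = 10, batch = 5, cap = 40)
  expect_equal(fit$replicates, 10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # noisy runner: replay the same deterministic draw sequence with plain lm
  # as the independent oracle for the stopping point
  make_runner <- function() {
    set.seed(501)
    draws <- lapply(t, function(temp) truth(temp) + rnorm(200, 0, 0.6))
    names(draws) <- as.character(t)
    used <- setNames(rep(0L, 5), as.character(t))
    function(temp) {
      key <- as.character(temp)
      used[key] <<- used[key] + 1L
      draws[[key]][used[key]]
    }
  }
  oracle_stop <- local({
    set.seed(501)
    draws <- lapply(t, function(temp) truth(temp) + rnorm(200, 0, 0.6))
    n <- 10
    repeat {
      means <- vapply(draws, function(v) mean(v[seq_len(n)]), numeric(1))
      r2 <- summary(lm(I(means / t) ~ I(1 / t)))$r.squared
      if (r2 > 0.8 || n + 5 > 120) break
      n <- n + 5
    }
    n
  })
  fit2 <- converge_activation(make_runner(), temperatures = t,
                              start = 10, batch = 5, cap = 120)
  expect_equal(fit2$replicates, oracle_stop)
  expect_gt(fit2$r_squared, 0.8)
  r2h <- attr(fit2, "r2_history")
  expect_true(all(r2h[-length(r2h)] <= 0.8))

  # cap exhaustion raises a non-convergence error carrying the R^2 trail
  set.seed(7)
  noise_only <- function(temp) rnorm(1, 18, 2)
  err <- tryCatch(converge_activation(noise_only, temperatures = t,
                                      start = 4, batch = 2, cap = 8),
                  coldevb_nonconvergence = function(e) e)
  expect_s3_class(err, "coldevb_nonconvergence")
  expect_true(length(err$r2_history) >= 1)
})

test_that("bootstrap CIs are deterministic and track the OLS noise scale", {
  t <- c(285, 290, 295, 300, 305)
  zero <- lapply(t, function(x) rep(17, 10))
  names(zero) <- t
  ci0 <- bootstrap_ci(zero, n_boot = 200, seed = 1)
  expect_equal(ci0$dh_half_width, 0)
  expect_equal(ci0$tds_half_width, 0)

  set.seed(31)
  ds <- -13.4 / 295.15
  barr <- lapply(t, function(temp) 4.6 - temp * ds + rnorm(50, 0, 0.5))
  names(barr) <- t
  ci <- bootstrap_ci(barr, n_boot = 500, seed = 6)
  ci_again <- bootstrap_ci(barr, n_boot = 500, seed = 6)
  expect_identical(ci$dh_ci, ci_again$dh_ci)
  # analytic OLS slope standard error for y = dG/T on x = 1/T
  x <- 1 / t
  sig_y <- mean(0.5 / sqrt(50) / t)
  se_slope <- sig_y / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(ci$dh_half_width / 1.96 - se_slope) / se_slope, 0.3)

  expect_error(bootstrap_ci(list(`290` = 1, `300` = c(1, 2))),
               class = "coldevb_config_error")
})
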