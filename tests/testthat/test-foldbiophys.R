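# Calibration, two-/three-state unfolding, melts, yield classification, PCA.

test_that("the calibration sigmoid is recovered, monotone, and invertible", {
  truth <- list(A = 0.843, K = 5.00, h = 0.483)
  x <- exp(seq(log(0.05), log(100), length.out = 25))
  cc <- fit_calibration(x, calibration_signal(x, truth),
                        start = list(A = 1, K = 1, h = 1))
  expect_lt(abs(cc$A - truth$A), 0.005)
  expect_lt(abs(cc$K - truth$K), 0.005)
  expect_lt(abs(cc$h - truth$h), 0.005)

  # y(K) = A/2 for any fitted curve, monotone increasing on a grid
  expect_equal(calibration_signal(cc$K, cc), cc$A / 2)
  grid <- seq(0.01, 50, length.out = 200)
  expect_true(all(diff(calibration_signal(grid, cc)) > 0))

  # closed-form inversion round trip
  xs <- exp(seq(log(0.1), log(80), length.out = 20))
  ys <- calibration_signal(xs, cc)
  expect_lt(max(abs(invert_calibration(ys, cc) - xs) / xs), 1e-9)
  expect_equal(invert_calibration(cc$A / 2, cc), cc$K)
  expect_error(invert_calibration(cc$A, cc), "range")
  expect_error(invert_calibration(0, cc), "range")
  expect_error(fit_calibration(c(-1, 1, 2, 3, 4), 1:5), "positive")
})

test_that("two-state fits recover midpoints and respond to cooperativity", {
  sp <- list(model = "two_state",
             params = list(Cm = 2.0, m = 2.0, aN = 1, bN = 0, aD = 0, bD = 0),
             noise_sd = 0.01, n_points = 61, x_range = c(0, 6), seed = 7)
  fit <- fit_two_state(simulate_curve(sp))
  expect_lt(abs(fit$Cm - 2.0), 0.05)
  expect_true(fit$apparent)

  # f_N = 0.5 exactly at the midpoint
  expect_equal(two_state_fraction(fit$Cm, fit$Cm, fit$m), 0.5)

  # fitted m is monotone in the generating m
  ms <- vapply(c(1, 2, 4), function(mm) {
    spm <- sp; spm$params$m <- mm; spm$seed <- 11
    fit_two_state(simulate_curve(spm))$m
  }, numeric(1))
  expect_true(all(diff(ms) > 0))

  # flat data carry no inflection
  flat <- denaturation_dataset(seq(0, 6, length.out = 30),
                               rnorm(30, 1, 0.005))
  expect_error(fit_two_state(flat), "inflection|converge")
})

test_that("three-state fits recover the inter-inflection interval", {
  d <- simulate_curve(unfolding_curve_spec(1.2, seed = 19))
  fit <- fit_three_state(d)
  expect_lt(abs(fit$delta_Cm - 1.2), 0.1)
  expect_equal(fit$Cm[2] - fit$Cm[1], fit$delta_Cm)
  expect_gt(fit$Cm[2], fit$Cm[1])

  # species fractions sum to one everywhere
  fr <- fit$fraction_curves
  expect_lt(max(abs(fr$f_N + fr$f_I + fr$f_D - 1)), 1e-9)

  # the intermediate peaks strictly between the midpoints (dense grid
  # against the closed-form fractions)
  xg <- seq(0, 6, length.out = 5000)
  fi <- three_state_fractions(xg, fit$Cm[1], fit$m[1], fit$Cm[2],
                              fit$m[2])$f_I
  xpk <- xg[which.max(fi)]
  expect_gt(xpk, fit$Cm[1])
  expect_lt(xpk, fit$Cm[2])
})

test_that("unfolding parameters are invariant to uniform signal rescaling", {
  d <- simulate_curve(unfolding_curve_spec(0.8, seed = 23))
  f1 <- fit_three_state(d)
  d2 <- denaturation_dataset(d$x, d$y * 1000)
  f2 <- fit_three_state(d2)
  expect_equal(f1$Cm, f2$Cm, tolerance = 1e-6)
  expect_equal(f1$m, f2$m, tolerance = 1e-6)
  expect_equal(f1$delta_Cm, f2$delta_Cm, tolerance = 1e-6)

  sp <- list(model = "two_state",
             params = list(Cm = 2.5, m = 3, aN = 1, bN = -0.02, aD = 0.1,
                           bD = 0.005),
             noise_sd = 0.01, n_points = 61, x_range = c(0, 6), seed = 29)
  d3 <- simulate_curve(sp)
  g1 <- fit_two_state(d3)
  g2 <- fit_two_state(denaturation_dataset(d3$x, d3$y * 250))
  expect_equal(g1$Cm, g2$Cm, tolerance = 1e-6)
  expect_equal(g1$m, g2$m, tolerance = 1e-6)
})

test_that("median interval error stays below 0.1 M over 100 simulations", {
  errs <- vapply(1:100, function(s) {
    d <- simulate_curve(unfolding_curve_spec(1.2, seed = s, n_points = 61))
    abs(fit_three_state(d)$delta_Cm - 1.2)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("BIC model selection matches the generating model", {
  sp2 <- list(model = "two_state",
              params = list(Cm = 2.5, m = 3, aN = 1, bN = -0.02, aD = 0.1,
                            bD = 0.005),
              noise_sd = 0.01, n_points = 61, x_range = c(0, 6))
  pick2 <- vapply(1:100, function(s) {
    select_model(simulate_curve(modifyList(sp2, list(seed = s))))
  }, integer(1))
  expect_gte(mean(pick2 == 2L), 0.95)

  sp3 <- unfolding_curve_spec(1.2, n_points = 61)
  pick3 <- vapply(1:100, function(s) {
    select_model(simulate_curve(modifyList(sp3, list(seed = s))))
  }, integer(1))
  expect_gte(mean(pick3 == 3L), 0.95)

  flat <- denaturation_dataset(seq(0, 6, length.out = 30),
                               rnorm(30, 1, 0.004))
  expect_error(select_model(flat), "failed")
})

test_that("the two-state ratio transform reduces apparent cooperativity", {
  expect_equal(two_state_transform(c(1, 2, 3), c(1, 2, 3)), c(1, 1, 1))
  expect_error(two_state_transform(1:3, 1:4), "mismatch")
  expect_error(two_state_transform(1:3, c(1, 0, 2)), "zero")

  # three-state spectra: native- and denatured-wavelength channels seen
  # through the ratio fit to two states give a pseudo-m below the m of a
  # matched genuinely two-state protein
  x <- seq(0, 6, length.out = 121)
  fr <- three_state_fractions(x, 2.2, 3, 3.4, 3)
  near_native <- 1.0 * fr$f_N + 0.75 * fr$f_I + 0.15 * fr$f_D + 0.02
  near_denat <- 0.15 * fr$f_N + 0.45 * fr$f_I + 1.0 * fr$f_D + 0.02
  set.seed(31)
  ratio <- two_state_transform(near_native + rnorm(121, 0, 0.004),
                               near_denat + rnorm(121, 0, 0.004))
  pseudo <- fit_two_state(denaturation_dataset(x, ratio))
  true2 <- fit_two_state(simulate_curve(list(
    model = "two_state",
    params = list(Cm = pseudo$Cm, m = 3, aN = max(ratio), bN = 0,
                  aD = min(ratio), bD = 0),
    noise_sd = 0.004, n_points = 121, x_range = c(0, 6), seed = 37)))
  expect_lt(pseudo$m, true2$m)
})

test_that("thermal melts are recovered or censored, never spurious", {
  spm <- list(model = "melt",
              params = list(Tm = 60, w = 2, aN = 1, bN = -0.001, aD = 0.2,
                            bD = 0),
              noise_sd = 0.01, n_points = 71, x_range = c(25, 95), seed = 41)
  mf <- fit_thermal_melt(simulate_curve(spm))
  expect_false(mf$censored)
  expect_lt(abs(mf$Tm - 60), 1)

  # midpoint above the scan: censored at the configured bound
  sph <- modifyList(spm, list(params = modifyList(spm$params,
                                                  list(Tm = 97))))
  mfh <- fit_thermal_melt(simulate_curve(sph), upper_limit = 90)
  expect_true(mfh$censored)
  expect_equal(mfh$censored_bound, 90)
  expect_true(is.na(mfh$Tm))

  # monotone-flat data: censored, never a point estimate
  set.seed(43)
  flat <- denaturation_dataset(seq(25, 95, length.out = 40),
                               rnorm(40, 0.9, 0.01), mode = "thermal")
  expect_true(fit_thermal_melt(flat)$censored)

  # estimator shift-equivariance: +21 C in generation moves Tm by 21 +- 1
  spl <- modifyList(spm, list(params = modifyList(spm$params,
                                                  list(Tm = 45)),
                              seed = 47))
  sph21 <- modifyList(spl, list(params = modifyList(spl$params,
                                                    list(Tm = 66))))
  t1 <- fit_thermal_melt(simulate_curve(spl))$Tm
  t2 <- fit_thermal_melt(simulate_curve(sph21))$Tm
  expect_lt(abs((t2 - t1) - 21), 1)
})

test_that("folding-yield concentration shapes are classified correctly", {
  expect_equal(classify_concentration_dependence(c(1, 5, 25),
                                                 c(0.4, 1.0, 0.5)), "bell")
  expect_equal(classify_concentration_dependence(c(1, 5, 25, 125),
                                                 c(1.0, 0.7, 0.4, 0.2)),
               "monotone_decreasing")
  expect_equal(classify_concentration_dependence(c(1, 5, 25, 125),
                                                 c(0.97, 1.0, 0.98, 0.99)),
               "flat")
  expect_error(classify_concentration_dependence(c(1, 2), c(1, 1)),
               "at least 3")

  # mechanistic toy generators: oligomers bell, monomers decreasing
  conc <- c(0.5, 2, 8, 32, 128)
  expect_equal(classify_concentration_dependence(
    conc, folding_yield_curve(conc, "oligomer")), "bell")
  expect_equal(classify_concentration_dependence(
    conc, folding_yield_curve(conc, "monomer")), "monotone_decreasing")
})

test_that("trait PCA reports correct variance fractions and loadings", {
  # two perfectly correlated traits + four independent: compare to a dense
  # eigensolve of the known correlation matrix
  set.seed(53)
  n <- 40
  z <- rnorm(n)
  tab <- data.frame(binding = z, solubility = 2 * z + 1,
                    insoluble = rnorm(n), affinity = rnorm(n),
                    stability = rnorm(n), refolding = rnorm(n))
  res <- trait_pca(tab)
  oracle <- eigen(cor(as.matrix(tab)), symmetric = TRUE)$values
  expect_equal(res$eigenvalues, oracle, tolerance = 1e-12)
  expect_equal(res$variance_fraction, oracle / sum(oracle),
               tolerance = 1e-12)
  # the correlated pair loads together on the top component
  l1 <- res$loadings[, 1]
  expect_gt(abs(l1["binding"]), 0.6)
  expect_equal(unname(sign(l1["binding"])), unname(sign(l1["solubility"])))

  expect_error(trait_pca(data.frame(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant trait column 'a'")
})

test_that("PCA of an exactly diagonal correlation splits variance evenly", {
  # construct six exactly uncorrelated columns via orthogonal contrasts
  cm <- stats::contr.helmert(7)   # 7 x 6, columns orthogonal, zero-sum
  tab <- as.data.frame(cm)
  res <- trait_pca(tab)
  expect_equal(max(abs(res$correlation[upper.tri(res$correlation)])), 0,
               tolerance = 1e-12)
  expect_equal(res$variance_fraction, rep(1 / 6, 6), tolerance = 1e-12)
})
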