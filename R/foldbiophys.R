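# Equilibrium biophysics: ELISA calibration sigmoid and its inversion,
# two-/three-state chemical denaturation fits (linear extrapolation
# parameterization), thermal melts with censoring, concentration-dependence
# classification of folding yield, and the trait correlation/PCA.

#' Gas constant times temperature at 25 degrees C, kcal/mol
#' @export
RT25 <- 0.592

#' Construct a denaturation dataset
#'
#' @param x denaturant concentration (M GdmCl) or temperature (degrees C),
#'   strictly increasing
#' @param y signal (fluorescence, ellipticity or ratio; arbitrary units)
#' @param mode `"chemical"` or `"thermal"`
#' @param ligand_present logical flag (10 mM GlcNAc present?)
#' @param protein_conc protein concentration in uM (default the dilute
#'   0.5 uM regime used for equilibria)
#' @export
denaturation_dataset <- function(x, y, mode = c("chemical", "thermal"),
                                 ligand_present = FALSE, protein_conc = 0.5) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 10) stop("need >= 10 points for fitting", call. = FALSE)
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  structure(data.frame(x = x, y = y),
            mode = mode, ligand_present = ligand_present,
            protein_conc = protein_conc,
            class = c("DenaturationDataset", "data.frame"))
}

.as_xy <- function(data) {
  if (is.list(data) && !is.null(data$x) && !is.null(data$y)) {
    list(x = data$x, y = data$y)
  } else stop("data must carry x and y", call. = FALSE)
}

## ---- calibration ----------------------------------------------------------

#' Evaluate the ELISA calibration sigmoid y = A / (1 + (K/x)^h)
#' @param x concentration (> 0)
#' @param curve a `CalibrationCurve` (or list with A, K, h)
#' @export
calibration_signal <- function(x, curve) {
  curve$A / (1 + (curve$K / x)^curve$h)
}

#' Fit the three-parameter ELISA calibration sigmoid
#'
#' Least-squares fit of `y = A / (1 + (K/x)^h)`: `A` is the saturation
#' absorbance, `K` the half-saturation concentration (`y(K) = A/2` by
#' construction), and `h` a dimensionless exponent governing how compressed
#' the response is.
#'
#' @param x concentrations (> 0)
#' @param y absorbances
#' @param start optional named list of starting values (A, K, h)
#' @return object of class `CalibrationCurve`: `A`, `K`, `h`,
#'   `resid_norm`
#' @export
fit_calibration <- function(x, y, start = NULL) {
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(x) < 5) stop("need >= 5 calibration points", call. = FALSE)
  if (is.null(start)) {
    start <- list(A = max(y) * 1.05, K = stats::median(x), h = 1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (1 + (K / x)^h), start = start,
                      lower = c(A = 1e-9, K = 1e-9, h = 1e-9),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) stop(sprintf("calibration fit failed: %s",
                                     conditionMessage(e)), call. = FALSE))
  cf <- stats::coef(fit)
  structure(list(A = unname(cf["A"]), K = unname(cf["K"]),
                 h = unname(cf["h"]),
                 resid_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "CalibrationCurve")
}

#' Invert the calibration sigmoid: absorbance to functional concentration
#'
#' Closed form `x = K * (A/y - 1)^(-1/h)`, the exact inverse of
#' [calibration_signal()] on `(0, A)`.
#'
#' @param y absorbance(s), strictly inside `(0, A)`
#' @param curve a `CalibrationCurve`
#' @export
invert_calibration <- function(y, curve) {
  if (any(y <= 0) || any(y >= curve$A)) {
    stop("absorbance out of invertible range (saturated or blank well)",
         call. = FALSE)
  }
  curve$K * (curve$A / y - 1)^(-1 / curve$h)
}

## ---- two- and three-state chemical unfolding ------------------------------

#' Native fraction of a two-state unfolding transition
#' @param x denaturant (M)
#' @param Cm midpoint (M); `m` m-value (kcal/mol/M)
#' @param m m-value
#' @export
two_state_fraction <- function(x, Cm, m) 1 / (1 + exp(m * (x - Cm) / RT25))

#' Two-state signal with linear baselines
#' @param x denaturant (M)
#' @param Cm,m transition midpoint and m-value
#' @param aN,bN,aD,bD native/denatured baseline intercepts and slopes
#' @export
two_state_signal <- function(x, Cm, m, aN, bN, aD, bD) {
  fN <- two_state_fraction(x, Cm, m)
  (aN + bN * x) * fN + (aD + bD * x) * (1 - fN)
}

#' Species fractions of a three-state N <-> I <-> D equilibrium
#' @param x denaturant (M)
#' @param Cm1,m1 first transition (N/I) midpoint and m-value
#' @param Cm2,m2 second transition (I/D) midpoint and m-value
#' @return data.frame with `f_N`, `f_I`, `f_D` (each row sums to 1)
#' @export
three_state_fractions <- function(x, Cm1, m1, Cm2, m2) {
  K1 <- exp(m1 * (x - Cm1) / RT25)
  K2 <- exp(m2 * (x - Cm2) / RT25)
  fN <- 1 / (1 + K1 + K1 * K2)
  data.frame(f_N = fN, f_I = K1 * fN, f_D = K1 * K2 * fN)
}

#' Three-state signal; intermediate baseline has free intercept, zero slope
#' @inheritParams three_state_fractions
#' @param aN,bN,aI,aD,bD baseline parameters
#' @export
three_state_signal <- function(x, Cm1, m1, Cm2, m2, aN, bN, aI, aD, bD) {
  fr <- three_state_fractions(x, Cm1, m1, Cm2, m2)
  (aN + bN * x) * fr$f_N + aI * fr$f_I + (aD + bD * x) * fr$f_D
}

# Coarse grid search over the nonlinear unfolding parameters with the
# linear baseline parameters profiled out exactly (they enter the signal
# linearly), used to seed the Levenberg-Marquardt polish.
.profile_two_state <- function(x, y, n_keep = 5) {
  grid <- expand.grid(
    Cm = seq(stats::quantile(x, 0.1), stats::quantile(x, 0.9),
             length.out = 41),
    m = c(0.5, 1, 1.5, 2, 3, 4, 6, 9))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    fN <- two_state_fraction(x, grid$Cm[i], grid$m[i])
    X <- cbind(fN, x * fN, 1 - fN, x * (1 - fN))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  ord <- order(sse)[seq_len(n_keep)]
  lapply(ord, function(i) {
    fN <- two_state_fraction(x, grid$Cm[i], grid$m[i])
    X <- cbind(fN, x * fN, 1 - fN, x * (1 - fN))
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    list(Cm = grid$Cm[i], m = grid$m[i], aN = cf[1], bN = cf[2],
         aD = cf[3], bD = cf[4])
  })
}

.profile_three_state <- function(x, y, n_keep = 4) {
  span <- diff(range(x))
  grid <- expand.grid(
    Cm1 = seq(stats::quantile(x, 0.05), stats::quantile(x, 0.9),
              length.out = 22),
    dCm = span * c(0.02, 0.04, 0.06, 0.09, 0.13, 0.18, 0.25, 0.35, 0.5),
    m = c(1, 2, 4, 6))
  keep <- grid$Cm1 + grid$dCm <= max(x)
  grid <- grid[keep, , drop = FALSE]
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    fr <- three_state_fractions(x, grid$Cm1[i], grid$m[i],
                                grid$Cm1[i] + grid$dCm[i], grid$m[i])
    X <- cbind(fr$f_N, x * fr$f_N, fr$f_I, fr$f_D, x * fr$f_D)
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  ord <- order(sse)[seq_len(min(n_keep, nrow(grid)))]
  lapply(ord, function(i) {
    fr <- three_state_fractions(x, grid$Cm1[i], grid$m[i],
                                grid$Cm1[i] + grid$dCm[i], grid$m[i])
    X <- cbind(fr$f_N, x * fr$f_N, fr$f_I, fr$f_D, x * fr$f_D)
    cf <- stats::lm.fit(X, y)$coefficients
    cf[is.na(cf)] <- 0
    list(Cm1 = grid$Cm1[i], dCm = grid$dCm[i], m1 = grid$m[i],
         m2 = grid$m[i], aN = cf[1], bN = cf[2], aI = cf[3],
         aD = cf[4], bD = cf[5])
  })
}

# data-driven start estimates; steepest-descent locations of a lightly
# smoothed derivative
.slope_peaks <- function(x, y, k = 2) {
  n <- length(y)
  w <- max(2, round(n / 12))
  ys <- stats::filter(y, rep(1 / w, w), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  dy <- abs(diff(ys) / diff(x))
  mids <- (x[-1] + x[-n]) / 2
  ord <- order(dy, decreasing = TRUE)
  picked <- c()
  span <- diff(range(x))
  for (i in ord) {
    if (!length(picked) || all(abs(mids[i] - mids[picked]) > span / 6)) {
      picked <- c(picked, i)
    }
    if (length(picked) == k) break
  }
  sort(mids[picked])
}

.fit_error <- function(msg) stop(msg, call. = FALSE)

#' Fit a two-state unfolding model
#'
#' Linear-extrapolation two-state fit: linear native and denatured baselines
#' joined by `f_N = 1/(1 + exp(m (x - Cm)/RT))` at 25 degrees C. Several
#' deterministic starts around the steepest-slope location are tried and the
#' best SSE kept. Fits of oligomer data carry no concentration term, so all
#' parameters are apparent values.
#'
#' @param data a [denaturation_dataset()] (or data.frame with x, y)
#' @return object of class `UnfoldingFit` with `n_states = 2`, `Cm`, `m`,
#'   baselines, species `fraction_curves`, `sse`, `apparent = TRUE`
#' @export
fit_two_state <- function(data) {
  d <- .as_xy(data)
  x <- d$x; y <- d$y
  best <- NULL
  for (st in .profile_two_state(x, y)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_state_signal(x, Cm, m, aN, bN, aD, bD),
        start = st,
        lower = c(Cm = min(x) - 1, m = 0.2, aN = -Inf, bN = -Inf,
                  aD = -Inf, bD = -Inf),
        upper = c(Cm = max(x) + 1, m = 12, aN = Inf, bN = Inf,
                  aD = Inf, bD = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) .fit_error("two-state fit failed to converge")
  cf <- as.list(stats::coef(best$fit))
  rsd <- sqrt(best$sse / max(1, length(x) - 6))
  amp <- abs((cf$aN + cf$bN * cf$Cm) - (cf$aD + cf$bD * cf$Cm))
  if (amp < 5 * rsd || cf$Cm <= min(x) || cf$Cm >= max(x)) {
    .fit_error("no unfolding inflection detected (non-sigmoidal data)")
  }
  fr <- two_state_fraction(x, cf$Cm, cf$m)
  structure(list(n_states = 2L, Cm = cf$Cm, m = cf$m,
                 baselines = list(native = c(intercept = cf$aN,
                                             slope = cf$bN),
                                  denatured = c(intercept = cf$aD,
                                                slope = cf$bD)),
                 RT = RT25, delta_Cm = NA_real_,
                 fraction_curves = data.frame(x = x, f_N = fr, f_D = 1 - fr),
                 sse = best$sse, apparent = TRUE, coef = cf),
            class = "UnfoldingFit")
}

#' Fit a three-state unfolding model
#'
#' N <-> I <-> D with `K1 = exp(m1 (x - Cm1)/RT)` and
#' `K2 = exp(m2 (x - Cm2)/RT)`; species fractions
#' `f_N = 1/(1 + K1 + K1 K2)`, `f_I = K1 f_N`, `f_D = K1 K2 f_N`. The
#' second midpoint is parameterized as `Cm1 + dCm` with `dCm > 0`, so the
#' inter-inflection interval `delta_Cm = Cm2 - Cm1` (the stability of the
#' folding intermediate) is a direct fit parameter. The intermediate
#' baseline has a free intercept and zero slope.
#'
#' @inheritParams fit_two_state
#' @return `UnfoldingFit` with `n_states = 3`, `Cm` (both midpoints), `m`,
#'   `delta_Cm`, baselines, species `fraction_curves`
#' @export
fit_three_state <- function(data) {
  d <- .as_xy(data)
  x <- d$x; y <- d$y
  best <- NULL; fallback <- NULL
  for (st in .profile_three_state(x, y)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ three_state_signal(x, Cm1, m1, Cm1 + dCm, m2, aN, bN, aI,
                               aD, bD),
        start = st,
        lower = c(Cm1 = min(x) - 1, dCm = 1e-3, m1 = 0.2, m2 = 0.2,
                  aN = -Inf, bN = -Inf, aI = -Inf, aD = -Inf, bD = -Inf),
        upper = c(Cm1 = max(x) + 1, dCm = diff(range(x)) + 1, m1 = 12,
                  m2 = 12, aN = Inf, bN = Inf, aI = Inf, aD = Inf,
                  bD = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      cf0 <- as.list(stats::coef(fit))
      fr0 <- three_state_fractions(range(x), cf0$Cm1, cf0$m1,
                                   cf0$Cm1 + cf0$dCm, cf0$m2)
      # both transitions must lie inside the scanned gradient: native
      # baseline established at low denaturant, denatured at high
      ok <- fr0$f_N[1] >= 0.8 && fr0$f_D[2] >= 0.8
      if (ok && (is.null(best) || sse < best$sse)) {
        best <- list(fit = fit, sse = sse)
      }
      if (is.null(fallback) || sse < fallback$sse) {
        fallback <- list(fit = fit, sse = sse)
      }
    }
  }
  if (is.null(best)) best <- fallback
  if (is.null(best)) .fit_error("three-state fit failed to converge")
  cf <- as.list(stats::coef(best$fit))
  if (cf$dCm <= 2e-3) {
    .fit_error(paste("degenerate three-state fit (Cm2 <= Cm1 at optimum);",
                     "a two-state model is recommended"))
  }
  rsd3 <- sqrt(best$sse / max(1, length(x) - 9))
  amp3 <- abs((cf$aN + cf$bN * cf$Cm1) -
                (cf$aD + cf$bD * (cf$Cm1 + cf$dCm)))
  if (amp3 < 5 * rsd3) {
    .fit_error("no unfolding inflection detected (non-sigmoidal data)")
  }
  fr <- three_state_fractions(x, cf$Cm1, cf$m1, cf$Cm1 + cf$dCm, cf$m2)
  structure(list(n_states = 3L, Cm = c(cf$Cm1, cf$Cm1 + cf$dCm),
                 m = c(cf$m1, cf$m2),
                 baselines = list(native = c(intercept = cf$aN,
                                             slope = cf$bN),
                                  intermediate = c(intercept = cf$aI,
                                                   slope = 0),
                                  denatured = c(intercept = cf$aD,
                                                slope = cf$bD)),
                 RT = RT25, delta_Cm = cf$dCm,
                 fraction_curves = cbind(data.frame(x = x), fr),
                 sse = best$sse, apparent = TRUE, coef = cf),
            class = "UnfoldingFit")
}

#' @export
print.UnfoldingFit <- function(x, ...) {
  cat(sprintf("<UnfoldingFit: %d-state, Cm = %s M%s>\n", x$n_states,
              paste(sprintf("%.2f", x$Cm), collapse = ", "),
              if (x$n_states == 3)
                sprintf(", delta_Cm = %.2f M", x$delta_Cm) else ""))
  invisible(x)
}

#' Choose between two- and three-state models by BIC
#'
#' Both fits are attempted; the Bayesian information criterion
#' (`n log(SSE/n) + k log n`) decides, with ties going to the parsimonious
#' two-state model.
#'
#' @inheritParams fit_two_state
#' @return 2 or 3
#' @export
select_model <- function(data) {
  d <- .as_xy(data)
  n <- length(d$x)
  f2 <- tryCatch(fit_two_state(data), error = function(e) e)
  f3 <- tryCatch(fit_three_state(data), error = function(e) e)
  if (inherits(f2, "error") && inherits(f3, "error")) {
    .fit_error(sprintf("both fits failed: [%s] / [%s]",
                       conditionMessage(f2), conditionMessage(f3)))
  }
  bic <- function(fit, k) n * log(fit$sse / n) + (k + 1) * log(n)
  b2 <- if (inherits(f2, "error")) Inf else bic(f2, 6)
  b3 <- if (inherits(f3, "error")) Inf else bic(f3, 9)
  if (b2 <= b3) 2L else 3L
}

#' Two-state transform of wavelength-resolved spectra
#'
#' Pointwise ratio of the native-wavelength to denatured-wavelength
#' intensity series. Fitting a two-state model to the ratio of a genuinely
#' three-state unfolder yields a less cooperative transition (a lower
#' pseudo-m).
#'
#' @param native,denatured equal-length intensity series
#' @return the ratio series
#' @export
two_state_transform <- function(native, denatured) {
  if (length(native) != length(denatured)) {
    stop("series length mismatch", call. = FALSE)
  }
  if (any(denatured == 0)) stop("zero denominator in ratio", call. = FALSE)
  native / denatured
}

## ---- thermal melts --------------------------------------------------------

#' Thermal-melt signal (logistic transition, linear baselines)
#' @param x temperature (degrees C)
#' @param Tm midpoint; `w` transition width (degrees C)
#' @param w width
#' @param aN,bN,aD,bD baseline parameters
#' @export
melt_signal <- function(x, Tm, w, aN, bN, aD, bD) {
  fD <- 1 / (1 + exp(-(x - Tm) / w))
  (aN + bN * x) * (1 - fD) + (aD + bD * x) * fD
}

#' Fit a thermal melt, with censoring above the scanned range
#'
#' Two-state logistic melt fit for the unfolding midpoint Tm. When the
#' transition is not resolved within the scan — the fit fails, the fitted
#' midpoint lies above `upper_limit`, or the denatured baseline is not
#' established inside the scanned range — the result is censored
#' (`Tm > upper_limit`) rather than a spurious point estimate.
#'
#' @param data a thermal [denaturation_dataset()]
#' @param upper_limit censoring bound in degrees C (default 90)
#' @return object of class `MeltFit`: `Tm` (NA when censored), `censored`,
#'   `censored_bound`
#' @export
fit_thermal_melt <- function(data, upper_limit = 90) {
  d <- .as_xy(data)
  x <- d$x; y <- d$y
  censored <- structure(list(Tm = NA_real_, censored = TRUE,
                             censored_bound = upper_limit),
                        class = "MeltFit")
  # profile linear baselines over a (Tm, w) grid to seed the polish
  grid <- expand.grid(Tm = seq(min(x), max(x), length.out = 25),
                      w = c(0.5, 1, 2, 5))
  sse0 <- vapply(seq_len(nrow(grid)), function(i) {
    fD <- 1 / (1 + exp(-(x - grid$Tm[i]) / grid$w[i]))
    X <- cbind(1 - fD, x * (1 - fD), fD, x * fD)
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  best <- NULL
  for (i in order(sse0)[1:3]) {
    fD <- 1 / (1 + exp(-(x - grid$Tm[i]) / grid$w[i]))
    X <- cbind(1 - fD, x * (1 - fD), fD, x * fD)
    cf0 <- stats::lm.fit(X, y)$coefficients
    cf0[is.na(cf0)] <- 0
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ melt_signal(x, Tm, w, aN, bN, aD, bD),
        start = list(Tm = grid$Tm[i], w = grid$w[i], aN = cf0[1],
                     bN = cf0[2], aD = cf0[3], bD = cf0[4]),
        lower = c(Tm = min(x) - 50, w = 0.1, aN = -Inf, bN = -Inf,
                  aD = -Inf, bD = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) return(censored)
  cf <- as.list(stats::coef(best$fit))
  rsd <- sqrt(best$sse / max(1, length(x) - 6))
  amp <- abs((cf$aN + cf$bN * cf$Tm) - (cf$aD + cf$bD * cf$Tm))
  if (amp < 5 * rsd) return(censored)              # monotone-flat data
  if (cf$Tm > upper_limit) return(censored)
  if (cf$Tm + 2 * cf$w > max(x)) return(censored)  # upper baseline unresolved
  structure(list(Tm = cf$Tm, censored = FALSE, censored_bound = NA_real_,
                 width = cf$w, sse = best$sse),
            class = "MeltFit")
}

#' @export
print.MeltFit <- function(x, ...) {
  if (x$censored) cat(sprintf("<MeltFit: Tm > %g C (censored)>\n",
                              x$censored_bound))
  else cat(sprintf("<MeltFit: Tm = %.1f C>\n", x$Tm))
  invisible(x)
}

## ---- folding-yield concentration dependence -------------------------------

#' Classify the concentration dependence of folding yield
#'
#' `bell` when an interior maximum exceeds both endpoint yields by more than
#' `margin` (oligomers: assembly favored then overtaken by intermolecular
#' misfolding); `monotone_decreasing` when the overall drop exceeds the
#' margin and a decreasing isotonic fit beats a flat fit (monomers);
#' otherwise `flat`. Yields are expected normalized to a maximum of 1.
#'
#' @param conc concentrations (uM), ascending
#' @param yield normalized folding efficiencies
#' @param margin noise margin on the normalized scale
#' @return one of "bell", "monotone_decreasing", "flat"
#' @export
classify_concentration_dependence <- function(conc, yield, margin = 0.1) {
  n <- length(conc)
  if (n != length(yield)) stop("length mismatch", call. = FALSE)
  if (n < 3) stop("need at least 3 concentrations", call. = FALSE)
  if (any(diff(conc) <= 0)) stop("concentrations must ascend", call. = FALSE)
  interior <- yield[-c(1, n)]
  imax <- max(interior)
  if (imax > yield[1] + margin && imax > yield[n] + margin) return("bell")
  dec <- -stats::isoreg(conc, -yield)$yf
  sse_dec <- sum((yield - dec)^2)
  sse_flat <- sum((yield - mean(yield))^2)
  if ((yield[1] - yield[n]) > margin && sse_dec < sse_flat) {
    return("monotone_decreasing")
  }
  "flat"
}

## ---- trait correlation and PCA --------------------------------------------

#' Trait correlation matrix and principal components
#'
#' Pearson correlation matrix over complete-case constructs, its
#' eigendecomposition (PCA on the correlation matrix), per-component
#' variance fractions, and loadings, from which correlated trait groups can
#' be read off by loading sign and magnitude.
#'
#' @param table data.frame of per-construct trait values (the six traits:
#'   total binding capacity, soluble level, insoluble level, ligand
#'   affinity, native thermal stability, in vitro folding efficiency)
#' @return list with `correlation`, `eigenvalues`, `variance_fraction`,
#'   `loadings`, `n_constructs`
#' @export
trait_pca <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("trait table must be numeric", call. = FALSE)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("need >= 3 complete-case constructs", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("correlation undefined: constant trait column '%s'",
                 colnames(m)[which(sds == 0)[1]]), call. = FALSE)
  }
  C <- stats::cor(m)
  es <- eigen(C, symmetric = TRUE)
  loadings <- es$vectors
  dimnames(loadings) <- list(colnames(m),
                             paste0("PC", seq_len(ncol(loadings))))
  list(correlation = C, eigenvalues = es$values,
       variance_fraction = es$values / sum(es$values),
       loadings = loadings, n_constructs = nrow(m))
}
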