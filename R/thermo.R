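# Solution thermodynamics: the two-state duplex melting model with sloping
# baselines, van't Hoff analysis of Ka(T), Gibbs-energy identities, and the
# exact 1:1 binding model for ITC titrations with dilution-heat handling.

#' Association constant from the duplex fraction
#'
#' For a non-self-complementary duplex at equal single-strand concentrations
#' `c0`, `Ka = 2 f / ((1 - f)^2 c0)`.  The inverse (fraction from `Ka`) uses
#' the numerically stable root of the same quadratic.
#'
#' @param f fraction of base-paired molecules, strictly in (0, 1).
#' @param c0 single-strand concentration (M).
#' @return `Ka` in 1/M.
#' @export
ka_from_fraction <- function(f, c0) {
  if (any(f <= 0 | f >= 1)) stop("f must lie strictly in (0, 1)")
  if (any(c0 <= 0)) stop("c0 must be positive")
  2 * f / ((1 - f)^2 * c0)
}

#' @rdname ka_from_fraction
#' @param ka association constant (1/M).
#' @export
fraction_from_ka <- function(ka, c0) {
  a <- ka * c0
  a / (1 + a + sqrt(1 + 2 * a))
}

# van't Hoff Ka(T); dH in kcal/mol, dS in kcal/(mol K), T in K
ka_of_temperature <- function(T_K, dH, dS) {
  exp(-dH / (.R_GAS * T_K) + dS / .R_GAS)
}

# melting temperature where f = 0.5, i.e. Ka = 4/c0
tm_from_params <- function(dH, dS, c0) {
  -dH / (.R_GAS * log(4 / c0) - dS) - 273.15
}

#' Gibbs energy identities
#'
#' `gibbs()` evaluates `dG = dH - TdS` from the enthalpy and the entropy
#' term (both kcal/mol); `gibbs_from_ka()` evaluates `dG = -R T ln Ka`.
#'
#' @param dH enthalpy change (kcal/mol).
#' @param TdS entropy term `T * dS` (kcal/mol).
#' @return Gibbs energy change (kcal/mol).
#' @export
gibbs <- function(dH, TdS) dH - TdS

#' @rdname gibbs
#' @param ka association constant (1/M), positive.
#' @param T_K temperature in Kelvin.
#' @export
gibbs_from_ka <- function(ka, T_K = .T_REF_K) {
  if (any(ka <= 0)) stop("Ka must be positive")
  -.R_GAS * T_K * log(ka)
}

#' Melting curve container
#'
#' @param temperature_C strictly increasing temperatures (deg C).
#' @param absorbance absorbance values (a.u.).
#' @param c0 single-strand concentration (M).
#' @return object of class `melting_curve` (a data frame).
#' @export
melting_curve <- function(temperature_C, absorbance, c0) {
  stopifnot(length(temperature_C) == length(absorbance),
            all(diff(temperature_C) > 0), c0 > 0)
  if (length(temperature_C) < 20)
    warning("melting curves should span both baselines with >= 20 points")
  structure(data.frame(temperature_C = temperature_C,
                       absorbance = absorbance),
            c0 = c0, class = c("melting_curve", "data.frame"))
}

#' Fit the two-state melting model with sloping baselines
#'
#' Nonlinear least squares of
#' `A(T) = f(T) (b_ds + m_ds T) + (1 - f(T)) (b_ss + m_ss T)` where `f(T)`
#' is the exact quadratic root of the duplex mass-action law with
#' `Ka(T) = exp(-dH/RT + dS/R)`.  The melting temperature is the
#' temperature at which the fitted duplex fraction equals 0.5; `dG` and
#' `TdS` are reported at `T_ref`.
#'
#' @param curve a [melting_curve].
#' @param T_ref reference temperature (K) for `dG`/`TdS` (default 294.15,
#'   i.e. 21 deg C).
#' @return object of class `melt_fit`: `dH`, `dS`, `TdS`, `dG`, `Tm_C`,
#'   baseline coefficients, `converged`, `message`, and the input curve.
#' @export
fit_two_state <- function(curve, T_ref = .T_REF_K) {
  stopifnot(inherits(curve, "melting_curve"))
  c0 <- attr(curve, "c0")
  Tc <- curve$temperature_C; A <- curve$absorbance
  TK <- Tc + 273.15
  n <- length(Tc)
  k <- max(3L, floor(0.15 * n))
  bl_f <- coef(lm(A[seq_len(k)] ~ Tc[seq_len(k)]))
  bl_u <- coef(lm(A[n - seq_len(k) + 1] ~ Tc[n - seq_len(k) + 1]))
  predict_A <- function(dH, dS, b_ds, m_ds, b_ss, m_ss) {
    f <- fraction_from_ka(ka_of_temperature(TK, dH, dS), c0)
    f * (b_ds + m_ds * Tc) + (1 - f) * (b_ss + m_ss * Tc)
  }
  # normalized signal for a Tm guess
  theta <- (A - (bl_u[1] + bl_u[2] * Tc)) /
    ((bl_f[1] + bl_f[2] * Tc) - (bl_u[1] + bl_u[2] * Tc))
  cross <- which(diff(sign(theta - 0.5)) != 0)
  Tm0 <- if (length(cross)) Tc[cross[1]] else Tc[which.min(abs(theta - 0.5))]
  best <- NULL
  for (dH0 in c(-50, -80, -110, -140)) {
    dS0 <- .R_GAS * log(4 / c0) + dH0 / (Tm0 + 273.15)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        A ~ predict_A(dH, dS, b_ds, m_ds, b_ss, m_ss),
        start = list(dH = dH0, dS = dS0, b_ds = bl_f[[1]], m_ds = bl_f[[2]],
                     b_ss = bl_u[[1]], m_ss = bl_u[[2]]),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  fail <- function(msg) {
    structure(list(dH = NA_real_, dS = NA_real_, TdS = NA_real_,
                   dG = NA_real_, Tm_C = NA_real_, baselines = NULL,
                   converged = FALSE, message = msg, curve = curve,
                   T_ref = T_ref),
              class = "melt_fit")
  }
  if (is.null(best)) return(fail("two-state fit did not converge"))
  cf <- coef(best$fit)
  f <- fraction_from_ka(ka_of_temperature(TK, cf[["dH"]], cf[["dS"]]), c0)
  if (cf[["dH"]] >= 0 || max(f) < 0.5 || min(f) > 0.5)
    return(fail("no biphasic transition in the temperature range"))
  # a flat/linear curve is fit perfectly by two coincident baselines; require
  # a real amplitude between the folded and unfolded branches at Tm
  tm <- tm_from_params(cf[["dH"]], cf[["dS"]], c0)
  amp <- abs((cf[["b_ds"]] - cf[["b_ss"]]) + (cf[["m_ds"]] - cf[["m_ss"]]) * tm)
  if (amp < 0.02 * diff(range(A)))
    return(fail("no biphasic transition in the temperature range"))
  structure(list(
    dH = cf[["dH"]], dS = cf[["dS"]],
    TdS = T_ref * cf[["dS"]], dG = cf[["dH"]] - T_ref * cf[["dS"]],
    Tm_C = tm_from_params(cf[["dH"]], cf[["dS"]], c0),
    baselines = cf[c("b_ds", "m_ds", "b_ss", "m_ss")],
    fraction = data.frame(temperature_C = Tc, f = f),
    residual = best$sse, converged = TRUE, message = "ok",
    curve = curve, T_ref = T_ref),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<melt_fit> failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<melt_fit> dH %.1f  TdS(%.2f K) %.1f  dG %.1f kcal/mol",
                     "  Tm %.1f C\n"),
              x$dH, x$T_ref, x$TdS, x$dG, x$Tm_C))
  invisible(x)
}

#' van't Hoff fit of ln Ka against 1/T
#'
#' Ordinary least squares of `ln Ka = -dH/R * (1/T) + dS/R`.
#'
#' @param T_K temperatures (K), at least 3.
#' @param ka positive association constants (1/M).
#' @return list with `dH` (kcal/mol), `dS` (kcal/(mol K)) and the `lm` fit.
#' @export
vant_hoff_fit <- function(T_K, ka) {
  if (length(T_K) < 3) stop("van't Hoff fit needs at least 3 points")
  if (any(ka <= 0)) stop("Ka must be positive")
  invT <- 1 / T_K
  fit <- lm(log(ka) ~ invT)
  list(dH = -coef(fit)[["invT"]] * .R_GAS,
       dS = coef(fit)[["(Intercept)"]] * .R_GAS,
       fit = fit)
}

#' van't Hoff analysis of a fitted melting curve
#'
#' Converts the fitted duplex fraction to `Ka(T)` on the subset of points
#' with `f` inside `f_range` (the baseline-dominated tails carry little
#' information about `Ka`), then applies [vant_hoff_fit()].
#'
#' @param fit a converged [fit_two_state()] result.
#' @param f_range fraction window used for the regression.
#' @return list with `dH`, `dS`, `TdS`, `dG` at the fit's `T_ref`.
#' @export
melt_vant_hoff <- function(fit, f_range = c(0.15, 0.85)) {
  stopifnot(inherits(fit, "melt_fit"), fit$converged)
  c0 <- attr(fit$curve, "c0")
  f <- fit$fraction$f
  keep <- f > f_range[1] & f < f_range[2]
  if (sum(keep) < 3) stop("fewer than 3 points inside the f window")
  vh <- vant_hoff_fit(fit$fraction$temperature_C[keep] + 273.15,
                      ka_from_fraction(f[keep], c0))
  list(dH = vh$dH, dS = vh$dS, TdS = fit$T_ref * vh$dS,
       dG = vh$dH - fit$T_ref * vh$dS)
}

# --- ITC --------------------------------------------------------------------

#' ITC titration series container
#'
#' @param heats per-injection integrated heats (ucal).
#' @param injection_volumes injection volumes (L), recycled to match.
#' @param cell_conc cell-species concentration (M).
#' @param syringe_conc titrant concentration (M).
#' @param cell_volume calorimeter cell volume (L).
#' @param T_C experiment temperature (deg C).
#' @return object of class `itc_series`.
#' @export
itc_series <- function(heats, injection_volumes, cell_conc, syringe_conc,
                       cell_volume, T_C = 21) {
  vol <- rep_len(injection_volumes, length(heats))
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0, all(vol > 0))
  structure(list(
    table = data.frame(injection = seq_along(heats),
                       volume_uL = vol * 1e6, heat_ucal = heats),
    cell_conc = cell_conc, syringe_conc = syringe_conc,
    cell_volume = cell_volume, T_C = T_C),
    class = "itc_series")
}

#' @export
print.itc_series <- function(x, ...) {
  cat("<itc_series> ", nrow(x$table), " injections, cell ",
      x$cell_conc * 1e6, " uM, syringe ", x$syringe_conc * 1e6,
      " uM, cell volume ", x$cell_volume * 1e6, " uL\n", sep = "")
  invisible(x)
}

# exact 1:1 binding heats (ucal per injection).  Perfusion cell at constant
# volume: each injection displaces its own volume of pre-injection solution,
# then the syringe aliquot mixes in; the complex concentration is the
# physical root of the binding quadratic with site concentration n * [B].
itc_model_heats <- function(ka, dH, n, qdil, cell_conc, syringe_conc,
                            cell_volume, inj_vol) {
  a <- 0; b <- cell_conc; c_prev <- 0
  heats <- numeric(length(inj_vol))
  for (k in seq_along(inj_vol)) {
    dil <- 1 - inj_vol[k] / cell_volume
    a <- a * dil + syringe_conc * inj_vol[k] / cell_volume
    b <- b * dil
    s <- a + n * b + 1 / ka
    cc <- (s - sqrt(s^2 - 4 * a * n * b)) / 2
    heats[k] <- dH * cell_volume * (cc - c_prev * dil) * 1e9 + qdil
    c_prev <- cc
  }
  heats
}

#' Fit the 1:1 binding model to an ITC series
#'
#' The dilution heat is either estimated as the mean of the final
#' `n_tail` post-saturation injections and subtracted (`qdil =
#' "subtract"`, the default), fitted as a free parameter (`"fit"`), fixed
#' at a numeric value, or ignored (`"none"`, equivalent to 0).  If no
#' saturation plateau is detected in subtract mode the fitter falls back to
#' the free-parameter mode with a warning.  The remaining heats are fitted
#' with the exact 1:1 binding model (quadratic root for the bound complex
#' before and after each injection, with volume-displacement dilution of
#' both species) over `(Ka, dH, n)`.
#'
#' @param series an [itc_series].
#' @param T_K temperature (K) for the Gibbs identities; default taken from
#'   the series.
#' @param qdil dilution-heat mode or fixed value (ucal).
#' @param n_tail tail injections used in subtract mode.
#' @return object of class `itc_fit`: `ka`, `dH`, `n`, `qdil`, `dG`,
#'   `TdS`, `residual`, `converged`, `message`.
#' @export
fit_itc <- function(series, T_K = NULL, qdil = "subtract", n_tail = 3L) {
  stopifnot(inherits(series, "itc_series"))
  h <- series$table$heat_ucal
  if (length(h) < 8) stop("ITC fitting needs at least 8 injections")
  if (is.null(T_K)) T_K <- series$T_C + 273.15
  inj_vol <- series$table$volume_uL * 1e-6
  if (sd(h) < 1e-9 * max(1, max(abs(h)))) {
    return(structure(list(ka = NA_real_, dH = 0, n = NA_real_,
                          qdil = mean(h), dG = NA_real_, TdS = NA_real_,
                          residual = 0, converged = FALSE,
                          message = "all heats identical; Ka indeterminate",
                          T_K = T_K),
                     class = "itc_fit"))
  }
  qdil_fixed <- NA_real_; fit_qdil <- FALSE
  if (is.numeric(qdil)) {
    qdil_fixed <- qdil
  } else if (qdil == "none") {
    qdil_fixed <- 0
  } else if (qdil == "fit") {
    fit_qdil <- TRUE
  } else if (qdil == "subtract") {
    tail_h <- tail(h, n_tail)
    plateau <- diff(range(tail_h)) < 0.05 * diff(range(h))
    if (!plateau) {
      warning("no saturation plateau detected; fitting Qdil as a free ",
              "parameter", call. = FALSE)
      fit_qdil <- TRUE
    } else {
      qdil_fixed <- mean(tail_h)
    }
  } else stop("unknown qdil mode")
  model <- function(p) {
    itc_model_heats(exp(p[1]), p[2], exp(p[3]),
                    if (fit_qdil) p[4] else qdil_fixed,
                    series$cell_conc, series$syringe_conc,
                    series$cell_volume, inj_vol)
  }
  # starting guesses: stoichiometry from the molar ratio at the steepest
  # change of heat, enthalpy from the first (fully binding) injection
  ratio <- cumsum(series$syringe_conc * inj_vol) /
    (series$cell_conc * series$cell_volume)
  q0 <- if (fit_qdil) mean(tail(h, 2)) else qdil_fixed
  n0 <- ratio[which.max(abs(diff(h - q0)))]
  n0 <- min(3, max(0.3, n0))
  dH0 <- (h[1] - q0) / (series$syringe_conc * inj_vol[1] * 1e9)
  best <- NULL
  for (lka0 in log(c(1e5, 1e6, 1e7, 1e8))) {
    p0 <- c(lka0, dH0, log(n0), if (fit_qdil) q0)
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = function(p) h - model(p),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    return(structure(list(ka = NA_real_, dH = NA_real_, n = NA_real_,
                          qdil = NA_real_, dG = NA_real_, TdS = NA_real_,
                          residual = NA_real_, converged = FALSE,
                          message = "1:1 fit did not converge", T_K = T_K),
                     class = "itc_fit"))
  p <- best$fit$par
  ka <- exp(p[1]); dH <- p[2]; nn <- exp(p[3])
  dG <- gibbs_from_ka(ka, T_K)
  structure(list(ka = ka, dH = dH, n = nn,
                 qdil = if (fit_qdil) p[4] else qdil_fixed,
                 dG = dG, TdS = dH - dG, residual = best$sse,
                 converged = TRUE, message = "ok", T_K = T_K),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<itc_fit> failed:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<itc_fit> Ka %.3g 1/M  dH %.1f  TdS %.1f  dG %.1f",
                     " kcal/mol  n %.2f\n"),
              x$ka, x$dH, x$TdS, x$dG, x$n))
  invisible(x)
}
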