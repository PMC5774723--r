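# Seeded generators for solution-thermodynamics data: two-state melting
# curves with sloping baselines and exact 1:1 ITC binding isotherms with
# dilution heat, both reproducible bit-for-bit for a fixed seed.

#' Parameters for the melting-curve generator
#'
#' @param dH enthalpy change of duplex formation (kcal/mol, < 0).
#' @param TdS entropy term at 294.15 K (kcal/mol); exactly one of `TdS`,
#'   `dS` must be given.
#' @param dS entropy change (kcal/(mol K)).
#' @param c0 single-strand concentration (M).
#' @param T_C temperature grid (deg C), strictly increasing.
#' @param baseline_folded,baseline_unfolded `c(intercept, slope)` of the
#'   folded/unfolded absorbance baselines (vs deg C).
#' @param noise_sd Gaussian absorbance noise standard deviation (>= 0).
#' @param seed integer seed for the noise.
#' @return list of class `melt_sim_params`.
#' @export
melt_sim_params <- function(dH, TdS = NULL, dS = NULL, c0 = 2e-6,
                            T_C = seq(10, 90, by = 0.5),
                            baseline_folded = c(0.80, 0.0006),
                            baseline_unfolded = c(0.95, 0.0010),
                            noise_sd = 0, seed = NULL) {
  if (is.null(dS) == is.null(TdS))
    stop("supply exactly one of dS, TdS")
  if (is.null(dS)) dS <- TdS / .T_REF_K
  stopifnot(all(diff(T_C) > 0), noise_sd >= 0, c0 > 0)
  structure(list(dH = dH, dS = dS, c0 = c0, T_C = T_C,
                 baseline_folded = baseline_folded,
                 baseline_unfolded = baseline_unfolded,
                 noise_sd = noise_sd, seed = seed),
            class = "melt_sim_params")
}

#' Generate a two-state melting curve
#'
#' `A(T) = f(T) (b_ds + m_ds T) + (1 - f(T)) (b_ss + m_ss T) + eps`, with
#' the duplex fraction `f(T)` solving the duplex mass-action law for
#' `Ka(T) = exp(-dH/RT + dS/R)` and `eps ~ N(0, noise_sd^2)` (seeded).
#'
#' @param p a [melt_sim_params].
#' @return a [melting_curve].
#' @export
generate_melting_curve <- function(p) {
  stopifnot(inherits(p, "melt_sim_params"))
  TK <- p$T_C + 273.15
  f <- fraction_from_ka(ka_of_temperature(TK, p$dH, p$dS), p$c0)
  A <- f * (p$baseline_folded[1] + p$baseline_folded[2] * p$T_C) +
    (1 - f) * (p$baseline_unfolded[1] + p$baseline_unfolded[2] * p$T_C)
  if (p$noise_sd > 0)
    A <- A + with_seed(p$seed, rnorm(length(A), sd = p$noise_sd))
  melting_curve(p$T_C, A, p$c0)
}

#' Parameters for the ITC series generator
#'
#' Defaults mirror the strand-association titration scheme: twenty 2 uL
#' injections of 100 uM titrant into a 10 uM cell solution at 21 deg C
#' (190 uL calorimeter cell).
#'
#' @param ka association constant (1/M).
#' @param dH binding enthalpy (kcal/mol).
#' @param n stoichiometry (> 0).
#' @param cell_conc,syringe_conc concentrations (M).
#' @param cell_volume cell volume (L).
#' @param injection_volumes injection volumes (L), recycled.
#' @param qdil dilution heat per injection (ucal).
#' @param noise_sd Gaussian heat noise (ucal).
#' @param seed integer seed.
#' @param T_C temperature (deg C).
#' @return list of class `itc_sim_params`.
#' @export
itc_sim_params <- function(ka, dH, n = 1, cell_conc = 10e-6,
                           syringe_conc = 100e-6, cell_volume = 190e-6,
                           injection_volumes = rep(2e-6, 20), qdil = 0,
                           noise_sd = 0, seed = NULL, T_C = 21) {
  stopifnot(ka > 0, n > 0, cell_conc > 0, syringe_conc > 0,
            cell_volume > 0, all(injection_volumes > 0), noise_sd >= 0)
  structure(list(ka = ka, dH = dH, n = n, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, cell_volume = cell_volume,
                 injection_volumes = injection_volumes, qdil = qdil,
                 noise_sd = noise_sd, seed = seed, T_C = T_C),
            class = "itc_sim_params")
}

#' Generate a 1:1 ITC titration series
#'
#' Per-injection heats from the exact 1:1 binding model (quadratic root for
#' the bound complex before and after each injection, volume-displacement
#' dilution of both species), plus the dilution heat and seeded Gaussian
#' noise.
#'
#' @param p an [itc_sim_params].
#' @return an [itc_series].
#' @export
generate_itc_series <- function(p) {
  stopifnot(inherits(p, "itc_sim_params"))
  heats <- itc_model_heats(p$ka, p$dH, p$n, p$qdil, p$cell_conc,
                           p$syringe_conc, p$cell_volume,
                           p$injection_volumes)
  if (p$noise_sd > 0)
    heats <- heats + with_seed(p$seed, rnorm(length(heats), sd = p$noise_sd))
  itc_series(heats, p$injection_volumes, p$cell_conc, p$syringe_conc,
             p$cell_volume, p$T_C)
}
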