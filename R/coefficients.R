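#' Default process coefficients
#'
#' The full set of process coefficients of the model: first-order and
#' Michaelis-Menten rate constants, half-saturation and inhibition constants,
#' equilibrium concentrations, stoichiometric ratios, temperature
#' coefficients and transport parameters, all at their calibrated shallow-lake
#' default values. Rates are values at 20 degC unless stated otherwise.
#' Every entry can be overridden through the model configuration.
#'
#' @param ... named overrides, e.g. `eco_coefficients(k_s = 5)`.
#' @return A named list of class `eco_coefficients`.
#' @export
eco_coefficients <- function(...) {
  co <- list(
    ## -- decomposition of detrital organic matter (five fractions) --------
    # min/max first-order mineralization rates at 20 degC, d^-1; the min/max
    # pair is interpolated by the nutrient availability function for the
    # bacteria (fractions 1 and 2; 3-5 have a single rate)
    k_d_min = c(0.15, 0.025, 0.0012, 0.000035, 0.002),
    k_d_max = c(0.20, 0.025, 0.0012, 0.000035, 0.002),
    # nutrient content bands steering the min/max interpolation, g X / g C
    a_n_min = c(0.075, 0.06), a_n_max = c(0.15, 0.12),
    a_p_min = c(0.0075, 0.006), a_p_max = c(0.015, 0.012),
    # target (objective) nutrient contents of refractory residue, g X / g C
    ar_n = 0.07, ar_p = 0.007,
    fac_max = 10,  # cap on the nutrient stripping acceleration factor
    # conversion ratios: POX1->POX2, POX2->POX3, POX3->POX4 and POX2/3->DOX
    fc_p = c(0.3, 0.2, 0.2), fc_d = 0.17,
    # electron-acceptor dependency of the mineralization rate (1 = ignored)
    fel = 1.0,
    kt_dec = 1.047,      # temperature coefficient, decomposition
    kt_mic = 1.07,       # temperature coefficient, other microbial processes
    ts = 1.25,           # low-temperature scaling factor (T <= 2 degC)
    ## -- electron acceptor cascade ----------------------------------------
    Ks_oc = 1.0,   # O2 limitation of aerobic mineralization, g O2 m-3
    Ks_de = 0.25,  # NO3 limitation of denitrification, g N m-3
    Ks_sr = 2.0,   # SO4 limitation of sulphate reduction, g S m-3
    Ks_doi = 1.0,  # O2 inhibition, g O2 m-3
    Ks_nii = 0.02, # NO3 inhibition, g N m-3
    Ks_sui = 1.0,  # SO4 inhibition of methanogenesis, g S m-3
    ## -- redox stoichiometry (half-reaction arithmetic, g per g C unless
    ##    stated; exposed so alternative electron balances can be configured)
    st_o2_c = 32 / 12,            # O2 demand of aerobic mineralization
    st_no3_c = 4 / 5 * 14 / 12,   # NO3-N demand of denitrification
    st_so4_c = 32 / 24,           # SO4-S demand of sulphate reduction
    st_ch4_c = 0.5,               # CH4-C yield of methanogenesis
    st_o2_n = 2 * 32 / 14,        # O2 demand of nitrification, g O2 / g N
    st_o2_su = 2 * 32 / 64,       # O2 demand of sulphide oxidation, g O2/g S
    st_o2_ch4 = 2 * 32 / 12,      # O2 demand of methane oxidation, g O2/g C
    st_so4_ch4 = 32 / 12,         # SO4-S demand of CH4 + SO4 oxidation
    ## -- nitrification -----------------------------------------------------
    k_ni_water = 0.2, k_ni_sediment = 25.0,  # MM maximum, g N m-3 d-1
    Ks_an = 0.4, Ks_do = 1.0,
    ## -- phosphate ----------------------------------------------------------
    K_ads = 2.2e3,  # Langmuir affinity, (mol/L)^(a-1)
    a_ads = 0.2,    # reaction constant of the pH dependency
    k_s = 10.0,     # sorption rate towards the Langmuir equilibrium, d-1
    fe_im1 = 0.025, fe_im1_top = 0.075,  # reactive Fe fraction of IM1 (bulk /
                                         # top 4 mm), g Fe / g
    fe_im3 = 0.05,                       # reactive Fe fraction of IM3
    f_ox = 0.1, f_ox_top = 0.2,  # oxidized Fe fraction at anoxia (deep / top)
    top_ox_depth = 0.004,        # m, extent of the Fe-enriched oxidized top
    do_crit = 0.25,  # g O2 m-3: full adsorption capacity above; vivianite
                     # precipitation below
    mw_fe = 55.85, mw_p = 30.97,
    kv_p = 0.6,      # vivianite precipitation rate, d-1
    kv_d = 0.05,     # vivianite dissolution rate, (g O2 m-3)-1 d-1
    k_ad = 0.0025,   # apatite dissolution rate, (g P m-3)-1 d-1
    r_av = 2.0,      # ratio apatite : vivianite precipitation
    PO4_ve = 0.15, PO4_ae = 0.15,  # equilibrium dissolved P, g P m-3 (pw)
    ## -- opal ----------------------------------------------------------------
    k_od = 0.00005,  # (g Si m-3)-1 d-1
    Si_e = 10.0,     # g Si m-3 (pw)
    kt_opal = 1.07,
    ## -- sulphur -------------------------------------------------------------
    k_so = 10.0,     # sulphide oxidation, (g O2 m-3)-1 d-1
    ks_p = 1e6, k_sd = 2e6,  # FeS precipitation / dissolution, d-1
    Cs_e = 0.2e-10,  # free sulphide at FeS saturation, mol/L
    Ks_1 = 1e-7, Ks_2 = 1e-14,  # sulphide acidity constants
    mw_s = 32.06,
    ## -- methane -------------------------------------------------------------
    k_moo = 0.1, k_mos = 0.05,  # MM maxima, g C m-3 d-1
    Ks_me = 0.5, Ks_moo = 1.0, Ks_mos = 1.0,
    ch4_sat_base = 100 * 12 / 64,  # g C m-3 at surface pressure, 20 degC
    ch4_sat_kt = 1.024,
    ## -- gas exchange ---------------------------------------------------------
    # transfer coefficient polynomial in wind speed (m/s), m d-1
    kl_a = 0.728, kl_b = -0.317, kl_c = 0.0372, kl_kt = 1.016,
    kl_ch4_factor = 1.0,
    ## -- light ----------------------------------------------------------------
    e_b = 0.08, es_poc = 0.1, es_doc = 0.3, es_im3 = 0.018,
    ## -- phytoplankton community ------------------------------------------------
    f_am = 1.0,        # hard preference for ammonium in N uptake
    f_aut = 0.35,      # autolysis fraction of mortality
    f_d1 = c(0.55, 0.62), f_d2 = c(0.45, 0.38),  # detritus split, types
                                                 # 1-8 / 9-14
    I_half = 20,       # W m-2 PAR, half-saturation of the light response
    seed_biomass = 1e-6,  # g C m-3 d-1 scale invasion seed per group
    st_o2_prod = 32 / 12,  # O2 yield of net primary production
    ## -- grazing ------------------------------------------------------------------
    k_grz = 0.1,       # (g C m-3 zooplankton)-1 d-1
    f_grz_resp = 0.3,  # respired/excreted share of grazed mass
    ## -- sediment transport ----------------------------------------------------
    D_mol = 0.75e-4,   # molecular diffusion, m2 d-1 (tortuosity-corrected
                       # with porosity^2 where applied)
    Ds_winter = 1.78e-4, Ds_summer = 7.73e-4,  # solute dispersion at the
                                               # interface, m2 d-1
    Dp_winter = 2.8e-7, Dp_summer = 2.8e-6,    # bioturbation, m2 d-1
    lambda_s = log(10) / 0.05,  # depth decay, solutes (10% at 5 cm), m-1
    lambda_p = log(10) / 0.04,  # depth decay, particulates (10% at 4 cm)
    summer_peak_day = 196,      # day of year of maximal benthic activity
    L0 = 0.0005,       # m, diffusive boundary layer above the sediment
    rho_solid = 2.6e6  # g m-3, dry solid density fixing burial velocity
  )
  class(co) <- "eco_coefficients"
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(co))
    if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "))
    co[names(ov)] <- ov
  }
  stopifnot(all(co$k_d_min <= co$k_d_max),
            all(unlist(co[grep("^k_|^Ks_", names(co))]) >= 0))
  co
}

#' Phytoplankton phenotype parameters
#'
#' The packaged parameter table for the 14 freshwater phytoplankton
#' phenotypes: five species groups (diatoms, green algae, and the
#' cyanobacteria *Aphanizomenon*, *Microcystis* and *Oscillatoria*), each
#' represented by an energy-, nitrogen- and/or phosphorus-adapted phenotype
#' with its own stoichiometry (g N, P, Si, S and chlorophyll-a per g C),
#' specific extinction, growth, respiration and mortality rates (values at
#' 0 degC) and temperature coefficients. `temp_fun` selects the growth-rate
#' temperature response: `"exp"` for `kp * kt_p^T`, `"lin"` for
#' `kp * max(0, T - kt_p)`.
#'
#' @param file optional path to an alternative delimited parameter file with
#'   the same columns.
#' @return data.frame with one row per phenotype.
#' @export
phyto_types <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "phyto_types.tsv", package = "eutrosim")
    if (file == "") file <- file.path("inst", "extdata", "phyto_types.tsv")
  }
  ph <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "group", "es_a", "s_n", "s_p", "s_si", "kp", "kt_p",
                  "km", "kt_m", "kr", "kt_r", "s_s", "v_a", "temp_fun")
                %in% names(ph)),
            all(ph$s_n > 0), all(ph$s_p > 0))
  ph
}

#' Temperature adjustment of a rate constant
#'
#' Scales a rate constant given at the 20 degC reference to ambient
#' temperature, `k20 * kt^(T - 20)`. Below 2 degC microbial activity is
#' additionally damped by the low-temperature scaling factor `ts`, applied as
#' `ts^(T - t_low)` (a factor 1/ts per degree below `t_low`).
#'
#' @param k20 rate constant at 20 degC.
#' @param kt dimensionless temperature coefficient (> 0); 1 means
#'   temperature-independent.
#' @param T_deg temperature, degC.
#' @param ts low-temperature scaling factor (>= 1); 1 disables it.
#' @param t_low threshold below which `ts` applies, degC.
#' @return adjusted rate, same units as `k20`.
#' @export
#' @examples
#' temperature_adjust(0.2, 1.047, 20)           # 0.2
#' temperature_adjust(0.15, 1.047, 10)          # 0.15 * 1.047^-10
temperature_adjust <- function(k20, kt, T_deg, ts = 1, t_low = 2) {
  if (any(kt <= 0)) stop("temperature coefficient kt must be positive")
  k <- k20 * kt^(T_deg - 20)
  cold <- !is.na(T_deg) & T_deg <= t_low
  if (any(cold) && any(ts > 1))
    k[cold] <- (k * ts^(pmin(T_deg, t_low) - t_low))[cold]
  k
}

#' Tortuosity-corrected molecular diffusion
#'
#' Corrects a free-solution molecular diffusion coefficient for sediment
#' tortuosity with the porosity-squared model, `D * phi^2`.
#'
#' @param D_mol molecular diffusion coefficient, m2 d-1.
#' @param phi porosity (0, 1].
#' @return effective diffusion coefficient in the pore network, m2 d-1.
#' @export
#' @examples
#' tortuosity_corrected_diffusion(0.75e-4, 0.55)  # 2.27e-5
tortuosity_corrected_diffusion <- function(D_mol, phi) {
  stopifnot(all(phi > 0), all(phi <= 1))
  D_mol * phi^2
}
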