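# Synthetic two-compartment shallow lake: a fully self-contained test
# system with seasonal sinusoidal forcing and constant loads, so the entire
# model can be exercised without any external data.

#' Synthetic shallow-lake configuration
#'
#' Builds a deterministic (seeded) two-compartment lake: a shallow sandy
#' compartment (60% of the area, 0.75 m deep, porosity 0.4, upward seepage)
#' and a deeper silty compartment (40%, 2.5 m, porosity 0.7, infiltration),
#' each with the default ten-layer sediment stack. Forcing is weekly:
#' sinusoidal temperature (2-22 degC) and PAR (20-180 W m-2), seeded noisy
#' wind around 4 m s-1, seasonal pH and zooplankton, constant suspended
#' sediment. Water inflows give a residence time of about a quarter year
#' and carry constant concentrations; nutrient and organic loads are
#' constant. The two compartments are coupled by a large exchange flow so
#' their water quality stays nearly identical.
#'
#' @param seed integer seed for the wind-noise draws; everything else is
#'   deterministic.
#' @param years length of the forcing series, yr.
#' @param ... overrides passed on to [eco_config()] (e.g. `processes`).
#' @return an `eco_config`.
#' @export
synthetic_lake <- function(seed = 1L, years = 1, ...) {
  stopifnot(years >= 1)
  area_tot <- 32.3e6
  cm <- data.frame(
    name = c("shallow", "deep"),
    area = c(0.6, 0.4) * area_tot,
    depth = c(0.75, 2.5),
    porosity = c(0.4, 0.7),
    v_settle = c(0.115, 0.23),
    v_spg = c(0.0057, -0.015),
    stringsAsFactors = FALSE)
  tt <- seq(0, 365 * years, by = 7)
  seas <- function(amp0, amp, lag = 15) amp0 - amp * cos(2 * pi * (tt - lag) / 365)
  set.seed(seed)
  wind <- pmax(0.5, 4 + stats::rnorm(length(tt), 0, 1.2))
  forcing <- list(
    temperature = data.frame(time = tt, value = seas(12, 10)),
    par = data.frame(time = tt, value = seas(100, 80)),
    wind = data.frame(time = tt, value = wind),
    ph = data.frame(time = tt, value = seas(8.2, -0.3, lag = 180)),
    im3 = data.frame(time = tt, value = rep(10, length(tt))),
    zoo = data.frame(time = tt, value = pmax(0, seas(0.12, 0.12, lag = 45))))
  V_tot <- sum(cm$area * cm$depth)
  Q_tot <- V_tot / (0.25 * 365)
  Qin <- stats::setNames(Q_tot * cm$area / area_tot, cm$name)
  inflow_conc <- c(Cl = 100, NO3 = 2.5, NH4 = 0.5, PO4 = 0.03, Si = 4,
                   SO4 = 60, DO = 9, DOC = 5, DON = 0.35, DOP = 0.035,
                   DOS = 0.0875, IM1 = 5, POC1 = 1, PON1 = 0.1,
                   POP1 = 0.01, POS1 = 0.0175)
  loads_gm2yr <- c(PO4 = 1.5, NO3 = 20, NH4 = 10, POC1 = 20, PON1 = 2,
                   POP1 = 0.2, POS1 = 0.35, IM1 = 50)
  loads <- loads_gm2yr * area_tot / 365
  deep_conc <- c(Cl = 100, NO3 = 0, NH4 = 2, PO4 = 0.3, Si = 8, SO4 = 30,
                 DO = 0, DOC = 10, DON = 0.7, DOP = 0.07, DOS = 0.175,
                 SUD = 0.5, CH4 = 0)
  ph <- phyto_types()
  subs <- substance_table(ph)
  water <- matrix(0, 2, nrow(subs), dimnames = list(cm$name, subs$name))
  wini <- c(Cl = 100, DO = 10, NO3 = 2, NH4 = 0.3, PO4 = 0.05, Si = 3,
            SO4 = 60, DOC = 5, DON = 0.35, DOP = 0.035, DOS = 0.0875,
            POC1 = 0.5, PON1 = 0.05, POP1 = 0.005, POS1 = 0.00875,
            POC2 = 0.5, PON2 = 0.045, POP2 = 0.0045, POS2 = 0.00875,
            IM3 = 10, IM1 = 2)
  water[, names(wini)] <- rep(wini, each = 2)
  energy_types <- paste0("ALG", which(ph$phenotype == "energy"))
  water[, energy_types] <- 0.02
  nl <- length(default_layers())
  sediment <- array(0, c(2, nl, nrow(subs)),
                    dimnames = list(cm$name, NULL, subs$name))
  for (c in 1:2) {
    phi <- cm$porosity[c]
    solids <- 2.6e6 * (1 - phi)
    oc <- if (c == 1) 1.6e-3 else 10e-3      # g OC per g DM
    poc <- oc * solids
    sediment[c, , "IM1"] <- solids * 0.97
    sediment[c, , "IM2"] <- solids * 0.02
    sediment[c, , "POC3"] <- 0.6 * poc
    sediment[c, , "POC4"] <- 0.4 * poc
    sediment[c, , "PON3"] <- 0.09 * 0.6 * poc
    sediment[c, , "PON4"] <- 0.07 * 0.4 * poc
    sediment[c, , "POP3"] <- 0.009 * 0.6 * poc
    sediment[c, , "POP4"] <- 0.007 * 0.4 * poc
    sediment[c, , "POS3"] <- 0.0175 * 0.6 * poc
    sediment[c, , "POS4"] <- 0.0175 * 0.4 * poc
    inorgP <- if (c == 1) c(60, 30, 45) else c(150, 90, 150)
    sediment[c, , "AAP"] <- inorgP[1]
    sediment[c, , "VIVP"] <- inorgP[2]
    sediment[c, , "APATP"] <- inorgP[3]
    sediment[c, , "SUP"] <- 20
    sediment[c, , "OPAL"] <- 50
    pw <- c(PO4 = 0.15, NH4 = 2, NO3 = 0.05, Si = 8, SO4 = 10, SUD = 0.1,
            CH4 = 1, DO = 0.2, Cl = 100, DOC = 20, DON = 1.4, DOP = 0.14,
            DOS = 0.35)
    for (s in names(pw)) sediment[c, , s] <- pw[[s]] * phi
  }
  eco_config(compartments = cm, forcing = forcing,
             inflow = Qin, outflow = Qin,
             exchange_flow = 1.5e7,
             inflow_conc = inflow_conc, loads = loads,
             deep_conc = deep_conc,
             initial = list(water = water, sediment = sediment),
             seed = seed, ...)
}
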