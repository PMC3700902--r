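# Per-step assembly of all kinetic process rates, vectorized over cells.
# Rates are bulk g m-3 d-1; process laws that act on dissolved
# concentrations are evaluated on the pore-water basis and scaled back by
# porosity. Carbon leaving the modelled pools as CO2 and nitrogen leaving
# as N2 are returned separately for the flux ledger.

kinetics_rates <- function(Cb, M, T_deg, ph_cell, W, zoo) {
  co <- M$co; i <- M$i; pr <- M$cfg$processes
  phi <- M$phi
  n <- M$ncell
  delta <- matrix(0, n, M$nsub)
  gasC <- numeric(n); gasN <- numeric(n)
  atmDO <- numeric(M$nc); atmCH4 <- numeric(M$nc)
  pwDO <- Cb[, i$DO] / phi
  pwNO3 <- Cb[, i$NO3] / phi
  pwNH4 <- Cb[, i$NH4] / phi
  pwSO4 <- Cb[, i$SO4] / phi
  pwPO4 <- Cb[, i$PO4] / phi
  pwSi <- Cb[, i$Si] / phi
  pwSUD <- Cb[, i$SUD] / phi
  pwCH4 <- Cb[, i$CH4] / phi
  f_dec <- temperature_adjust(1, co$kt_dec, T_deg, ts = co$ts)

  ## ---- multi-G decomposition and the electron-acceptor cascade ----
  if (pr$organic_matter) {
    POC <- Cb[, i$POC, drop = FALSE]; PON <- Cb[, i$PON, drop = FALSE]
    POP <- Cb[, i$POP, drop = FALSE]; POS <- Cb[, i$POS, drop = FALSE]
    eps <- 1e-30
    NC1 <- PON[, 1] / pmax(POC[, 1], eps)
    PC1 <- POP[, 1] / pmax(POC[, 1], eps)
    fnut1 <- nutrient_rate_modifier(NC1, PC1, co$a_n_min[1], co$a_n_max[1],
                                    co$a_p_min[1], co$a_p_max[1])
    kd <- cbind((co$k_d_min[1] + fnut1 * (co$k_d_max[1] - co$k_d_min[1])),
                co$k_d_min[2], co$k_d_min[3], co$k_d_min[4]) * f_dec * co$fel
    k5 <- co$k_d_min[5] * f_dec * co$fel
    minC <- kd * POC
    minC5 <- k5 * Cb[, i$DOC]
    facN <- pmin(pmax(1, PON / pmax(POC, eps) / co$ar_n), co$fac_max)
    facP <- pmin(pmax(1, POP / pmax(POC, eps) / co$ar_p), co$fac_max)
    minN <- facN * kd * PON
    minP <- facP * kd * POP
    minS <- kd * POS
    facN5 <- pmin(pmax(1, Cb[, i$DON] / pmax(Cb[, i$DOC], eps) / co$ar_n),
                  co$fac_max)
    facP5 <- pmin(pmax(1, Cb[, i$DOP] / pmax(Cb[, i$DOC], eps) / co$ar_p),
                  co$fac_max)
    minN5 <- facN5 * k5 * Cb[, i$DON]
    minP5 <- facP5 * k5 * Cb[, i$DOP]
    minS5 <- k5 * Cb[, i$DOS]
    fcp <- co$fc_p; fcd <- co$fc_d
    apply_pool <- function(idx, m, m5, i5) {
      delta[, idx[1]] <<- delta[, idx[1]] - m[, 1] * (1 + fcp[1])
      delta[, idx[2]] <<- delta[, idx[2]] + fcp[1] * m[, 1] -
        m[, 2] * (1 + fcp[2] + fcd)
      delta[, idx[3]] <<- delta[, idx[3]] + fcp[2] * m[, 2] -
        m[, 3] * (1 + fcp[3] + fcd)
      delta[, idx[4]] <<- delta[, idx[4]] + fcp[3] * m[, 3] - m[, 4]
      delta[, i5] <<- delta[, i5] + fcd * (m[, 2] + m[, 3]) - m5
    }
    apply_pool(i$POC, minC, minC5, i$DOC)
    apply_pool(i$PON, minN, minN5, i$DON)
    apply_pool(i$POP, minP, minP5, i$DOP)
    apply_pool(i$POS, minS, minS5, i$DOS)
    mintC <- rowSums(minC) + minC5
    fr <- electron_acceptor_fractions(pwDO, pwNO3, pwSO4, co)
    cons <- acceptor_consumption(mintC, fr, rowSums(minN) + minN5,
                                 rowSums(minP) + minP5,
                                 rowSums(minS) + minS5, co)
    delta[, i$DO] <- delta[, i$DO] + cons$dDO
    delta[, i$NO3] <- delta[, i$NO3] + cons$dNO3
    delta[, i$SO4] <- delta[, i$SO4] + cons$dSO4
    delta[, i$CH4] <- delta[, i$CH4] + cons$dCH4
    delta[, i$NH4] <- delta[, i$NH4] + cons$dNH4
    delta[, i$PO4] <- delta[, i$PO4] + cons$dPO4
    delta[, i$SUD] <- delta[, i$SUD] + cons$dSUD
    gasC <- gasC + cons$co2
    gasN <- gasN + cons$n2
  }

  ## ---- nitrification ----
  if (pr$nutrients) {
    nit <- phi * nitrification_rate(pwNH4, pwDO, M$k_ni, T_deg, co)
    delta[, i$NH4] <- delta[, i$NH4] - nit
    delta[, i$NO3] <- delta[, i$NO3] + nit
    delta[, i$DO] <- delta[, i$DO] - co$st_o2_n * nit

    ## ---- phosphate minerals ----
    ## (sorption is handled as an analytic relaxation substep, see
    ## sorption_step(): the Langmuir equilibrium of the total P pool is the
    ## target, so the exchange is unconditionally mass-limited)
    viv <- vivianite_kinetics(pwPO4, Cb[, i$VIVP], pwDO, co)
    apa <- apatite_kinetics(pwPO4, Cb[, i$APATP], co)
    pre_v <- phi * viv$precipitation
    pre_a <- phi * apa$precipitation
    dis_v <- viv$dissolution
    dis_a <- apa$dissolution
    delta[, i$PO4] <- delta[, i$PO4] + dis_v + dis_a - pre_v - pre_a
    delta[, i$VIVP] <- delta[, i$VIVP] + pre_v - dis_v
    delta[, i$APATP] <- delta[, i$APATP] + pre_a - dis_a

    ## ---- opal dissolution ----
    od <- opal_dissolution(Cb[, i$OPAL], pwSi, co$k_od, co$Si_e, T_deg, co)
    delta[, i$OPAL] <- delta[, i$OPAL] - od
    delta[, i$Si] <- delta[, i$Si] + od
  }

  ## ---- sulphide and methane oxidation ----
  if (pr$sulphur) {
    sox <- phi * sulphide_oxidation(pwSUD, pwDO, co$k_so, T_deg, co)
    delta[, i$SUD] <- delta[, i$SUD] - sox
    delta[, i$SO4] <- delta[, i$SO4] + sox
    delta[, i$DO] <- delta[, i$DO] - co$st_o2_su * sox
    mox <- methane_oxidation(pwCH4, pwDO, pwSO4, T_deg, co)
    moo <- phi * mox$rate_O2
    mos <- phi * mox$rate_SO4
    delta[, i$CH4] <- delta[, i$CH4] - moo - mos
    delta[, i$DO] <- delta[, i$DO] - co$st_o2_ch4 * moo
    delta[, i$SO4] <- delta[, i$SO4] - co$st_so4_ch4 * mos
    delta[, i$SUD] <- delta[, i$SUD] + co$st_so4_ch4 * mos
    gasC <- gasC + moo + mos
  }

  ## ---- zooplankton grazing (water column) ----
  if (pr$grazing && zoo > 0) {
    gz <- grazing_fluxes(zoo, co)
    iw <- M$iw
    ph <- M$cfg$phyto
    algW <- Cb[iw, i$ALG, drop = FALSE]
    remA <- gz$rate * algW
    delta[iw, i$ALG] <- delta[iw, i$ALG] - remA
    gC <- rowSums(remA)
    gN <- as.vector(remA %*% ph$s_n)
    gP <- as.vector(remA %*% ph$s_p)
    gS <- as.vector(remA %*% ph$s_s)
    gSi <- as.vector(remA %*% ph$s_si)
    ## labile detritus: net removal is the respired/excreted share only
    detC <- gz$rate * gz$f_resp * (Cb[iw, i$POC[1]] + Cb[iw, i$POC[2]])
    detN <- gz$rate * gz$f_resp * (Cb[iw, i$PON[1]] + Cb[iw, i$PON[2]])
    detP <- gz$rate * gz$f_resp * (Cb[iw, i$POP[1]] + Cb[iw, i$POP[2]])
    detS <- gz$rate * gz$f_resp * (Cb[iw, i$POS[1]] + Cb[iw, i$POS[2]])
    for (j in 1:2) {
      delta[iw, i$POC[j]] <- delta[iw, i$POC[j]] -
        gz$rate * gz$f_resp * Cb[iw, i$POC[j]]
      delta[iw, i$PON[j]] <- delta[iw, i$PON[j]] -
        gz$rate * gz$f_resp * Cb[iw, i$PON[j]]
      delta[iw, i$POP[j]] <- delta[iw, i$POP[j]] -
        gz$rate * gz$f_resp * Cb[iw, i$POP[j]]
      delta[iw, i$POS[j]] <- delta[iw, i$POS[j]] -
        gz$rate * gz$f_resp * Cb[iw, i$POS[j]]
    }
    respC <- gz$f_resp * gC + detC
    delta[iw, i$NH4] <- delta[iw, i$NH4] + gz$f_resp * gN + detN
    delta[iw, i$PO4] <- delta[iw, i$PO4] + gz$f_resp * gP + detP
    delta[iw, i$SUD] <- delta[iw, i$SUD] + gz$f_resp * gS + detS
    delta[iw, i$DO] <- delta[iw, i$DO] - co$st_o2_c * respC
    gasC[iw] <- gasC[iw] + respC
    delta[iw, i$POC[1]] <- delta[iw, i$POC[1]] + gz$f_egest * gC
    delta[iw, i$PON[1]] <- delta[iw, i$PON[1]] + gz$f_egest * gN
    delta[iw, i$POP[1]] <- delta[iw, i$POP[1]] + gz$f_egest * gP
    delta[iw, i$POS[1]] <- delta[iw, i$POS[1]] + gz$f_egest * gS
    delta[iw, i$OPAL] <- delta[iw, i$OPAL] + gSi
  }

  ## ---- surface gas exchange ----
  if (pr$gas_exchange) {
    iw <- M$iw
    depth <- M$cfg$compartments$depth
    kl <- transfer_coefficient(W, T_deg, co)
    DOs <- oxygen_saturation(T_deg, Cb[iw, i$Cl] / 1000)
    rea <- gas_flux(Cb[iw, i$DO], DOs, kl, depth)
    vol <- gas_flux(Cb[iw, i$CH4], 0, kl * co$kl_ch4_factor, depth)
    delta[iw, i$DO] <- delta[iw, i$DO] + rea
    delta[iw, i$CH4] <- delta[iw, i$CH4] + vol
    atmDO <- rea
    atmCH4 <- vol
  }
  list(delta = delta, gasC = gasC, gasN = gasN,
       atmDO = atmDO, atmCH4 = atmCH4)
}

# analytic sorption substep: relax PO4/AAP towards the Langmuir equilibrium
# partition of their summed pool, with the redox-corrected capacity
sorption_step <- function(Cb, M, T_deg, ph_cell, dt) {
  co <- M$co; i <- M$i
  phi <- M$phi
  pwDO <- Cb[, i$DO] / phi
  cap <- adsorption_capacity(Cb[, i$IM1], Cb[, i$IM3], M$fe, M$fei,
                             M$fox, pwDO, phi, co)
  tot_pw <- (Cb[, i$PO4] + Cb[, i$AAP]) / phi          # g P m-3 pw
  eq <- phosphate_partition_equilibrium(cap, po4_gm3_to_molL(tot_pw, co),
                                        ph_cell, co)
  AAPe <- po4_molL_to_gm3(eq$Cap, co) * phi            # bulk
  ks <- temperature_adjust(co$k_s, co$kt_mic, T_deg)
  tr <- (AAPe - Cb[, i$AAP]) * (1 - exp(-ks * dt))
  Cb[, i$AAP] <- Cb[, i$AAP] + tr
  Cb[, i$PO4] <- Cb[, i$PO4] - tr
  Cb
}
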