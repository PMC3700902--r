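# Daily phytoplankton community update. Water compartments run the full
# competition LP (growth, mortality, phenotype switching, nutrient uptake);
# phytoplankton that reached the sediment only dies, with the same
# autolysis/detritus allocation.

bloom_step <- function(Cb, M, T_deg, I0, bnd_env) {
  co <- M$co; i <- M$i; ph <- M$cfg$phyto
  dtb <- M$cfg$bloom_dt_days
  rt <- phyto_rates(ph, T_deg)
  ## ---- mortality of settled phytoplankton (sediment cells) ----
  sed <- which(M$is_sed)
  algS <- Cb[sed, i$ALG, drop = FALSE]
  if (any(algS > 0)) {
    died <- algS * rep(1 - exp(-rt$km * dtb), each = length(sed))
    Cb[sed, i$ALG] <- algS - died
    Cb <- allocate_mortality(Cb, sed, died, M)
  }
  ## ---- competition in the water compartments ----
  for (c in M$iw) {
    b0 <- Cb[c, i$ALG]
    avail <- c(N = Cb[c, i$NH4] + Cb[c, i$NO3], P = Cb[c, i$PO4],
               Si = Cb[c, i$Si])
    et <- extinction_total(IM3 = Cb[c, i$IM3],
                           POC = sum(Cb[c, i$POC]),
                           DOC = Cb[c, i$DOC], ALG = b0,
                           phyto = ph, co = co)$e_t
    res <- bloom_compete(b0, pmax(avail, 0), I0, et,
                         Z = M$cfg$compartments$depth[c], T_deg,
                         dt = dtb, phyto = ph, co = co)
    Cb[c, i$ALG] <- res$biomass
    Vw <- M$V[c]
    bnd_env$bnd["CO2", "gas"] <- bnd_env$bnd["CO2", "gas"] +
      res$production * Vw
    Cb[c, i$DO] <- Cb[c, i$DO] + co$st_o2_prod * res$production
    u <- res$uptake
    if (u["N"] >= 0) {
      if (co$f_am >= 1) {            # hard ammonium preference
        from_nh4 <- min(Cb[c, i$NH4], u["N"])
      } else {
        from_nh4 <- min(Cb[c, i$NH4], co$f_am * u["N"])
      }
      Cb[c, i$NH4] <- Cb[c, i$NH4] - from_nh4
      Cb[c, i$NO3] <- Cb[c, i$NO3] - (u["N"] - from_nh4)
    } else {
      Cb[c, i$NH4] <- Cb[c, i$NH4] - u["N"]
    }
    Cb[c, i$PO4] <- Cb[c, i$PO4] - u["P"]
    Cb[c, i$Si] <- Cb[c, i$Si] - u["Si"]
    Cb[c, i$SO4] <- Cb[c, i$SO4] - u["S"]
    Cb <- allocate_mortality(Cb, c, matrix(res$died, 1), M)
    ## LP round-off can leave tiny negative pools; clip with audit
    row <- Cb[c, ]
    if (any(row < 0)) {
      bnd_env$bnd[seq_len(M$nsub), "clip"] <-
        bnd_env$bnd[seq_len(M$nsub), "clip"] - pmin(row, 0) * Vw
      Cb[c, ] <- pmax(row, 0)
    }
  }
  Cb
}

# element-conserving allocation of died biomass (rows = cells)
allocate_mortality <- function(Cb, rows, died, M) {
  co <- M$co; i <- M$i; ph <- M$cfg$phyto
  nty <- nrow(ph)
  f1 <- ifelse(seq_len(nty) > 8, co$f_d1[2], co$f_d1[1])
  f2 <- ifelse(seq_len(nty) > 8, co$f_d2[2], co$f_d2[1])
  fa <- co$f_aut
  Cb[rows, i$DOC] <- Cb[rows, i$DOC] + rowSums(died) * fa
  Cb[rows, i$NH4] <- Cb[rows, i$NH4] + as.vector(died %*% (fa * ph$s_n))
  Cb[rows, i$PO4] <- Cb[rows, i$PO4] + as.vector(died %*% (fa * ph$s_p))
  Cb[rows, i$SUD] <- Cb[rows, i$SUD] + as.vector(died %*% (fa * ph$s_s))
  Cb[rows, i$OPAL] <- Cb[rows, i$OPAL] + as.vector(died %*% ph$s_si)
  r <- 1 - fa
  Cb[rows, i$POC[1]] <- Cb[rows, i$POC[1]] + as.vector(died %*% (r * f1))
  Cb[rows, i$POC[2]] <- Cb[rows, i$POC[2]] + as.vector(died %*% (r * f2))
  Cb[rows, i$PON[1]] <- Cb[rows, i$PON[1]] +
    as.vector(died %*% (r * f1 * ph$s_n))
  Cb[rows, i$PON[2]] <- Cb[rows, i$PON[2]] +
    as.vector(died %*% (r * f2 * ph$s_n))
  Cb[rows, i$POP[1]] <- Cb[rows, i$POP[1]] +
    as.vector(died %*% (r * f1 * ph$s_p))
  Cb[rows, i$POP[2]] <- Cb[rows, i$POP[2]] +
    as.vector(died %*% (r * f2 * ph$s_p))
  Cb[rows, i$POS[1]] <- Cb[rows, i$POS[1]] +
    as.vector(died %*% (r * f1 * ph$s_s))
  Cb[rows, i$POS[2]] <- Cb[rows, i$POS[2]] +
    as.vector(died %*% (r * f2 * ph$s_s))
  Cb
}
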