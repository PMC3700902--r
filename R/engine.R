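# Time integration engine: grid assembly, operator-split transport
# (water-balance flows, settling, burial, seepage, dispersion), kinetic
# processes, the daily phytoplankton community step, and the flux ledger
# that keeps elemental mass balances closed.
#
# State is a matrix (cell x substance) of bulk concentrations, g m-3 of
# cell volume. Water cells come first, then the sediment layers of each
# column top-down. The per-step scheme is first-order operator splitting:
# explicit transport and kinetics, an implicit (tridiagonal) solve for
# vertical sediment dispersion (stable for mm-scale top layers), and
# analytic integration of the quasi-equilibrium sulphide exchange.

LEDGER_CATS <- c("load", "outflow", "seepage", "burial", "atmosphere",
                 "gas", "clip")

# assemble precomputed model structure from a configuration
build_model <- function(cfg) {
  co <- cfg$coefficients
  subs <- cfg$substances
  cm <- cfg$compartments
  nc <- nrow(cm)
  nl <- length(cfg$layers)
  nsub <- nrow(subs)
  ncell <- nc + nc * nl
  sed_idx <- lapply(seq_len(nc), function(c) nc + (c - 1) * nl + seq_len(nl))
  L <- cfg$layers
  z_top <- cumsum(c(0, L[-nl]))          # depth of layer tops
  z_mid <- z_top + L / 2
  phi <- rep(1, ncell); V <- numeric(ncell); thick <- numeric(ncell)
  zmid_cell <- numeric(ncell); zpress <- numeric(ncell)
  for (c in seq_len(nc)) {
    V[c] <- cm$area[c] * cm$depth[c]
    thick[c] <- cm$depth[c]
    zpress[c] <- cm$depth[c] / 2
    s <- sed_idx[[c]]
    phi[s] <- cm$porosity[c]
    V[s] <- cm$area[c] * L
    thick[s] <- L
    zmid_cell[s] <- z_mid
    zpress[s] <- cm$depth[c] + z_mid
  }
  is_sed <- seq_len(ncell) > nc
  # reactive-iron and oxidized-fraction profiles
  fe <- numeric(ncell); fei <- numeric(ncell); fox <- numeric(ncell)
  fe[is_sed] <- ifelse(zmid_cell[is_sed] < co$top_ox_depth,
                       co$fe_im1_top, co$fe_im1)
  fei[!is_sed] <- co$fe_im3
  fox[is_sed] <- ifelse(zmid_cell[is_sed] < co$top_ox_depth,
                        co$f_ox_top, co$f_ox)
  fox[!is_sed] <- co$f_ox_top
  k_ni <- ifelse(is_sed, co$k_ni_sediment, co$k_ni_water)
  # substance index helpers
  nm <- subs$name
  ii <- function(x) match(x, nm)
  i <- list(ALG = grep("^ALG", nm),
            POC = ii(paste0("POC", 1:4)), PON = ii(paste0("PON", 1:4)),
            POP = ii(paste0("POP", 1:4)), POS = ii(paste0("POS", 1:4)),
            DOC = ii("DOC"), DON = ii("DON"), DOP = ii("DOP"),
            DOS = ii("DOS"), NO3 = ii("NO3"), NH4 = ii("NH4"),
            PO4 = ii("PO4"), AAP = ii("AAP"), VIVP = ii("VIVP"),
            APATP = ii("APATP"), Si = ii("Si"), OPAL = ii("OPAL"),
            DO = ii("DO"), SO4 = ii("SO4"), SUD = ii("SUD"),
            SUP = ii("SUP"), CH4 = ii("CH4"), IM1 = ii("IM1"),
            IM2 = ii("IM2"), IM3 = ii("IM3"), Cl = ii("Cl"))
  dis <- which(subs$phase == "dissolved")
  part <- which(subs$phase == "particulate")
  # settling velocity vectors per compartment
  vs <- lapply(seq_len(nc), function(c) {
    v <- numeric(nsub)
    v[subs$settles] <- cm$v_settle[c]
    v[i$ALG] <- cfg$phyto$v_a
    v
  })
  solid_sub <- unique(c(which(subs$settles), i$ALG))
  # dispersion geometry: interface distances and depth-decay factors
  d_sol <- c(co$L0 + L[1] / 2, (L[-nl] + L[-1]) / 2)   # nl interfaces
  decay_s <- exp(-co$lambda_s * z_top)
  d_par <- (L[-nl] + L[-1]) / 2                        # nl-1 interfaces
  decay_p <- exp(-co$lambda_p * z_top[-1])
  cells <- data.frame(
    id = c(cm$name, unlist(lapply(seq_len(nc), function(c)
      paste0(cm$name[c], "_s", seq_len(nl))))),
    kind = ifelse(is_sed, "sediment", "water"),
    column = c(cm$name, rep(cm$name, each = nl)),
    thickness = thick, porosity = phi, volume = V,
    depth_below_interface = zmid_cell, stringsAsFactors = FALSE)
  list(cfg = cfg, co = co, subs = subs, nm = nm, nc = nc, nl = nl,
       nsub = nsub, ncell = ncell, sed_idx = sed_idx, iw = seq_len(nc),
       V = V, phi = phi, is_sed = is_sed, zmid = zmid_cell,
       zpress = zpress, fe = fe, fei = fei, fox = fox, k_ni = k_ni,
       i = i, dis = dis, part = part, vs = vs, solid_sub = solid_sub,
       d_sol = d_sol, decay_s = decay_s, d_par = d_par, decay_p = decay_p,
       cells = cells)
}

# initial bulk state matrix from config$initial
initial_state <- function(M) {
  cfg <- M$cfg
  Cb <- matrix(0, M$ncell, M$nsub, dimnames = list(M$cells$id, M$nm))
  ini <- cfg$initial
  if (!is.null(ini$water)) {
    w <- ini$water
    Cb[M$iw, colnames(w)] <- w
  }
  if (!is.null(ini$sediment)) {
    a <- ini$sediment  # comp x layer x substance
    for (c in seq_len(M$nc))
      Cb[M$sed_idx[[c]], dimnames(a)[[3]]] <- a[c, , ]
  }
  if (any(Cb < 0)) stop("initial concentrations must be non-negative")
  Cb
}

# implicit exchange solve: conductances g (n-1), capacities cap (n),
# X (n x m) concentrations; returns relaxed concentrations, conserving
# sum(cap * x) exactly (Thomas algorithm, symmetric tridiagonal system)
solve_exchange <- function(g, cap, X) {
  n <- length(cap)
  b <- cap + c(g, 0) + c(0, g)
  d <- X * cap
  cp <- numeric(n - 1)
  m <- b[1]
  cp[1] <- -g[1] / m
  d[1, ] <- d[1, ] / m
  for (k in 2:n) {
    m <- b[k] + g[k - 1] * cp[k - 1]
    if (k < n) cp[k] <- -g[k] / m
    d[k, ] <- (d[k, ] + g[k - 1] * d[k - 1, ]) / m
  }
  for (k in (n - 1):1) d[k, ] <- d[k, ] - cp[k] * d[k + 1, ]
  d
}

#' Run a simulation
#'
#' Integrates the coupled water-column / sediment model forward with
#' operator splitting at the configured time step, recording every boundary
#' flux in the ledger and taking a state snapshot at a fixed interval.
#'
#' @param cfg configuration from [eco_config()] or [synthetic_lake()].
#' @param days simulated duration, d.
#' @param dt_minutes optional override of the configured time step.
#' @param snapshot_days interval between state snapshots, d.
#' @param progress print a progress line every simulated 30 days.
#' @return object of class `eco_run`: final `state` (cell x substance bulk
#'   concentrations), `snapshots` (time x cell x substance array),
#'   `snap_times`, the flux `ledger` (initial masses, boundary-flux matrix,
#'   cumulative sediment-water diffusive fluxes), cell geometry and the
#'   configuration.
#' @export
eco_run <- function(cfg, days, dt_minutes = cfg$dt_minutes,
                    snapshot_days = 1, progress = FALSE) {
  M <- build_model(cfg)
  co <- M$co; pr <- cfg$processes; i <- M$i
  dt <- dt_minutes / 1440
  nsteps <- as.integer(round(days / dt))
  tmid <- (seq_len(nsteps) - 0.5) * dt
  ## forcing evaluated on the step grid
  fT <- forcing_at(cfg$forcing$temperature, tmid)
  fW <- forcing_at(cfg$forcing$wind, tmid)
  fI <- forcing_at(cfg$forcing$par, tmid)
  fpH <- forcing_at(cfg$forcing$ph, tmid)
  fIM3 <- forcing_at(cfg$forcing$im3, tmid)
  fzoo <- forcing_at(cfg$forcing$zoo, tmid)
  day_of <- pmin(floor(tmid), days - 1) + 1
  I0day <- as.vector(rowsum(fI, day_of) / tabulate(day_of))
  ## seasonal benthic activity scaling of the dispersion profiles
  doy <- tmid %% 365
  seas <- 0.5 * (1 + cos(2 * pi * (doy - co$summer_peak_day) / 365))
  Ds_t <- co$Ds_winter + (co$Ds_summer - co$Ds_winter) * seas
  Dp_t <- co$Dp_winter + (co$Dp_summer - co$Dp_winter) * seas
  cm <- cfg$compartments
  nc <- M$nc; nl <- M$nl; nsub <- M$nsub
  Qin <- cfg$inflow[cm$name]; Qout <- cfg$outflow[cm$name]
  E <- cfg$exchange_flow
  Vw <- M$V[M$iw]
  loads_dt <- cfg$loads * dt
  Cin <- cfg$inflow_conc
  deep <- numeric(nsub)
  if (!is.null(cfg$deep_conc)) deep[match(names(cfg$deep_conc), M$nm)] <-
      cfg$deep_conc
  Dmol_eff <- co$D_mol * cm$porosity^2
  ## ledger
  bnd <- matrix(0, nsub + 2, length(LEDGER_CATS),
                dimnames = list(c(M$nm, "CO2", "N2"), LEDGER_CATS))
  swi <- matrix(0, nsub, nc, dimnames = list(M$nm, cm$name))
  Cb <- initial_state(M)
  Cb[M$iw, i$IM3] <- fIM3[1]   # suspended inorganic sediment is a forcing
  mass0 <- colSums(Cb * M$V)
  ## snapshots
  snap_every <- max(1L, as.integer(round(snapshot_days / dt)))
  nsnap <- nsteps %/% snap_every
  snaps <- array(NA_real_, c(nsnap, M$ncell, nsub),
                 dimnames = list(NULL, M$cells$id, M$nm))
  snap_times <- numeric(nsnap)
  ph_cell <- ifelse(M$is_sed, 7.0, fpH[1])
  last_day <- -1L
  sub_clip_rows <- seq_len(nsub)
  for (k in seq_len(nsteps)) {
    Tk <- fT[k]
    ph_cell[M$iw] <- fpH[k]
    ## ---- phytoplankton community (daily cadence) ----
    dcur <- (k - 1L) %/% as.integer(round(cfg$bloom_dt_days / dt))
    if (pr$phyto && dcur != last_day) {
      last_day <- dcur
      Cb <- bloom_step(Cb, M, Tk, I0day[min(dcur + 1L, length(I0day))],
                       bnd_env = environment())
    }
    ## ---- transport: water balance flows ----
    if (pr$water_exchange) {
      Cw <- Cb[M$iw, , drop = FALSE]
      out_m <- (Qout * dt) * Cw
      bnd[sub_clip_rows, "outflow"] <- bnd[sub_clip_rows, "outflow"] -
        colSums(out_m)
      in_m <- (Qin * dt) * Cin
      bnd[sub_clip_rows, "load"] <- bnd[sub_clip_rows, "load"] +
        colSums(in_m) + colSums(loads_dt)
      Cw <- Cw + (in_m + loads_dt - out_m) / Vw
      if (nc == 2 && E > 0) {
        mx <- E * dt * (Cw[1, ] - Cw[2, ])
        Cw[1, ] <- Cw[1, ] - mx / Vw[1]
        Cw[2, ] <- Cw[2, ] + mx / Vw[2]
      }
      Cb[M$iw, ] <- Cw
    }
    ## ---- settling and burial ----
    for (c in seq_len(nc)) {
      sed <- M$sed_idx[[c]]
      A <- cm$area[c]
      phi_c <- cm$porosity[c]
      Vs <- M$V[sed]
      vb <- 0
      if (pr$settling) {
        fm <- (M$vs[[c]] * dt * A) * Cb[c, ]
        Cb[c, ] <- Cb[c, ] - fm / Vw[c]
        Cb[sed[1], ] <- Cb[sed[1], ] + fm / Vs[1]
        vb <- sum(fm[M$solid_sub]) / (dt * A) / (co$rho_solid * (1 - phi_c))
      }
      if (pr$burial && vb > 0) {
        mnl <- (vb * dt * A) * Cb[sed, , drop = FALSE]
        Cb[sed, ] <- Cb[sed, ] +
          (rbind(0, mnl[-nl, , drop = FALSE]) - mnl) / Vs
        bnd[sub_clip_rows, "burial"] <- bnd[sub_clip_rows, "burial"] -
          mnl[nl, ]
      }
      ## ---- seepage (solutes) ----
      vsp <- cm$v_spg[c]
      if (pr$seepage && vsp != 0) {
        q <- abs(vsp) * dt * A
        pw <- Cb[sed, M$dis, drop = FALSE] / phi_c
        if (vsp < 0) {           # infiltration: water -> sediment -> out
          m <- rbind(q * Cb[c, M$dis], q * pw)
          Cb[c, M$dis] <- Cb[c, M$dis] - m[1, ] / Vw[c]
          Cb[sed, M$dis] <- Cb[sed, M$dis] +
            (m[-(nl + 1), , drop = FALSE] - m[-1, , drop = FALSE]) / Vs
          bnd[M$dis, "seepage"] <- bnd[M$dis, "seepage"] - m[nl + 1, ]
        } else {                 # upward seepage: deep boundary -> water
          m_in <- q * deep[M$dis]
          m <- q * pw
          Cb[sed, M$dis] <- Cb[sed, M$dis] +
            (rbind(m[-1, , drop = FALSE], m_in) - m) / Vs
          Cb[c, M$dis] <- Cb[c, M$dis] + m[1, ] / Vw[c]
          bnd[M$dis, "seepage"] <- bnd[M$dis, "seepage"] + m_in
        }
      }
      ## ---- sediment dispersion (implicit) ----
      if (pr$dispersion) {
        Dbio <- max(0, Ds_t[k] - Dmol_eff[c])
        Dsol <- Dbio * M$decay_s + Dmol_eff[c]
        g <- A * Dsol / M$d_sol * dt
        capv <- c(Vw[c], phi_c * Vs)
        X <- rbind(Cb[c, M$dis], Cb[sed, M$dis, drop = FALSE] / phi_c)
        Xn <- solve_exchange(g, capv, X)
        swi[M$dis, c] <- swi[M$dis, c] + g[1] * (Xn[2, ] - Xn[1, ])
        Cb[c, M$dis] <- Xn[1, ]
        Cb[sed, M$dis] <- Xn[-1, , drop = FALSE] * phi_c
        Dpar <- Dp_t[k] * M$decay_p
        gp <- A * Dpar / M$d_par * dt
        capp <- (1 - phi_c) * Vs
        Y <- Cb[sed, M$part, drop = FALSE] / (1 - phi_c)
        Cb[sed, M$part] <- solve_exchange(gp, capp, Y) * (1 - phi_c)
      }
    }
    ## ---- kinetic processes ----
    kin <- kinetics_rates(Cb, M, Tk, ph_cell, fW[k], fzoo[k])
    inc <- kin$delta * dt
    bnd["CO2", "gas"] <- bnd["CO2", "gas"] - sum(kin$gasC * M$V) * dt
    bnd["N2", "gas"] <- bnd["N2", "gas"] - sum(kin$gasN * M$V) * dt
    bnd[i$DO, "atmosphere"] <- bnd[i$DO, "atmosphere"] +
      sum(kin$atmDO * Vw) * dt
    bnd[i$CH4, "atmosphere"] <- bnd[i$CH4, "atmosphere"] +
      sum(kin$atmCH4 * Vw) * dt
    new <- Cb + inc
    if (anyNA(new)) {
      bad <- which(is.na(new), arr.ind = TRUE)[1, ]
      stop("NaN in state at t = ", round(k * dt, 3), " d, cell ",
           M$cells$id[bad[1]], ", substance ", M$nm[bad[2]])
    }
    if (any(new < 0)) {
      clipm <- colSums(M$V * pmin(new, 0))
      bnd[sub_clip_rows, "clip"] <- bnd[sub_clip_rows, "clip"] - clipm
      new[new < 0] <- 0
    }
    Cb <- new
    ## ---- phosphate sorption (analytic relaxation) ----
    if (pr$nutrients) Cb <- sorption_step(Cb, M, Tk, ph_cell, dt)
    ## ---- quasi-equilibrium sulphide precipitation/dissolution ----
    if (pr$sulphur) {
      pwSUD <- Cb[, i$SUD] / M$phi
      pwSUP <- Cb[, i$SUP] / M$phi
      tr <- sulphide_equilibration(pwSUD, pwSUP, ph_cell, dt, co) * M$phi
      # the pore-water round trip can leave 1e-30-scale dust below zero
      Cb[, i$SUD] <- pmax(Cb[, i$SUD] - tr, 0)
      Cb[, i$SUP] <- pmax(Cb[, i$SUP] + tr, 0)
      ## ---- ebullition of supersaturated methane ----
      sat <- methane_saturation(M$zpress, Tk, co)
      rem <- ebullition_excess(Cb[, i$CH4] / M$phi, sat) * M$phi
      if (any(rem > 0)) {
        Cb[, i$CH4] <- Cb[, i$CH4] - rem
        bnd[i$CH4, "atmosphere"] <- bnd[i$CH4, "atmosphere"] -
          sum(rem * M$V)
      }
    }
    ## forced suspended inorganic sediment in the water column
    Cb[M$iw, i$IM3] <- fIM3[k]
    if (anyNA(Cb)) {
      bad <- which(is.na(Cb), arr.ind = TRUE)[1, ]
      stop("NaN in state at t = ", round(k * dt, 3), " d, cell ",
           M$cells$id[bad[1]], ", substance ", M$nm[bad[2]])
    }
    if (k %% snap_every == 0) {
      ks <- k %/% snap_every
      snaps[ks, , ] <- Cb
      snap_times[ks] <- k * dt
    }
    if (progress && k %% (288 * 30) == 0)
      message(sprintf("day %.0f / %.0f", k * dt, days))
  }
  structure(list(config = cfg, state = Cb, snapshots = snaps,
                 snap_times = snap_times,
                 ledger = list(mass0 = mass0, bnd = bnd, swi = swi),
                 cells = M$cells, V = M$V, days = days, dt = dt),
            class = "eco_run")
}

#' @export
print.eco_run <- function(x, ...) {
  cat("<eco_run>", x$days, "days,", nrow(x$cells), "cells,",
      ncol(x$state), "substances\n")
  cl <- elemental_closure(x)
  cat("elemental closure (relative):\n")
  print(signif(cl, 3))
  invisible(x)
}
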