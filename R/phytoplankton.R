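# Light climate and phytoplankton community dynamics. The community is a
# set of species groups, each with energy-, nitrogen- and phosphorus-adapted
# phenotypes; a daily linear program reallocates biomass over phenotypes and
# lets the community grow within nutrient, light-energy, growth-rate and
# mortality-rate constraints.

#' Total light extinction and light climate
#'
#' The total extinction coefficient is the sum of the background extinction
#' of water and the contributions of suspended inorganic matter, particulate
#' detritus, dissolved organic matter and each phytoplankton phenotype.
#'
#' @param IM3 suspended inorganic matter, g m-3.
#' @param POC summed particulate detrital carbon (POC1-4), g C m-3.
#' @param DOC dissolved organic carbon, g C m-3.
#' @param ALG biomass vector over phenotypes, g C m-3.
#' @param phyto phenotype table (for specific extinctions `es_a`).
#' @param co coefficients.
#' @return list with `e_t` (m-1) and the additive components `e_b`, `e_im`,
#'   `e_poc`, `e_doc`, `e_alg`.
#' @export
extinction_total <- function(IM3 = 0, POC = 0, DOC = 0, ALG = NULL,
                             phyto = phyto_types(), co = eco_coefficients()) {
  e_alg <- if (is.null(ALG)) 0 else sum(phyto$es_a * ALG)
  comp <- c(e_b = co$e_b, e_im = co$es_im3 * IM3, e_poc = co$es_poc * POC,
            e_doc = co$es_doc * DOC, e_alg = e_alg)
  c(as.list(comp), list(e_t = sum(comp)))
}

#' Lambert-Beer light profile
#'
#' @param I0 surface irradiance (PAR), W m-2.
#' @param e_t total extinction coefficient, m-1.
#' @param z depth, m (vectorized).
#' @return irradiance at depth, W m-2.
#' @export
light_profile <- function(I0, e_t, z) {
  stopifnot(all(I0 >= 0), all(e_t > 0))
  I0 * exp(-e_t * z)
}

# depth-averaged irradiance over a mixed layer of depth Z
mean_light <- function(I0, e_t, Z) I0 * (1 - exp(-e_t * Z)) / (e_t * Z)

# growth, respiration and mortality rates at temperature T (d-1);
# the growth temperature response is exponential or linear-offset per type
phyto_rates <- function(phyto, T_deg) {
  kp <- ifelse(phyto$temp_fun == "exp",
               phyto$kp * phyto$kt_p^T_deg,
               phyto$kp * pmax(0, T_deg - phyto$kt_p))
  list(kp = kp,
       kr = phyto$kr * phyto$kt_r^T_deg,
       km = phyto$km * phyto$kt_m^T_deg)
}

#' Phytoplankton competition by linear programming
#'
#' Reallocates community biomass over phenotypes for one (daily) time step by
#' maximizing total community biomass -- equivalent to maximizing total net
#' production, since the starting biomass is fixed -- subject to:
#' \itemize{
#'   \item nutrient constraints: the N, P and Si bound in the new biomass may
#'     not exceed the dissolved pool plus the content of the surviving
#'     biomass (phenotype switching frees its nutrients);
#'   \item a growth (energy) constraint per species group: new group biomass
#'     may not exceed the sum over its phenotypes of
#'     `b_i * exp((fL_i * kp_i(T) - kr_i(T)) * dt)`, where `fL_i` is the
#'     saturating response to depth-averaged light, plus a small seed
#'     allowing invasion;
#'   \item a mortality constraint per group: new group biomass is at least
#'     the surviving biomass `sum(b_i * exp(-km_i(T) * dt))`.
#' }
#'
#' @param biomass biomass per phenotype, g C m-3.
#' @param avail named vector of available nutrients (dissolved pools), with
#'   elements `N`, `P`, `Si`, g m-3; use `Inf` for non-limiting pools.
#' @param I0 daily mean surface PAR, W m-2.
#' @param e_t total extinction, m-1.
#' @param Z depth of the mixed water column, m.
#' @param T_deg temperature, degC.
#' @param dt time step, d (the community cadence; 1 by default).
#' @param phyto phenotype table.
#' @param co coefficients.
#' @param seed invasion seed per group, g C m-3 (default from `co`).
#' @return list: `biomass` (new allocation), `production` (net community
#'   production, g C m-3), `died` (mortality flux per phenotype over the
#'   step), `uptake` (named N/P/Si/S taken from the dissolved pools;
#'   negative = release), `growth_bound`, `survivors`, `feasible`.
#' @export
bloom_compete <- function(biomass, avail, I0, e_t, Z, T_deg, dt = 1,
                          phyto = phyto_types(), co = eco_coefficients(),
                          seed = NULL) {
  stopifnot(length(biomass) == nrow(phyto), all(biomass >= 0))
  if (is.null(seed)) seed <- co$seed_biomass * dt
  rt <- phyto_rates(phyto, T_deg)
  Ibar <- if (I0 > 0) mean_light(I0, e_t, Z) else 0
  fL <- Ibar / (Ibar + co$I_half)
  grow <- exp((fL * rt$kp - rt$kr) * dt)
  surv <- biomass * exp(-rt$km * dt)
  died <- biomass - surv
  groups <- unique(phyto$group)
  gmat <- outer(groups, phyto$group, "==") * 1  # group x type indicator
  G <- as.vector(gmat %*% (biomass * grow)) + seed
  M <- as.vector(gmat %*% surv)
  stoich <- rbind(N = phyto$s_n, P = phyto$s_p, Si = phyto$s_si)
  avail_tot <- c(N = unname(avail["N"]), P = unname(avail["P"]),
                 Si = unname(avail["Si"])) + as.vector(stoich %*% surv)
  lim <- is.finite(avail_tot)
  ## restrict the LP to phenotypes of groups that can hold biomass; empty
  ## groups would contribute degenerate x <= 0 rows
  gkeep <- G > 0
  keep <- gkeep[match(phyto$group, groups)]
  x <- numeric(length(biomass))
  if (any(keep)) {
    gm <- gmat[gkeep, keep, drop = FALSE]
    A1 <- rbind(stoich[lim, keep, drop = FALSE], gm)
    b1 <- c(avail_tot[lim], G[gkeep])
    Mk <- M[gkeep]
    lower <- Mk > 0
    x[keep] <- tryCatch({
      sol <- boot::simplex(a = rep(1, sum(keep)), A1 = A1, b1 = b1,
                           A2 = if (any(lower)) gm[lower, , drop = FALSE],
                           b2 = if (any(lower)) Mk[lower],
                           maxi = TRUE, n.iter = 500, eps = 1e-10)
      if (sol$solved != 1) stop("LP not solved")
      pmax(sol$soln, 0)
    }, error = function(e) {
      warning("community LP infeasible; falling back to mortality-only: ",
              conditionMessage(e))
      surv[keep]
    })
  }
  uptake <- as.vector(stoich %*% x) - as.vector(stoich %*% surv)
  names(uptake) <- rownames(stoich)
  uptake <- c(uptake, S = sum(phyto$s_s * (x - surv)))
  list(biomass = x, production = sum(x) - sum(surv), died = died,
       uptake = uptake, growth_bound = G, survivors = surv,
       feasible = TRUE)
}

#' Mortality allocation: autolysis and detritus production
#'
#' A fraction `f_aut` of the elements of died biomass is released directly
#' to the dissolved pools (C to dissolved organic carbon, N to ammonium, P
#' to phosphate, S to dissolved sulphide); all silica goes to opal (diatom
#' frustules). The remainder is split over the fast and moderately slow
#' particulate detritus fractions, with a split that differs between the
#' eukaryotic groups (phenotypes 1-8) and the cyanobacteria (9-14).
#'
#' @param died mortality flux per phenotype, g C m-3 (or per day).
#' @param phyto phenotype table.
#' @param co coefficients.
#' @return list of element fluxes: `autolysis` (named C/N/P/S), `opal_si`,
#'   and `detritus`, a 2 x 4 matrix (rows POX1, POX2; columns C, N, P, S).
#' @export
mortality_allocation <- function(died, phyto = phyto_types(),
                                 co = eco_coefficients()) {
  stopifnot(length(died) == nrow(phyto), all(died >= 0))
  cyano <- as.integer(seq_len(nrow(phyto)) > 8) + 1L
  f1 <- co$f_d1[cyano]
  f2 <- co$f_d2[cyano]
  el <- cbind(C = died, N = died * phyto$s_n, P = died * phyto$s_p,
              S = died * phyto$s_s)
  aut <- colSums(el) * co$f_aut
  det <- rbind(POX1 = colSums(el * (1 - co$f_aut) * f1),
               POX2 = colSums(el * (1 - co$f_aut) * f2))
  list(autolysis = aut, opal_si = sum(died * phyto$s_si), detritus = det)
}

#' Zooplankton grazing fluxes
#'
#' First-order removal of phytoplankton and labile detritus proportional to
#' the imposed zooplankton biomass. A configurable share of each grazed
#' element is respired (C) or excreted (N to ammonium, P to phosphate, S to
#' sulphide); the remainder is egested: algal egesta enter the fast
#' particulate detritus fraction, detrital egesta return to their source
#' fraction.
#'
#' @param zoo zooplankton biomass (forcing), g C m-3.
#' @param co coefficients (`k_grz`, `f_grz_resp`).
#' @return list with the first-order grazing rate `rate` (d-1), the respired
#'   or excreted share `f_resp` and the egested share `f_egest`.
#' @export
grazing_fluxes <- function(zoo, co = eco_coefficients()) {
  stopifnot(all(zoo >= 0))
  list(rate = co$k_grz * zoo, f_resp = co$f_grz_resp,
       f_egest = 1 - co$f_grz_resp)
}
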