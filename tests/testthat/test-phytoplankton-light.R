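# Light climate and the community competition LP.

test_that("extinction is the additive sum of the component contributions", {
  co <- eco_coefficients()
  expect_equal(extinction_total()$e_t, 0.08)               # pure water
  expect_equal(extinction_total(DOC = 10)$e_t, 0.08 + 3.0) # 0.3 per g DOC
  expect_equal(extinction_total(IM3 = 10, POC = 5)$e_t,
               0.08 + 0.18 + 0.5)
  ph <- phyto_types()
  alg <- rep(0, nrow(ph)); alg[1] <- 2
  expect_equal(extinction_total(ALG = alg)$e_t, 0.08 + 2 * ph$es_a[1])
  # additivity: a mixture equals the sum of single-component extinctions
  # minus the repeatedly counted background
  e_mix <- extinction_total(IM3 = 7, DOC = 3, POC = 2)$e_t
  singles <- c(extinction_total(IM3 = 7)$e_t, extinction_total(DOC = 3)$e_t,
               extinction_total(POC = 2)$e_t)
  expect_equal(e_mix, sum(singles) - 2 * co$e_b)
})

test_that("the light profile is Lambert-Beer", {
  expect_equal(light_profile(120, 1.5, 0), 120)
  expect_equal(light_profile(120, 2, log(2) / 2), 60)
  z <- seq(0, 5, 0.5)
  expect_true(all(diff(light_profile(100, 0.8, z)) < 0))
})

test_that("unlimited growth hits the growth-rate bound exactly", {
  ph <- phyto_types()
  b <- rep(0, nrow(ph)); b[1] <- 1   # one diatom type
  co <- eco_coefficients(I_half = 0) # saturating light response
  res <- bloom_compete(b, c(N = Inf, P = Inf, Si = Inf), I0 = 200,
                       e_t = 1, Z = 2, T_deg = 15, phyto = ph, co = co,
                       seed = 0)
  rt <- eutrosim:::phyto_rates(ph, 15)
  expect_equal(sum(res$biomass), exp(rt$kp[1] - rt$kr[1]),
               tolerance = 1e-9)
})

test_that("zero biomass and zero nutrients stay zero", {
  ph <- phyto_types()
  res <- bloom_compete(rep(0, nrow(ph)), c(N = 0, P = 0, Si = 0),
                       I0 = 100, e_t = 1, Z = 2, T_deg = 15, phyto = ph)
  expect_equal(sum(res$biomass), 0, tolerance = 1e-12)
})

test_that("the LP matches brute-force vertex enumeration (2 types, 1 nutrient)", {
  ph <- phyto_types()
  co <- eco_coefficients(I_half = 0)
  set.seed(7)
  n_match <- 0
  for (case in 1:100) {
    pair <- sample(nrow(ph), 2)
    sub <- ph[pair, ]
    b0 <- runif(2, 0, 1)
    avail_N <- runif(1, 0, 0.3)
    T_deg <- runif(1, 5, 25)
    res <- bloom_compete(b0, c(N = avail_N, P = Inf, Si = Inf), I0 = 150,
                         e_t = 1, Z = 2, T_deg = T_deg, phyto = sub,
                         co = co, seed = 0)
    ## oracle: enumerate candidate vertices of the 2-variable LP
    rt <- eutrosim:::phyto_rates(sub, T_deg)
    surv <- b0 * exp(-rt$km)
    grow <- b0 * exp(rt$kp - rt$kr)
    sN <- sub$s_n
    A <- avail_N + sum(sN * surv)
    same_group <- sub$group[1] == sub$group[2]
    cand <- list()
    if (same_group) {
      G <- sum(grow); M <- sum(surv)
      # vertices of {x>=0, x1+x2 in [M,G], sN.x <= A}
      for (tot in c(M, G)) cand <- c(cand,
        list(c(tot, 0), c(0, tot)))
      for (j in 1:2) {            # nutrient boundary with one var at 0
        v <- c(0, 0); v[j] <- A / sN[j]; cand <- c(cand, list(v))
      }
      # nutrient boundary intersect total = M or G
      for (tot in c(M, G)) {
        det <- sN[1] - sN[2]
        if (abs(det) > 1e-12) {
          x1 <- (A - sN[2] * tot) / det
          cand <- c(cand, list(c(x1, tot - x1)))
        }
      }
      feasible <- function(x) all(x >= -1e-9) &&
        sum(x) >= M - 1e-9 && sum(x) <= G + 1e-9 &&
        sum(sN * x) <= A + 1e-9
    } else {
      # separate box bounds per group plus the nutrient constraint
      for (x1 in c(surv[1], grow[1])) for (x2 in c(surv[2], grow[2]))
        cand <- c(cand, list(c(x1, x2)))
      for (j in 1:2) {
        v <- c(surv[1], surv[2]); o <- 3 - j
        for (vo in c(surv[o], grow[o])) {
          v2 <- v; v2[o] <- vo
          v2[j] <- (A - sN[o] * vo) / sN[j]
          cand <- c(cand, list(v2))
        }
      }
      feasible <- function(x) all(x >= -1e-9) &&
        x[1] >= surv[1] - 1e-9 && x[1] <= grow[1] + 1e-9 &&
        x[2] >= surv[2] - 1e-9 && x[2] <= grow[2] + 1e-9 &&
        sum(sN * x) <= A + 1e-9
    }
    best <- max(vapply(Filter(feasible, cand), sum, 0))
    if (isTRUE(all.equal(sum(res$biomass), best, tolerance = 1e-6)))
      n_match <- n_match + 1
  }
  expect_equal(n_match, 100)
})

test_that("LP uptake never exceeds the available nutrient pools", {
  ph <- phyto_types()
  set.seed(11)
  for (case in 1:20) {
    b0 <- runif(nrow(ph), 0, 0.5)
    avail <- c(N = runif(1, 0, 0.5), P = runif(1, 0, 0.05),
               Si = runif(1, 0, 0.5))
    res <- bloom_compete(b0, avail, I0 = 120, e_t = 1.2, Z = 1.5,
                         T_deg = 18, phyto = ph)
    u <- res$uptake
    expect_lte(u["N"], avail["N"] + 1e-7)
    expect_lte(u["P"], avail["P"] + 1e-7)
    expect_lte(u["Si"], avail["Si"] + 1e-7)
  }
})

test_that("mortality allocation conserves every element", {
  ph <- phyto_types()
  co <- eco_coefficients()
  died <- rep(0, nrow(ph)); died[1] <- 1
  ma <- mortality_allocation(died, ph, co)
  # worked case: 1 g C of a eukaryotic type: 0.65 * 0.55 to POC1
  expect_equal(ma$detritus["POX1", "C"], 0.65 * 0.55)
  expect_equal(ma$detritus["POX2", "C"], 0.65 * 0.45)
  expect_equal(ma$autolysis[["C"]], 0.35)
  # cyanobacteria use the 0.62/0.38 split
  died2 <- rep(0, nrow(ph)); died2[10] <- 2
  ma2 <- mortality_allocation(died2, ph, co)
  expect_equal(ma2$detritus["POX1", "C"], 2 * 0.65 * 0.62)
  # element closure for a random community
  set.seed(3)
  died3 <- runif(nrow(ph))
  ma3 <- mortality_allocation(died3, ph, co)
  for (el in c("C", "N", "P", "S")) {
    s <- switch(el, C = rep(1, nrow(ph)), N = ph$s_n, P = ph$s_p, S = ph$s_s)
    expect_equal(ma3$autolysis[[el]] + sum(ma3$detritus[, el]),
                 sum(died3 * s))
  }
  expect_equal(ma3$opal_si, sum(died3 * ph$s_si))
})

test_that("grazing is proportional to zooplankton biomass", {
  expect_equal(grazing_fluxes(0)$rate, 0)
  expect_equal(grazing_fluxes(0.4)$rate, 2 * grazing_fluxes(0.2)$rate)
  g <- grazing_fluxes(1)
  expect_equal(g$f_resp + g$f_egest, 1)
})

test_that("diatoms draw down silicate while green algae barely touch it", {
  ph <- phyto_types()
  expect_equal(ph$s_si[1], 0.66)
  expect_equal(ph$s_si[3], 0.0018)
  # one community step with plenty N/P: a diatom community consumes Si at
  # hundreds of times the rate of a green-algae community
  co <- eco_coefficients(I_half = 0)
  b_dia <- rep(0, nrow(ph)); b_dia[1] <- 0.5
  res_d <- bloom_compete(b_dia, c(N = 10, P = 1, Si = 10), I0 = 150,
                         e_t = 1, Z = 2, T_deg = 10, phyto = ph, co = co,
                         seed = 0)
  prod_d <- sum(res_d$biomass) - sum(res_d$survivors)
  expect_gte(res_d$uptake[["Si"]], 0.54 * prod_d)
  b_grn <- rep(0, nrow(ph)); b_grn[3] <- 0.5
  res_g <- bloom_compete(b_grn, c(N = 10, P = 1, Si = 10), I0 = 150,
                         e_t = 1, Z = 2, T_deg = 10, phyto = ph, co = co,
                         seed = 0)
  prod_g <- sum(res_g$biomass) - sum(res_g$survivors)
  expect_gt(prod_g, 0)
  expect_lte(res_g$uptake[["Si"]], 0.002 * prod_g + 1e-9)
})
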