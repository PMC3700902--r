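# Transport, time integration and mass-balance accounting.

test_that("temperature adjustment has the reference point at 20 degC", {
  expect_equal(temperature_adjust(0.2, 1.047, 20), 0.2)
  expect_equal(temperature_adjust(0.2, 1.0, 35), 0.2)
  expect_equal(temperature_adjust(0.15, 1.047, 10), 0.15 * 1.047^-10)
  # monotone in T for kt > 1
  Ts <- seq(3, 30, 1)
  expect_true(all(diff(temperature_adjust(1, 1.07, Ts)) > 0))
  # low-temperature damping below 2 degC
  expect_equal(temperature_adjust(1, 1.047, 2, ts = 1.25),
               1.047^-18)
  expect_equal(temperature_adjust(1, 1.047, 0, ts = 1.25),
               1.047^-20 / 1.25^2)
  expect_error(temperature_adjust(1, -0.5, 10), "positive")
})

test_that("tortuosity correction reproduces the worked coefficient", {
  expect_equal(tortuosity_corrected_diffusion(0.75e-4, 0.55),
               0.75e-4 * 0.55^2)
  expect_equal(signif(tortuosity_corrected_diffusion(0.75e-4, 0.55), 3),
               2.27e-5)
})

test_that("settling flux is velocity times concentration", {
  # settling is linear in both arguments; the deep-compartment velocity
  # 0.23 m/d removes 2.3 g m-2 d-1 from 10 g m-3
  cfg <- one_box(depth = 2, area = 100, v_settle = 0.23,
                 processes = list(settling = TRUE),
                 initial = list(water = water_initial(IM1 = 10)))
  run <- eco_run(cfg, days = 1 / 288, snapshot_days = 1 / 288)
  moved <- (10 - run$state[1, "IM1"]) * run$V[1]
  expect_equal(moved, 0.23 * 10 * 100 / 288, tolerance = 1e-12)
  # everything removed from the water arrived in the top sediment layer
  sed1 <- run$state[2, "IM1"] * run$V[2]
  expect_equal(sed1, moved)
  # algae do not settle (v_a = 0): a run with only algae leaves them be
  cfg2 <- one_box(v_settle = 0.23, processes = list(settling = TRUE),
                  initial = list(water = water_initial(ALG1 = 5)))
  run2 <- eco_run(cfg2, days = 1)
  expect_equal(run2$state[1, "ALG1"], 5)
})

test_that("steady settling of inert matter leaves the column mass unchanged", {
  # column pre-filled with solids at the packing density: burial expels
  # exactly what settles, so the column inventory is invariant
  phi <- 0.5
  subs <- substance_table()
  nl <- length(default_layers())
  sed <- array(0, c(1, nl, nrow(subs)),
               dimnames = list("box", NULL, subs$name))
  sed[1, , "IM1"] <- 2.6e6 * (1 - phi)
  cfg <- one_box(porosity = phi, v_settle = 0.115, area = 1000,
                 processes = list(settling = TRUE, burial = TRUE,
                                  water_exchange = TRUE),
                 loads = c(IM1 = 5e4),
                 initial = list(water = water_initial(IM1 = 20),
                                sediment = sed))
  run <- eco_run(cfg, days = 20)
  V <- run$V
  col0 <- sum(sed[1, , "IM1"] * V[-1])
  col1 <- sum(run$state[-1, "IM1"] * V[-1])
  expect_equal(col1, col0, tolerance = 1e-6)
  # burial export equals the settled input (load minus water storage change)
  settled <- run$ledger$bnd["IM1", "load"] -
    (run$state[1, "IM1"] - 20) * V[1]
  expect_equal(-run$ledger$bnd["IM1", "burial"], settled, tolerance = 1e-6)
})

test_that("uniform pore water produces no dispersive fluxes", {
  subs <- substance_table()
  nl <- length(default_layers())
  phi <- 0.6
  sed <- array(0, c(1, nl, nrow(subs)), dimnames = list("box", NULL, subs$name))
  sed[1, , "Cl"] <- 100 * phi          # pore water equal to the water column
  cfg <- one_box(porosity = phi, processes = list(dispersion = TRUE),
                 initial = list(water = water_initial(Cl = 100),
                                sediment = sed))
  run <- eco_run(cfg, days = 1)
  expect_equal(run$state[, "Cl"] / run$cells$porosity,
               rep(100, nrow(run$cells)), ignore_attr = TRUE)
  expect_equal(run$ledger$swi["Cl", 1], 0)
})

test_that("two-box diffusive exchange matches the analytic relaxation", {
  # two closed boxes exchanging by Fickian diffusion; the implicit solve at
  # a 5-minute step must track the exponential approach to the common mean
  dt <- 5 / 1440
  cap <- c(25, 25)                      # phi * V, m3
  g_day <- 0.04 * 25                    # conductance A*D/d, m3/d
  g <- g_day * dt
  x <- matrix(c(10, 0), 2, 1)
  lam <- g_day * (1 / cap[1] + 1 / cap[2])
  times <- seq(dt, 10, by = dt)
  num <- numeric(length(times))
  for (k in seq_along(times)) {
    x <- eutrosim:::solve_exchange(g, cap, x)
    num[k] <- x[1, 1]
  }
  exact <- 5 + 5 * exp(-lam * times)
  expect_equal(num, exact, tolerance = 1e-3)
  # total mass conserved to numerical precision
  expect_equal(sum(cap * x[, 1]), 250, tolerance = 1e-12)
})

test_that("a fully inert configuration leaves the state unchanged", {
  cfg <- one_box(initial = list(water = water_initial(Cl = 80, DO = 5,
                                                      POC1 = 3)))
  run <- eco_run(cfg, days = 2)
  expect_equal(run$state[1, c("Cl", "DO", "POC1")],
               c(Cl = 80, DO = 5, POC1 = 3))
  expect_true(all(run$ledger$bnd == 0))
})

test_that("a CSTR washout follows the closed-form exponential", {
  Q <- 2000; V <- 1e4 * 2               # area 1e4, depth 2
  cfg <- one_box(processes = list(water_exchange = TRUE),
                 inflow = c(box = Q), outflow = c(box = Q),
                 inflow_conc = c(Cl = 30),
                 initial = list(water = water_initial(Cl = 100)))
  run <- eco_run(cfg, days = 15)
  k <- Q / V
  expected <- 30 + (100 - 30) * exp(-k * run$snap_times)
  expect_equal(run$snapshots[, 1, "Cl"], expected, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_lt(elemental_closure(run)["Cl"], 1e-12)
})

test_that("transport alone conserves mass in a closed system", {
  # settling + burial off at the bottom is the only open boundary; with a
  # sealed column (no load, no flows) every transport operator conserves
  cfg <- synthetic_lake(1, processes = list(
    organic_matter = FALSE, nutrients = FALSE, sulphur = FALSE,
    phyto = FALSE, grazing = FALSE, gas_exchange = FALSE,
    settling = FALSE, burial = FALSE, seepage = FALSE,
    water_exchange = FALSE))
  run <- eco_run(cfg, days = 3)
  mass_end <- colSums(run$state * run$V)
  keep <- setdiff(colnames(run$state), "IM3")  # IM3 is a forcing
  expect_equal(mass_end[keep], run$ledger$mass0[keep], tolerance = 1e-12)
})

test_that("halving the time step changes a 30-day trajectory by < 1%", {
  cfg <- synthetic_lake(1)
  run5 <- eco_run(cfg, days = 30)
  run25 <- eco_run(cfg, days = 30, dt_minutes = 2.5)
  key <- c("DO", "NO3", "NH4", "PO4", "Si", "Cl", "POC1", "SO4")
  for (s in key) {
    a <- run5$snapshots[, 1, s]
    b <- run25$snapshots[, 1, s]
    expect_lt(max(abs(a - b)) / max(abs(b), 1e-6), 0.01)
  }
})

test_that("mass balance reports carry the budget categories", {
  # conservative tracer in a closed system: everything zero
  cfg <- one_box(initial = list(water = water_initial(Cl = 50)))
  run <- eco_run(cfg, days = 1)
  rep_cl <- mass_balance_report(run, "Cl")
  expect_true(all(abs(rep_cl$mass) < 1e-9))
  # N report includes a denitrification sink; P report does not
  run_y <- year_run()
  rep_n <- mass_balance_report(run_y, "N")
  rep_p <- mass_balance_report(run_y, "P")
  expect_true("denitrification" %in% rep_n$category)
  expect_false("denitrification" %in% rep_p$category)
  expect_lt(rep_n$mass[rep_n$category == "denitrification"], 0)
  # closure residual is negligible against the external load
  for (r in list(rep_n, rep_p)) {
    load <- r$mass[r$category == "external_load"]
    expect_lt(abs(r$mass[r$category == "closure_residual"]), 1e-6 * load)
  }
  expect_error(mass_balance_report(run_y, "Xx"))
})

test_that("a NaN state aborts with a diagnostic naming cell and substance", {
  cfg <- one_box(processes = list(organic_matter = TRUE),
                 initial = list(water = water_initial(POC1 = 3, DO = 8)))
  cfg$forcing$temperature <- NaN
  expect_error(eco_run(cfg, days = 1 / 288), "substance")
})
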