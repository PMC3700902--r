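# Shared fixtures: minimal single-compartment configurations with selected
# processes enabled, and a memoized one-year synthetic run shared by the
# slower whole-model checks.

one_box <- function(depth = 2, area = 1e4, porosity = 0.5,
                    v_settle = 0, v_spg = 0, processes = list(), ...) {
  all_off <- list(organic_matter = FALSE, nutrients = FALSE, sulphur = FALSE,
                  phyto = FALSE, grazing = FALSE, gas_exchange = FALSE,
                  settling = FALSE, burial = FALSE, seepage = FALSE,
                  dispersion = FALSE, water_exchange = FALSE)
  eco_config(
    compartments = data.frame(name = "box", area = area, depth = depth,
                              porosity = porosity, v_settle = v_settle,
                              v_spg = v_spg, stringsAsFactors = FALSE),
    processes = utils::modifyList(all_off, processes), ...)
}

water_initial <- function(...) {
  vals <- c(...)
  subs <- substance_table()
  m <- matrix(0, 1, nrow(subs), dimnames = list("box", subs$name))
  m[, names(vals)] <- vals
  m
}

# memoized 1-year synthetic two-compartment run (used by the mass-closure
# and seasonal-diagenesis checks)
.run_cache <- new.env(parent = emptyenv())
year_run <- function() {
  if (is.null(.run_cache$year)) {
    cfg <- synthetic_lake(seed = 1L, years = 1)
    .run_cache$year <- eco_run(cfg, days = 365)
  }
  .run_cache$year
}
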