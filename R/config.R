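# Model configuration: compartment geometry, sediment layer stack, process
# coefficients, forcing series, flows, loads and initial state.

#' Build a model configuration
#'
#' Assembles and validates the full definition of a simulation: one or two
#' fully mixed water compartments, each carrying a multi-layer sediment
#' column, plus coefficients, forcing, water balance, loads and the initial
#' state. All arguments have working defaults so a minimal lake can be
#' configured in a few lines; [synthetic_lake()] builds the packaged
#' two-compartment test system.
#'
#' @param compartments data.frame with one row per water compartment:
#'   `name`, `area` (m2), `depth` (m), `porosity` (sediment porosity,
#'   m3/m3), `v_settle` (net settling velocity, m/d), `v_spg` (seepage
#'   velocity, m/d, positive upward into the water column).
#' @param layers sediment layer thicknesses top-down, m.
#' @param coefficients from [eco_coefficients()].
#' @param phyto from [phyto_types()].
#' @param forcing named list of forcing series (`temperature` degC, `wind`
#'   m/s, `par` W/m2, `ph`, `im3` g/m3, `zoo` g C/m3). Each entry is either
#'   a single number (constant) or a data.frame `time` (d), `value` with
#'   strictly increasing times, interpolated linearly.
#' @param inflow,outflow named numeric vectors of water flows per
#'   compartment, m3/d.
#' @param exchange_flow water exchange between the two compartments, m3/d.
#' @param inflow_conc matrix (compartment x substance) of inflow
#'   concentrations, g/m3; a named vector is recycled across compartments.
#' @param loads matrix (compartment x substance) of additional dry loads,
#'   g/d; a named vector is divided over compartments by area.
#' @param deep_conc named vector of solute concentrations below the deepest
#'   sediment layer, g/m3 pore water (required where `v_spg > 0`).
#' @param initial list with `water` (compartment x substance matrix, g/m3)
#'   and `sediment` (array compartment x layer x substance, bulk g/m3);
#'   missing entries default to zero.
#' @param processes named list of logical switches:
#'   `organic_matter`, `nutrients`, `sulphur`, `phyto`, `grazing`,
#'   `gas_exchange`, `settling`, `burial`, `seepage`, `dispersion`,
#'   `water_exchange`. Defaults all `TRUE`.
#' @param dt_minutes computational time step, minutes.
#' @param bloom_dt_days cadence of the phytoplankton community step, d.
#' @param seed integer seed stored with the configuration (the simulator
#'   itself is deterministic; the seed governs fixture generation only).
#' @return object of class `eco_config`.
#' @export
eco_config <- function(compartments,
                       layers = default_layers(),
                       coefficients = eco_coefficients(),
                       phyto = phyto_types(),
                       forcing = list(),
                       inflow = NULL, outflow = NULL, exchange_flow = 0,
                       inflow_conc = NULL, loads = NULL, deep_conc = NULL,
                       initial = list(),
                       processes = list(),
                       dt_minutes = 5, bloom_dt_days = 1, seed = 1L) {
  subs <- substance_table(phyto)
  nc <- nrow(compartments)
  defaults_f <- list(temperature = 20, wind = 4, par = 100, ph = 8,
                     im3 = 0, zoo = 0)
  forcing <- utils::modifyList(defaults_f, forcing)
  proc_defaults <- list(organic_matter = TRUE, nutrients = TRUE,
                        sulphur = TRUE, phyto = TRUE, grazing = TRUE,
                        gas_exchange = TRUE, settling = TRUE, burial = TRUE,
                        seepage = TRUE, dispersion = TRUE,
                        water_exchange = TRUE)
  processes <- utils::modifyList(proc_defaults, processes)
  expand <- function(x, what) {
    m <- matrix(0, nc, nrow(subs), dimnames = list(compartments$name, subs$name))
    if (is.null(x)) return(m)
    if (is.matrix(x)) {
      stopifnot(nrow(x) == nc)
      m[, colnames(x)] <- x
      return(m)
    }
    bad <- setdiff(names(x), subs$name)
    if (length(bad)) stop("unknown substance in ", what, ": ",
                          paste(bad, collapse = ", "))
    for (s in names(x)) m[, s] <- x[[s]]
    m
  }
  loads_m <- expand(NULL, "loads")
  if (!is.null(loads)) {
    if (is.matrix(loads)) loads_m <- expand(loads, "loads")
    else {
      lv <- expand(loads, "loads")
      loads_m <- lv * compartments$area / sum(compartments$area)
    }
  }
  cfg <- list(compartments = compartments, layers = layers,
              coefficients = coefficients, phyto = phyto, substances = subs,
              forcing = forcing,
              inflow = inflow %||% stats::setNames(rep(0, nc), compartments$name),
              outflow = outflow %||% stats::setNames(rep(0, nc), compartments$name),
              exchange_flow = exchange_flow,
              inflow_conc = expand(inflow_conc, "inflow_conc"),
              loads = loads_m,
              deep_conc = deep_conc,
              initial = initial,
              processes = processes,
              dt_minutes = dt_minutes, bloom_dt_days = bloom_dt_days,
              seed = as.integer(seed))
  class(cfg) <- "eco_config"
  validate_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default sediment layer stack
#'
#' Ten layers with thicknesses increasing with depth (4 x 1 mm, 2 mm, 4 mm,
#' 1 cm, 2 cm, 6 cm, 10 cm; 20 cm in total). Thin top layers resolve the
#' steep redox gradients across the sediment-water interface; the deepest
#' layer acts as a buffer above the burial boundary.
#'
#' @return numeric vector of thicknesses, m.
#' @export
default_layers <- function() c(rep(0.001, 4), 0.002, 0.004, 0.01, 0.02,
                               0.06, 0.10)

#' Validate a model configuration
#'
#' Checks geometric invariants (positive thicknesses and areas, porosities
#' in (0, 1]), coefficient sanity (non-negative rates, min <= max bands),
#' forcing series monotonicity, and the presence of deep boundary
#' concentrations wherever upward seepage would import mass.
#'
#' @param cfg an `eco_config`.
#' @return the configuration, invisibly; stops with a descriptive message on
#'   the first violation.
#' @export
validate_config <- function(cfg) {
  cm <- cfg$compartments
  if (!all(c("name", "area", "depth", "porosity", "v_settle", "v_spg")
           %in% names(cm)))
    stop("compartments must have name, area, depth, porosity, v_settle, v_spg")
  if (any(cm$area <= 0) || any(cm$depth <= 0)) stop("areas and depths must be positive")
  if (any(cm$porosity <= 0) || any(cm$porosity > 1)) stop("porosity must be in (0, 1]")
  if (any(cm$v_settle < 0)) stop("settling velocities must be >= 0")
  if (any(cfg$layers <= 0)) stop("layer thicknesses must be positive")
  co <- cfg$coefficients
  if (any(co$k_d_min > co$k_d_max)) stop("k_d_min must not exceed k_d_max")
  rates <- unlist(co[c("k_s", "k_od", "k_so", "ks_p", "k_sd", "kv_p", "kv_d",
                       "k_ad", "k_moo", "k_mos", "k_ni_water", "k_ni_sediment")])
  if (any(rates < 0)) stop("negative rate constant: ",
                           paste(names(rates)[rates < 0], collapse = ", "))
  for (nmf in names(cfg$forcing)) {
    f <- cfg$forcing[[nmf]]
    if (is.data.frame(f)) {
      if (!all(c("time", "value") %in% names(f)))
        stop("forcing '", nmf, "' needs columns time, value")
      if (any(diff(f$time) <= 0))
        stop("forcing '", nmf, "' timestamps must be strictly increasing")
    } else if (!(is.numeric(f) && length(f) == 1)) {
      stop("forcing '", nmf, "' must be a constant or a time/value data.frame")
    }
  }
  if (any(cm$v_spg > 0) && is.null(cfg$deep_conc))
    stop("upward seepage requires deep boundary concentrations (deep_conc)")
  if (cfg$dt_minutes <= 0) stop("dt_minutes must be positive")
  invisible(cfg)
}

# evaluate a forcing entry on a vector of times (days), linear interpolation
forcing_at <- function(f, times) {
  if (is.data.frame(f))
    stats::approx(f$time, f$value, xout = times, rule = 2)$y
  else rep(f, length(times))
}
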