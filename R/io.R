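# Configuration serialization (YAML + delimited forcing tables with
# ISO-8601 dates) and result writers.

FORCING_ORIGIN <- as.Date("2000-01-01")

#' Write a configuration bundle
#'
#' Serializes a configuration to a directory: `config.yaml` with geometry,
#' coefficients, water balance, loads and initial state, one delimited
#' forcing file per series (`forcing_<name>.csv` with ISO-8601 dates), and
#' the phytoplankton parameter table.
#'
#' @param cfg an `eco_config`.
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_config <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nmf in names(cfg$forcing)) {
    f <- cfg$forcing[[nmf]]
    if (is.data.frame(f)) {
      out <- data.frame(date = format(FORCING_ORIGIN + f$time, "%Y-%m-%d"),
                        value = f$value)
      utils::write.csv(out, file.path(dir, paste0("forcing_", nmf, ".csv")),
                       row.names = FALSE)
    }
  }
  utils::write.table(cfg$phyto, file.path(dir, "phyto_types.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  named_list <- function(x) as.list(stats::setNames(as.numeric(x), names(x)))
  y <- list(
    compartments = lapply(seq_len(nrow(cfg$compartments)), function(r)
      as.list(cfg$compartments[r, ])),
    layers = as.numeric(cfg$layers),
    coefficients = lapply(unclass(cfg$coefficients), as.numeric),
    forcing_constants = Filter(Negate(is.null), lapply(cfg$forcing, function(f)
      if (is.data.frame(f)) NULL else as.numeric(f))),
    inflow = named_list(cfg$inflow),
    outflow = named_list(cfg$outflow),
    exchange_flow = cfg$exchange_flow,
    inflow_conc = apply(cfg$inflow_conc, 1, named_list, simplify = FALSE),
    loads = apply(cfg$loads, 1, named_list, simplify = FALSE),
    deep_conc = if (is.null(cfg$deep_conc)) NULL else named_list(cfg$deep_conc),
    initial_water = if (is.null(cfg$initial$water)) NULL else
      apply(cfg$initial$water, 1, named_list, simplify = FALSE),
    initial_sediment = if (is.null(cfg$initial$sediment)) NULL else
      lapply(seq_len(dim(cfg$initial$sediment)[1]), function(c)
        apply(cfg$initial$sediment[c, , ], 1, named_list, simplify = FALSE)),
    processes = cfg$processes,
    dt_minutes = cfg$dt_minutes,
    bloom_dt_days = cfg$bloom_dt_days,
    seed = cfg$seed)
  yaml::write_yaml(y, file.path(dir, "config.yaml"), precision = 15)
  invisible(dir)
}

#' Load a configuration bundle
#'
#' Reads a directory written by [write_config()] back into a validated
#' configuration; defaults fill any coefficient not present in the file and
#' every override of a default is checked against the known coefficient
#' names.
#'
#' @param dir directory containing `config.yaml`.
#' @return an `eco_config`.
#' @export
load_config <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "config.yaml") else dir
  if (!file.exists(path)) stop("no configuration found at ", dir)
  y <- yaml::read_yaml(path)
  dir <- dirname(path)
  cm <- do.call(rbind, lapply(y$compartments, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  co <- do.call(eco_coefficients, y$coefficients[
    setdiff(names(y$coefficients), names(which(
      vapply(y$coefficients, length, 1L) == 0)))])
  phyto_file <- file.path(dir, "phyto_types.tsv")
  phyto <- if (file.exists(phyto_file)) phyto_types(phyto_file) else phyto_types()
  forcing <- list()
  for (f in list.files(dir, pattern = "^forcing_.*\\.csv$")) {
    nmf <- sub("^forcing_(.*)\\.csv$", "\\1", f)
    d <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    forcing[[nmf]] <- data.frame(
      time = as.numeric(as.Date(d$date) - FORCING_ORIGIN), value = d$value)
  }
  for (nmf in names(y$forcing_constants))
    forcing[[nmf]] <- as.numeric(y$forcing_constants[[nmf]])
  unvec <- function(x) if (is.null(x)) NULL else unlist(x)
  mat_from <- function(rows) {
    if (is.null(rows)) return(NULL)
    m <- do.call(rbind, lapply(rows, unlist))
    rownames(m) <- cm$name
    m
  }
  sed <- NULL
  if (!is.null(y$initial_sediment)) {
    layers1 <- y$initial_sediment[[1]]
    nl <- length(layers1); nsub <- length(layers1[[1]])
    sed <- array(0, c(length(y$initial_sediment), nl, nsub),
                 dimnames = list(cm$name, NULL, names(layers1[[1]])))
    for (c in seq_along(y$initial_sediment))
      sed[c, , ] <- do.call(rbind, lapply(y$initial_sediment[[c]], unlist))
  }
  eco_config(compartments = cm, layers = unlist(y$layers),
             coefficients = co, phyto = phyto, forcing = forcing,
             inflow = unvec(y$inflow), outflow = unvec(y$outflow),
             exchange_flow = y$exchange_flow,
             inflow_conc = mat_from(y$inflow_conc),
             loads = mat_from(y$loads),
             deep_conc = unvec(y$deep_conc),
             initial = list(water = mat_from(y$initial_water), sediment = sed),
             processes = y$processes, dt_minutes = y$dt_minutes,
             bloom_dt_days = y$bloom_dt_days, seed = y$seed)
}

#' Write simulation outputs
#'
#' Writes deterministic delimited/JSON result files for a completed run:
#' `concentrations.csv` (one row per snapshot time and cell, one column per
#' substance), `boundary_fluxes.csv` (the cumulative ledger), `swi_fluxes.csv`
#' (cumulative diffusive sediment-water exchange per substance and column)
#' and `balance_<element>.json` for all six audited elements.
#'
#' @param run an `eco_run`.
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ns <- dim(run$snapshots)[1]
  conc <- data.frame(
    time = rep(run$snap_times, each = nrow(run$cells)),
    cell = rep(run$cells$id, ns))
  flat <- matrix(aperm(run$snapshots, c(2, 1, 3)), ns * nrow(run$cells),
                 dim(run$snapshots)[3])
  colnames(flat) <- dimnames(run$snapshots)[[3]]
  utils::write.csv(cbind(conc, flat), file.path(dir, "concentrations.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(substance = rownames(run$ledger$bnd),
                              run$ledger$bnd),
                   file.path(dir, "boundary_fluxes.csv"), row.names = FALSE)
  utils::write.csv(data.frame(substance = rownames(run$ledger$swi),
                              run$ledger$swi),
                   file.path(dir, "swi_fluxes.csv"), row.names = FALSE)
  for (el in ECO_ELEMENTS) {
    rep_el <- mass_balance_report(run, el)
    jsonlite::write_json(rep_el, file.path(dir, paste0("balance_", el, ".json")),
                         dataframe = "rows", digits = NA)
  }
  invisible(dir)
}
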