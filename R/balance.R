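# Mass-balance auditing: elemental closure of the flux ledger and
# per-element balance reports in load / internal-load / outflow / seepage /
# burial / atmosphere / denitrification / storage categories.

#' Elemental mass-balance closure
#'
#' For each conserved element, the change in stored mass over the run must
#' equal the sum of all ledgered boundary fluxes (external loads, outflow,
#' seepage, burial, atmosphere exchange, carbon exchanged with the implicit
#' CO2 pool, nitrogen lost as N2, and clipping credits). The residual is
#' normalized by the total element inventory plus throughput.
#'
#' @param run an `eco_run`.
#' @return named vector of relative closure residuals for C, N, P, S, Si
#'   and Cl.
#' @export
elemental_closure <- function(run) {
  W <- element_weights(substance_table(run$config$phyto))
  nsub <- ncol(run$state)
  mass_end <- colSums(run$state * run$V)
  dstore <- mass_end - run$ledger$mass0
  bnd <- run$ledger$bnd
  src <- as.vector(t(W) %*% rowSums(bnd))
  sto <- as.vector(t(W[seq_len(nsub), ]) %*% dstore)
  denom <- as.vector(t(W[seq_len(nsub), ]) %*% abs(run$ledger$mass0)) +
    as.vector(t(abs(W)) %*% rowSums(abs(bnd)))
  res <- abs(sto - src) / pmax(denom, 1e-12)
  stats::setNames(res, ECO_ELEMENTS)
}

#' Mass balance report for one element
#'
#' Aggregates the flux ledger of a completed run into the classical lake
#' budget categories: total external load, internal load (the diffusive
#' return flux from the sediment to the overlying water), outflow,
#' seepage/infiltration, burial below the model domain, atmosphere
#' exchange, denitrification (nitrogen only), net exchange with the
#' implicit CO2 pool (carbon only), clipping credits, storage change and
#' the closure residual.
#'
#' @param run an `eco_run`.
#' @param element one of `"C"`, `"N"`, `"P"`, `"S"`, `"Si"`, `"Cl"`.
#' @param per_area report fluxes per m2 of lake surface (g m-2 over the
#'   run) instead of g.
#' @return data.frame with `category` and `mass` columns.
#' @export
mass_balance_report <- function(run, element = c("C", "N", "P", "S", "Si", "Cl"),
                                per_area = FALSE) {
  element <- match.arg(element)
  subs <- substance_table(run$config$phyto)
  W <- element_weights(subs)
  w <- W[, element]
  nsub <- nrow(subs)
  wsub <- w[seq_len(nsub)]
  bnd <- run$ledger$bnd
  wcat <- as.vector(t(bnd) %*% w)
  names(wcat) <- colnames(bnd)
  internal <- sum(wsub * rowSums(run$ledger$swi))
  mass_end <- colSums(run$state * run$V)
  storage <- sum(wsub * (mass_end - run$ledger$mass0))
  rows <- data.frame(
    category = c("external_load", "internal_load", "outflow", "seepage",
                 "burial", "atmosphere", "clip", "storage"),
    mass = c(wcat["load"], internal, wcat["outflow"], wcat["seepage"],
             wcat["burial"], wcat["atmosphere"], wcat["clip"], storage),
    stringsAsFactors = FALSE)
  if (element == "N")
    rows <- rbind(rows, data.frame(category = "denitrification",
                                   mass = bnd["N2", "gas"]))
  if (element == "C")
    rows <- rbind(rows, data.frame(category = "net_co2_exchange",
                                   mass = bnd["CO2", "gas"]))
  boundary <- sum(wcat)
  rows <- rbind(rows, data.frame(category = "closure_residual",
                                 mass = storage - boundary))
  if (per_area) {
    A <- sum(run$config$compartments$area)
    rows$mass <- rows$mass / A
  }
  rownames(rows) <- NULL
  rows
}

#' Oxygen penetration depth in the sediment
#'
#' Depth below the sediment-water interface at which the pore-water oxygen
#' concentration falls below a threshold, linearly interpolated between
#' layer midpoints, for one snapshot of a run.
#'
#' @param run an `eco_run`.
#' @param snapshot snapshot index (rows of `run$snapshots`).
#' @param compartment compartment name (default: first).
#' @param threshold pore-water oxygen defining "oxic", g O2 m-3.
#' @return depth, m; the full column depth if oxygen never drops below the
#'   threshold.
#' @export
oxygen_penetration_depth <- function(run, snapshot,
                                     compartment = run$config$compartments$name[1],
                                     threshold = 0.1) {
  cells <- run$cells
  sel <- cells$kind == "sediment" & cells$column == compartment
  phi <- cells$porosity[sel]
  z <- cells$depth_below_interface[sel]
  do_pw <- run$snapshots[snapshot, sel, "DO"] / phi
  below <- which(do_pw < threshold)
  if (!length(below)) return(sum(cells$thickness[sel]))
  j <- below[1]
  if (j == 1) return(z[1] * min(1, do_pw[1] / threshold))
  # interpolate between the last oxic and the first anoxic midpoint
  z[j - 1] + (z[j] - z[j - 1]) *
    (do_pw[j - 1] - threshold) / max(do_pw[j - 1] - do_pw[j], 1e-12)
}
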