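# Substance registry: names, phase, element contents, transport class.
# Concentrations are bulk g per m3 of cell volume throughout the engine;
# solutes are converted to a pore-water basis (bulk / porosity) wherever a
# process law acts on dissolved concentrations.

ECO_ELEMENTS <- c("C", "N", "P", "S", "Si", "Cl")

#' Substance registry
#'
#' Returns the table of state variables simulated by the model: 14
#' phytoplankton phenotypes (carbon biomass), four particulate and one
#' dissolved detrital organic matter fraction for each of C, N, P and S,
#' dissolved nutrients and electron acceptors, phosphate species (dissolved,
#' adsorbed, vivianite-like, apatite-like), silica (dissolved and opal),
#' sulphur species, methane, inorganic sediment fractions and chloride.
#'
#' @param phyto phytoplankton parameter table, as returned by
#'   [phyto_types()]; supplies the elemental stoichiometry of the biomass
#'   state variables.
#' @return A data.frame with one row per substance: `name`, `phase`
#'   (`"dissolved"` or `"particulate"`), `settles` (subject to the net
#'   settling velocity of the compartment), and the element content columns
#'   `C`, `N`, `P`, `S`, `Si`, `Cl` in g element per g substance.
#' @export
substance_table <- function(phyto = phyto_types()) {
  alg <- paste0("ALG", seq_len(nrow(phyto)))
  pox <- c(t(outer(c("POC", "PON", "POP", "POS"), 1:4, paste0)))
  nm <- c(alg, pox, "DOC", "DON", "DOP", "DOS",
          "NO3", "NH4", "PO4", "AAP", "VIVP", "APATP",
          "Si", "OPAL", "DO", "SO4", "SUD", "SUP", "CH4",
          "IM1", "IM2", "IM3", "Cl")
  n <- length(nm)
  tab <- data.frame(name = nm, phase = "particulate", settles = FALSE,
                    C = 0, N = 0, P = 0, S = 0, Si = 0, Cl = 0,
                    stringsAsFactors = FALSE)
  rownames(tab) <- nm
  dis <- c("DOC", "DON", "DOP", "DOS", "NO3", "NH4", "PO4", "Si",
           "DO", "SO4", "SUD", "CH4", "Cl")
  tab[dis, "phase"] <- "dissolved"
  # element contents (g element per g substance-as-carried)
  tab[alg, "C"] <- 1
  tab[alg, "N"] <- phyto$s_n
  tab[alg, "P"] <- phyto$s_p
  tab[alg, "Si"] <- phyto$s_si
  tab[alg, "S"] <- phyto$s_s
  tab[grep("^POC|^DOC$|^CH4$", nm), "C"] <- 1
  tab[grep("^PON|^DON$|^NO3$|^NH4$", nm), "N"] <- 1
  tab[grep("^POP|^DOP$|^PO4$|^AAP$|^VIVP$|^APATP$", nm), "P"] <- 1
  tab[grep("^POS|^DOS$|^SO4$|^SUD$|^SUP$", nm), "S"] <- 1
  tab[c("Si", "OPAL"), "Si"] <- 1
  tab["Cl", "Cl"] <- 1
  # substances removed from the bottom water cell by net settling
  tab[c(pox, "AAP", "VIVP", "APATP", "OPAL", "SUP", "IM1", "IM2"),
      "settles"] <- TRUE
  tab
}

# element weight matrix (n_substance x 6) with two pseudo rows used by the
# flux ledger for carbon exchanged with the implicit CO2 pool and nitrogen
# lost as N2 by denitrification
element_weights <- function(subs) {
  w <- as.matrix(subs[, ECO_ELEMENTS])
  w <- rbind(w, CO2 = c(1, 0, 0, 0, 0, 0), N2 = c(0, 1, 0, 0, 0, 0))
  rownames(w) <- c(subs$name, "CO2", "N2")
  w
}
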