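#' @include sbml.R
NULL

## Enzyme complement of the canonical arachidonic-acid network: standard gene
## symbols, default subcellular localization and baseline (unstimulated)
## concentrations in uM. All values are placeholders with literature-plausible
## orders of magnitude; none are measured quantities.
.EICO_ENZYMES <- data.frame(
  gene = c("PLA2G4A", "PLA2G4A", "PLA2G4A",
           "PTGS1", "PTGS2", "PTGDS", "PTGES", "AKR1C3", "PTGIS", "TBXAS1",
           "ALOX5", "ALOX12", "ALOX15", "LTA4H", "LTC4S"),
  compartment = c("Cyt", "ERMem", "GolgiMem",
                  "ERMem", "ERMem", "ERMem", "Cyt", "Cyt", "ERMem", "ERMem",
                  "Cyt", "Cyt", "Cyt", "Cyt", "ERMem"),
  initial = c(0.05, 0, 0,
              0.02, 0.01, 0.03, 0.02, 0.02, 0.01, 0.03,
              0.02, 0.01, 0.01, 0.02, 0.01),
  proteoform = c("cytosolic", "membrane", "membrane",
                 NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA),
  name = c("cytosolic phospholipase A2 (cytosolic)",
           "cytosolic phospholipase A2 (ER membrane)",
           "cytosolic phospholipase A2 (Golgi membrane)",
           "cyclooxygenase 1", "cyclooxygenase 2",
           "prostaglandin D2 synthase", "prostaglandin E synthase",
           "prostaglandin F synthase", "prostacyclin synthase",
           "thromboxane A synthase 1",
           "arachidonate 5-lipoxygenase", "arachidonate 12-lipoxygenase",
           "arachidonate 15-lipoxygenase", "leukotriene A4 hydrolase",
           "leukotriene C4 synthase"),
  stringsAsFactors = FALSE
)

## reaction_id, form, substrate, product, enzyme gene (resolved to its default
## compartment), and placeholder kinetic constants
.EICO_REACTIONS <- list(
  list(id = "r_aa_release_er", type = "michaelis_menten",
       sub = "AAest@ERMem", prod = "AA@Cyt", enz = "PLA2G4A@ERMem",
       kcat = 200, Km = 20),
  list(id = "r_aa_release_golgi", type = "michaelis_menten",
       sub = "AAest@GolgiMem", prod = "AA@Cyt", enz = "PLA2G4A@GolgiMem",
       kcat = 200, Km = 20),
  list(id = "r_aa_reacylation", type = "mass_action",
       sub = "AA@Cyt", prod = "AAest@ERMem", k = 2),
  list(id = "r_cox1", type = "michaelis_menten",
       sub = "AA@Cyt", prod = "PGH2@Cyt", enz = "PTGS1@ERMem",
       kcat = 800, Km = 5),
  list(id = "r_cox2", type = "michaelis_menten",
       sub = "AA@Cyt", prod = "PGH2@Cyt", enz = "PTGS2@ERMem",
       kcat = 3000, Km = 5),
  list(id = "r_pgd_synthase", type = "michaelis_menten",
       sub = "PGH2@Cyt", prod = "PGD2@Cyt", enz = "PTGDS@ERMem",
       kcat = 2000, Km = 3),
  list(id = "r_pge_synthase", type = "michaelis_menten",
       sub = "PGH2@Cyt", prod = "PGE2@Cyt", enz = "PTGES@Cyt",
       kcat = 1500, Km = 5),
  list(id = "r_pgf_synthase", type = "michaelis_menten",
       sub = "PGH2@Cyt", prod = "PGF2A@Cyt", enz = "AKR1C3@Cyt",
       kcat = 500, Km = 10),
  list(id = "r_pgi_synthase", type = "michaelis_menten",
       sub = "PGH2@Cyt", prod = "PGI2@Cyt", enz = "PTGIS@ERMem",
       kcat = 1000, Km = 10),
  list(id = "r_tx_synthase", type = "michaelis_menten",
       sub = "PGH2@Cyt", prod = "TXA2@Cyt", enz = "TBXAS1@ERMem",
       kcat = 2500, Km = 4),
  list(id = "r_txa2_hydrolysis", type = "mass_action",
       sub = "TXA2@Cyt", prod = "TXB2@Cyt", k = 80),
  list(id = "r_alox5_hpete", type = "michaelis_menten",
       sub = "AA@Cyt", prod = "HPETE5@Cyt", enz = "ALOX5@Cyt",
       kcat = 600, Km = 10),
  list(id = "r_alox5_lta4", type = "michaelis_menten",
       sub = "HPETE5@Cyt", prod = "LTA4@Cyt", enz = "ALOX5@Cyt",
       kcat = 600, Km = 8),
  list(id = "r_lta4_hydrolase", type = "michaelis_menten",
       sub = "LTA4@Cyt", prod = "LTB4@Cyt", enz = "LTA4H@Cyt",
       kcat = 800, Km = 6),
  list(id = "r_ltc4_synthase", type = "michaelis_menten",
       sub = "LTA4@Cyt", prod = "LTC4@Cyt", enz = "LTC4S@ERMem",
       kcat = 400, Km = 6),
  list(id = "r_alox12", type = "michaelis_menten",
       sub = "AA@Cyt", prod = "HETE12@Cyt", enz = "ALOX12@Cyt",
       kcat = 300, Km = 15),
  list(id = "r_alox15", type = "michaelis_menten",
       sub = "AA@Cyt", prod = "HETE15@Cyt", enz = "ALOX15@Cyt",
       kcat = 300, Km = 15),
  list(id = "r_secr_pgd2", type = "transport_first_order",
       sub = "PGD2@Cyt", prod = "PGD2@Ecs", k = 5),
  list(id = "r_secr_pge2", type = "transport_first_order",
       sub = "PGE2@Cyt", prod = "PGE2@Ecs", k = 5),
  list(id = "r_secr_txb2", type = "transport_first_order",
       sub = "TXB2@Cyt", prod = "TXB2@Ecs", k = 5),
  list(id = "r_secr_ltb4", type = "transport_first_order",
       sub = "LTB4@Cyt", prod = "LTB4@Ecs", k = 5)
)

#' Genes of the canonical eicosanoid network
#' @return character vector of standard gene symbols
#' @export
canonicalGenes <- function() sort(unique(.EICO_ENZYMES$gene))

#' Build the canonical arachidonic-acid metabolism network
#'
#' The bundled flagship network: compartments Cyt (cytoplasm), ERMem
#' (endoplasmic reticulum / nuclear membranes), GolgiMem (Golgi membranes)
#' and Ecs (extracellular space), a membrane-esterified arachidonic-acid
#' (AAest) seed pool, calcium-recruitable cytosolic phospholipase A2
#' (PLA2G4A, with cytosolic and membrane proteoforms) releasing free AA,
#' first-order AA reacylation back into the membrane pool, cyclooxygenases
#' (PTGS1/PTGS2) producing PGH2, terminal synthase branches to PGD2 (PTGDS),
#' PGE2 (PTGES), PGF2a (AKR1C3), prostacyclin PGI2 (PTGIS) and thromboxane
#' TXA2 (TBXAS1, non-enzymatically hydrolyzed to stable TXB2), the
#' 5-lipoxygenase leukotriene branch (HPETE5 - LTA4 - LTB4/LTC4) and the
#' 12-/15-HETE branches, and first-order secretion of PGD2, PGE2, TXB2 and
#' LTB4 into the extracellular medium.
#'
#' All kinetic constants and concentrations are placeholders in
#' literature-plausible ranges (Km 1-50 uM, kcat in the hundreds to
#' thousands per hour); see [defaultParameters()] for the provenance-tagged
#' table.
#'
#' @param config optional list: `volumes` (named, relative to Cyt = 1;
#'   defaults Cyt 1, ERMem 0.15, GolgiMem 0.05, Ecs 10), `aaPool` (named
#'   initial esterified-AA concentrations for `AAest@ERMem` /
#'   `AAest@GolgiMem`).
#' @return a validated [ReactionNetwork-class]
#' @export
buildCanonicalNetwork <- function(config = list()) {
  volumes <- c(Cyt = 1, ERMem = 0.15, GolgiMem = 0.05, Ecs = 10)
  if (!is.null(config$volumes)) volumes[names(config$volumes)] <- config$volumes
  aa <- c("AAest@ERMem" = 60, "AAest@GolgiMem" = 20)
  if (!is.null(config$aaPool)) aa[names(config$aaPool)] <- config$aaPool

  cmp <- data.frame(
    id = c("Cyt", "ERMem", "GolgiMem", "Ecs"),
    volume = unname(volumes[c("Cyt", "ERMem", "GolgiMem", "Ecs")]),
    kind = c("aqueous", "membrane", "membrane", "extracellular"),
    stringsAsFactors = FALSE)

  mets <- data.frame(
    id = c("AAest", "AAest", "AA", "PGH2", "PGD2", "PGE2", "PGF2A", "PGI2",
           "TXA2", "TXB2", "HPETE5", "LTA4", "LTB4", "LTC4", "HETE12",
           "HETE15", "PGD2", "PGE2", "TXB2", "LTB4"),
    compartment = c("ERMem", "GolgiMem", rep("Cyt", 14), rep("Ecs", 4)),
    stringsAsFactors = FALSE)
  mets$name <- mets$id
  mets$role <- "metabolite"
  mets$initial <- 0
  mets$initial[1] <- aa[["AAest@ERMem"]]
  mets$initial[2] <- aa[["AAest@GolgiMem"]]
  mets$gene <- NA_character_
  mets$proteoform <- NA_character_

  prots <- data.frame(
    id = .EICO_ENZYMES$gene, name = .EICO_ENZYMES$name, role = "protein",
    compartment = .EICO_ENZYMES$compartment, initial = .EICO_ENZYMES$initial,
    gene = .EICO_ENZYMES$gene, proteoform = .EICO_ENZYMES$proteoform,
    stringsAsFactors = FALSE)

  species <- rbind(mets[, c("id", "name", "role", "compartment", "initial",
                            "gene", "proteoform")], prots)

  rxns <- lapply(.EICO_REACTIONS, function(r) {
    rl <- if (r$type == "michaelis_menten")
      RateLaw("michaelis_menten", kcat = r$kcat, Km = r$Km)
    else RateLaw(r$type, k = r$k)
    Reaction(id = r$id,
             substrates = stats::setNames(1, r$sub),
             products = stats::setNames(1, r$prod),
             rateLaw = rl,
             enzyme = if (is.null(r$enz)) NA_character_ else r$enz)
  })

  net <- ReactionNetwork(
    compartments = cmp, species = species, reactions = rxns,
    seeds = c("AAest@ERMem", "AAest@GolgiMem"),
    annotations = c(
      "Canonical arachidonic-acid (eicosanoid) biosynthesis network",
      "Gene symbol note: thromboxane A synthase is TBXAS1 (alias label 'TBXA1' seen in some figure legends)",
      "All kinetic parameters are placeholders; see the bundled parameter table for provenance tags"))
  .assert_valid(net, "canonical eicosanoid network")
  net
}

#' Default (placeholder) kinetic parameters of the canonical network
#'
#' One row per kinetic constant of every canonical reaction, with a
#' provenance tag. All values are `placeholder`: literature-plausible orders
#' of magnitude standing in for curated constants.
#'
#' @return data.frame with columns `reaction_id`, `parameter`, `value`,
#'   `units`, `provenance`
#' @export
defaultParameters <- function() {
  rows <- lapply(.EICO_REACTIONS, function(r) {
    if (r$type == "michaelis_menten")
      data.frame(reaction_id = r$id, parameter = c("kcat", "Km"),
                 value = c(r$kcat, r$Km), units = c("1/h", "uM"),
                 provenance = "placeholder", stringsAsFactors = FALSE)
    else
      data.frame(reaction_id = r$id, parameter = "k", value = r$k,
                 units = "1/h", provenance = "placeholder",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default macrophage-activation stimulation schedule
#'
#' Lipid A (LPS analogue) priming at `lipidATime` (a marker event: the
#' transcriptomic response it drives enters through the mRNA profiles), ATP
#' at `atpTime` triggering the cytoplasmic calcium burst, abstracted as
#' instantaneous translocation of PLA2G4A from the cytoplasm to the ER and
#' Golgi membranes with first-order return.
#'
#' @param lipidATime hours, default 0
#' @param atpTime hours, default 4
#' @param fractionER fraction of cytosolic PLA2G4A moved to the ER membrane
#' @param fractionGolgi fraction of the remaining cytosolic PLA2G4A then
#'   moved to the Golgi membrane (translocations apply sequentially)
#' @param kRet first-order return rate to the cytoplasm (per hour)
#' @return an [EventSchedule-class]
#' @export
defaultEventSchedule <- function(lipidATime = 0, atpTime = 4,
                                 fractionER = 0.6, fractionGolgi = 0.5,
                                 kRet = 0.5) {
  EventSchedule(list(
    list(time = lipidATime, kind = "add_ligand", payload = NULL),   # Lipid A
    list(time = atpTime, kind = "add_ligand", payload = NULL),      # ATP
    list(time = atpTime, kind = "calcium_translocation",
         payload = data.frame(
           species = c("PLA2G4A", "PLA2G4A"),
           from = c("Cyt", "Cyt"),
           to = c("ERMem", "GolgiMem"),
           fraction = c(fractionER, fractionGolgi),
           k_ret = c(kRet, kRet), stringsAsFactors = FALSE))
  ))
}

#' Load the bundled canonical network document
#'
#' Parses the network document shipped under `inst/extdata/`; equal to
#' [buildCanonicalNetwork()] with default configuration.
#'
#' @return a [ReactionNetwork-class]
#' @export
loadCanonicalNetwork <- function() {
  parseNetwork(system.file("extdata", "eicosanoid_network.json",
                           package = "eicotwin", mustWork = TRUE))
}

#' Override kinetic parameters
#'
#' Applies a parameter table (as from [defaultParameters()], optionally with
#' edited values) or a named override vector (`"reaction_id:parameter"` ->
#' value) to a network or model.
#'
#' @param x a [ReactionNetwork-class] or [DynamicModel-class]
#' @param table data.frame with columns `reaction_id`, `parameter`, `value`
#' @param overrides named numeric, names `"reaction_id:parameter"`
#' @return object of the same class with parameters replaced
#' @export
applyParameters <- function(x, table = NULL, overrides = NULL) {
  if (is(x, "DynamicModel")) {
    x@network <- applyParameters(x@network, table, overrides)
    return(x)
  }
  stopifnot(is(x, "ReactionNetwork"))
  pairs <- list()
  if (!is.null(table))
    for (i in seq_len(nrow(table)))
      pairs[[paste0(table$reaction_id[i], ":", table$parameter[i])]] <- table$value[i]
  if (!is.null(overrides))
    for (nm in names(overrides)) pairs[[nm]] <- overrides[[nm]]
  rids <- vapply(x@reactions, function(r) r@id, character(1))
  for (nm in names(pairs)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    j <- match(parts[1], rids)
    if (is.na(j))
      stop(sprintf("no reaction '%s' in the network", parts[1]), call. = FALSE)
    r <- x@reactions[[j]]
    if (!parts[2] %in% names(r@rateLaw@params))
      stop(sprintf("reaction '%s' has no parameter '%s'", parts[1], parts[2]),
           call. = FALSE)
    r@rateLaw@params[[parts[2]]] <- as.numeric(pairs[[nm]])
    x@reactions[[j]] <- r
  }
  x
}
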