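#' @include AllClasses.R
NULL

#' Accessors for network containers
#'
#' `compartments()`, `speciesTable()`, `reactions()`, `seedMetabolites()` and
#' `stateNames()` expose the slots of a [ReactionNetwork-class] (or the
#' network inside a [DynamicModel-class]) without touching `@`.
#'
#' @param x a `ReactionNetwork` or `DynamicModel`
#' @return `compartments`/`speciesTable`: data.frame; `reactions`: list of
#'   [Reaction-class]; `seedMetabolites`: character keys; `stateNames`:
#'   character keys of all state variables (metabolites and proteins; mRNA
#'   species are forcing functions, not states).
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname compartments
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname compartments
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname compartments
#' @export
setGeneric("seedMetabolites", function(x) standardGeneric("seedMetabolites"))

#' @rdname compartments
#' @export
setGeneric("stateNames", function(x) standardGeneric("stateNames"))

setMethod("compartments", "ReactionNetwork", function(x) x@compartments)
setMethod("speciesTable", "ReactionNetwork", function(x) x@species)
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)
setMethod("seedMetabolites", "ReactionNetwork", function(x) x@seeds)
setMethod("stateNames", "ReactionNetwork", function(x) {
  sp <- x@species
  sp <- sp[sp$role != "mRNA", , drop = FALSE]
  speciesKey(sp$id, sp$compartment)
})

setMethod("compartments", "DynamicModel", function(x) x@network@compartments)
setMethod("speciesTable", "DynamicModel", function(x) x@network@species)
setMethod("reactions", "DynamicModel", function(x) x@network@reactions)
setMethod("seedMetabolites", "DynamicModel", function(x) x@network@seeds)
setMethod("stateNames", "DynamicModel", function(x) stateNames(x@network))

#' Network of a dynamic model
#' @param x a [DynamicModel-class]
#' @return the underlying [ReactionNetwork-class]
#' @export
setGeneric("modelNetwork", function(x) standardGeneric("modelNetwork"))
setMethod("modelNetwork", "DynamicModel", function(x) x@network)

#' Forcing profiles of a dynamic model
#' @param x a [DynamicModel-class]
#' @return named list of [ContinuousProfile-class], keyed by gene
#' @export
setGeneric("modelProfiles", function(x) standardGeneric("modelProfiles"))
setMethod("modelProfiles", "DynamicModel", function(x) x@profiles)

#' Expression links of a dynamic model
#' @param x a [DynamicModel-class]
#' @return data.frame with columns gene, compartment, protein, baseline, ks, kd
#' @export
setGeneric("expressionLinks", function(x) standardGeneric("expressionLinks"))
setMethod("expressionLinks", "DynamicModel", function(x) x@links)

#' Event schedule of a dynamic model
#' @param x a [DynamicModel-class]
#' @return an [EventSchedule-class]
#' @export
setGeneric("modelEvents", function(x) standardGeneric("modelEvents"))
setMethod("modelEvents", "DynamicModel", function(x) x@events)

#' Time grid and state matrix of a simulation result
#' @param x a [SimulationResult-class]
#' @return `resultTime`: numeric vector; `resultStates`: matrix with one
#'   column per species key
#' @export
setGeneric("resultTime", function(x) standardGeneric("resultTime"))
setMethod("resultTime", "SimulationResult", function(x) x@time)

#' @rdname resultTime
#' @export
setGeneric("resultStates", function(x) standardGeneric("resultStates"))
setMethod("resultStates", "SimulationResult", function(x) x@states)

## ---- show methods ----------------------------------------------------------

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf(
    "ReactionNetwork: %d compartments, %d species, %d reactions, %d seed(s)\n",
    nrow(object@compartments), nrow(object@species),
    length(object@reactions), length(object@seeds)))
  cat("  compartments:", paste(object@compartments$id, collapse = ", "), "\n")
  roles <- table(object@species$role)
  cat("  species roles:",
      paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
})

setMethod("show", "DynamicModel", function(object) {
  cat("DynamicModel\n")
  show(object@network)
  cat(sprintf("  expression links: %d (genes: %s)\n", nrow(object@links),
              paste(unique(object@links$gene), collapse = ", ")))
  cat(sprintf("  constant proteins: %d; events: %d\n",
              length(object@constantProteins), length(object@events@events)))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d time points on [%g, %g] h, %d states\n",
              length(object@time), min(object@time), max(object@time),
              ncol(object@states)))
})

setMethod("show", "GeneratedProgram", function(object) {
  cat(sprintf("GeneratedProgram (dialect '%s'): %d states, %d source lines, md5 %s\n",
              object@dialect, nrow(object@manifest),
              length(strsplit(object@source, "\n", fixed = TRUE)[[1]]),
              object@checksum))
})

setMethod("show", "ContinuousProfile", function(object) {
  cat(sprintf("ContinuousProfile: %d knots on [%g, %g] h, range [%g, %g]\n",
              length(object@knots), min(object@knots), max(object@knots),
              min(object@values), max(object@values)))
})

setMethod("show", "EventSchedule", function(object) {
  if (!length(object@events)) { cat("EventSchedule: empty\n"); return(invisible()) }
  cat(sprintf("EventSchedule: %d event(s)\n", length(object@events)))
  for (e in object@events)
    cat(sprintf("  t = %g h: %s\n", e$time, e$kind))
})
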