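#' @import methods
NULL

.COMPARTMENT_KINDS <- c("aqueous", "membrane", "extracellular")
.SPECIES_ROLES <- c("metabolite", "protein", "mRNA")
.RATE_FORMS <- c("michaelis_menten", "mass_action", "transport_first_order",
                 "translation", "degradation_first_order")
.EVENT_KINDS <- c("add_ligand", "calcium_translocation")

## parameters each rate-law form must (and may only) carry
.RATE_REQUIRED <- list(
  michaelis_menten        = c("kcat", "Km"),
  mass_action             = "k",
  transport_first_order   = "k",
  translation             = "ks",
  degradation_first_order = "k"
)

#' Kinetic rate law
#'
#' A rate law attached to a reaction. `form` selects the functional form and
#' `params` carries exactly the kinetic constants that form requires:
#' Michaelis-Menten needs `kcat` (per hour) and `Km` (uM); the first-order
#' forms (`mass_action`, `transport_first_order`, `degradation_first_order`)
#' need `k` (per hour); `translation` needs `ks` (protein uM per mRNA unit per
#' hour).
#'
#' @slot form character, one of the registered forms.
#' @slot params named numeric vector of kinetic constants.
#' @export
setClass("RateLaw", representation(form = "character", params = "numeric"))

#' A single irreversible reaction
#'
#' Substrates and products are named numeric vectors mapping species keys
#' (`"id@compartment"`) to positive integer stoichiometries. Michaelis-Menten
#' reactions name exactly one enzyme species (a protein). Translation
#' reactions carry the gene whose mRNA forcing profile drives them.
#'
#' @slot id character reaction identifier.
#' @slot substrates named numeric, stoichiometries by species key.
#' @slot products named numeric, stoichiometries by species key.
#' @slot enzyme character species key or `NA`.
#' @slot gene character gene id (translation reactions) or `NA`.
#' @slot rateLaw a [RateLaw-class] object.
#' @slot reversible logical, always `FALSE`; reversibility is modeled as two
#'   reactions.
#' @export
setClass("Reaction", representation(
  id = "character", substrates = "numeric", products = "numeric",
  enzyme = "character", gene = "character", rateLaw = "RateLaw",
  reversible = "logical"
))

#' Compartmental reaction network
#'
#' The central container: compartments with relative volumes, species located
#' in compartments, irreversible reactions, and the seed metabolites treated
#' as primary precursors (e.g. the membrane-esterified arachidonic-acid
#' pool). Species are addressed by key `"id@compartment"`; the same chemical
#' id may appear in several compartments. Use [validateNetwork()] for the
#' full semantic invariant check; the S4 validity here is type-level only so
#' that deliberately broken networks can be constructed and reported on.
#'
#' @slot compartments data.frame with columns `id`, `volume` (relative to
#'   cytoplasm = 1), `kind` (aqueous/membrane/extracellular).
#' @slot species data.frame with columns `id`, `name`, `role`, `compartment`,
#'   `initial` (uM), `gene`, `proteoform`.
#' @slot reactions list of [Reaction-class] objects.
#' @slot seeds character vector of seed species keys.
#' @slot annotations character free-text provenance.
#' @export
setClass("ReactionNetwork", representation(
  compartments = "data.frame", species = "data.frame",
  reactions = "list", seeds = "character", annotations = "character"
))

#' Continuous forcing profile
#'
#' A piecewise natural cubic interpolant through replicate-mean measurements,
#' with constant extrapolation outside the measured window and negative
#' values clipped to zero on evaluation. Polynomial coefficients are stored
#' explicitly (one row per interval: value = a + b dt + c dt^2 + d dt^3) so
#' generated programs can embed them verbatim.
#'
#' @slot knots strictly increasing times (hours).
#' @slot values interpolated values at the knots.
#' @slot coefs numeric matrix, `length(knots) - 1` rows, columns a, b, c, d.
#' @export
setClass("ContinuousProfile",
         representation(knots = "numeric", values = "numeric",
                        coefs = "matrix"))

#' Timed stimulation / translocation schedule
#'
#' Each event is a list with `time` (hours), `kind` (`add_ligand` or
#' `calcium_translocation`) and a `payload`. An `add_ligand` payload may be
#' `NULL` (a marker; the transcriptomic response to the ligand is carried by
#' the measured mRNA profiles) or a list with `species`, `compartment`,
#' `amount` to add. A `calcium_translocation` payload is a data.frame with
#' columns `species`, `from`, `to`, `fraction`, `k_ret`: at the event time a
#' fraction of the source-compartment amount moves instantly to the
#' destination and a first-order return flux at `k_ret` (per hour) is armed.
#'
#' @slot events list of event records, sorted by time.
#' @export
setClass("EventSchedule", representation(events = "list"),
         prototype(events = list()))

#' Executable cell-type-selective dynamical model
#'
#' A pruned [ReactionNetwork-class] whose enzymes are coupled to measured
#' mRNA levels through translation/degradation reactions, plus the continuous
#' mRNA forcing profiles and the stimulation event schedule.
#'
#' @slot network the (pruned, expression-linked) reaction network.
#' @slot profiles named list, gene id -> [ContinuousProfile-class].
#' @slot links data.frame describing each translation/degradation link:
#'   columns `gene`, `compartment`, `protein` (species key), `baseline` (uM),
#'   `ks`, `kd`.
#' @slot constantProteins character keys of proteins lacking profiles, held
#'   constant.
#' @slot events an [EventSchedule-class].
#' @export
setClass("DynamicModel", representation(
  network = "ReactionNetwork", profiles = "list", links = "data.frame",
  constantProteins = "character", events = "EventSchedule"
))

#' Simulation result
#'
#' Dense trajectory of every state variable (species x compartment, uM) on a
#' strictly increasing time grid, with solver diagnostics.
#'
#' @slot time numeric grid (hours), strictly increasing.
#' @slot states numeric matrix, one row per time, one column per state
#'   variable; column names are species keys (`"id@compartment"`).
#' @slot diagnostics list (solver, tolerances, segment count, steps).
#' @export
setClass("SimulationResult", representation(
  time = "numeric", states = "matrix", diagnostics = "list"
))

#' Generated standalone solver program
#'
#' @slot dialect character dialect id.
#' @slot source character, the full program text (one string).
#' @slot manifest data.frame mapping state index -> species, compartment.
#' @slot checksum character md5 of the source text.
#' @export
setClass("GeneratedProgram", representation(
  dialect = "character", source = "character", manifest = "data.frame",
  checksum = "character"
))

## ---- light constructors ----------------------------------------------------

#' Construct a rate law
#' @param form one of `r paste0('"', .RATE_FORMS, '"', collapse = ", ")`.
#' @param ... kinetic constants required by `form` (e.g. `kcat=`, `Km=`).
#' @return a [RateLaw-class]
#' @export
RateLaw <- function(form, ...) {
  params <- unlist(list(...))
  if (length(params) == 0) params <- numeric(0)
  new("RateLaw", form = form, params = params)
}

#' Construct a reaction
#' @param id reaction id.
#' @param substrates,products named numeric vectors of stoichiometries keyed
#'   by species key; may be empty (translation reactions have no substrate
#'   state variable, the mRNA being a forcing function).
#' @param rateLaw a [RateLaw-class].
#' @param enzyme species key of the catalyzing enzyme (Michaelis-Menten only).
#' @param gene gene id driving a translation reaction.
#' @return a [Reaction-class]
#' @export
Reaction <- function(id, substrates = numeric(0), products = numeric(0),
                     rateLaw, enzyme = NA_character_, gene = NA_character_) {
  new("Reaction", id = id,
      substrates = .as_stoich(substrates), products = .as_stoich(products),
      enzyme = enzyme, gene = gene, rateLaw = rateLaw, reversible = FALSE)
}

.as_stoich <- function(x) {
  if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
  storage.mode(x) <- "double"
  x
}

#' Construct an event schedule
#' @param events list of event records (`time`, `kind`, `payload`); sorted by
#'   time on construction.
#' @return an [EventSchedule-class]
#' @export
EventSchedule <- function(events = list()) {
  if (length(events)) {
    times <- vapply(events, function(e) as.numeric(e$time), numeric(1))
    if (any(times < 0)) stop("event times must be >= 0")
    kinds <- vapply(events, function(e) e$kind, character(1))
    bad <- setdiff(kinds, .EVENT_KINDS)
    if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
    events <- events[order(times)]
  }
  new("EventSchedule", events = events)
}

## ---- species-key helpers ---------------------------------------------------

#' Species keys
#'
#' State variables are addressed as `"id@compartment"`. `speciesKey` builds a
#' key, `splitSpeciesKey` decomposes one.
#' @param id species id
#' @param compartment compartment id
#' @return `speciesKey`: character key; `splitSpeciesKey`: data.frame with
#'   columns `id` and `compartment`.
#' @export
speciesKey <- function(id, compartment) paste0(id, "@", compartment)

#' @rdname speciesKey
#' @param key character vector of keys
#' @export
splitSpeciesKey <- function(key) {
  parts <- strsplit(key, "@", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[`, character(1), 1L),
    compartment = vapply(parts, function(p)
      if (length(p) >= 2) paste(p[-1], collapse = "@") else NA_character_,
      character(1)),
    stringsAsFactors = FALSE
  )
}
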