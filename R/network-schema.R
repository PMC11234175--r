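#' @include AllClasses.R
NULL

#' Construct a reaction network
#'
#' Low-level constructor. Components are normalized (compartments and
#' reactions sorted by id, species by key, numeric columns coerced to double)
#' so that serialization is deterministic and structural equality is
#' well-defined. No semantic validation is performed here; run
#' [validateNetwork()] (as [parseNetwork()] does) to check the invariants.
#'
#' @param compartments data.frame with columns `id`, `volume`, `kind`.
#' @param species data.frame with columns `id`, `name`, `role`,
#'   `compartment`, `initial` and optionally `gene`, `proteoform`.
#' @param reactions list of [Reaction-class] objects.
#' @param seeds character vector of seed species keys (primary precursors).
#' @param annotations character vector of free-text provenance.
#' @return a [ReactionNetwork-class]
#' @export
ReactionNetwork <- function(compartments, species, reactions = list(),
                            seeds = character(0),
                            annotations = character(0)) {
  compartments <- data.frame(
    id = as.character(compartments$id),
    volume = as.numeric(compartments$volume),
    kind = as.character(compartments$kind),
    stringsAsFactors = FALSE)
  compartments <- compartments[order(compartments$id), , drop = FALSE]
  rownames(compartments) <- NULL

  species <- data.frame(
    id = as.character(species$id),
    name = if (is.null(species$name)) as.character(species$id) else as.character(species$name),
    role = as.character(species$role),
    compartment = as.character(species$compartment),
    initial = as.numeric(species$initial),
    gene = if (is.null(species$gene)) NA_character_ else as.character(species$gene),
    proteoform = if (is.null(species$proteoform)) NA_character_ else as.character(species$proteoform),
    stringsAsFactors = FALSE)
  species <- species[order(speciesKey(species$id, species$compartment)), , drop = FALSE]
  rownames(species) <- NULL

  if (length(reactions)) {
    ids <- vapply(reactions, function(r) r@id, character(1))
    reactions <- lapply(reactions[order(ids)], .normalize_reaction)
  }

  new("ReactionNetwork", compartments = compartments, species = species,
      reactions = reactions, seeds = sort(as.character(seeds)),
      annotations = as.character(annotations))
}

.normalize_reaction <- function(r) {
  r@substrates <- .sort_stoich(r@substrates)
  r@products <- .sort_stoich(r@products)
  r@rateLaw@params <- r@rateLaw@params[order(names(r@rateLaw@params))]
  r
}

.sort_stoich <- function(x) {
  x <- .as_stoich(x)
  if (length(x)) x[order(names(x))] else x
}

## ---- validation ------------------------------------------------------------

.violation <- function(element, rule, message) {
  data.frame(element = element, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a reaction network
#'
#' Checks every semantic invariant of the network data model and returns the
#' violations as data, not exceptions: an empty data.frame means the network
#' is valid. Each violation names the offending element and the broken rule.
#'
#' Rules checked: unique compartment ids, positive volumes, known kinds;
#' unique (species, compartment) pairs, non-negative initial concentrations,
#' known roles, existing compartments, `gene` present exactly for proteins
#' and mRNAs; unique reaction ids, resolvable species references, integer
#' stoichiometries >= 1, non-negative kinetic constants matching the rate-law
#' form exactly, Michaelis-Menten reactions with exactly one (protein) enzyme
#' and one substrate, transport reactions connecting the same chemical id in
#' two different compartments, irreversibility; non-empty seed set referring
#' to existing species.
#'
#' @param net a [ReactionNetwork-class]
#' @return data.frame with columns `element`, `rule`, `message`; zero rows
#'   iff all invariants hold.
#' @export
validateNetwork <- function(net) {
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- .violation(...)
  cmp <- net@compartments
  sp <- net@species

  dup <- cmp$id[duplicated(cmp$id)]
  for (d in unique(dup)) add(d, "compartment_id_unique", sprintf("duplicated compartment id '%s'", d))
  for (i in seq_len(nrow(cmp))) {
    if (!is.finite(cmp$volume[i]) || cmp$volume[i] <= 0)
      add(cmp$id[i], "compartment_volume_positive",
          sprintf("compartment '%s' has non-positive volume", cmp$id[i]))
    if (!cmp$kind[i] %in% .COMPARTMENT_KINDS)
      add(cmp$id[i], "compartment_kind",
          sprintf("compartment '%s' has unknown kind '%s'", cmp$id[i], cmp$kind[i]))
  }

  keys <- speciesKey(sp$id, sp$compartment)
  dup <- keys[duplicated(keys)]
  for (d in unique(dup)) add(d, "species_key_unique", sprintf("duplicated species '%s'", d))
  for (i in seq_len(nrow(sp))) {
    k <- keys[i]
    if (!is.finite(sp$initial[i]) || sp$initial[i] < 0)
      add(k, "species_initial_nonnegative",
          sprintf("species '%s' has negative initial concentration", k))
    if (!sp$role[i] %in% .SPECIES_ROLES)
      add(k, "species_role", sprintf("species '%s' has unknown role '%s'", k, sp$role[i]))
    if (!sp$compartment[i] %in% cmp$id)
      add(k, "species_compartment_exists",
          sprintf("species '%s' references undeclared compartment '%s'", k, sp$compartment[i]))
    needs_gene <- sp$role[i] %in% c("protein", "mRNA")
    if (needs_gene && is.na(sp$gene[i]))
      add(k, "species_gene_required", sprintf("%s species '%s' lacks a gene id", sp$role[i], k))
    if (!needs_gene && !is.na(sp$gene[i]))
      add(k, "species_gene_forbidden", sprintf("metabolite species '%s' carries a gene id", k))
  }

  rids <- vapply(net@reactions, function(r) r@id, character(1))
  dup <- rids[duplicated(rids)]
  for (d in unique(dup)) add(d, "reaction_id_unique", sprintf("duplicated reaction id '%s'", d))

  for (r in net@reactions) {
    refd <- c(names(r@substrates), names(r@products),
              if (!is.na(r@enzyme)) r@enzyme)
    for (m in setdiff(refd, keys))
      add(r@id, "reaction_species_exists",
          sprintf("reaction '%s' references undeclared species '%s'", r@id, m))
    st <- c(r@substrates, r@products)
    if (length(st) && any(st < 1 | st != round(st)))
      add(r@id, "reaction_stoichiometry",
          sprintf("reaction '%s' has non positive-integer stoichiometry", r@id))
    if (isTRUE(r@reversible))
      add(r@id, "reaction_irreversible",
          sprintf("reaction '%s' is marked reversible; model reversibility as two reactions", r@id))

    rl <- r@rateLaw
    if (!rl@form %in% .RATE_FORMS) {
      add(r@id, "rate_law_form", sprintf("reaction '%s' has unknown rate-law form '%s'", r@id, rl@form))
    } else {
      req <- .RATE_REQUIRED[[rl@form]]
      have <- names(rl@params)
      for (m in setdiff(req, have))
        add(r@id, "rate_law_params",
            sprintf("reaction '%s' (%s) lacks parameter '%s'", r@id, rl@form, m))
      for (m in setdiff(have, req))
        add(r@id, "rate_law_params",
            sprintf("reaction '%s' (%s) carries extraneous parameter '%s'", r@id, rl@form, m))
      if (any(!is.finite(rl@params) | rl@params < 0))
        add(r@id, "rate_law_nonnegative",
            sprintf("reaction '%s' has a negative kinetic constant", r@id))
    }

    if (rl@form == "michaelis_menten") {
      if (is.na(r@enzyme)) {
        add(r@id, "mm_enzyme_required",
            sprintf("Michaelis-Menten reaction '%s' names no enzyme", r@id))
      } else if (r@enzyme %in% keys) {
        erow <- which(keys == r@enzyme)[1]
        if (sp$role[erow] != "protein")
          add(r@id, "mm_enzyme_protein",
              sprintf("enzyme '%s' of reaction '%s' is not a protein", r@enzyme, r@id))
        else if (is.na(sp$gene[erow]))
          add(r@id, "mm_enzyme_gene",
              sprintf("enzyme '%s' of reaction '%s' has no gene mapping", r@enzyme, r@id))
      }
      if (length(r@substrates) != 1L)
        add(r@id, "mm_single_substrate",
            sprintf("Michaelis-Menten reaction '%s' must have exactly one substrate", r@id))
    } else if (!is.na(r@enzyme)) {
      add(r@id, "enzyme_mm_only",
          sprintf("reaction '%s' (%s) names an enzyme but is not Michaelis-Menten", r@id, rl@form))
    }

    if (rl@form == "transport_first_order") {
      ok <- length(r@substrates) == 1L && length(r@products) == 1L
      if (ok) {
        a <- splitSpeciesKey(names(r@substrates))
        b <- splitSpeciesKey(names(r@products))
        ok <- identical(a$id, b$id) && !identical(a$compartment, b$compartment)
      }
      if (!ok)
        add(r@id, "transport_identity",
            sprintf("transport reaction '%s' must move one chemical id between two different compartments", r@id))
    }
  }

  if (length(net@seeds) == 0)
    add("<network>", "seeds_nonempty", "seed metabolite set is empty")
  for (m in setdiff(net@seeds, keys))
    add(m, "seed_exists", sprintf("seed '%s' is not a declared species", m))

  if (length(v)) do.call(rbind, v) else
    .violation(character(0), character(0), character(0))
}

.assert_valid <- function(net, context = "network") {
  v <- validateNetwork(net)
  if (nrow(v))
    stop(sprintf("invalid %s (%d violation(s)):\n%s", context, nrow(v),
                 paste(sprintf("  [%s] %s", v$rule, v$message), collapse = "\n")),
         call. = FALSE)
  invisible(net)
}

## ---- parsing ---------------------------------------------------------------

#' Read a reaction-network document
#'
#' Parses a structured-text network document (JSON, the canonical format, or
#' YAML) with top-level keys `compartments`, `species`, `reactions`, `seeds`,
#' `annotations`, and returns a validated [ReactionNetwork-class]. Species
#' references in reactions and seeds use the full `"id@compartment"` form; a
#' bare id is accepted when unambiguous. Schema violations raise a parse
#' error naming the offending element; semantic violations raise a
#' validation error listing them.
#'
#' @param document path to a `.json`/`.yaml`/`.yml` file, or a single string
#'   holding the document text.
#' @return a validated [ReactionNetwork-class]
#' @seealso [writeNetwork()], [validateNetwork()]
#' @export
parseNetwork <- function(document) {
  doc <- .read_structured(document)
  .network_from_list(doc)
}

.read_structured <- function(document) {
  txt <- if (length(document) == 1 && !grepl("[{\n:]", document) &&
             file.exists(document)) {
    paste(readLines(document, warn = FALSE), collapse = "\n")
  } else paste(document, collapse = "\n")
  trimmed <- trimws(txt)
  if (startsWith(trimmed, "{") || startsWith(trimmed, "[")) {
    jsonlite::fromJSON(txt, simplifyVector = FALSE)
  } else {
    yaml::yaml.load(txt)
  }
}

.network_from_list <- function(doc) {
  for (k in c("compartments", "species", "seeds"))
    if (is.null(doc[[k]]))
      stop(sprintf("network document lacks required key '%s'", k), call. = FALSE)

  cmp <- do.call(rbind, lapply(doc$compartments, function(x) {
    for (k in c("id", "volume", "kind"))
      if (is.null(x[[k]]))
        stop(sprintf("compartment entry lacks '%s' (near '%s')", k,
                     if (is.null(x$id)) "?" else x$id), call. = FALSE)
    data.frame(id = as.character(x$id), volume = as.numeric(x$volume),
               kind = as.character(x$kind), stringsAsFactors = FALSE)
  }))

  sp <- do.call(rbind, lapply(doc$species, function(x) {
    for (k in c("id", "role", "compartment"))
      if (is.null(x[[k]]))
        stop(sprintf("species entry lacks '%s' (near '%s')", k,
                     if (is.null(x$id)) "?" else x$id), call. = FALSE)
    data.frame(
      id = as.character(x$id),
      name = if (is.null(x$name)) as.character(x$id) else as.character(x$name),
      role = as.character(x$role),
      compartment = as.character(x$compartment),
      initial = if (is.null(x$initial)) 0 else as.numeric(x$initial),
      gene = if (is.null(x$gene)) NA_character_ else as.character(x$gene),
      proteoform = if (is.null(x$proteoform)) NA_character_ else as.character(x$proteoform),
      stringsAsFactors = FALSE)
  }))
  keys <- speciesKey(sp$id, sp$compartment)

  resolve <- function(ref, where) {
    ref <- as.character(ref)
    if (grepl("@", ref, fixed = TRUE)) return(ref)
    hits <- keys[sp$id == ref]
    if (length(hits) == 0)
      stop(sprintf("validation error in %s: species '%s' is not declared", where, ref),
           call. = FALSE)
    if (length(hits) > 1)
      stop(sprintf("ambiguous species reference '%s' in %s; use 'id@compartment' (candidates: %s)",
                   ref, where, paste(hits, collapse = ", ")), call. = FALSE)
    hits
  }

  parse_stoich <- function(entries, where) {
    if (is.null(entries) || length(entries) == 0)
      return(stats::setNames(numeric(0), character(0)))
    ks <- character(length(entries)); vs <- numeric(length(entries))
    for (i in seq_along(entries)) {
      e <- entries[[i]]
      if (is.null(e$species))
        stop(sprintf("stoichiometry entry in %s lacks 'species'", where), call. = FALSE)
      ks[i] <- resolve(e$species, where)
      vs[i] <- if (is.null(e$stoich)) 1 else as.numeric(e$stoich)
    }
    stats::setNames(vs, ks)
  }

  reactions <- lapply(doc$reactions, function(x) {
    if (is.null(x$id)) stop("reaction entry lacks 'id'", call. = FALSE)
    if (is.null(x$type))
      stop(sprintf("reaction '%s' lacks 'type'", x$id), call. = FALSE)
    where <- sprintf("reaction '%s'", x$id)
    params <- if (is.null(x$params)) numeric(0) else
      stats::setNames(vapply(x$params, as.numeric, numeric(1)), names(x$params))
    Reaction(
      id = as.character(x$id),
      substrates = parse_stoich(x$substrates, where),
      products = parse_stoich(x$products, where),
      rateLaw = new("RateLaw", form = as.character(x$type), params = params),
      enzyme = if (is.null(x$enzyme)) NA_character_ else resolve(x$enzyme, where),
      gene = if (is.null(x$gene)) NA_character_ else as.character(x$gene))
  })

  seeds <- vapply(doc$seeds, function(s) resolve(s, "seeds"), character(1))
  ann <- if (is.null(doc$annotations)) character(0) else
    vapply(doc$annotations, as.character, character(1))

  net <- ReactionNetwork(cmp, sp, reactions, seeds, ann)
  .assert_valid(net)
  net
}

## ---- writing ---------------------------------------------------------------

.network_to_list <- function(net) {
  cmp <- net@compartments
  sp <- net@species
  drop_na <- function(x) Filter(function(e) !(length(e) == 1 && is.na(e)), x)
  list(
    compartments = lapply(seq_len(nrow(cmp)), function(i)
      list(id = cmp$id[i], volume = cmp$volume[i], kind = cmp$kind[i])),
    species = lapply(seq_len(nrow(sp)), function(i) drop_na(list(
      id = sp$id[i], name = sp$name[i], role = sp$role[i],
      compartment = sp$compartment[i], initial = sp$initial[i],
      gene = sp$gene[i], proteoform = sp$proteoform[i]))),
    reactions = lapply(net@reactions, function(r) drop_na(list(
      id = r@id, type = r@rateLaw@form,
      substrates = .stoich_to_list(r@substrates),
      products = .stoich_to_list(r@products),
      enzyme = r@enzyme, gene = r@gene,
      params = as.list(r@rateLaw@params)))),
    seeds = as.list(net@seeds),
    annotations = as.list(net@annotations)
  )
}

.stoich_to_list <- function(x)
  lapply(seq_along(x), function(i) list(species = names(x)[i], stoich = x[[i]]))

#' Write a reaction-network document
#'
#' Serializes a valid network to the canonical JSON document format. Output
#' is deterministic: compartments, species, reactions and seeds are emitted
#' in lexicographic id order and numbers at full double precision, so two
#' calls on the same network are byte-identical and `parseNetwork(
#' writeNetwork(net))` reconstructs an equal network. An invalid network is
#' refused with its violation list.
#'
#' @param net a valid [ReactionNetwork-class]
#' @param path optional file path; when given the document is written there.
#' @return the document text, invisibly when `path` is given.
#' @export
writeNetwork <- function(net, path = NULL) {
  .assert_valid(net)
  txt <- .to_json(.network_to_list(net))
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

.to_json <- function(x)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"))

#' Structural equality of two networks
#'
#' Compares the normalized components (compartments, species, reactions with
#' their rate laws, seeds, annotations) of two networks.
#'
#' @param a,b [ReactionNetwork-class] objects
#' @return TRUE iff the two networks are structurally equal
#' @export
networkEquals <- function(a, b) {
  eq_df <- function(x, y) isTRUE(all.equal(x, y, tolerance = 0, check.attributes = FALSE))
  if (!eq_df(a@compartments, b@compartments)) return(FALSE)
  if (!eq_df(a@species, b@species)) return(FALSE)
  if (!identical(a@seeds, b@seeds)) return(FALSE)
  if (!identical(a@annotations, b@annotations)) return(FALSE)
  if (length(a@reactions) != length(b@reactions)) return(FALSE)
  for (i in seq_along(a@reactions)) {
    x <- a@reactions[[i]]; y <- b@reactions[[i]]
    if (!identical(x@id, y@id)) return(FALSE)
    if (!identical(x@substrates, y@substrates)) return(FALSE)
    if (!identical(x@products, y@products)) return(FALSE)
    if (!identical(x@enzyme, y@enzyme)) return(FALSE)
    if (!identical(x@gene, y@gene)) return(FALSE)
    if (!identical(x@rateLaw@form, y@rateLaw@form)) return(FALSE)
    if (!identical(x@rateLaw@params, y@rateLaw@params)) return(FALSE)
  }
  TRUE
}
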