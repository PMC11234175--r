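#' @include synthetic-data.R
NULL

## ---- model / event document IO ---------------------------------------------

#' Write / read an event schedule document
#' @param schedule an [EventSchedule-class]
#' @param path file path (JSON)
#' @return `writeEventSchedule`: the JSON text (invisibly when written);
#'   `readEventSchedule`: an [EventSchedule-class]
#' @export
writeEventSchedule <- function(schedule, path = NULL) {
  evs <- lapply(schedule@events, function(e) {
    pl <- e$payload
    out <- list(time = e$time, kind = e$kind)
    if (!is.null(pl)) {
      out$payload <- if (is.data.frame(pl))
        lapply(seq_len(nrow(pl)), function(i) as.list(pl[i, , drop = FALSE]))
      else as.list(pl)
    }
    out
  })
  txt <- .to_json(list(events = evs))
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname writeEventSchedule
#' @export
readEventSchedule <- function(path) {
  doc <- .read_structured(path)
  evs <- lapply(doc$events, function(e) {
    pl <- e$payload
    if (!is.null(pl)) {
      pl <- if (e$kind == "calcium_translocation")
        do.call(rbind, lapply(pl, function(r)
          data.frame(species = r$species, from = r$from, to = r$to,
                     fraction = as.numeric(r$fraction),
                     k_ret = as.numeric(r$k_ret), stringsAsFactors = FALSE)))
      else list(species = pl$species, compartment = pl$compartment,
                amount = as.numeric(pl$amount))
    }
    list(time = as.numeric(e$time), kind = e$kind, payload = pl)
  })
  EventSchedule(evs)
}

#' Write / read a dynamic-model document
#'
#' The model document is the network document plus `expression_links`
#' (per-link gene, protein, baseline, ks, kd and the spline knots/values of
#' the gene's forcing profile), `constant_proteins` and `events`.
#'
#' @param model a [DynamicModel-class]
#' @param path file path (JSON)
#' @return `writeModelDocument`: JSON text (invisibly when written);
#'   `readModelDocument`: a [DynamicModel-class]
#' @export
writeModelDocument <- function(model, path = NULL) {
  doc <- .network_to_list(model@network)
  lk <- model@links
  doc$expression_links <- lapply(seq_len(nrow(lk)), function(i) list(
    gene = lk$gene[i], compartment = lk$compartment[i],
    protein = lk$protein[i], baseline = lk$baseline[i],
    ks = lk$ks[i], kd = lk$kd[i]))
  doc$profiles <- lapply(model@profiles, function(p)
    list(knots = as.list(p@knots), values = as.list(p@values)))
  doc$constant_proteins <- as.list(model@constantProteins)
  doc$events <- jsonlite::fromJSON(writeEventSchedule(model@events),
                                   simplifyVector = FALSE)$events
  txt <- .to_json(doc)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' @rdname writeModelDocument
#' @export
readModelDocument <- function(path) {
  doc <- .read_structured(path)
  net <- .network_from_list(doc[c("compartments", "species", "reactions",
                                  "seeds", "annotations")])
  profiles <- lapply(doc$profiles, function(p) {
    knots <- vapply(p$knots, as.numeric, numeric(1))
    vals <- vapply(p$values, as.numeric, numeric(1))
    new("ContinuousProfile", knots = knots, values = vals,
        coefs = .natural_spline_coefs(knots, vals))
  })
  links <- if (length(doc$expression_links))
    do.call(rbind, lapply(doc$expression_links, function(l)
      data.frame(gene = l$gene, compartment = l$compartment,
                 protein = l$protein, baseline = as.numeric(l$baseline),
                 ks = as.numeric(l$ks), kd = as.numeric(l$kd),
                 stringsAsFactors = FALSE)))
  else data.frame(gene = character(0), compartment = character(0),
                  protein = character(0), baseline = numeric(0),
                  ks = numeric(0), kd = numeric(0))
  ev <- EventSchedule(lapply(doc$events, function(e) {
    pl <- e$payload
    if (!is.null(pl) && e$kind == "calcium_translocation")
      pl <- do.call(rbind, lapply(pl, function(r)
        data.frame(species = r$species, from = r$from, to = r$to,
                   fraction = as.numeric(r$fraction),
                   k_ret = as.numeric(r$k_ret), stringsAsFactors = FALSE)))
    list(time = as.numeric(e$time), kind = e$kind, payload = pl)
  }))
  new("DynamicModel", network = net, profiles = profiles, links = links,
      constantProteins = vapply(doc$constant_proteins, as.character, character(1)),
      events = ev)
}

## ---- convenience: the bundled worked example -------------------------------

#' Build the worked-example macrophage model
#'
#' End-to-end construction of the flagship model: canonical eicosanoid
#' network, synthetic Lipid A / ATP activation scenario, expression-based
#' pruning, spline forcing profiles, translation/degradation coupling and
#' the default stimulation schedule.
#'
#' @param seed scenario seed
#' @param scenario a [syntheticScenario()]; defaults to
#'   `syntheticScenario(seed)`
#' @param threshold expression cutoff for pruning
#' @param kdDefault default protein degradation rate (per hour)
#' @param events stimulation schedule (default [defaultEventSchedule()])
#' @param net canonical network (default [buildCanonicalNetwork()])
#' @return a [DynamicModel-class]
#' @export
buildExampleModel <- function(seed = 1L, scenario = syntheticScenario(seed),
                              threshold = 0, kdDefault = 2,
                              events = defaultEventSchedule(),
                              net = buildCanonicalNetwork()) {
  expr <- generateMrnaProfiles(scenario)
  pruned <- pruneNetwork(net, expr, threshold)$network
  genes <- intersect(unique(expr$gene_id), speciesTable(pruned)$gene)
  profiles <- lapply(stats::setNames(genes, genes), function(g) {
    sub <- expr[expr$gene_id == g, ]
    interpolateProfile(sub$time_h, sub$value)
  })
  attachExpressionReactions(pruned, profiles, kdDefault = kdDefault,
                            events = events)
}

## ---- comparison metrics ----------------------------------------------------

#' Compare a simulated trajectory to observed measurements
#'
#' Per observed species: root-mean-square error of the simulation
#' (linearly interpolated at the observed times) against the measurements,
#' the RMSE normalized by the observed range, and the Pearson concordance.
#' Agreement is summarized by normalized RMSE; no hypothesis test is
#' involved.
#'
#' @param trajectory data.frame with `time_h` plus `species@compartment`
#'   columns (as written by [writeSimulationResult()])
#' @param observed data.frame (`species`, `time_h`, `value`, optionally
#'   `replicate`)
#' @param compartment compartment of the observed species (default `"Ecs"`)
#' @return data.frame (`species`, `n`, `rmse`, `nrmse`, `concordance`)
#' @export
compareToMeasurements <- function(trajectory, observed, compartment = "Ecs") {
  species <- unique(observed$species)
  rows <- lapply(species, function(s) {
    key <- speciesKey(s, compartment)
    if (!key %in% colnames(trajectory))
      stop(sprintf("trajectory lacks column '%s'", key), call. = FALSE)
    obs <- observed[observed$species == s, , drop = FALSE]
    sim <- stats::approx(trajectory$time_h, trajectory[[key]],
                         xout = obs$time_h, rule = 2)$y
    rmse <- sqrt(mean((sim - obs$value)^2))
    rng <- diff(range(obs$value))
    data.frame(species = s, n = nrow(obs), rmse = rmse,
               nrmse = if (rng > 0) rmse / rng else NA_real_,
               concordance = if (stats::sd(obs$value) > 0 && stats::sd(sim) > 0)
                 stats::cor(sim, obs$value) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- end-to-end orchestration ----------------------------------------------

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

## distribute a per-gene proteomic baseline over that gene's proteoforms,
## preserving the network's relative proteoform proportions
.apply_proteome <- function(net, proteome) {
  sp <- net@species
  for (i in seq_len(nrow(proteome))) {
    g <- proteome$gene_id[i]
    rows <- which(sp$role == "protein" & sp$gene == g)
    if (!length(rows)) next
    tot <- sum(sp$initial[rows])
    if (tot > 0) sp$initial[rows] <- sp$initial[rows] / tot * proteome$value[i]
    else sp$initial[rows[1]] <- proteome$value[i]
  }
  net@species <- sp
  net
}

#' Run the full pipeline
#'
#' Orchestrates parse - prune - expression linking - simulation - code
#' generation and writes all artifacts plus a checksum manifest to the
#' output directory. Any stage error aborts with the stage name, removing
#' partial artifacts. With a fixed configuration the manifest (which carries
#' no timestamps) is byte-identical across runs.
#'
#' @param config list (or path to a JSON/YAML config file) with fields:
#'   `network` (path or [ReactionNetwork-class]; default the bundled
#'   canonical network), `expression` (path or expression table; required),
#'   `proteome` (optional path or data.frame `gene_id`, `value`),
#'   `events` (optional path or [EventSchedule-class]; default
#'   [defaultEventSchedule()]), `threshold` (default 0), `kd` (default 2),
#'   `tEnd` (default 24), `rtol`/`atol` (defaults 1e-8/1e-10), `dialect`
#'   (default `"r"`), `out` (output directory; required).
#' @return the manifest (list), invisibly; also written as `manifest.json`
#' @export
runEndToEnd <- function(config) {
  if (is.character(config)) config <- .read_structured(config)
  if (is.null(config$out)) stop("config lacks 'out' directory", call. = FALSE)
  out <- config$out
  created <- !dir.exists(out)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  on_failure <- function(e) {
    unlink(file.path(out, artifacts))
    stop(e)
  }

  tryCatch({
    net <- .stage("parse", {
      if (is(config$network, "ReactionNetwork")) config$network
      else if (is.null(config$network)) buildCanonicalNetwork()
      else parseNetwork(config$network)
    })
    expr <- .stage("expression", {
      if (is.data.frame(config$expression)) .check_expression_table(config$expression)
      else if (is.null(config$expression)) stop("config lacks 'expression'")
      else readExpressionTable(config$expression)
    })
    if (!is.null(config$proteome)) {
      prot <- if (is.data.frame(config$proteome)) config$proteome else
        utils::read.delim(config$proteome, stringsAsFactors = FALSE)
      net <- .stage("proteome", .apply_proteome(net, prot))
    }
    events <- .stage("events", {
      if (is(config$events, "EventSchedule")) config$events
      else if (is.null(config$events)) defaultEventSchedule()
      else readEventSchedule(config$events)
    })
    threshold <- if (is.null(config$threshold)) 0 else as.numeric(config$threshold)
    kd <- if (is.null(config$kd)) 2 else as.numeric(config$kd)
    tEnd <- if (is.null(config$tEnd)) 24 else as.numeric(config$tEnd)
    rtol <- if (is.null(config$rtol)) 1e-8 else as.numeric(config$rtol)
    atol <- if (is.null(config$atol)) 1e-10 else as.numeric(config$atol)
    dialect <- if (is.null(config$dialect)) "r" else config$dialect

    pr <- .stage("prune", pruneNetwork(net, expr, threshold))
    writeNetwork(pr$network, file.path(out, "pruned_network.json"))
    artifacts <- c(artifacts, "pruned_network.json")
    writePruneReport(pr$report, file.path(out, "prune_report.json"))
    artifacts <- c(artifacts, "prune_report.json")

    model <- .stage("expression_dynamics", {
      genes <- intersect(unique(expr$gene_id), speciesTable(pr$network)$gene)
      profiles <- lapply(stats::setNames(genes, genes), function(g) {
        sub <- expr[expr$gene_id == g, ]
        interpolateProfile(sub$time_h, sub$value)
      })
      attachExpressionReactions(pr$network, profiles, kdDefault = kd,
                                events = events)
    })
    writeModelDocument(model, file.path(out, "model.json"))
    artifacts <- c(artifacts, "model.json")

    result <- .stage("simulate",
                     simulateModel(model, tEnd = tEnd, rtol = rtol, atol = atol))
    writeSimulationResult(result, file.path(out, "trajectory.tsv"))
    artifacts <- c(artifacts, "trajectory.tsv")

    if (!identical(dialect, FALSE) && !is.null(dialect)) {
      prog <- .stage("codegen", emitScript(model, dialect, tEnd = tEnd,
                                           rtol = rtol, atol = atol))
      ext <- c(r = ".R", matlab = ".m", python = ".py")[dialect]
      if (is.na(ext)) ext <- ".txt"
      fn <- paste0("model_", dialect, ext)
      writeLines(prog@source, file.path(out, fn))
      artifacts <- c(artifacts, fn)
    }

    cfg_echo <- config
    cfg_echo$network <- if (is.character(config$network)) config$network else "<in-memory>"
    cfg_echo$expression <- if (is.character(config$expression)) config$expression else "<in-memory>"
    cfg_echo$events <- if (is.character(config$events)) config$events else
      if (is.null(config$events)) "<default>" else "<in-memory>"
    if (!is.null(config$proteome) && !is.character(config$proteome))
      cfg_echo$proteome <- "<in-memory>"
    manifest <- list(
      artifacts = lapply(artifacts, function(a) list(
        name = a,
        md5 = unname(tools::md5sum(file.path(out, a))))),
      config = cfg_echo[order(names(cfg_echo))])
    writeLines(.to_json(manifest), file.path(out, "manifest.json"))
    invisible(manifest)
  }, error = on_failure)
}
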