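#' @include canonical-eicosanoid.R
NULL

.default_induction <- function(genes) {
  ## stimulus-induced logistic induction settings per gene: baseline b, fold
  ## change F, onset tOn (h), rise time tau (h). PTGS2 is the strongly
  ## LPS-inducible enzyme; most housekeeping-like genes barely move.
  preset <- list(
    PLA2G4A = c(1.0, 1.8, 0.5, 1.5), PTGS2 = c(0.3, 12, 0.5, 1.0),
    PTGS1 = c(1.0, 1.1, 1, 2), PTGDS = c(0.8, 2.0, 1, 2),
    TBXAS1 = c(1.0, 1.5, 1, 2), PTGES = c(0.8, 3.0, 1, 1.5))
  rows <- lapply(genes, function(g) {
    p <- if (g %in% names(preset)) preset[[g]] else c(1, 1.2, 1, 2)
    data.frame(gene = g, baseline = p[1], fold = p[2], t_on = p[3],
               tau = p[4], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Define a synthetic macrophage-activation scenario
#'
#' Bundles everything the synthetic-omics generators need: the gene set with
#' per-gene logistic induction parameters (emulating Lipid A-driven mRNA
#' induction on the hours scale), sampling times, replicate count,
#' lognormal noise levels and the lipidomics sampling design. Identical
#' seeds give byte-identical tables.
#'
#' @param seed integer RNG seed
#' @param genes gene ids (default: the canonical eicosanoid genes)
#' @param induction data.frame (`gene`, `baseline`, `fold`, `t_on`, `tau`);
#'   default settings emulate Lipid A induction (PTGS2 strongly induced).
#' @param times mRNA sampling times (hours)
#' @param replicates replicates per time point (>= 3, matching the n >= 3
#'   of the emulated experiments)
#' @param cvMrna lognormal coefficient of variation of mRNA replicates
#' @param cvLipid lognormal coefficient of variation of lipid measurements
#' @param lipidTimes lipidomics sampling times (hours)
#' @param lipidSpecies secreted species measured in the culture medium
#' @return a list of class `SyntheticScenario`
#' @export
syntheticScenario <- function(seed = 1L, genes = canonicalGenes(),
                              induction = .default_induction(genes),
                              times = c(0, 0.5, 1, 2, 4, 6, 8, 12, 24),
                              replicates = 3L, cvMrna = 0.2, cvLipid = 0.1,
                              lipidTimes = c(0, 2, 4, 4.5, 5, 6, 8, 12, 16, 24),
                              lipidSpecies = c("PGD2", "TXB2")) {
  stopifnot(length(times) >= 2, replicates >= 1, cvMrna >= 0, cvLipid >= 0,
            all(induction$baseline >= 0), all(induction$fold >= 0),
            all(induction$tau > 0))
  structure(list(seed = as.integer(seed), genes = genes, induction = induction,
                 times = sort(times), replicates = as.integer(replicates),
                 cvMrna = cvMrna, cvLipid = cvLipid,
                 lipidTimes = sort(lipidTimes), lipidSpecies = lipidSpecies),
            class = "SyntheticScenario")
}

#' Logistic stimulus-induction curve
#'
#' `m(t) = b * (1 + (F - 1) / (1 + exp(-(t - t_on - 2 tau) / tau)))`: a
#' baseline-anchored sigmoid rising from about `b` to `b * F` with onset
#' `t_on` and rise time `tau`.
#'
#' @param t times (hours)
#' @param baseline b, baseline expression
#' @param fold F, fold change
#' @param t_on onset time (hours)
#' @param tau rise time (hours)
#' @return expression values at `t`
#' @export
inductionCurve <- function(t, baseline, fold, t_on, tau)
  baseline * (1 + (fold - 1) / (1 + exp(-(t - t_on - 2 * tau) / tau)))

## mean-one lognormal multipliers with coefficient of variation cv
.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic mRNA expression table
#'
#' Noisy replicated logistic induction time courses for every gene of the
#' scenario, in the standard expression-table layout. Deterministic given
#' the scenario seed.
#'
#' @param scenario a [syntheticScenario()]
#' @return data.frame (`gene_id`, `time_h`, `value`, `replicate`)
#' @export
generateMrnaProfiles <- function(scenario) {
  stopifnot(inherits(scenario, "SyntheticScenario"), scenario$replicates >= 3)
  ind <- scenario$induction
  withr::with_seed(scenario$seed, {
    rows <- lapply(seq_len(nrow(ind)), function(i) {
      m <- inductionCurve(scenario$times, ind$baseline[i], ind$fold[i],
                          ind$t_on[i], ind$tau[i])
      reps <- lapply(seq_len(scenario$replicates), function(r)
        data.frame(gene_id = ind$gene[i], time_h = scenario$times,
                   value = m * .lognormal_noise(length(m), scenario$cvMrna),
                   replicate = r, stringsAsFactors = FALSE))
      do.call(rbind, reps)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic proteomic baseline snapshot
#'
#' Baseline (unstimulated) protein concentrations per gene, drawn from the
#' canonical network's cytosolic-plus-membrane proteoform initials with
#' optional lognormal noise.
#'
#' @param scenario a [syntheticScenario()]
#' @param net network providing baseline protein levels (default: the
#'   canonical eicosanoid network)
#' @param cv lognormal CV of the snapshot (default 0: exact baseline)
#' @return data.frame (`gene_id`, `value`) in uM (per-gene total)
#' @export
generateProteomeBaseline <- function(scenario, net = buildCanonicalNetwork(),
                                     cv = 0) {
  sp <- speciesTable(net)
  sp <- sp[sp$role == "protein", , drop = FALSE]
  tot <- tapply(sp$initial, sp$gene, sum)
  withr::with_seed(scenario$seed + 20011L, {
    data.frame(gene_id = names(tot),
               value = as.numeric(tot) * .lognormal_noise(length(tot), cv),
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic extracellular lipidomics measurements
#'
#' Forward-simulates the model, samples the secreted observables at the
#' scenario's lipidomics times and applies mean-one lognormal measurement
#' noise. The noise-free ground truth is returned alongside.
#'
#' @param model a simulable [DynamicModel-class]
#' @param scenario a [syntheticScenario()]
#' @param compartment compartment sampled (default `"Ecs"`, the culture
#'   medium)
#' @return list with `observed` (data.frame `species`, `time_h`, `value`,
#'   `replicate`) and `truth` (data.frame `species`, `time_h`, `value`)
#' @export
generateLipidomics <- function(model, scenario, compartment = "Ecs") {
  tEnd <- max(scenario$lipidTimes)
  res <- simulateModel(model, tEnd = tEnd,
                       grid = sort(unique(c(0, scenario$lipidTimes))))
  truth <- do.call(rbind, lapply(scenario$lipidSpecies, function(s) {
    obs <- extractObservable(res, s, compartment)
    obs <- obs[obs$time_h %in% scenario$lipidTimes, , drop = FALSE]
    data.frame(species = s, time_h = obs$time_h, value = obs$value,
               stringsAsFactors = FALSE)
  }))
  observed <- withr::with_seed(scenario$seed + 40009L, {
    do.call(rbind, lapply(seq_len(scenario$replicates), function(r)
      data.frame(species = truth$species, time_h = truth$time_h,
                 value = truth$value * .lognormal_noise(nrow(truth), scenario$cvLipid),
                 replicate = r, stringsAsFactors = FALSE)))
  })
  rownames(truth) <- rownames(observed) <- NULL
  list(observed = observed, truth = truth)
}

#' Recover kinetic parameters from observed lipidomics
#'
#' Bounded least-squares fit of log-parameters to log-observations:
#' free parameters (at most 5, named `"reaction_id:parameter"`) are
#' optimized by Nelder-Mead on the log scale from a small deterministic set
#' of starts spread over the log-bound range, minimizing the sum of squared
#' `log(pred + eps) - log(obs + eps)` residuals over all observed rows.
#' Non-convergence from every start is flagged in the result, not thrown.
#'
#' @param model the [DynamicModel-class] whose parameters are fitted
#' @param observed data.frame (`species`, `time_h`, `value`, `replicate`)
#'   of extracellular measurements
#' @param freeParams character, `"reaction_id:parameter"` ids (length 0-5)
#' @param bounds list with numeric vectors `lower` and `upper` (same order
#'   as `freeParams`), finite and positive
#' @param nStarts number of deterministic starts (1-3)
#' @param eps additive floor inside the logs (uM)
#' @param compartment observed compartment (default `"Ecs"`)
#' @param control passed to [stats::optim()]
#' @return list: `estimates` (named), `residual` (best objective),
#'   `converged`, `residuals0` (objective at the unmodified model),
#'   `starts` (per-start summaries)
#' @export
recoverParameters <- function(model, observed, freeParams, bounds,
                              nStarts = 3, eps = 1e-6, compartment = "Ecs",
                              control = list(maxit = 400, reltol = 1e-10)) {
  k <- length(freeParams)
  if (k > 5) stop("at most 5 free parameters are supported", call. = FALSE)
  tgrid <- sort(unique(c(0, observed$time_h)))
  species <- unique(observed$species)

  predict_rows <- function(m) {
    res <- simulateModel(m, tEnd = max(tgrid), grid = tgrid)
    pred <- lapply(species, function(s) {
      o <- extractObservable(res, s, compartment)
      stats::setNames(o$value, as.character(o$time_h))
    })
    names(pred) <- species
    vapply(seq_len(nrow(observed)), function(i)
      pred[[observed$species[i]]][[as.character(observed$time_h[i])]],
      numeric(1))
  }

  objective <- function(logtheta) {
    m <- applyParameters(model, overrides = stats::setNames(exp(logtheta), freeParams))
    p <- tryCatch(predict_rows(m), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    sum((log(p + eps) - log(observed$value + eps))^2)
  }

  resid0 <- {
    p0 <- predict_rows(model)
    sum((log(p0 + eps) - log(observed$value + eps))^2)
  }
  if (k == 0)
    return(list(estimates = stats::setNames(numeric(0), character(0)),
                residual = resid0, residuals0 = resid0, converged = TRUE,
                starts = list()))

  lo <- log(bounds$lower); hi <- log(bounds$upper)
  stopifnot(length(lo) == k, length(hi) == k, all(is.finite(c(lo, hi))),
            all(hi >= lo))
  start_frac <- list(rep(0.5, k), rep(0.2, k), rep(0.8, k))[seq_len(min(nStarts, 3))]
  starts <- lapply(start_frac, function(f) lo + f * (hi - lo))

  fits <- if (k == 1) {
    ## one-dimensional: bounded Brent search, a single start suffices
    fit <- stats::optim(starts[[1]], objective, method = "Brent",
                        lower = lo, upper = hi,
                        control = control[setdiff(names(control), "reltol")])
    list(list(par = fit$par, value = fit$value, convergence = fit$convergence))
  } else lapply(starts, function(s0) {
    fit <- stats::optim(s0, function(lt) {
      if (any(lt < lo - 1e-9) || any(lt > hi + 1e-9)) return(1e10)
      objective(lt)
    }, method = "Nelder-Mead", control = control)
    list(par = fit$par, value = fit$value, convergence = fit$convergence)
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  list(estimates = stats::setNames(exp(best$par), freeParams),
       residual = best$value,
       residuals0 = resid0,
       converged = any(vapply(fits, function(f) f$convergence == 0, logical(1))),
       starts = fits)
}

## ---- random valid networks (for property tests) ----------------------------

#' Generate a random valid reaction network
#'
#' Small random networks (metabolite chains/branches, Michaelis-Menten and
#' mass-action steps, cross-compartment transports, protein enzymes) used by
#' the round-trip and pruning property tests. Construction guarantees
#' validity; the result is checked before returning. Deterministic given the
#' seed.
#'
#' @param seed integer seed
#' @param nMetabolites number of metabolite species (>= 3)
#' @param nReactions target number of reactions
#' @param nCompartments 1 or 2
#' @return a valid [ReactionNetwork-class]
#' @export
generateRandomNetwork <- function(seed, nMetabolites = 8, nReactions = 10,
                                  nCompartments = 2) {
  withr::with_seed(as.integer(seed), {
    cids <- paste0("C", seq_len(nCompartments))
    cmp <- data.frame(id = cids,
                      volume = round(stats::runif(nCompartments, 0.5, 2), 3),
                      kind = "aqueous", stringsAsFactors = FALSE)
    nm <- max(3L, as.integer(nMetabolites))
    mids <- paste0("M", seq_len(nm))
    mcmp <- sample(cids, nm, replace = TRUE)
    nEnz <- sample(2:4, 1)
    eids <- paste0("E", seq_len(nEnz))
    ecmp <- sample(cids, nEnz, replace = TRUE)

    species <- data.frame(
      id = c(mids, eids), name = c(mids, eids),
      role = c(rep("metabolite", nm), rep("protein", nEnz)),
      compartment = c(mcmp, ecmp),
      initial = round(stats::runif(nm + nEnz, 0, 10), 4),
      gene = c(rep(NA_character_, nm), paste0("G", seq_len(nEnz))),
      proteoform = NA_character_, stringsAsFactors = FALSE)

    mkeys <- speciesKey(mids, mcmp)
    ekeys <- speciesKey(eids, ecmp)
    rxns <- list()
    for (j in seq_len(max(2L, as.integer(nReactions)))) {
      type <- sample(c("michaelis_menten", "mass_action", "transport"), 1,
                     prob = c(0.5, 0.3, 0.2))
      id <- sprintf("r%02d", j)
      if (type == "transport" && nCompartments > 1) {
        mi <- sample(seq_len(nm), 1)
        other <- setdiff(cids, mcmp[mi])[1]
        otherk <- speciesKey(mids[mi], other)
        if (!otherk %in% speciesKey(species$id, species$compartment)) {
          species <- rbind(species, data.frame(
            id = mids[mi], name = mids[mi], role = "metabolite",
            compartment = other, initial = 0, gene = NA_character_,
            proteoform = NA_character_, stringsAsFactors = FALSE))
        }
        rxns[[j]] <- Reaction(id,
          substrates = stats::setNames(1, mkeys[mi]),
          products = stats::setNames(1, otherk),
          rateLaw = RateLaw("transport_first_order",
                            k = round(stats::runif(1, 0.1, 5), 3)))
      } else if (type == "michaelis_menten") {
        sm <- sample(seq_len(nm), 2)
        rxns[[j]] <- Reaction(id,
          substrates = stats::setNames(1, mkeys[sm[1]]),
          products = stats::setNames(1, mkeys[sm[2]]),
          rateLaw = RateLaw("michaelis_menten",
                            kcat = round(stats::runif(1, 1, 100), 3),
                            Km = round(stats::runif(1, 0.5, 20), 3)),
          enzyme = ekeys[sample(nEnz, 1)])
      } else {
        sm <- sample(seq_len(nm), 2)
        rxns[[j]] <- Reaction(id,
          substrates = stats::setNames(1, mkeys[sm[1]]),
          products = stats::setNames(1, mkeys[sm[2]]),
          rateLaw = RateLaw("mass_action",
                            k = round(stats::runif(1, 0.05, 5), 3)))
      }
    }
    rxns <- Filter(Negate(is.null), rxns)
    seeds <- sample(mkeys, sample(1:2, 1))
    net <- ReactionNetwork(cmp, species, rxns, seeds = unique(seeds),
                           annotations = sprintf("random network (seed %d)", seed))
    .assert_valid(net, "randomly generated network")
    net
  })
}
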