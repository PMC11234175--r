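# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-implement semantics with different algorithms
# than the package (queue-based closure, term-by-term derivative summation,
# stats::splinefun natural splines) so agreement is informative.

# queue-based breadth-first substrate-flow closure over metabolites
oracle_closure <- function(net, seeds = seedMetabolites(net)) {
  sp <- speciesTable(net)
  keys <- speciesKey(sp$id, sp$compartment)
  role <- stats::setNames(sp$role, keys)
  have <- seeds
  queue <- seeds
  rxns <- reactions(net)
  fired <- rep(FALSE, length(rxns))
  while (length(queue)) {
    queue <- character(0)
    for (j in seq_along(rxns)) {
      if (fired[j]) next
      r <- rxns[[j]]
      if (!is.na(r@enzyme) && !(r@enzyme %in% keys)) next
      subs <- names(r@substrates)
      met_subs <- subs[role[subs] == "metabolite"]
      if (!all(met_subs %in% have)) next
      fired[j] <- TRUE
      prods <- names(r@products)
      new_ones <- setdiff(prods[role[prods] == "metabolite"], have)
      have <- c(have, new_ones)
      queue <- c(queue, new_ones)
    }
  }
  sort(have)
}

# delete-then-closure-filter pruning oracle; returns surviving reaction ids
# and species keys
oracle_prune <- function(net, expr, threshold = 0) {
  t0 <- min(expr$time_h)
  base <- expr[expr$time_h == t0, ]
  means <- tapply(base$value, base$gene_id, mean)
  expressed <- names(means)[means > threshold]

  sp <- speciesTable(net)
  keys <- speciesKey(sp$id, sp$compartment)
  bad_prot <- keys[sp$role == "protein" & !(sp$gene %in% expressed)]
  rxns <- reactions(net)
  keep <- Filter(function(r) {
    if (r@rateLaw@form == "michaelis_menten" && r@enzyme %in% bad_prot)
      return(FALSE)
    !any(c(names(r@substrates), names(r@products)) %in% bad_prot)
  }, rxns)

  net2 <- net
  net2@reactions <- keep
  net2@species <- sp[!(keys %in% bad_prot), , drop = FALSE]
  closure <- oracle_closure(net2)
  role2 <- stats::setNames(net2@species$role,
                           speciesKey(net2@species$id, net2@species$compartment))
  keep2 <- Filter(function(r) {
    ms <- names(r@substrates)[role2[names(r@substrates)] == "metabolite"]
    all(ms %in% closure)
  }, keep)

  used <- unique(unlist(lapply(keep2, function(r)
    c(names(r@substrates), names(r@products),
      if (!is.na(r@enzyme)) r@enzyme))))
  k2 <- speciesKey(net2@species$id, net2@species$compartment)
  surviving <- k2[net2@species$role == "protein" | k2 %in% used |
                    k2 %in% seedMetabolites(net)]
  list(reactions = sort(vapply(keep2, function(r) r@id, character(1))),
       species = sort(unique(surviving)))
}

# term-by-term derivative summation, straight from the rate-law definitions
oracle_rhs <- function(model, t, y) {
  net <- modelNetwork(model)
  sp <- speciesTable(net)
  sp <- sp[sp$role != "mRNA", , drop = FALSE]
  keys <- speciesKey(sp$id, sp$compartment)
  cvol <- stats::setNames(compartments(net)$volume, compartments(net)$id)
  vol <- stats::setNames(unname(cvol[sp$compartment]), keys)
  d <- stats::setNames(numeric(length(keys)), keys)
  for (r in reactions(net)) {
    p <- r@rateLaw@params
    v <- switch(r@rateLaw@form,
      michaelis_menten = {
        S <- y[[names(r@substrates)[1]]]
        if (S == 0) 0 else p[["kcat"]] * y[[r@enzyme]] * S / (p[["Km"]] + S)
      },
      mass_action = p[["k"]] * prod(y[names(r@substrates)]^unname(r@substrates)),
      transport_first_order = p[["k"]] * y[[names(r@substrates)[1]]],
      degradation_first_order = p[["k"]] * y[[names(r@substrates)[1]]],
      translation = p[["ks"]] *
        evaluateProfile(modelProfiles(model)[[r@gene]], t))
    refk <- if (length(r@substrates)) names(r@substrates)[1] else names(r@products)[1]
    for (k in names(r@substrates))
      d[[k]] <- d[[k]] - r@substrates[[k]] * v * vol[[refk]] / vol[[k]]
    for (k in names(r@products))
      d[[k]] <- d[[k]] + r@products[[k]] * v * vol[[refk]] / vol[[k]]
  }
  d
}

# flat baseline table covering every gene of a network, optionally zeroing some
make_expr_all <- function(net, value = 5, zero = character(0), replicates = 3) {
  genes <- sort(unique(stats::na.omit(speciesTable(net)$gene)))
  do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g, time_h = 0,
               value = rep(if (g %in% zero) 0 else value, replicates),
               replicate = seq_len(replicates), stringsAsFactors = FALSE)))
}

# random baseline expression table over a network's genes; about pZero of the
# genes are silenced (all-zero baseline)
random_expression <- function(net, seed, pZero = 0.4, replicates = 3) {
  genes <- sort(unique(stats::na.omit(speciesTable(net)$gene)))
  withr::with_seed(seed, {
    silenced <- genes[stats::runif(length(genes)) < pZero]
    rows <- lapply(genes, function(g) {
      base <- if (g %in% silenced) 0 else stats::runif(1, 0.5, 10)
      data.frame(gene_id = g, time_h = 0,
                 value = base * (if (base > 0) stats::runif(replicates, 0.8, 1.2) else rep(0, replicates)),
                 replicate = seq_len(replicates), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# single-compartment network with one first-order decay reaction P -> (sink)
decay_network <- function(k = 1, P0 = 1) {
  ReactionNetwork(
    compartments = data.frame(id = "Cyt", volume = 1, kind = "aqueous"),
    species = data.frame(id = c("P", "X"), name = c("P", "X"),
                         role = "metabolite", compartment = "Cyt",
                         initial = c(P0, 0), gene = NA_character_,
                         proteoform = NA_character_),
    reactions = list(Reaction("r_decay",
                              substrates = c("P@Cyt" = 1),
                              products = c("X@Cyt" = 1),
                              rateLaw = RateLaw("degradation_first_order", k = k))),
    seeds = "P@Cyt")
}

as_model <- function(net, profiles = list(), events = EventSchedule()) {
  attachExpressionReactions(net, profiles, events = events)
}

# one Michaelis-Menten step S -> P with a constant enzyme
single_mm_network <- function(kcat = 1, Km = 2, E0 = 1, S0 = 10) {
  ReactionNetwork(
    compartments = data.frame(id = "Cyt", volume = 1, kind = "aqueous"),
    species = data.frame(
      id = c("S", "P", "Enz"), name = c("S", "P", "Enz"),
      role = c("metabolite", "metabolite", "protein"),
      compartment = "Cyt", initial = c(S0, 0, E0),
      gene = c(NA, NA, "GENZ"), proteoform = NA_character_),
    reactions = list(Reaction("r_mm", substrates = c("S@Cyt" = 1),
                              products = c("P@Cyt" = 1),
                              rateLaw = RateLaw("michaelis_menten",
                                                kcat = kcat, Km = Km),
                              enzyme = "Enz@Cyt")),
    seeds = "S@Cyt")
}

# linear three-metabolite chain seed -> B -> C, each step enzymatic
chain_network <- function(drop_first_enzyme = FALSE) {
  sp <- data.frame(
    id = c("Seed", "B", "C", "E1", "E2"),
    name = c("Seed", "B", "C", "E1", "E2"),
    role = c("metabolite", "metabolite", "metabolite", "protein", "protein"),
    compartment = "Cyt", initial = c(10, 0, 0, 1, 1),
    gene = c(NA, NA, NA, "G1", "G2"), proteoform = NA_character_,
    stringsAsFactors = FALSE)
  if (drop_first_enzyme) sp <- sp[sp$id != "E1", ]
  rxns <- list(
    if (!drop_first_enzyme)
      Reaction("r1", substrates = c("Seed@Cyt" = 1), products = c("B@Cyt" = 1),
               rateLaw = RateLaw("michaelis_menten", kcat = 10, Km = 1),
               enzyme = "E1@Cyt"),
    Reaction("r2", substrates = c("B@Cyt" = 1), products = c("C@Cyt" = 1),
             rateLaw = RateLaw("michaelis_menten", kcat = 10, Km = 1),
             enzyme = "E2@Cyt"))
  rxns <- Filter(Negate(is.null), rxns)
  ReactionNetwork(
    compartments = data.frame(id = "Cyt", volume = 1, kind = "aqueous"),
    species = sp, reactions = rxns, seeds = "Seed@Cyt")
}

# protein tracking of a pulse-shaped mRNA profile under a given turnover rate;
# the forcing enters through the attached translation/degradation reactions
tracking_deviation <- function(kd) {
  tt <- seq(0, 12, 0.5)
  pulse <- 1 + 4 * exp(-(tt - 6)^2 / 4)
  net <- single_mm_network(S0 = 0, E0 = 1)   # no substrate flux; isolate P(t)
  prof <- list(GENZ = interpolateProfile(tt, pulse))
  m <- attachExpressionReactions(net, prof, kdDefault = kd)
  res <- simulateModel(m, 12, grid = seq(0, 12, 0.02))
  P <- extractObservable(res, "Enz", "Cyt")$value
  mt <- evaluateProfile(prof$GENZ, resultTime(res))
  list(dev = max(abs(P / max(P) - mt / max(mt))),
       lag = resultTime(res)[which.max(P)] - resultTime(res)[which.max(mt)])
}

# random small closed dynamic model (no events, no forcing) for RHS and
# codegen round-trip checks
random_toy_model <- function(seed) {
  net <- generateRandomNetwork(seed, nMetabolites = 5, nReactions = 6)
  as_model(net)
}
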