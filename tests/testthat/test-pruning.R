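make_expr <- function(...) {
  vals <- list(...)
  do.call(rbind, lapply(names(vals), function(g)
    data.frame(gene_id = g, time_h = 0, value = vals[[g]],
               replicate = seq_along(vals[[g]]), stringsAsFactors = FALSE)))
}

test_that("expressedGenes gates on the baseline replicate mean", {
  expect_equal(expressedGenes(make_expr(A = c(5, 5, 5))), "A")
  expect_equal(expressedGenes(make_expr(A = c(0, 0, 0))), character(0))
  # only the earliest time is the baseline
  expr <- rbind(make_expr(A = c(0, 0)),
                data.frame(gene_id = "A", time_h = 4, value = c(9, 9),
                           replicate = 1:2))
  expect_equal(expressedGenes(expr), character(0))
  expect_error(expressedGenes(make_expr(A = 1)[0, ]), "empty")
})

test_that("a median threshold keeps exactly the genes above the median", {
  withr::with_seed(42, {
    genes <- sprintf("g%02d", 1:20)
    means <- runif(20, 0, 10)
    expr <- do.call(rbind, lapply(seq_along(genes), function(i)
      data.frame(gene_id = genes[i], time_h = 0,
                 value = means[i] * runif(3, 0.9, 1.1), replicate = 1:3)))
    # brute-force recomputation of replicate means
    bf <- vapply(genes, function(g)
      mean(expr$value[expr$gene_id == g]), numeric(1))
    thr <- median(bf)
    expect_setequal(expressedGenes(expr, thr), genes[bf > thr])
  })
})

test_that("substrate-flow closure walks an intact chain and stops at a break", {
  expect_equal(producibleMetabolites(chain_network()),
               c("B@Cyt", "C@Cyt", "Seed@Cyt"))
  expect_equal(producibleMetabolites(chain_network(drop_first_enzyme = TRUE)),
               "Seed@Cyt")
  expect_error(producibleMetabolites(chain_network(), seeds = "Zz@Cyt"),
               "unknown seed")
})

test_that("closure equals the brute-force breadth-first oracle on random networks", {
  for (seed in 1:100) {
    net <- generateRandomNetwork(seed, nMetabolites = sample(3:10, 1),
                                 nReactions = sample(3:12, 1))
    expect_identical(producibleMetabolites(net), oracle_closure(net),
                     info = sprintf("seed %d", seed))
  }
})

test_that("pruning with everything expressed is the identity", {
  net <- buildCanonicalNetwork()
  expr <- make_expr_all(net, value = 5)
  pr <- pruneNetwork(net, expr)
  expect_true(networkEquals(pr$network, net))
  expect_equal(nrow(pr$report$removed_reactions), 0)
  expect_length(pr$report$removed_enzymes, 0)
})

test_that("silencing the PGD2 synthase removes only its branch", {
  net <- buildCanonicalNetwork()
  expr <- make_expr_all(net, value = 5, zero = "PTGDS")
  pr <- pruneNetwork(net, expr)
  ids <- vapply(reactions(pr$network), function(r) r@id, character(1))
  expect_false("r_pgd_synthase" %in% ids)
  expect_false("r_secr_pgd2" %in% ids)            # PGD2 became unproducible
  expect_true(all(c("r_tx_synthase", "r_txa2_hydrolysis", "r_secr_txb2") %in% ids))
  keys <- speciesKey(speciesTable(pr$network)$id, speciesTable(pr$network)$compartment)
  expect_false(any(c("PGD2@Cyt", "PGD2@Ecs", "PTGDS@ERMem") %in% keys))
  expect_true("TXB2@Ecs" %in% keys)
  expect_equal(pr$report$removed_enzymes, "PTGDS")
  expect_setequal(
    pr$report$removed_reactions$reason[pr$report$removed_reactions$id == "r_pgd_synthase"],
    "enzyme_unexpressed")
  expect_setequal(
    pr$report$removed_reactions$reason[pr$report$removed_reactions$id == "r_secr_pgd2"],
    "substrate_unproducible")
})

test_that("pruning matches the delete-and-closure oracle on random instances", {
  for (seed in 1:120) {
    net <- generateRandomNetwork(seed, nMetabolites = sample(4:10, 1),
                                 nReactions = sample(4:12, 1))
    expr <- random_expression(net, seed + 1000)
    got <- suppressWarnings(pruneNetwork(net, expr))
    want <- oracle_prune(net, expr)
    ids <- sort(vapply(reactions(got$network), function(r) r@id, character(1)))
    keys <- sort(speciesKey(speciesTable(got$network)$id,
                            speciesTable(got$network)$compartment))
    expect_identical(ids, want$reactions, info = sprintf("seed %d", seed))
    expect_identical(keys, want$species, info = sprintf("seed %d", seed))
  }
})

test_that("pruning is idempotent and leaves no unproducible substrates", {
  for (seed in c(3, 17, 55)) {
    net <- generateRandomNetwork(seed)
    expr <- random_expression(net, seed)
    p1 <- suppressWarnings(pruneNetwork(net, expr))
    p2 <- suppressWarnings(pruneNetwork(p1$network, expr))
    expect_true(networkEquals(p1$network, p2$network))
    expect_equal(nrow(p2$report$removed_reactions), 0)

    if (length(reactions(p1$network))) {
      closure <- producibleMetabolites(p1$network)
      sp <- speciesTable(p1$network)
      role <- stats::setNames(sp$role, speciesKey(sp$id, sp$compartment))
      for (r in reactions(p1$network)) {
        ms <- names(r@substrates)[role[names(r@substrates)] == "metabolite"]
        expect_true(all(ms %in% closure))
      }
    }
  }
})

test_that("enlarging the expressed set never removes a surviving reaction", {
  for (seed in c(5, 23, 71)) {
    net <- generateRandomNetwork(seed)
    expr_small <- random_expression(net, seed, pZero = 0.6)
    expr_big <- expr_small
    expr_big$value[expr_big$value == 0] <- 3   # silence lifted
    ids_small <- vapply(reactions(suppressWarnings(pruneNetwork(net, expr_small))$network),
                        function(r) r@id, character(1))
    ids_big <- vapply(reactions(suppressWarnings(pruneNetwork(net, expr_big))$network),
                      function(r) r@id, character(1))
    expect_true(all(ids_small %in% ids_big), info = sprintf("seed %d", seed))
  }
})

test_that("a fully silenced table yields a warning and an empty model", {
  net <- chain_network()
  expr <- make_expr(G1 = c(0, 0), G2 = c(0, 0))
  expect_warning(pr <- pruneNetwork(net, expr), "empty")
  expect_length(reactions(pr$network), 0)
})
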