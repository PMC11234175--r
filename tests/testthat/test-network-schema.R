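test_that("a minimal document parses to a one-reaction network", {
  doc <- '{
    "compartments": [{"id": "Cyt", "volume": 1, "kind": "aqueous"}],
    "species": [
      {"id": "A", "role": "metabolite", "compartment": "Cyt", "initial": 1},
      {"id": "B", "role": "metabolite", "compartment": "Cyt", "initial": 0}
    ],
    "reactions": [{"id": "r1", "type": "mass_action",
                   "substrates": [{"species": "A", "stoich": 1}],
                   "products": [{"species": "B", "stoich": 1}],
                   "params": {"k": 0.5}}],
    "seeds": ["A"]
  }'
  net <- parseNetwork(doc)
  expect_s4_class(net, "ReactionNetwork")
  expect_length(reactions(net), 1)
  expect_equal(seedMetabolites(net), "A@Cyt")
  expect_equal(nrow(validateNetwork(net)), 0)
})

test_that("undeclared species references are rejected by name", {
  doc <- '{
    "compartments": [{"id": "Cyt", "volume": 1, "kind": "aqueous"}],
    "species": [{"id": "A", "role": "metabolite", "compartment": "Cyt"}],
    "reactions": [{"id": "r1", "type": "mass_action",
                   "substrates": [{"species": "A"}],
                   "products": [{"species": "X"}],
                   "params": {"k": 1}}],
    "seeds": ["A"]
  }'
  expect_error(parseNetwork(doc), "'X'")
})

test_that("missing schema keys name the offending element", {
  expect_error(parseNetwork('{"species": [], "seeds": []}'), "compartments")
  doc <- '{
    "compartments": [{"id": "Cyt", "volume": 1}],
    "species": [], "seeds": []
  }'
  expect_error(parseNetwork(doc), "kind.*Cyt|Cyt")
})

test_that("parse-write round trip is the identity on random valid networks", {
  for (seed in 1:50) {
    net <- generateRandomNetwork(seed)
    txt <- writeNetwork(net)
    expect_true(networkEquals(net, parseNetwork(txt)),
                info = sprintf("seed %d", seed))
  }
})

test_that("serialization is deterministic, byte for byte", {
  net <- generateRandomNetwork(7)
  expect_identical(writeNetwork(net), writeNetwork(net))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writeNetwork(net, f1); writeNetwork(net, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("YAML documents are also accepted", {
  net <- chain_network()
  js <- writeNetwork(net)
  ym <- yaml::as.yaml(jsonlite::fromJSON(js, simplifyVector = FALSE))
  expect_true(networkEquals(net, parseNetwork(ym)))
})

test_that("validateNetwork reports exactly the broken invariant", {
  base <- chain_network()
  expect_equal(nrow(validateNetwork(base)), 0)

  mutate <- function(net, fn) { fn(net); net }

  # MM reaction without an enzyme
  net <- base
  net@reactions[[1]]@enzyme <- NA_character_
  v <- validateNetwork(net)
  expect_true("mm_enzyme_required" %in% v$rule)
  expect_true(any(grepl("r1", v$message)))

  # negative Km names the reaction
  net <- base
  net@reactions[[2]]@rateLaw@params[["Km"]] <- -1
  v <- validateNetwork(net)
  expect_identical(v$rule, "rate_law_nonnegative")
  expect_identical(v$element, "r2")

  # negative initial concentration
  net <- base
  net@species$initial[1] <- -0.5
  expect_true("species_initial_nonnegative" %in% validateNetwork(net)$rule)

  # duplicated compartment id
  net <- base
  net@compartments <- rbind(net@compartments, net@compartments)
  expect_true("compartment_id_unique" %in% validateNetwork(net)$rule)

  # non-positive volume
  net <- base
  net@compartments$volume[1] <- 0
  expect_true("compartment_volume_positive" %in% validateNetwork(net)$rule)

  # metabolite carrying a gene id / protein lacking one
  net <- base
  net@species$gene[net@species$id == "B"] <- "GX"
  expect_true("species_gene_forbidden" %in% validateNetwork(net)$rule)
  net <- base
  net@species$gene[net@species$id == "E1"] <- NA_character_
  v <- validateNetwork(net)
  expect_true("species_gene_required" %in% v$rule)

  # empty / dangling seeds
  net <- base
  net@seeds <- character(0)
  expect_true("seeds_nonempty" %in% validateNetwork(net)$rule)
  net <- base
  net@seeds <- "Nope@Cyt"
  expect_true("seed_exists" %in% validateNetwork(net)$rule)

  # reversible flag is refused
  net <- base
  net@reactions[[1]]@reversible <- TRUE
  expect_true("reaction_irreversible" %in% validateNetwork(net)$rule)

  # fractional stoichiometry
  net <- base
  net@reactions[[1]]@substrates[] <- 0.5
  expect_true("reaction_stoichiometry" %in% validateNetwork(net)$rule)

  # transport must connect the same chemical across compartments
  net <- base
  net@compartments <- rbind(net@compartments,
                            data.frame(id = "Ecs", volume = 10, kind = "extracellular"))
  net@reactions[[1]] <- Reaction("r1", substrates = c("Seed@Cyt" = 1),
                                 products = c("B@Cyt" = 1),
                                 rateLaw = RateLaw("transport_first_order", k = 1))
  expect_true("transport_identity" %in% validateNetwork(net)$rule)

  # extraneous rate-law parameter
  net <- base
  net@reactions[[1]]@rateLaw@params <- c(kcat = 1, Km = 1, k = 2)
  expect_true("rate_law_params" %in% validateNetwork(net)$rule)
})

test_that("writeNetwork refuses an invalid network with its violations", {
  net <- chain_network()
  net@seeds <- character(0)
  expect_error(writeNetwork(net), "seeds_nonempty")
})
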