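test_that("constant data give a constant profile", {
  p <- interpolateProfile(c(0, 4, 8), c(1, 1, 1))
  expect_equal(evaluateProfile(p, 2.7), 1)
  expect_equal(evaluateProfile(p, c(-1, 100)), c(1, 1))  # constant extrapolation
})

test_that("the interpolant passes through every replicate mean", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      times <- sort(sample(seq(0, 24, 0.5), sample(3:9, 1)))
      vals <- runif(length(times), 0, 50)
      expr_t <- rep(times, each = 3)
      expr_v <- rep(vals, each = 3) * rep(c(0.9, 1.0, 1.1), length(times))
      p <- interpolateProfile(expr_t, expr_v)
      means <- tapply(expr_v, expr_t, mean)
      expect_lt(max(abs(evaluateProfile(p, times) - means) /
                      pmax(abs(means), 1)), 1e-9)
    }
  })
})

test_that("the spline matches an independent natural-cubic oracle on dense grids", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(4:10, 1)
      times <- sort(runif(n, 0, 24)); times <- times + seq_len(n) * 1e-3
      vals <- sort(runif(n, 1, 20))  # monotone increasing data stay positive
      p <- interpolateProfile(times, vals)
      oracle <- stats::splinefun(times, vals, method = "natural")
      grid <- seq(min(times), max(times), length.out = 400)
      # raw interpolant (clipping to zero is a separate, tested behavior)
      expect_lt(max(abs(evaluateProfile(p, grid, clip = FALSE) - oracle(grid))),
                1e-9)
    }
  })
})

test_that("interpolation rejects degenerate inputs", {
  expect_error(interpolateProfile(0, 1), "at least 2")
  expect_error(interpolateProfile(c(2, 2, 2), c(1, 2, 3)), "at least 2")
})

test_that("negative interpolated values are clipped to zero", {
  # strong overshoot below zero between knots
  p <- interpolateProfile(c(0, 1, 2, 3), c(5, 0.01, 0.01, 5))
  grid <- seq(0, 3, length.out = 300)
  expect_true(all(evaluateProfile(p, grid) >= 0))
  expect_true(any(evaluateProfile(p, grid, clip = FALSE) < 0))
})

test_that("range scaling maps endpoints affinely and preserves ranks", {
  p <- interpolateProfile(c(0, 1), c(1, 3))
  s <- scaleToRange(p, 10, 20)
  expect_equal(s@values, c(10, 20))
  p <- interpolateProfile(c(0, 1, 2), c(1, 2, 3))
  expect_equal(scaleToRange(p, 0, 1)@values, c(0, 0.5, 1))
  # constant profiles collapse to the target minimum
  pc <- interpolateProfile(c(0, 1), c(4, 4))
  expect_equal(scaleToRange(pc, 2, 9)@values, c(2, 2))
  withr::with_seed(5, {
    for (rep in 1:100) {
      v <- runif(sample(3:8, 1), 0, 100)
      p <- interpolateProfile(seq_along(v), v)
      s <- scaleToRange(p, runif(1, 0, 1), runif(1, 2, 5))
      expect_identical(rank(s@values), rank(p@values))
    }
  })
})

test_that("translation calibration anchors the baseline steady state", {
  expect_equal(calibrateTranslation(10, 2, 0.5), 2.5)
  expect_equal(calibrateTranslation(0, 2, 0.5), 0)
  expect_error(calibrateTranslation(3, 0, 1), "manual parameterization")

  # dP/dt = ks m0 - kd P from P(0) = P0 must not drift over 100 h
  withr::with_seed(31, {
    for (rep in 1:10) {
      P0 <- runif(1, 0.1, 20); m0 <- runif(1, 0.1, 5); kd <- runif(1, 0.2, 5)
      ks <- calibrateTranslation(P0, m0, kd)
      sol <- deSolve::ode(c(P = P0), seq(0, 100, 10),
                          function(t, y, p) list(ks * m0 - kd * y),
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
      expect_lt(max(abs(sol[, "P"] - P0)) / P0, 1e-8)
    }
  })
})

test_that("each proteoform in each compartment gains translation + degradation", {
  net <- single_mm_network()
  prof <- list(GENZ = interpolateProfile(c(0, 4, 8), c(1, 2, 3)))
  m <- attachExpressionReactions(net, prof)
  expect_length(reactions(m), length(reactions(net)) + 2)
  ids <- vapply(reactions(m), function(r) r@id, character(1))
  expect_true(all(c("tl_Enz_Cyt", "deg_Enz_Cyt") %in% ids))

  # the same gene product present in two compartments: 4 added reactions
  net2 <- net
  net2@compartments <- rbind(net2@compartments,
                             data.frame(id = "ERMem", volume = 0.2, kind = "membrane"))
  net2@species <- rbind(net2@species,
                        data.frame(id = "Enz", name = "Enz", role = "protein",
                                   compartment = "ERMem", initial = 0.5,
                                   gene = "GENZ", proteoform = "membrane"))
  net2 <- ReactionNetwork(net2@compartments, net2@species, net2@reactions,
                          net2@seeds)
  m2 <- attachExpressionReactions(net2, prof)
  expect_length(reactions(m2), length(reactions(net2)) + 4)

  # metabolite reactions are untouched: the structural diff is additions only
  old_ids <- vapply(reactions(net), function(r) r@id, character(1))
  kept <- Filter(function(r) r@id %in% old_ids, reactions(m))
  expect_identical(lapply(kept, function(r) r@rateLaw@params),
                   lapply(reactions(net), function(r) r@rateLaw@params))

  # proteins without a profile are held constant and reported
  m3 <- attachExpressionReactions(net, list())
  expect_identical(m3@constantProteins, "Enz@Cyt")
  expect_length(reactions(m3), length(reactions(net)))
})

test_that("an explicit baseline map is honored and missing entries are named", {
  net <- single_mm_network()
  prof <- list(GENZ = interpolateProfile(c(0, 4), c(2, 2)))
  m <- attachExpressionReactions(net, prof, baselines = c("Enz@Cyt" = 7))
  expect_equal(expressionLinks(m)$baseline, 7)
  sp <- speciesTable(m)
  expect_equal(sp$initial[sp$id == "Enz"], 7)
  expect_error(attachExpressionReactions(net, prof, baselines = c("Other@Cyt" = 1)),
               "GENZ")
})

test_that("high-turnover proteins track mRNA with a short delay", {
  tr <- tracking_deviation(kd = 10)
  expect_lt(tr$dev, 0.05)
  expect_lt(abs(tr$lag), 0.2)
})

test_that("tracking approaches the quasi-steady-state limit as kd grows", {
  devs <- vapply(c(1, 10, 100), function(kd) tracking_deviation(kd)$dev, numeric(1))
  expect_true(all(diff(devs) < 0))
})
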