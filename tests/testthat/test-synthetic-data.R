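test_that("synthetic tables are byte-identical under a fixed seed", {
  sc <- syntheticScenario(123)
  t1 <- generateMrnaProfiles(sc)
  t2 <- generateMrnaProfiles(sc)
  expect_identical(t1, t2)
  f1 <- tempfile(); f2 <- tempfile()
  writeExpressionTable(t1, f1); writeExpressionTable(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed produces different noise
  expect_false(identical(t1$value, generateMrnaProfiles(syntheticScenario(124))$value))
})

test_that("the noise-free limit reproduces the induction curve exactly", {
  sc <- syntheticScenario(1, cvMrna = 0)
  tab <- generateMrnaProfiles(sc)
  ind <- sc$induction
  for (g in c("PTGS2", "ALOX5")) {
    sub <- tab[tab$gene_id == g, ]
    i <- match(g, ind$gene)
    want <- inductionCurve(sub$time_h, ind$baseline[i], ind$fold[i],
                           ind$t_on[i], ind$tau[i])
    expect_equal(sub$value, want)
    # replicates identical
    expect_equal(as.vector(tapply(sub$value, sub$time_h,
                                  function(v) length(unique(v)))),
                 rep(1L, length(sc$times)))
  }
})

test_that("a fold change of 1 gives a flat profile at baseline", {
  expect_equal(inductionCurve(c(0, 5, 24), baseline = 2, fold = 1,
                              t_on = 1, tau = 2), rep(2, 3))
})

test_that("the empirical replicate CV matches the requested noise level", {
  sc <- syntheticScenario(7, cvMrna = 0.2)
  withr::with_seed(7, {
    draws <- eicotwin:::.lognormal_noise(1e4, 0.2)
    expect_lt(abs(sd(draws) / mean(draws) - 0.2) / 0.2, 0.1)
    expect_lt(abs(mean(draws) - 1), 0.01)   # mean-one multipliers
  })
})

test_that("lipidomics sampling matches the forward simulation", {
  m <- buildExampleModel(5)
  sc <- syntheticScenario(5, cvLipid = 0)
  lip <- generateLipidomics(m, sc)
  expect_equal(lip$observed$value,
               rep(lip$truth$value, sc$replicates))
  # pre-stimulation samples are zero for secreted species
  pre <- lip$truth[lip$truth$time_h < 4, ]
  expect_true(all(pre$value == 0))
  # direct cross-check against an explicit simulation
  res <- simulateModel(m, 24, grid = sort(unique(c(0, sc$lipidTimes))))
  pg <- extractObservable(res, "PGD2", "Ecs")
  truth_pg <- lip$truth[lip$truth$species == "PGD2", ]
  expect_equal(truth_pg$value, pg$value[match(truth_pg$time_h, pg$time_h)])
})

test_that("replicate means converge to the ground truth", {
  m <- buildExampleModel(3)
  sc <- syntheticScenario(3, cvLipid = 0.1)
  sc$replicates <- 100L
  lip <- generateLipidomics(m, sc)
  post <- lip$truth$value > 0.01
  means <- tapply(lip$observed$value,
                  paste(lip$observed$species, lip$observed$time_h), mean)
  keyed <- paste(lip$truth$species, lip$truth$time_h)
  relerr <- abs(means[keyed][post] - lip$truth$value[post]) / lip$truth$value[post]
  expect_true(all(relerr < 3 * 0.1 / sqrt(100)))
})

test_that("zero free parameters returns the raw model-data mismatch", {
  m <- buildExampleModel(2)
  sc <- syntheticScenario(2, cvLipid = 0.05)
  lip <- generateLipidomics(m, sc)
  fit <- recoverParameters(m, lip$observed, character(0), bounds = NULL)
  expect_true(fit$converged)
  expect_length(fit$estimates, 0)
  expect_gt(fit$residual, 0)        # noise makes the mismatch non-zero
  expect_equal(fit$residual, fit$residuals0)
})

test_that("a free kcat is recovered from noise-free data", {
  m <- buildExampleModel(4)
  sc <- syntheticScenario(4, cvLipid = 0)
  lip <- generateLipidomics(m, sc)
  true_kcat <- 2000   # r_pgd_synthase placeholder value
  wrong <- applyParameters(m, overrides = c("r_pgd_synthase:kcat" = 700))
  fit <- recoverParameters(wrong, lip$observed, "r_pgd_synthase:kcat",
                           bounds = list(lower = 200, upper = 20000))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["r_pgd_synthase:kcat"]] - true_kcat) / true_kcat,
            1e-3)
})

test_that("recovery error shrinks as measurement noise decreases", {
  true_vals <- c("r_pgd_synthase:kcat" = 2000)
  err_at_cv <- function(cv, seeds = c(11, 12, 13)) {
    errs <- vapply(seeds, function(s) {
      m <- buildExampleModel(s)
      sc <- syntheticScenario(s, cvLipid = cv)
      lip <- generateLipidomics(m, sc)
      wrong <- applyParameters(m, overrides = c("r_pgd_synthase:kcat" = 600))
      fit <- recoverParameters(wrong, lip$observed, names(true_vals),
                               bounds = list(lower = 200, upper = 20000),
                               nStarts = 1,
                               control = list(maxit = 60, reltol = 1e-6))
      abs(fit$estimates[[1]] - true_vals[[1]]) / true_vals[[1]]
    }, numeric(1))
    median(errs)
  }
  errs <- vapply(c(0.2, 0.1, 0.05, 0), err_at_cv, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("random network generation is deterministic and valid", {
  n1 <- generateRandomNetwork(42); n2 <- generateRandomNetwork(42)
  expect_true(networkEquals(n1, n2))
  expect_identical(writeNetwork(n1), writeNetwork(n2))
})
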