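#' @include network-schema.R
NULL

## Natural cubic spline coefficients through (x, y): second derivative zero at
## both boundaries; Thomas tridiagonal solve. Coefficients are stored
## explicitly (rather than kept inside an interpolator closure) because
## generated programs embed them verbatim, guaranteeing bit-identical forcing
## between the internal engine and emitted code.
.natural_spline_coefs <- function(x, y) {
  n <- length(x)
  if (n == 2) {
    b <- (y[2] - y[1]) / (x[2] - x[1])
    return(matrix(c(y[1], b, 0, 0), nrow = 1,
                  dimnames = list(NULL, c("a", "b", "c", "d"))))
  }
  h <- diff(x)
  ## tridiagonal system for interior second derivatives M[2..n-1]
  m <- n - 2
  diag_ <- 2 * (h[-length(h)] + h[-1])
  sub <- h[2:(m)]            # below-diagonal entries (length m-1) when m > 1
  rhs <- 6 * (diff(y)[-1] / h[-1] - diff(y)[-length(h)] / h[-length(h)])
  ## Thomas algorithm
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- if (m > 1) h[2] / diag_[1] else 0
  dp[1] <- rhs[1] / diag_[1]
  if (m > 1) {
    for (i in 2:m) {
      denom <- diag_[i] - h[i] * cp[i - 1]
      cp[i] <- if (i < m) h[i + 1] / denom else 0
      dp[i] <- (rhs[i] - h[i] * dp[i - 1]) / denom
    }
  }
  Mi <- numeric(m)
  Mi[m] <- dp[m]
  if (m > 1) for (i in (m - 1):1) Mi[i] <- dp[i] - cp[i] * Mi[i + 1]
  M <- c(0, Mi, 0)

  i <- seq_len(n - 1)
  a <- y[i]
  b <- diff(y) / h - h * (2 * M[i] + M[i + 1]) / 6
  cc <- M[i] / 2
  d <- (M[i + 1] - M[i]) / (6 * h)
  matrix(c(a, b, cc, d), ncol = 4, dimnames = list(NULL, c("a", "b", "c", "d")))
}

#' Spline a measured time course into a continuous forcing profile
#'
#' Replicate values are averaged per time point first, then a natural cubic
#' spline is fitted through the means. Evaluation ([evaluateProfile()]) uses
#' constant extrapolation outside the measured window (so no runaway
#' synthesis beyond the last sample) and clips negative interpolated values
#' to zero.
#'
#' @param times measurement times (hours); duplicates allowed (replicates).
#' @param values measured values, same length as `times`.
#' @param replicates optional replicate labels; only `times` grouping is used
#'   for averaging, so this argument is informational.
#' @return a [ContinuousProfile-class]
#' @export
interpolateProfile <- function(times, values, replicates = NULL) {
  stopifnot(length(times) == length(values))
  keep <- is.finite(times) & is.finite(values)
  times <- times[keep]; values <- values[keep]
  means <- tapply(values, times, mean)
  knots <- as.numeric(names(means))
  o <- order(knots)
  knots <- knots[o]
  vals <- as.numeric(means)[o]
  if (length(knots) < 2)
    stop("need at least 2 distinct time points to interpolate", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("times are not strictly increasing after replicate averaging",
         call. = FALSE)
  new("ContinuousProfile", knots = knots, values = vals,
      coefs = .natural_spline_coefs(knots, vals))
}

#' Evaluate a continuous profile
#'
#' @param profile a [ContinuousProfile-class]
#' @param t numeric vector of times (hours); any `t >= 0` is defined.
#' @param clip clip negative interpolated values to 0 (default TRUE).
#' @return numeric vector of profile values
#' @export
evaluateProfile <- function(profile, t, clip = TRUE) {
  k <- profile@knots
  tt <- pmin(pmax(t, k[1]), k[length(k)])          # constant extrapolation
  idx <- findInterval(tt, k, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(k) - 1L)
  dt <- tt - k[idx]
  cf <- profile@coefs
  out <- cf[idx, "a"] + dt * (cf[idx, "b"] + dt * (cf[idx, "c"] + dt * cf[idx, "d"]))
  if (clip) out <- pmax(out, 0)
  unname(out)
}

#' Rescale a profile into a target range
#'
#' Affine map of the knot values so that the profile minimum lands on
#' `targetMin` and the maximum on `targetMax` (used to place mRNA profiles on
#' the scale of the corresponding protein concentrations). A constant profile
#' maps to `targetMin`. Ranks of values are preserved.
#'
#' @param profile a [ContinuousProfile-class]
#' @param targetMin,targetMax target range, `targetMax >= targetMin`
#' @return a rescaled [ContinuousProfile-class]
#' @export
scaleToRange <- function(profile, targetMin, targetMax) {
  stopifnot(targetMax >= targetMin)
  v <- profile@values
  rng <- range(v)
  newv <- if (diff(rng) == 0) rep(targetMin, length(v)) else
    targetMin + (v - rng[1]) / diff(rng) * (targetMax - targetMin)
  new("ContinuousProfile", knots = profile@knots, values = newv,
      coefs = .natural_spline_coefs(profile@knots, newv))
}

#' Steady-state translation-rate calibration
#'
#' Given the baseline protein concentration `P0` (uM, from proteomics), the
#' baseline mRNA level `m0` (profile units) and the degradation rate `kd`
#' (per hour), returns the translation rate `ks = P0 * kd / m0` such that
#' `dP/dt = ks * m0 - kd * P0 = 0` at baseline: the enzyme starts at its
#' proteomics-determined steady state and follows the mRNA profile from
#' there.
#'
#' @param P0 baseline protein concentration (uM), `>= 0`
#' @param m0 baseline mRNA level, `> 0` unless `P0 == 0`
#' @param kd degradation rate (per hour), `> 0`
#' @return translation rate `ks` (uM protein per mRNA unit per hour)
#' @export
calibrateTranslation <- function(P0, m0, kd) {
  stopifnot(P0 >= 0, kd > 0)
  if (P0 == 0) return(0)
  if (m0 <= 0)
    stop("baseline mRNA level is 0 while baseline protein > 0; ",
         "flag this gene for manual parameterization", call. = FALSE)
  P0 * kd / m0
}

#' Couple enzyme levels to measured mRNA profiles
#'
#' For every protein proteoform in every compartment whose gene has an mRNA
#' forcing profile, adds one translation reaction (rate `ks * m(t)`, with
#' `ks` anchored by [calibrateTranslation()] at the profile's first knot) and
#' one first-order degradation reaction (rate `kd * P`). The mRNA is a
#' forcing function, not a state variable. Proteins without a profile are
#' held constant and reported in the model's `constantProteins`.
#'
#' @param net pruned [ReactionNetwork-class]
#' @param profiles named list, gene id -> [ContinuousProfile-class]
#' @param baselines optional named numeric of baseline protein
#'   concentrations (uM) keyed by species key (`"id@compartment"`); defaults
#'   to the species' initial concentrations. When provided for a profiled
#'   protein, the species initial is reset to it. A profiled protein with no
#'   resolvable baseline is an error naming the gene.
#' @param kdDefault default degradation rate (per hour); the default 2/h
#'   corresponds to a protein half-life of about 21 minutes ("high
#'   turnover"), under which enzyme levels track the mRNA profile with only a
#'   short delay.
#' @param kdPerGene optional named numeric overriding `kdDefault` per gene.
#' @param events an [EventSchedule-class] for the resulting model.
#' @return a [DynamicModel-class]
#' @export
attachExpressionReactions <- function(net, profiles, baselines = NULL,
                                      kdDefault = 2, kdPerGene = NULL,
                                      events = EventSchedule()) {
  .assert_valid(net, "network (before expression linking)")
  stopifnot(kdDefault > 0)
  sp <- net@species
  keys <- speciesKey(sp$id, sp$compartment)
  prot <- which(sp$role == "protein")

  links <- list()
  added <- list()
  constant <- character(0)
  sp2 <- sp

  for (i in prot) {
    key <- keys[i]
    gene <- sp$gene[i]
    if (!gene %in% names(profiles)) {
      constant <- c(constant, key)
      next
    }
    prof <- profiles[[gene]]
    P0 <- if (!is.null(baselines)) {
      if (!key %in% names(baselines))
        stop(sprintf("no baseline protein concentration for gene '%s' (%s)",
                     gene, key), call. = FALSE)
      baselines[[key]]
    } else sp$initial[i]
    sp2$initial[i] <- P0
    kd <- if (!is.null(kdPerGene) && gene %in% names(kdPerGene))
      kdPerGene[[gene]] else kdDefault
    m0 <- evaluateProfile(prof, prof@knots[1])
    ks <- calibrateTranslation(P0, m0, kd)

    tag <- gsub("@", "_", key, fixed = TRUE)
    added[[length(added) + 1L]] <- Reaction(
      id = paste0("tl_", tag),
      products = stats::setNames(1, key),
      rateLaw = RateLaw("translation", ks = ks), gene = gene)
    added[[length(added) + 1L]] <- Reaction(
      id = paste0("deg_", tag),
      substrates = stats::setNames(1, key),
      rateLaw = RateLaw("degradation_first_order", k = kd))
    links[[length(links) + 1L]] <- data.frame(
      gene = gene, compartment = sp$compartment[i], protein = key,
      baseline = P0, ks = ks, kd = kd, stringsAsFactors = FALSE)
  }

  net2 <- ReactionNetwork(net@compartments, sp2,
                          c(net@reactions, added), net@seeds, net@annotations)
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(gene = character(0), compartment = character(0),
               protein = character(0), baseline = numeric(0),
               ks = numeric(0), kd = numeric(0), stringsAsFactors = FALSE)
  links <- links[order(links$protein), , drop = FALSE]
  rownames(links) <- NULL
  new("DynamicModel", network = net2,
      profiles = profiles[sort(intersect(names(profiles), links$gene))],
      links = links, constantProteins = sort(constant), events = events)
}
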