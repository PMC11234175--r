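#' @include expression-dynamics.R
NULL

#' Michaelis-Menten rate
#'
#' `v = kcat * E * S / (Km + S)`, the enzymatic rate law used throughout the
#' engine. Returns 0 when `S = 0`, including the degenerate `Km = S = 0`
#' limit.
#'
#' @param E enzyme concentration (uM)
#' @param S substrate concentration (uM)
#' @param kcat turnover number (per hour)
#' @param Km Michaelis constant (uM)
#' @return flux (uM per hour); vectorized over all arguments
#' @export
mmRate <- function(E, S, kcat, Km) {
  v <- kcat * E * S / (Km + S)
  v[!is.finite(v) | S == 0] <- 0
  v
}

#' First-order (mass action) rate
#' @param k rate constant (per hour)
#' @param S substrate concentration (uM)
#' @return flux `k * S` (uM per hour)
#' @export
massActionRate <- function(k, S) k * S

## ---- assembly --------------------------------------------------------------

## Precompute everything the derivative function needs: a stoichiometry/volume
## coefficient matrix M (state x reaction) and per-form index vectors, so the
## RHS is a handful of vectorized operations. Rates are computed in the
## concentration units of a reaction's reference compartment (first substrate's
## compartment; for translation, the product's); the amount flux v * V_ref is
## then distributed to each participating state as +/- stoich * V_ref / V_state,
## which conserves amount (concentration x volume) across compartments.
.assemble <- function(model, armed = NULL) {
  net <- model@network
  .assert_valid(net, "model network")
  sn <- stateNames(net)
  n <- length(sn)
  sp <- net@species
  sp <- sp[sp$role != "mRNA", , drop = FALSE]
  volofcmp <- stats::setNames(net@compartments$volume, net@compartments$id)
  vol <- stats::setNames(volofcmp[sp$compartment], sn)
  y0 <- stats::setNames(sp$initial, sn)

  rxns <- net@reactions
  nr <- length(rxns)
  M <- matrix(0, n, nr, dimnames = list(sn, vapply(rxns, function(r) r@id, character(1))))

  kind <- character(nr); k1 <- numeric(nr)
  sidx <- rep(NA_integer_, nr); eidx <- rep(NA_integer_, nr)
  kcat <- numeric(nr); Km <- numeric(nr)
  gene <- rep(NA_character_, nr)
  multi <- vector("list", nr)   # multi-substrate mass action: list(idx, stoich)

  for (j in seq_len(nr)) {
    r <- rxns[[j]]
    form <- r@rateLaw@form
    p <- r@rateLaw@params
    refk <- if (length(r@substrates)) names(r@substrates)[1] else names(r@products)[1]
    vref <- vol[[refk]]
    for (k in names(r@substrates))
      M[k, j] <- M[k, j] - r@substrates[[k]] * vref / vol[[k]]
    for (k in names(r@products))
      M[k, j] <- M[k, j] + r@products[[k]] * vref / vol[[k]]

    if (form == "michaelis_menten") {
      kind[j] <- "mm"
      sidx[j] <- match(names(r@substrates)[1], sn)
      eidx[j] <- match(r@enzyme, sn)
      kcat[j] <- p[["kcat"]]; Km[j] <- p[["Km"]]
    } else if (form == "translation") {
      kind[j] <- "translation"
      k1[j] <- p[["ks"]]
      gene[j] <- r@gene
      if (is.na(gene[j]) || !gene[j] %in% names(model@profiles))
        stop(sprintf("translation reaction '%s' has no mRNA profile", r@id),
             call. = FALSE)
    } else if (form %in% c("mass_action", "transport_first_order",
                           "degradation_first_order")) {
      if (form == "mass_action" && length(r@substrates) != 1) {
        kind[j] <- "multi"
        k1[j] <- p[["k"]]
        multi[[j]] <- list(idx = match(names(r@substrates), sn),
                           stoich = unname(r@substrates))
      } else {
        kind[j] <- "first_order"
        k1[j] <- p[["k"]]
        sidx[j] <- match(names(r@substrates)[1], sn)
      }
    } else stop("unknown rate-law form: ", form, call. = FALSE)
  }

  ## armed translocation returns: first-order flux dst -> src
  arm <- if (is.null(armed) || nrow2(armed) == 0) NULL else armed
  if (!is.null(arm)) {
    for (i in seq_len(nrow(arm))) {
      jd <- match(arm$dst[i], sn); js <- match(arm$src[i], sn)
      M <- cbind(M, 0)
      nr <- nr + 1L
      M[jd, nr] <- -1
      M[js, nr] <- vol[[arm$dst[i]]] / vol[[arm$src[i]]]
      kind <- c(kind, "first_order"); k1 <- c(k1, arm$k_ret[i])
      sidx <- c(sidx, jd); eidx <- c(eidx, NA_integer_)
      kcat <- c(kcat, 0); Km <- c(Km, 0); gene <- c(gene, NA_character_)
      multi <- c(multi, list(NULL))
    }
  }

  i_mm <- which(kind == "mm")
  i_fo <- which(kind == "first_order")
  i_tl <- which(kind == "translation")
  i_mu <- which(kind == "multi")
  genes_used <- unique(gene[i_tl])
  profs <- model@profiles[genes_used]
  gmap <- match(gene[i_tl], genes_used)

  ## hot-path precomputation: plain vectors, no S4 access inside the RHS
  k1_fo <- k1[i_fo]; s_fo <- sidx[i_fo]
  kc_mm <- kcat[i_mm]; Km_mm <- Km[i_mm]; s_mm <- sidx[i_mm]; e_mm <- eidx[i_mm]
  k1_tl <- k1[i_tl]
  ng <- length(profs)
  pk <- lapply(profs, function(p) p@knots)
  pcf <- lapply(profs, function(p) unname(p@coefs))

  rhs <- function(t, y, parms = NULL) {
    v <- numeric(nr)
    if (length(i_fo)) v[i_fo] <- k1_fo * y[s_fo]
    if (length(i_mm)) {
      S <- y[s_mm]
      vv <- kc_mm * y[e_mm] * S / (Km_mm + S)
      vv[!is.finite(vv) | S == 0] <- 0
      v[i_mm] <- vv
    }
    if (ng) {
      mv <- numeric(ng)
      for (g in seq_len(ng)) {
        k <- pk[[g]]; nk <- length(k)
        tt <- if (t < k[1]) k[1] else if (t > k[nk]) k[nk] else t
        i <- findInterval(tt, k, rightmost.closed = TRUE)
        if (i < 1L) i <- 1L else if (i > nk - 1L) i <- nk - 1L
        cf <- pcf[[g]]; dt <- tt - k[i]
        val <- cf[i, 1L] + dt * (cf[i, 2L] + dt * (cf[i, 3L] + dt * cf[i, 4L]))
        mv[g] <- if (val > 0) val else 0
      }
      v[i_tl] <- k1_tl * mv[gmap]
    }
    for (j in i_mu)
      v[j] <- k1[j] * prod(y[multi[[j]]$idx]^multi[[j]]$stoich)
    list(as.vector(M %*% v))
  }

  list(rhs = rhs, stateNames = sn, y0 = y0, vol = vol, M = M,
       kind = kind, k1 = k1, sidx = sidx, eidx = eidx, kcat = kcat, Km = Km,
       gene = gene, multi = multi, nr = nr)
}

nrow2 <- function(x) if (is.null(x)) 0L else nrow(x)

#' Assemble the derivative function of a model
#'
#' Builds and returns the ODE right-hand side `f(t, state)` summing, per
#' state variable, the stoichiometry- and volume-weighted reaction fluxes
#' (Michaelis-Menten, mass action, transport), the translation forcing
#' `ks * m(t)` and the first-order degradation terms. Unparameterized or
#' invalid reactions fail here, at assembly time, not during integration.
#'
#' @param model a [DynamicModel-class]
#' @return a function `(t, state) -> list(d state / dt)` (deSolve calling
#'   convention); the state vector follows `stateNames(model)`.
#' @export
assembleRHS <- function(model) .assemble(model)$rhs

## ---- events ----------------------------------------------------------------

#' Apply a calcium-translocation event to a state vector
#'
#' Moves a fraction `f` of the source-compartment *amount* (concentration
#' times volume) of each listed protein to its destination compartment: the
#' source concentration drops by `f * C_src`, the destination gains
#' `f * C_src * V_src / V_dst`, so total amount is conserved exactly. The
#' returned `returns` table arms the first-order return flux (rate `k_ret`)
#' that the integrator adds for subsequent segments.
#'
#' @param state named numeric state vector (keys `"id@compartment"`)
#' @param payload data.frame with columns `species`, `from`, `to`,
#'   `fraction` (in `[0, 1]`) and `k_ret` (per hour)
#' @param network the [ReactionNetwork-class] providing compartment volumes
#' @return list with `state` (updated vector) and `returns` (data.frame
#'   `src`, `dst`, `k_ret`)
#' @export
applyTranslocationEvent <- function(state, payload, network) {
  volofcmp <- stats::setNames(network@compartments$volume, network@compartments$id)
  rets <- list()
  for (i in seq_len(nrow(payload))) {
    srck <- speciesKey(payload$species[i], payload$from[i])
    dstk <- speciesKey(payload$species[i], payload$to[i])
    if (!srck %in% names(state) || !dstk %in% names(state))
      stop(sprintf("translocation references unknown state '%s' or '%s'",
                   srck, dstk), call. = FALSE)
    f <- payload$fraction[i]
    if (f < 0 || f > 1) stop("translocation fraction must lie in [0, 1]", call. = FALSE)
    vsrc <- volofcmp[[payload$from[i]]]; vdst <- volofcmp[[payload$to[i]]]
    moved_amount <- f * state[[srck]] * vsrc
    state[[srck]] <- state[[srck]] * (1 - f)
    state[[dstk]] <- state[[dstk]] + moved_amount / vdst
    rets[[i]] <- data.frame(src = srck, dst = dstk,
                            k_ret = payload$k_ret[i], stringsAsFactors = FALSE)
  }
  list(state = state,
       returns = if (length(rets)) do.call(rbind, rets) else
         data.frame(src = character(0), dst = character(0), k_ret = numeric(0)))
}

.apply_add_ligand <- function(state, payload, network) {
  if (is.null(payload)) return(state)   # marker event (response carried by mRNA profiles)
  key <- speciesKey(payload$species, payload$compartment)
  if (!key %in% names(state))
    stop(sprintf("add_ligand references unknown state '%s'", key), call. = FALSE)
  state[[key]] <- state[[key]] + payload$amount
  state
}

## ---- integration -----------------------------------------------------------

#' Simulate a dynamic model
#'
#' Integrates the compartmental ODE system with a stiff-capable solver
#' (deSolve's `lsoda`), restarting the integration at each scheduled event:
#' `add_ligand` payloads add to a state, `calcium_translocation` payloads
#' move protein amount between compartments and arm first-order return
#' fluxes. Output is reported on the requested grid; at an interior event
#' time the pre-event state is reported. Tiny negative solver undershoot
#' (above `-1e-6` uM) is clipped to zero; anything lower is an error.
#'
#' @param model a [DynamicModel-class]
#' @param tEnd end time (hours), `> 0`
#' @param grid output times; defaults to 481 equidistant points on
#'   `[0, tEnd]`
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-10)
#' @param method deSolve integration method (default `"lsoda"`)
#' @return a [SimulationResult-class]
#' @export
simulateModel <- function(model, tEnd, grid = NULL, rtol = 1e-8, atol = 1e-10,
                          method = "lsoda") {
  stopifnot(tEnd > 0)
  if (is.null(grid)) grid <- seq(0, tEnd, length.out = 481L)
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid < 0) || any(grid > tEnd))
    stop("output grid must lie within [0, tEnd]", call. = FALSE)

  ev <- model@events@events
  ev_times <- vapply(ev, function(e) as.numeric(e$time), numeric(1))
  keep <- ev_times <= tEnd
  ev <- ev[keep]; ev_times <- ev_times[keep]

  base <- .assemble(model)
  y <- base$y0
  armed <- NULL

  apply_events_at <- function(tau, y) {
    for (e in ev[ev_times == tau]) {
      if (e$kind == "add_ligand") {
        y <- .apply_add_ligand(y, e$payload, model@network)
      } else if (e$kind == "calcium_translocation") {
        res <- applyTranslocationEvent(y, e$payload, model@network)
        y <- res$state
        armed <<- rbind(armed, res$returns)
      }
    }
    y
  }

  y <- apply_events_at(0, y)
  bounds <- sort(unique(c(0, ev_times[ev_times > 0 & ev_times < tEnd], tEnd)))
  out <- matrix(NA_real_, length(grid), length(base$stateNames),
                dimnames = list(NULL, base$stateNames))
  if (grid[1] == 0) out[1, ] <- y
  steps <- 0L

  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    asm <- if (is.null(armed)) base else .assemble(model, armed)
    seg_grid <- grid[grid > t0 & grid <= t1]
    times <- sort(unique(c(t0, seg_grid, t1)))
    sol <- deSolve::ode(y = y, times = times, func = asm$rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integrator failure on segment [%g, %g] h (istate = %d)",
                   t0, t1, attr(sol, "istate")[1]), call. = FALSE)
    steps <- steps + attr(sol, "istate")[2]
    smat <- sol[, -1, drop = FALSE]
    if (min(smat) < -1e-6)
      stop(sprintf("negative concentration beyond solver noise floor (min %g)",
                   min(smat)), call. = FALSE)
    smat[smat < 0] <- 0
    if (length(seg_grid))
      out[match(seg_grid, grid), ] <- smat[match(seg_grid, times), , drop = FALSE]
    y <- stats::setNames(smat[nrow(smat), ], base$stateNames)
    y <- apply_events_at(t1, y)
  }

  new("SimulationResult", time = grid, states = out,
      diagnostics = list(method = method, rtol = rtol, atol = atol,
                         segments = length(bounds) - 1L, steps = steps,
                         events_applied = sum(ev_times <= tEnd)))
}

#' Extract one observable time series
#'
#' @param result a [SimulationResult-class]
#' @param species species id (e.g. `"PGD2"`)
#' @param compartment compartment id (e.g. `"Ecs"`)
#' @return data.frame with columns `time_h` and `value` (uM)
#' @export
extractObservable <- function(result, species, compartment) {
  key <- speciesKey(species, compartment)
  if (!key %in% colnames(result@states))
    stop(sprintf("no state variable '%s' in the result", key), call. = FALSE)
  data.frame(time_h = result@time, value = unname(result@states[, key]))
}

#' Write a simulation result as tab-separated text
#'
#' First column `time_h`, then one column per `species@compartment`.
#'
#' @param result a [SimulationResult-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSimulationResult <- function(result, path) {
  df <- data.frame(time_h = result@time, result@states, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory table written by [writeSimulationResult()]
#' @param path file path
#' @return data.frame with `time_h` plus one column per state
#' @export
readTrajectoryTable <- function(path)
  utils::read.delim(path, check.names = FALSE)
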