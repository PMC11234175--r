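#' @include dynamics-engine.R
NULL

.dialect_registry <- new.env(parent = emptyenv())

#' Registered code-generation dialects
#' @return character vector of dialect ids
#' @export
registeredDialects <- function() sort(ls(.dialect_registry))

.num <- function(x) sprintf("%.17g", x)
.numvec <- function(x) paste0("c(", paste(.num(x), collapse = ", "), ")")

## Build the shared emission plan: state manifest, flux expression fragments,
## event actions and armed-return terms. Each dialect template renders this
## plan into its own syntax.
.emission_plan <- function(model, tEnd, grid, rtol, atol) {
  asm <- .assemble(model)
  sn <- asm$stateNames
  n <- length(sn)
  parts <- splitSpeciesKey(sn)
  manifest <- data.frame(index = seq_len(n), species = parts$id,
                         compartment = parts$compartment,
                         stringsAsFactors = FALSE)
  if (is.null(grid)) grid <- seq(0, tEnd, length.out = 481L)
  grid <- sort(unique(as.numeric(grid)))

  ev <- model@events@events
  ev_times <- vapply(ev, function(e) as.numeric(e$time), numeric(1))
  keep <- ev_times <= tEnd
  ev <- ev[keep]; ev_times <- ev_times[keep]

  ## enumerate every potential translocation return flux up front; generated
  ## code holds one armed flag per return, switched on when its event fires
  returns <- list()
  events <- list()
  volofcmp <- stats::setNames(model@network@compartments$volume,
                              model@network@compartments$id)
  for (i in seq_along(ev)) {
    e <- ev[[i]]
    acts <- list()
    if (e$kind == "add_ligand" && !is.null(e$payload)) {
      key <- speciesKey(e$payload$species, e$payload$compartment)
      acts[[length(acts) + 1L]] <- list(op = "add", idx = match(key, sn),
                                        amount = e$payload$amount)
    } else if (e$kind == "calcium_translocation") {
      pl <- e$payload
      for (r in seq_len(nrow(pl))) {
        srck <- speciesKey(pl$species[r], pl$from[r])
        dstk <- speciesKey(pl$species[r], pl$to[r])
        kret <- pl$k_ret[r]
        returns[[length(returns) + 1L]] <- list(
          src = match(srck, sn), dst = match(dstk, sn),
          k_ret = kret,
          vratio = volofcmp[[pl$from[r]]] / volofcmp[[pl$to[r]]],
          vratio_back = volofcmp[[pl$to[r]]] / volofcmp[[pl$from[r]]])
        acts[[length(acts) + 1L]] <- list(
          op = "move", src = match(srck, sn), dst = match(dstk, sn),
          fraction = pl$fraction[r],
          vratio = volofcmp[[pl$from[r]]] / volofcmp[[pl$to[r]]],
          arm = length(returns))
      }
    }
    events[[length(events) + 1L]] <- list(time = ev_times[i], actions = acts)
  }

  list(asm = asm, manifest = manifest, grid = grid, tEnd = tEnd,
       rtol = rtol, atol = atol, events = events, returns = returns,
       profiles = model@profiles)
}

## R-dialect flux expression for reaction j of the assembly
.flux_expr_r <- function(asm, j) {
  switch(asm$kind[j],
    first_order = sprintf("(%s * y[%d])", .num(asm$k1[j]), asm$sidx[j]),
    mm = sprintf(".mm(%s, y[%d], y[%d], %s)",
                 .num(asm$kcat[j]), asm$eidx[j], asm$sidx[j], .num(asm$Km[j])),
    translation = sprintf("(%s * .spline_eval(.splines[[\"%s\"]], t))",
                          .num(asm$k1[j]), asm$gene[j]),
    multi = {
      m <- asm$multi[[j]]
      sprintf("(%s * %s)", .num(asm$k1[j]),
              paste(sprintf("y[%d]^%s", m$idx, .num(m$stoich)), collapse = " * "))
    },
    stop("unhandled kind"))
}

.emit_r <- function(plan) {
  asm <- plan$asm
  n <- length(asm$stateNames)
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))

  push("#!/usr/bin/env Rscript")
  push("# Standalone cell-type-selective kinetic model (generated code, dialect 'r').")
  push("# Usage: Rscript <this-file> [output.tsv]; trajectory printed as TSV.")
  push("suppressPackageStartupMessages(library(deSolve))")
  push(".states <- %s", paste0("c(", paste(sprintf('"%s"', asm$stateNames), collapse = ", "), ")"))
  push(".y0 <- %s", .numvec(unname(asm$y0)))
  push(".grid <- %s", .numvec(plan$grid))
  if (length(plan$profiles)) {
    push(".splines <- list(")
    gs <- names(plan$profiles)
    for (i in seq_along(gs)) {
      p <- plan$profiles[[gs[i]]]
      push("  \"%s\" = list(knots = %s, coefs = matrix(%s, ncol = 4))%s",
           gs[i], .numvec(p@knots), .numvec(as.vector(p@coefs)),
           if (i < length(gs)) "," else "")
    }
    push(")")
  } else push(".splines <- list()")
  push(".spline_eval <- function(s, t) {")
  push("  k <- s$knots")
  push("  tt <- min(max(t, k[1]), k[length(k)])")
  push("  i <- findInterval(tt, k, rightmost.closed = TRUE)")
  push("  i <- min(max(i, 1L), length(k) - 1L)")
  push("  dt <- tt - k[i]")
  push("  cf <- s$coefs")
  push("  max(cf[i, 1] + dt * (cf[i, 2] + dt * (cf[i, 3] + dt * cf[i, 4])), 0)")
  push("}")
  push(".mm <- function(kcat, E, S, Km) {")
  push("  v <- kcat * E * S / (Km + S)")
  push("  if (!is.finite(v) || S == 0) 0 else v")
  push("}")
  push(".armed <- rep(FALSE, %d)", max(1L, length(plan$returns)))

  push(".rhs <- function(t, y, p) {")
  push("  d <- numeric(%d)", n)
  for (i in seq_len(n)) {
    terms <- character(0)
    for (j in seq_len(asm$nr)) {
      cij <- asm$M[i, j]
      if (cij != 0)
        terms <- c(terms, sprintf("%s * %s", .num(cij), .flux_expr_r(asm, j)))
    }
    for (k in seq_along(plan$returns)) {
      r <- plan$returns[[k]]
      flux <- sprintf("(.armed[%d] * %s * y[%d])", k, .num(r$k_ret), r$dst)
      if (r$dst == i) terms <- c(terms, sprintf("-1 * %s", flux))
      if (r$src == i) terms <- c(terms, sprintf("%s * %s", .num(r$vratio_back), flux))
    }
    push("  d[%d] <- %s", i, if (length(terms)) paste(terms, collapse = " + ") else "0")
  }
  push("  list(d)")
  push("}")

  ## event application, one function per scheduled time
  push(".apply_events <- function(tau, y) {")
  for (e in plan$events) {
    push("  if (tau == %s) {", .num(e$time))
    for (a in e$actions) {
      if (a$op == "add") {
        push("    y[%d] <- y[%d] + %s", a$idx, a$idx, .num(a$amount))
      } else {
        push("    moved <- %s * y[%d]", .num(a$fraction), a$src)
        push("    y[%d] <- y[%d] - moved", a$src, a$src)
        push("    y[%d] <- y[%d] + moved * %s", a$dst, a$dst, .num(a$vratio))
        push("    .armed[%d] <<- TRUE", a$arm)
      }
    }
    push("  }")
  }
  push("  y")
  push("}")

  bounds <- sort(unique(c(0, vapply(plan$events, `[[`, numeric(1), "time"), plan$tEnd)))
  bounds <- bounds[bounds <= plan$tEnd]
  push(".bounds <- %s", .numvec(bounds))
  push(".run <- function() {")
  push("  y <- .y0")
  push("  y <- .apply_events(0, y)")
  push("  out <- matrix(NA_real_, length(.grid), length(.states))")
  push("  if (.grid[1] == 0) out[1, ] <- y")
  push("  for (s in seq_len(length(.bounds) - 1L)) {")
  push("    t0 <- .bounds[s]; t1 <- .bounds[s + 1L]")
  push("    segg <- .grid[.grid > t0 & .grid <= t1]")
  push("    times <- sort(unique(c(t0, segg, t1)))")
  push("    sol <- deSolve::ode(y = y, times = times, func = .rhs, parms = NULL,")
  push("                        method = \"lsoda\", rtol = %s, atol = %s)", .num(plan$rtol), .num(plan$atol))
  push("    smat <- sol[, -1, drop = FALSE]")
  push("    smat[smat < 0] <- 0")
  push("    if (length(segg)) out[match(segg, .grid), ] <- smat[match(segg, times), , drop = FALSE]")
  push("    y <- smat[nrow(smat), ]")
  push("    y <- .apply_events(t1, y)")
  push("  }")
  push("  out")
  push("}")
  push("out <- .run()")
  push("df <- data.frame(time_h = .grid, out, check.names = FALSE)")
  push("colnames(df) <- c(\"time_h\", .states)")
  push("args <- commandArgs(trailingOnly = TRUE)")
  push("dest <- if (length(args) >= 1) args[1] else stdout()")
  push("write.table(df, dest, sep = \"\\t\", quote = FALSE, row.names = FALSE)")
  paste(out, collapse = "\n")
}

## MATLAB/Octave template: same structure rendered as an .m script with
## ode15s; shipped for use in that environment, not executed by the tests.
.emit_matlab <- function(plan) {
  asm <- plan$asm
  n <- length(asm$stateNames)
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))
  flux <- function(j) switch(asm$kind[j],
    first_order = sprintf("(%s * y(%d))", .num(asm$k1[j]), asm$sidx[j]),
    mm = sprintf("mm(%s, y(%d), y(%d), %s)", .num(asm$kcat[j]), asm$eidx[j],
                 asm$sidx[j], .num(asm$Km[j])),
    translation = sprintf("(%s * spline_eval(splines.%s, t))",
                          .num(asm$k1[j]), gsub("[^A-Za-z0-9_]", "_", asm$gene[j])),
    multi = {
      m <- asm$multi[[j]]
      sprintf("(%s * %s)", .num(asm$k1[j]),
              paste(sprintf("y(%d)^%s", m$idx, .num(m$stoich)), collapse = " * "))
    })
  push("%% Standalone cell-type-selective kinetic model (generated code, dialect 'matlab').")
  push("function model_main()")
  push("states = {%s};", paste(sprintf("'%s'", asm$stateNames), collapse = ", "))
  push("y0 = [%s];", paste(.num(unname(asm$y0)), collapse = "; "))
  push("grid = [%s];", paste(.num(plan$grid), collapse = ", "))
  for (g in names(plan$profiles)) {
    p <- plan$profiles[[g]]
    gm <- gsub("[^A-Za-z0-9_]", "_", g)
    push("splines.%s.knots = [%s];", gm, paste(.num(p@knots), collapse = ", "))
    push("splines.%s.coefs = reshape([%s], [], 4);", gm,
         paste(.num(as.vector(p@coefs)), collapse = ", "))
  }
  push("armed = false(1, %d);", max(1L, length(plan$returns)))
  push("bounds = [%s];", paste(.num(sort(unique(c(0,
       vapply(plan$events, `[[`, numeric(1), "time"), plan$tEnd)))), collapse = ", "))
  push("out = NaN(numel(grid), %d);", n)
  push("y = apply_events(0, y0);")
  push("if grid(1) == 0; out(1, :) = y'; end")
  push("opts = odeset('RelTol', %s, 'AbsTol', %s);", .num(plan$rtol), .num(plan$atol))
  push("for s = 1:numel(bounds) - 1")
  push("  t0 = bounds(s); t1 = bounds(s + 1);")
  push("  segg = grid(grid > t0 & grid <= t1);")
  push("  times = unique([t0, segg, t1]);")
  push("  [tt, yy] = ode15s(@rhs, times, y, opts);")
  push("  yy(yy < 0) = 0;")
  push("  [tf, loc] = ismember(segg, tt);")
  push("  out(ismember(grid, segg), :) = yy(loc(tf), :);")
  push("  y = yy(end, :)';")
  push("  y = apply_events(t1, y);")
  push("end")
  push("tab = [grid', out];")
  push("dlmwrite('trajectory.tsv', tab, '\\t');")
  push("  function d = rhs(t, y)")
  push("    d = zeros(%d, 1);", n)
  for (i in seq_len(n)) {
    terms <- character(0)
    for (j in seq_len(asm$nr))
      if (asm$M[i, j] != 0)
        terms <- c(terms, sprintf("%s * %s", .num(asm$M[i, j]), flux(j)))
    for (k in seq_along(plan$returns)) {
      r <- plan$returns[[k]]
      fx <- sprintf("(armed(%d) * %s * y(%d))", k, .num(r$k_ret), r$dst)
      if (r$dst == i) terms <- c(terms, sprintf("-1 * %s", fx))
      if (r$src == i) terms <- c(terms, sprintf("%s * %s", .num(r$vratio_back), fx))
    }
    push("    d(%d) = %s;", i, if (length(terms)) paste(terms, collapse = " + ") else "0")
  }
  push("  end")
  push("  function y = apply_events(tau, y)")
  for (e in plan$events) {
    push("    if tau == %s", .num(e$time))
    for (a in e$actions) {
      if (a$op == "add") {
        push("      y(%d) = y(%d) + %s;", a$idx, a$idx, .num(a$amount))
      } else {
        push("      moved = %s * y(%d);", .num(a$fraction), a$src)
        push("      y(%d) = y(%d) - moved;", a$src, a$src)
        push("      y(%d) = y(%d) + moved * %s;", a$dst, a$dst, .num(a$vratio))
        push("      armed(%d) = true;", a$arm)
      }
    }
    push("    end")
  }
  push("  end")
  push("  function v = mm(kcat, E, S, Km)")
  push("    if S == 0 || Km + S == 0; v = 0; else; v = kcat * E * S / (Km + S); end")
  push("  end")
  push("  function v = spline_eval(s, t)")
  push("    k = s.knots; tt = min(max(t, k(1)), k(end));")
  push("    i = find(k <= tt, 1, 'last'); i = min(max(i, 1), numel(k) - 1);")
  push("    dt = tt - k(i); cf = s.coefs;")
  push("    v = max(cf(i,1) + dt*(cf(i,2) + dt*(cf(i,3) + dt*cf(i,4))), 0);")
  push("  end")
  push("end")
  paste(out, collapse = "\n")
}

## Python template: scipy.integrate.solve_ivp (LSODA), same piecewise scheme.
.emit_python <- function(plan) {
  asm <- plan$asm
  n <- length(asm$stateNames)
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))
  flux <- function(j) switch(asm$kind[j],
    first_order = sprintf("(%s * y[%d])", .num(asm$k1[j]), asm$sidx[j] - 1L),
    mm = sprintf("mm(%s, y[%d], y[%d], %s)", .num(asm$kcat[j]), asm$eidx[j] - 1L,
                 asm$sidx[j] - 1L, .num(asm$Km[j])),
    translation = sprintf("(%s * spline_eval(SPLINES[\"%s\"], t))",
                          .num(asm$k1[j]), asm$gene[j]),
    multi = {
      m <- asm$multi[[j]]
      sprintf("(%s * %s)", .num(asm$k1[j]),
              paste(sprintf("y[%d]**%s", m$idx - 1L, .num(m$stoich)), collapse = " * "))
    })
  push("#!/usr/bin/env python")
  push("# Standalone cell-type-selective kinetic model (generated code, dialect 'python').")
  push("import sys")
  push("import numpy as np")
  push("from scipy.integrate import solve_ivp")
  push("STATES = [%s]", paste(sprintf("\"%s\"", asm$stateNames), collapse = ", "))
  push("Y0 = np.array([%s])", paste(.num(unname(asm$y0)), collapse = ", "))
  push("GRID = np.array([%s])", paste(.num(plan$grid), collapse = ", "))
  push("SPLINES = {")
  for (g in names(plan$profiles)) {
    p <- plan$profiles[[g]]
    push("  \"%s\": (np.array([%s]), np.array([%s]).reshape(4, -1).T),", g,
         paste(.num(p@knots), collapse = ", "),
         paste(.num(as.vector(p@coefs)), collapse = ", "))
  }
  push("}")
  push("ARMED = [False] * %d", max(1L, length(plan$returns)))
  push("def spline_eval(s, t):")
  push("    k, cf = s")
  push("    tt = min(max(t, k[0]), k[-1])")
  push("    i = int(np.searchsorted(k, tt, side='right')) - 1")
  push("    i = min(max(i, 0), len(k) - 2)")
  push("    dt = tt - k[i]")
  push("    return max(cf[i, 0] + dt * (cf[i, 1] + dt * (cf[i, 2] + dt * cf[i, 3])), 0.0)")
  push("def mm(kcat, E, S, Km):")
  push("    if S == 0 or Km + S == 0:")
  push("        return 0.0")
  push("    return kcat * E * S / (Km + S)")
  push("def rhs(t, y):")
  push("    d = np.zeros(%d)", n)
  for (i in seq_len(n)) {
    terms <- character(0)
    for (j in seq_len(asm$nr))
      if (asm$M[i, j] != 0)
        terms <- c(terms, sprintf("%s * %s", .num(asm$M[i, j]), flux(j)))
    for (k in seq_along(plan$returns)) {
      r <- plan$returns[[k]]
      fx <- sprintf("(ARMED[%d] * %s * y[%d])", k - 1L, .num(r$k_ret), r$dst - 1L)
      if (r$dst == i) terms <- c(terms, sprintf("-1 * %s", fx))
      if (r$src == i) terms <- c(terms, sprintf("%s * %s", .num(r$vratio_back), fx))
    }
    push("    d[%d] = %s", i - 1L, if (length(terms)) paste(terms, collapse = " + ") else "0.0")
  }
  push("    return d")
  push("def apply_events(tau, y):")
  push("    y = y.copy()")
  if (!length(plan$events)) push("    return y") else {
    for (e in plan$events) {
      push("    if tau == %s:", .num(e$time))
      for (a in e$actions) {
        if (a$op == "add") {
          push("        y[%d] += %s", a$idx - 1L, .num(a$amount))
        } else {
          push("        moved = %s * y[%d]", .num(a$fraction), a$src - 1L)
          push("        y[%d] -= moved", a$src - 1L)
          push("        y[%d] += moved * %s", a$dst - 1L, .num(a$vratio))
          push("        ARMED[%d] = True", a$arm - 1L)
        }
      }
    }
    push("    return y")
  }
  bounds <- sort(unique(c(0, vapply(plan$events, `[[`, numeric(1), "time"), plan$tEnd)))
  push("BOUNDS = [%s]", paste(.num(bounds), collapse = ", "))
  push("def run():")
  push("    y = apply_events(0.0, Y0)")
  push("    out = np.full((len(GRID), %d), np.nan)", n)
  push("    if GRID[0] == 0:")
  push("        out[0, :] = y")
  push("    for t0, t1 in zip(BOUNDS[:-1], BOUNDS[1:]):")
  push("        segg = GRID[(GRID > t0) & (GRID <= t1)]")
  push("        times = np.unique(np.concatenate(([t0], segg, [t1])))")
  push("        sol = solve_ivp(rhs, (t0, t1), y, method='LSODA', t_eval=times,")
  push("                        rtol=%s, atol=%s)", .num(plan$rtol), .num(plan$atol))
  push("        yy = np.clip(sol.y.T, 0.0, None)")
  push("        for i, tv in enumerate(times):")
  push("            hit = np.nonzero(GRID == tv)[0]")
  push("            if hit.size and tv > t0:")
  push("                out[hit[0], :] = yy[i, :]")
  push("        y = apply_events(t1, yy[-1, :])")
  push("    return out")
  push("if __name__ == '__main__':")
  push("    out = run()")
  push("    dest = open(sys.argv[1], 'w') if len(sys.argv) > 1 else sys.stdout")
  push("    dest.write('time_h\\t' + '\\t'.join(STATES) + '\\n')")
  push("    for i, t in enumerate(GRID):")
  push("        dest.write('%%.17g' %% t + '\\t' + '\\t'.join('%%.17g' %% v for v in out[i]) + '\\n')")
  paste(out, collapse = "\n")
}

assign("r", .emit_r, envir = .dialect_registry)
assign("matlab", .emit_matlab, envir = .dialect_registry)
assign("python", .emit_python, envir = .dialect_registry)

#' Emit a standalone solver program for a model
#'
#' Renders the model as a self-contained executable script in the requested
#' dialect: all kinetic parameters, spline knots and coefficients, the event
#' schedule and the output grid are embedded numerically, so the program
#' needs only its target environment's standard ODE solver. Emission is a
#' pure function of (model, dialect, grid settings): repeated calls give
#' byte-identical sources and checksums. The `"r"` dialect is the reference
#' one, executable in the package's own environment; `"matlab"` (also runs
#' under Octave) and `"python"` (scipy) templates target external
#' environments.
#'
#' @param model a [DynamicModel-class]
#' @param dialect dialect id, see [registeredDialects()]
#' @param tEnd simulation end time (hours)
#' @param grid output grid; default as in [simulateModel()]
#' @param rtol,atol solver tolerances embedded in the program
#' @return a [GeneratedProgram-class]
#' @export
emitScript <- function(model, dialect = "r", tEnd = 24, grid = NULL,
                       rtol = 1e-8, atol = 1e-10) {
  if (!dialect %in% registeredDialects())
    stop(sprintf("unknown dialect '%s'; registered dialects: %s", dialect,
                 paste(registeredDialects(), collapse = ", ")), call. = FALSE)
  plan <- .emission_plan(model, tEnd, grid, rtol, atol)
  src <- get(dialect, envir = .dialect_registry)(plan)
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(src, tf)
  new("GeneratedProgram", dialect = dialect, source = src,
      manifest = plan$manifest, checksum = unname(tools::md5sum(tf)))
}

#' Execute a generated reference-dialect program
#'
#' Writes the program to disk and runs it with `Rscript`, returning the
#' trajectory table it produces. Only the `"r"` reference dialect can be
#' executed here; other dialects target external environments.
#'
#' @param program a [GeneratedProgram-class]
#' @param dir directory to run in (default a fresh temporary directory)
#' @return data.frame with `time_h` plus one column per state
#' @export
runGeneratedProgram <- function(program, dir = tempfile("codegen")) {
  if (program@dialect != "r")
    stop(sprintf("dialect '%s' targets an external environment; only 'r' runs here",
                 program@dialect), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  script <- file.path(dir, "model.R")
  outfile <- file.path(dir, "trajectory.tsv")
  writeLines(program@source, script)
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(script, outfile), stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outfile))
    stop("generated program failed to execute", call. = FALSE)
  readTrajectoryTable(outfile)
}

#' Verify emitted-program fidelity against the internal engine
#'
#' Compares an external trajectory table (produced by a generated program)
#' with the internal [SimulationResult-class] on a matching grid. The
#' deviation of each state variable is normalized by that variable's
#' trajectory maximum; the check passes when every variable stays below
#' `tol`.
#'
#' @param internal a [SimulationResult-class]
#' @param external data.frame with `time_h` plus one column per state
#' @param tol maximum tolerated normalized deviation (default 1e-6)
#' @return data.frame (`variable`, `maxRelDev`, `pass`) with attribute
#'   `pass` giving the overall verdict
#' @export
verifyRoundtrip <- function(internal, external, tol = 1e-6) {
  if (!isTRUE(all.equal(internal@time, external$time_h, tolerance = 1e-12)))
    stop("grids of internal and external trajectories differ", call. = FALSE)
  vars <- colnames(internal@states)
  miss <- setdiff(vars, colnames(external))
  if (length(miss))
    stop("external table lacks state column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dev <- vapply(vars, function(v) {
    a <- internal@states[, v]; b <- external[[v]]
    max(abs(a - b)) / max(max(abs(a)), 1e-12)
  }, numeric(1))
  rep <- data.frame(variable = vars, maxRelDev = unname(dev),
                    pass = unname(dev) < tol, stringsAsFactors = FALSE)
  attr(rep, "pass") <- all(rep$pass)
  rep
}
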