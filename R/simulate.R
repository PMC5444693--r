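# ODE compilation and piecewise-event integration. Signaling models are
# routinely stiff, so the default integrator is LSODA (adaptive, switches to
# BDF on stiffness) with tight tolerances; interventions are applied as exact
# state/parameter discontinuities with an integrator restart.

#' Compile a reaction network into rate and derivative functions
#'
#' Builds (i) a velocity function evaluating every kinetic law at a state and
#' (ii) the derivative function dc/dt = S v, where S is the net stoichiometry
#' matrix (products minus reactants) with boundary-species rows zeroed.
#'
#' @param net A valid [reaction_network()].
#' @return A list with elements `rates(t, conc, params)` (nM/min per
#'   reaction), `deriv(t, conc, params)` (nM/min per species), the
#'   stoichiometry matrix `stoich`, and the id vectors `species_ids`,
#'   `reaction_ids`.
#' @export
compile_odes <- function(net) {
  validate_network(net)
  sids <- net$species$id
  pids <- names(net$parameters)
  known <- c(sids, pids, names(net$compartments), "time", "pi")
  for (rx in net$reactions) {
    free <- if (is.numeric(rx$kinetic_law)) character() else all.vars(rx$kinetic_law)
    bad <- setdiff(free, known)
    if (length(bad))
      stop("cannot compile reaction '", rx$id, "': unresolvable symbol(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  S <- stoichiometry_matrix(net)
  exprs <- lapply(net$reactions, `[[`, "kinetic_law")
  rate_call <- as.call(c(quote(c), exprs))
  comp <- as.list(net$compartments)
  nrx <- length(exprs)
  rates <- function(t, conc, params) {
    if (nrx == 0L) return(numeric())
    env <- c(as.list(conc), as.list(params), comp, list(time = t))
    as.numeric(eval(rate_call, env))
  }
  deriv <- function(t, conc, params) {
    if (nrx == 0L) return(numeric(length(conc)))
    as.numeric(S %*% rates(t, conc, params))
  }
  list(rates = rates, deriv = deriv, stoich = S,
       species_ids = sids, reaction_ids = reaction_ids(net))
}

#' Simulate a network under an intervention regime
#'
#' Integrates the compiled ODE system piecewise between consecutive
#' intervention times: each intervention is applied as an instantaneous
#' state/parameter discontinuity and the integrator is restarted from the
#' post-discontinuity state. Concentrations and reaction velocities are
#' sampled onto a uniform time grid; at a grid point coinciding with an
#' intervention the post-discontinuity values are reported.
#'
#' @param net A [reaction_network()].
#' @param rg A [regime()]; the default empty regime is the untreated control.
#' @param t_end Simulation horizon, minutes (> 0).
#' @param n_points Number of uniform grid points including both endpoints
#'   (>= 2); default 601.
#' @param rtol,atol Relative/absolute integrator tolerances (nM for `atol`).
#' @param method deSolve integration method; default `"lsoda"`.
#' @param hmax Maximum internal step size, minutes; defaults to the grid
#'   spacing, which makes the solver trace depend only on the grid and the
#'   state (not on the horizon), so runs sharing a grid are bitwise
#'   reproducible up to their first differing intervention.
#' @return An object of class `"trajectory"`: the time grid (minutes), a
#'   species-by-time concentration matrix (nM, clipped at 0), a
#'   reaction-by-time velocity matrix (nM/min), the regime label and solver
#'   settings.
#' @export
simulate_network <- function(net, rg = regime(), t_end = 10, n_points = 601,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda",
                             hmax = NULL) {
  stopifnot(t_end > 0, n_points >= 2)
  if (is.null(hmax)) hmax <- t_end / (n_points - 1)
  rg <- validate_regime(rg, net, t_end)
  ode <- compile_odes(net)
  grid <- seq(0, t_end, length.out = n_points)
  nsp <- length(ode$species_ids)
  conc_out <- matrix(NA_real_, nsp, n_points,
                     dimnames = list(ode$species_ids, NULL))
  vel_out <- matrix(NA_real_, length(ode$reaction_ids), n_points,
                    dimnames = list(ode$reaction_ids, NULL))

  conc <- stats::setNames(net$species$initial_concentration, ode$species_ids)
  params <- net$parameters

  iv_times <- vapply(rg$interventions, `[[`, 0, "time")
  apply_at <- function(tt, conc, params) {
    for (iv in rg$interventions[iv_times == tt]) {
      st <- apply_intervention(conc, params, iv)
      conc <- st$conc; params <- st$params
    }
    list(conc = conc, params = params)
  }

  # t = 0 interventions take effect before integration starts
  if (any(iv_times == 0)) {
    st <- apply_at(0, conc, params)
    conc <- st$conc; params <- st$params
  }
  boundaries <- unique(c(0, sort(iv_times[iv_times > 0 & iv_times < t_end]),
                         t_end))
  record <- function(idx, tt, conc, params) {
    conc_out[, idx] <<- conc
    vel_out[, idx] <<- ode$rates(tt, conc, params)
  }
  record(1L, 0, conc, params)

  rhs <- function(t, y, p) list(ode$deriv(t, y, p))
  eps <- 1e-9 * max(t_end, 1)
  for (k in seq_len(length(boundaries) - 1L)) {
    a <- boundaries[k]; b <- boundaries[k + 1L]
    inside <- which(grid > a + eps & grid < b - eps)
    times <- unique(c(a, grid[inside], b))
    sol <- tryCatch(
      deSolve::ode(y = conc, times = times, func = rhs, parms = params,
                   method = method, rtol = rtol, atol = atol, hmax = hmax),
      warning = function(w) stop("simulation error in [", a, ", ", b,
                                 "] min: ", conditionMessage(w), call. = FALSE))
    if (nrow(sol) < length(times))
      stop("simulation error: integrator stopped at t=",
           sol[nrow(sol), 1], " min", call. = FALSE)
    ymat <- sol[, ode$species_ids, drop = FALSE]
    for (ii in seq_along(inside))
      record(inside[ii], grid[inside[ii]],
             stats::setNames(ymat[1L + ii, ], ode$species_ids), params)
    conc <- stats::setNames(ymat[nrow(ymat), ], ode$species_ids)
    if (b %in% iv_times) {
      st <- apply_at(b, conc, params)
      conc <- st$conc; params <- st$params
    }
    # grid point at (or numerically at) the segment end
    gi <- which(abs(grid - b) <= eps)
    if (length(gi)) record(gi[1], b, conc, params)
  }

  neg <- min(conc_out)
  if (neg < -100 * atol)
    warning("concentrations reached ", signif(neg, 3),
            " nM below zero; clipped to 0 in the reported trajectory")
  conc_out[conc_out < 0] <- 0

  structure(list(time = grid, conc = conc_out, vel = vel_out,
                 regime_label = rg$label, network_id = net$id,
                 settings = list(t_end = t_end, n_points = n_points,
                                 rtol = rtol, atol = atol, method = method,
                                 hmax = hmax)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> regime '", x$regime_label, "' on model '", x$network_id,
      "': ", nrow(x$conc), " species x ", length(x$time), " time points over [0, ",
      x$settings$t_end, "] min\n", sep = "")
  invisible(x)
}

#' Integrated signal of a species over a time window
#'
#' Trapezoidal integral of a species' concentration over `[t0, t1]`, the
#' scalar pathway-activity readout used for inset summaries (e.g. integrated
#' AKT signaling). Window endpoints off the grid are linearly interpolated.
#'
#' @param traj A [simulate_network()] trajectory.
#' @param species_id Species id.
#' @param window Numeric `c(t0, t1)` within `[0, t_end]`; defaults to the
#'   full run.
#' @return The integral in nM·min.
#' @export
integrated_signal <- function(traj, species_id,
                              window = range(traj$time)) {
  stopifnot(inherits(traj, "trajectory"), length(window) == 2L)
  if (!species_id %in% rownames(traj$conc))
    stop("unknown species '", species_id, "'", call. = FALSE)
  t0 <- window[1]; t1 <- window[2]
  if (t0 < min(traj$time) - 1e-12 || t1 > max(traj$time) + 1e-12 || t1 < t0)
    stop("window must lie within [0, t_end]", call. = FALSE)
  y <- traj$conc[species_id, ]
  inside <- traj$time > t0 & traj$time < t1
  tt <- c(t0, traj$time[inside], t1)
  yy <- c(stats::approx(traj$time, y, t0)$y, y[inside],
          stats::approx(traj$time, y, t1)$y)
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

# ---- trajectory CSV round-trip ----------------------------------------------

#' Write a trajectory as CSV tables plus a JSON sidecar
#'
#' Emits `<prefix>_concentrations.csv` and `<prefix>_velocities.csv` (wide
#' tables: first column `time_min`, one column per species/reaction) and
#' `<prefix>_meta.json` recording the regime label and solver settings.
#'
#' @param traj A trajectory.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "trajectory"))
  wide <- function(m) {
    df <- data.frame(time_min = traj$time)
    for (i in seq_len(nrow(m))) df[[rownames(m)[i]]] <- m[i, ]
    df
  }
  pc <- paste0(prefix, "_concentrations.csv")
  pv <- paste0(prefix, "_velocities.csv")
  pm <- paste0(prefix, "_meta.json")
  utils::write.csv(wide(traj$conc), pc, row.names = FALSE, quote = FALSE)
  utils::write.csv(wide(traj$vel), pv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(regime_label = traj$regime_label, network_id = traj$network_id,
         settings = traj$settings),
    pm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pc, pv, pm))
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param prefix The path prefix used when writing.
#' @return A `trajectory` equal to the original within CSV formatting
#'   precision.
#' @export
read_trajectory <- function(prefix) {
  pc <- paste0(prefix, "_concentrations.csv")
  pv <- paste0(prefix, "_velocities.csv")
  pm <- paste0(prefix, "_meta.json")
  for (p in c(pc, pv, pm))
    if (!file.exists(p)) stop("missing trajectory file: ", p, call. = FALSE)
  dc <- utils::read.csv(pc, check.names = FALSE)
  dv <- utils::read.csv(pv, check.names = FALSE)
  meta <- jsonlite::read_json(pm, simplifyVector = TRUE)
  tall <- function(df) {
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    rownames(m) <- colnames(df)[-1]
    colnames(m) <- NULL
    m
  }
  structure(list(time = dc$time_min, conc = tall(dc), vel = tall(dv),
                 regime_label = meta$regime_label,
                 network_id = meta$network_id,
                 settings = as.list(meta$settings)),
            class = "trajectory")
}
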