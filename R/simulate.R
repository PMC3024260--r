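#' Simulation time grid
#'
#' Strictly increasing times in seconds starting at 0. The study grid is
#' `seq(0, 12600, by = 100)` (0 to 3.5 h every 100 s); in-silico experiments
#' that look beyond the data window extend `t_max` (e.g. 5 h for the C4BP
#' titration).
#'
#' @param t_max final time (s).
#' @param by grid step (s).
#' @return numeric vector of time points.
#' @export
time_grid <- function(t_max = 12600, by = 100) {
  g <- seq(0, t_max, by = by)
  if (g[length(g)] < t_max) g <- c(g, t_max)
  g
}

check_grid <- function(grid) {
  if (length(grid) < 1 || grid[1] != 0 || is.unsorted(grid, strictly = TRUE))
    stop("time grid must start at 0 and increase strictly")
  grid
}

#' Integrate the network ODEs on a time grid
#'
#' Stiff-capable numerical integration (via [deSolve::lsoda()], which
#' switches between Adams and BDF methods automatically) of the network ODEs,
#' evaluated at the grid points. Small integrator undershoots below zero are
#' clipped to 0 on output; undershoots beyond `-1e-9` nM are flagged with a
#' warning. When the network declares conservation groups their sums are
#' checked to stay constant within relative tolerance `1e-6`.
#'
#' @param network a `reaction_network` with all parameters resolved (or
#'   resolved through `params`).
#' @param grid time grid from [time_grid()].
#' @param initial_overrides named vector replacing selected initial
#'   concentrations.
#' @param params optional named vector overriding registered parameter
#'   values.
#' @param rtol,atol integrator tolerances (defaults 1e-8, 1e-12 nM).
#' @param check_conservation logical.
#' @return A `trajectory`: list with `grid` and `values`
#'   (species x time matrix, nM).
#' @export
simulate <- function(network, grid = time_grid(),
                     initial_overrides = NULL, params = NULL,
                     rtol = 1e-8, atol = 1e-12,
                     check_conservation = TRUE) {
  check_grid(grid)
  x0 <- initial_state(network, initial_overrides)
  p <- param_values(network)
  if (!is.null(params)) {
    i <- match(names(params), names(p))
    if (anyNA(i)) stop("unknown parameter names in 'params'")
    p[i] <- unname(params)
  }
  if (anyNA(p)) stop("unresolved UNKNOWN parameters")
  rhs <- ode_rhs(network)
  sol <- deSolve::lsoda(y = x0, times = grid,
                        func = function(t, y, parms) rhs(t, y, parms),
                        parms = p, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failure (istate ", attr(sol, "istate")[1],
         ") with parameters: ",
         paste(names(p), signif(p, 4), sep = "=", collapse = ", "))
  vals <- t(unclass(sol)[, -1, drop = FALSE])
  rownames(vals) <- names(x0)
  if (min(vals) < -1e-9)
    warning("integrator undershoot below -1e-9 nM (min ",
            signif(min(vals), 3), "); clipped to 0")
  vals[vals < 0] <- 0
  traj <- structure(list(grid = grid, values = vals,
                         species = names(x0)), class = "trajectory")
  if (check_conservation && length(network$conservation)) {
    for (g in names(network$conservation)) {
      s <- colSums(vals[network$conservation[[g]], , drop = FALSE])
      ref <- max(abs(s[1]), atol)
      if (max(abs(s - s[1])) > 1e-6 * ref)
        warning("conservation group '", g, "' drifts by relative ",
                signif(max(abs(s - s[1])) / ref, 3))
    }
  }
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$species), "species x", length(x$grid),
      "time points, t in [0,", x$grid[length(x$grid)], "] s\n")
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x a `trajectory`.
#' @param ... unused.
#' @return data.frame with columns `time_s`, `species`, `concentration_nM`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = rep(x$grid, each = length(x$species)),
             species = rep(x$species, length(x$grid)),
             concentration_nM = as.vector(x$values))
}

#' Extract a species or observable series from a trajectory
#'
#' Observables declared on the network (named species sums such as total
#' deposited C4) are resolved against the trajectory rows.
#'
#' @param traj a `trajectory`.
#' @param what species name or observable name.
#' @param network optional network supplying observable definitions.
#' @return numeric vector over the grid.
#' @export
series <- function(traj, what, network = NULL) {
  if (what %in% traj$species) return(traj$values[what, ])
  if (!is.null(network) && what %in% names(network$observables)) {
    g <- network$observables[[what]]
    return(colSums(traj$values[g, , drop = FALSE]))
  }
  stop("no species or observable named '", what, "'")
}

#' Response summaries of a deposition time course
#'
#' `peak_amplitude` is the maximum over the grid; `peak_time` the earliest
#' time attaining it (ties broken towards the earliest grid point);
#' `integrated_response` the trapezoidal area under the curve, the
#' overall-activity summary used alongside the peak.
#'
#' @param traj a `trajectory`.
#' @param what species or observable name.
#' @param network optional network for observables.
#' @return list with `peak_amplitude` (nM), `peak_time` (s),
#'   `integrated_response` (nM s).
#' @export
summarize <- function(traj, what, network = NULL) {
  y <- series(traj, what, network)
  if (!length(y)) stop("empty grid")
  i <- which.max(y)  # which.max returns the first maximum
  list(peak_amplitude = unname(y[i]), peak_time = unname(traj$grid[i]),
       integrated_response = trapz(traj$grid, y))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Normalise a panel of C3 endpoints into predicted killing rates
#'
#' Deposited C3 at the endpoint predicts the antibacterial activity; the
#' panel is normalised so that its maximum equals `max_rate` percent (95 by
#' default, the maximum bacterial killing rate reported for the validation
#' experiments): `rate = max_rate * value / max(values)`.
#'
#' @param values named numeric vector of deposited C3 endpoint values per
#'   condition (nM).
#' @param max_rate percent assigned to the panel maximum.
#' @return list with `rates` (named percent vector) and `argmax` (name of
#'   the maximal condition).
#' @export
killing_panel <- function(values, max_rate = 95) {
  if (!length(values)) stop("empty panel")
  m <- max(values)
  if (m <= 0) stop("all panel endpoint values are zero")
  list(rates = max_rate * values / m,
       argmax = names(values)[which.max(values)])
}
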