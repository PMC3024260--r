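# Dynamic Bayesian network approximation of the ODE dynamics.
#
# The DBN is a two-slice, time-variant factored Markov chain: one node per
# species and per unknown parameter at each grid time point. Value spaces
# are discretised (6 quantile intervals for variables, 5 equal intervals for
# parameters); trajectories sampled from the prior are binned, and each
# node's conditional probability table for the slice t -> t+1 is obtained by
# counting interval transitions given the parent-interval assignment.
# Parameter nodes keep their initial value forever, so their CPTs are exact
# identities and are never stored explicitly.

#' Derive the DBN parent structure from a network
#'
#' A species node's parents at slice t are itself plus every node (species
#' or unknown parameter) appearing on the right-hand side of its ODE:
#' reactants and Michaelis-Menten modifiers of every active reaction that
#' produces or consumes it, and the unknown rate constants of those
#' reactions. A parameter node's only parent is itself.
#'
#' @param network a `reaction_network`.
#' @return A `dbn_structure`: list with `parents` (named list), and the node
#'   bookkeeping (`species_nodes`, `param_nodes`, `u_max` the maximal number
#'   of unknown parameters in one equation).
#' @export
derive_structure <- function(network) {
  cn <- compile_network(network)
  unknown <- network$params$name[!network$params$known]
  parents <- setNames(vector("list", cn$n), cn$species)
  n_unknown_eq <- setNames(integer(cn$n), cn$species)
  for (i in seq_len(cn$n)) parents[[i]] <- cn$species[i]
  for (r in cn$rx) {
    touched <- cn$species[unique(c(r$ridx, r$pidx))]
    dep_sp <- cn$species[unique(c(r$ridx, if (r$eidx > 0L) r$eidx))]
    dep_par <- intersect(c(r$pk, r$pc, r$pch), unknown)
    for (s in touched)
      parents[[s]] <- union(parents[[s]], c(dep_sp, dep_par))
  }
  for (s in cn$species)
    n_unknown_eq[s] <- length(intersect(parents[[s]], unknown))
  for (p in unknown) parents[[p]] <- p
  structure(list(parents = parents, species_nodes = cn$species,
                 param_nodes = unknown, u_max = max(0L, n_unknown_eq),
                 n_unknown_eq = n_unknown_eq),
            class = "dbn_structure")
}

#' Per-equation coverage heuristic for the trajectory count
#'
#' The number of sampled trajectories is chosen so that, for the equation
#' with the most unknown parameters, every combination of parameter
#' intervals receives a minimum expected coverage of `K` samples:
#' `J = K * I^u` with `I` intervals per parameter and `u` the maximal number
#' of unknowns per equation.
#'
#' @param I intervals per parameter (>= 2).
#' @param u maximal unknown parameters per equation (>= 0).
#' @param K minimum coverage per interval combination (default 5).
#' @param cap guard against runaway sample counts; exceeding it errors
#'   unless `override = TRUE`.
#' @param override allow J above the cap.
#' @return integer-valued sample count J.
#' @export
required_samples <- function(I, u, K = 5, cap = 1e7, override = FALSE) {
  stopifnot(I >= 2, u >= 0, K >= 1)
  J <- K * I^u
  if (J > cap && !override)
    stop("required sample count ", format(J, scientific = TRUE),
         " exceeds the cap (", format(cap, scientific = TRUE),
         "); pass override = TRUE to proceed")
  J
}

#' Default sampling prior of a network
#'
#' Initial concentrations are treated as known (point priors at the declared
#' initials); unknown parameters get uniform priors over their registered
#' bounds. Individual entries can be replaced to widen initial-state
#' uncertainty or narrow a parameter.
#'
#' @param network a `reaction_network`.
#' @return named list of prior entries (`point`, `range` or `interval`).
#' @export
default_prior <- function(network) {
  pr <- list()
  for (i in seq_len(nrow(network$species)))
    pr[[network$species$name[i]]] <-
      list(type = "point", value = network$species$init[i])
  unk <- which(!network$params$known)
  for (i in unk)
    pr[[network$params$name[i]]] <-
      list(type = "range", lo = network$params$lo[i],
           hi = network$params$hi[i])
  pr
}

sample_prior_node <- function(entry, J) {
  switch(entry$type,
         point = rep(entry$value, J),
         range = runif(J, entry$lo, entry$hi),
         interval = {
           b <- entry$boundaries
           k <- sample.int(length(entry$probs), J, replace = TRUE,
                           prob = entry$probs)
           runif(J, b[k], b[k + 1])
         },
         stop("unknown prior type: ", entry$type))
}

#' Discretise variable and parameter value spaces
#'
#' Parameters get `n_param` equal-width intervals over their registered
#' bounds. Variables get `n_var` equal-frequency intervals at the quantile
#' boundaries of the pooled pilot-ensemble values; duplicated boundaries are
#' collapsed (reducing the interval count) and a constant-valued variable is
#' stored as a single degenerate interval and flagged.
#'
#' @param network a `reaction_network`.
#' @param pilot result of [pilot_ensemble()] (required unless every variable
#'   has an explicit boundary override).
#' @param n_var,n_param interval counts for variables / parameters.
#' @param boundaries named list of explicit boundary overrides.
#' @return A `discretization`: named list of
#'   `list(boundaries, kind, degenerate)` per node.
#' @export
make_discretization <- function(network, pilot = NULL, n_var = 6,
                                n_param = 5, boundaries = NULL) {
  disc <- list()
  for (s in network$species$name) {
    if (!is.null(boundaries[[s]])) {
      b <- sort(unique(boundaries[[s]]))
    } else {
      if (is.null(pilot)) stop("variable ", s, " needs pilot values or an override")
      v <- as.vector(pilot$values[, match(s, pilot$species), ])
      b <- unique(quantile(v, probs = seq(0, 1, length.out = n_var + 1),
                           names = FALSE))
    }
    disc[[s]] <- list(boundaries = b, kind = "variable",
                      degenerate = length(b) < 2)
    if (length(b) < 2) disc[[s]]$boundaries <- c(b, b)
  }
  unk <- which(!network$params$known)
  for (i in unk) {
    nm <- network$params$name[i]
    b <- if (!is.null(boundaries[[nm]])) sort(unique(boundaries[[nm]]))
    else seq(network$params$lo[i], network$params$hi[i],
             length.out = n_param + 1)
    disc[[nm]] <- list(boundaries = b, kind = "parameter",
                       degenerate = length(b) < 2)
  }
  structure(disc, class = "discretization")
}

n_intervals <- function(disc, node) {
  d <- disc[[node]]
  if (d$degenerate) 1L else length(d$boundaries) - 1L
}

interval_midpoints <- function(disc, node) {
  d <- disc[[node]]
  if (d$degenerate) return(d$boundaries[1])
  b <- d$boundaries
  (head(b, -1) + tail(b, -1)) / 2
}

code_values <- function(disc, node, x) {
  d <- disc[[node]]
  if (d$degenerate) return(rep(1L, length(x)))
  b <- d$boundaries
  m <- length(b) - 1L
  ## inner boundaries only: out-of-range values clamp into the edge intervals
  pmin(pmax(findInterval(x, b[-c(1L, length(b))]) + 1L, 1L), m)
}

code_matrix <- function(disc, X, nodes) {
  out <- matrix(0L, nrow(X), length(nodes))
  for (j in seq_along(nodes)) out[, j] <- code_values(disc, nodes[j], X[, j])
  out
}

#' Pilot ensemble for range discovery
#'
#' A small trajectory ensemble (values kept) used to place the variable
#' interval boundaries where the dynamics actually live. Trajectories on
#' which the integrator fails are redrawn from the prior.
#'
#' @inheritParams sample_trajectories
#' @param J pilot size (default 200).
#' @return list with `values` (J x species x time array), `species`, `grid`.
#' @export
pilot_ensemble <- function(network, prior = default_prior(network), J = 200,
                           grid = time_grid(), seed = 1, substeps = 10L,
                           integrator = "rk4", ...) {
  set.seed(seed)
  out <- integrate_with_redraw(network, prior, J, grid, substeps, integrator,
                               ...)
  list(values = out$values, species = out$species, grid = grid,
       redraws = out$redraws)
}

## draw from the prior, integrate, and redraw failed trajectories (up to a
## bounded number of rounds); the redraw count is reported
integrate_with_redraw <- function(network, prior, J, grid, substeps,
                                  integrator, max_rounds = 10L, ...) {
  draws <- draw_initials(network, prior, J)
  out <- ensemble_simulate(network, draws$X0, draws$P, grid,
                           substeps = substeps, integrator = integrator, ...)
  redraws <- 0L
  round <- 0L
  while (any(out$failed) && round < max_rounds) {
    bad <- which(out$failed)
    redraws <- redraws + length(bad)
    nd <- draw_initials(network, prior, length(bad))
    draws$X0[bad, ] <- nd$X0
    draws$P[bad, ] <- nd$P
    sub <- ensemble_simulate(network, nd$X0, nd$P, grid,
                             substeps = substeps, integrator = integrator,
                             ...)
    out$values[bad, , ] <- sub$values
    out$failed[bad] <- sub$failed
    round <- round + 1L
  }
  if (any(out$failed))
    stop(sum(out$failed), " trajectories failed to integrate after ",
         max_rounds, " redraw rounds")
  out$P <- draws$P
  out$redraws <- redraws
  out
}

draw_initials <- function(network, prior, J) {
  sp <- network$species$name
  X0 <- matrix(0, J, length(sp), dimnames = list(NULL, sp))
  for (s in sp) {
    e <- prior[[s]]
    if (is.null(e)) e <- list(type = "point",
                              value = network$species$init[match(s, sp)])
    X0[, s] <- sample_prior_node(e, J)
  }
  pn <- network$params$name
  P <- matrix(rep(network$params$value, each = J), J, length(pn),
              dimnames = list(NULL, pn))
  for (nm in pn[!network$params$known]) {
    e <- prior[[nm]]
    if (!is.null(e)) P[, nm] <- sample_prior_node(e, J)
  }
  if (anyNA(P)) stop("prior leaves unresolved parameters without draws")
  list(X0 = X0, P = P)
}

#' Sample an interval-coded trajectory ensemble
#'
#' Draws `J` initial states and parameter vectors from the prior,
#' integrates all trajectories, redraws failed ones (count reported), and
#' assigns every (node, time) its containing discretisation interval.
#' Values outside the discretised range are clamped into the nearest edge
#' interval.
#'
#' @param network a `reaction_network`.
#' @param prior named list of prior entries (see [default_prior()]).
#' @param disc a `discretization`.
#' @param J ensemble size.
#' @param grid time grid.
#' @param seed RNG seed (the ensemble is a pure function of its arguments).
#' @param substeps RK4 substeps per grid interval.
#' @param integrator `"rk4"` or `"lsoda"` (see [ensemble_simulate()]).
#' @param ... further arguments to [ensemble_simulate()] (tolerances).
#' @return An `ensemble`: interval codes for species (`J x n x T` raw
#'   array) and parameters (`J x p` integer matrix), the per-species
#'   ensemble-mean series, and bookkeeping.
#' @export
sample_trajectories <- function(network, prior, disc, J, grid = time_grid(),
                                seed = 1, substeps = 10L,
                                integrator = "rk4", ...) {
  stopifnot(J >= 1)
  set.seed(seed)
  out <- integrate_with_redraw(network, prior, J, grid, substeps, integrator,
                               ...)
  Tn <- length(grid)
  sp <- out$species
  codes <- array(raw(1), c(J, length(sp), Tn))
  for (ti in seq_len(Tn))
    codes[, , ti] <- as.raw(code_matrix(disc,
                                        matrix(out$values[, , ti], J,
                                               length(sp)), sp))
  mean_mat <- matrix(apply(out$values, c(2, 3), mean), length(sp), Tn,
                     dimnames = list(sp, NULL))
  unk <- network$params$name[!network$params$known]
  pc <- code_matrix(disc, out$P[, unk, drop = FALSE], unk)
  colnames(pc) <- unk
  structure(list(codes = codes, param_codes = pc,
                 species = sp, param_nodes = unk, grid = grid,
                 mean = mean_mat, J = J, seed = seed,
                 redraws = out$redraws), class = "ensemble")
}

#' Count conditional probability tables from a coded ensemble
#'
#' For every species node and every slice t -> t+1, the trajectories are
#' grouped by their parent-interval assignment at t; the CPT row for an
#' observed assignment is the empirical distribution of the node's interval
#' at t+1 within the group, with the group size stored as the row's support.
#' Unseen assignments are not stored (inference falls back to a uniform
#' distribution over the child's intervals, with a counter). Parameter-node
#' CPTs are exact identities by construction and are represented implicitly.
#'
#' @param ensemble an `ensemble` from [sample_trajectories()].
#' @param structure a `dbn_structure` from [derive_structure()].
#' @param disc the `discretization` used for the coding.
#' @param prior the sampling prior (stored for inference initialisation).
#' @param network the underlying network (stored by reference information
#'   only: name and parameter bounds).
#' @return A `dbn` object.
#' @export
count_cpts <- function(ensemble, structure, disc, prior, network = NULL) {
  sp <- ensemble$species
  Tn <- length(ensemble$grid)
  J <- ensemble$J
  codes <- ensemble$codes
  cpts <- setNames(vector("list", length(sp)), sp)
  for (s in sp) {
    si <- match(s, sp)
    pa <- structure$parents[[s]]
    pa_sp <- intersect(pa, sp)
    pa_par <- intersect(pa, ensemble$param_nodes)
    m_child <- n_intervals(disc, s)
    m_pa <- vapply(c(pa_sp, pa_par), function(p) n_intervals(disc, p), 0L)
    wts <- cumprod(c(1, head(m_pa, -1)))
    Ppart <- ensemble$param_codes[, pa_par, drop = FALSE]
    key_par <- if (length(pa_par))
      drop((Ppart - 1L) %*% tail(wts, length(pa_par))) else numeric(J)
    slices <- vector("list", Tn - 1L)
    for (t in seq_len(Tn - 1L)) {
      U <- matrix(0L, J, length(pa_sp))
      for (k in seq_along(pa_sp))
        U[, k] <- as.integer(codes[, match(pa_sp[k], sp), t])
      key <- drop((U - 1L) %*% wts[seq_along(pa_sp)]) + key_par
      child <- as.integer(codes[, si, t + 1L])
      uk <- unique(key)
      rid <- match(key, uk)
      cnt <- matrix(tabulate((rid - 1L) * m_child + child,
                             nbins = length(uk) * m_child),
                    nrow = length(uk), byrow = TRUE)
      sup <- rowSums(cnt)
      first <- match(uk, key)
      rows <- cbind(U[first, , drop = FALSE],
                    Ppart[first, , drop = FALSE])
      dimnames(rows) <- NULL
      slices[[t]] <- list(rows = rows, cpt = cnt / sup, support = sup)
    }
    cpts[[s]] <- list(parents = c(pa_sp, pa_par), slices = slices,
                      m = m_child)
  }
  structure(list(structure = structure, disc = disc, prior = prior,
                 cpts = cpts, grid = ensemble$grid, J = J,
                 seed = ensemble$seed,
                 param_nodes = ensemble$param_nodes,
                 species_nodes = sp,
                 observables = if (!is.null(network)) network$observables,
                 network_name = if (!is.null(network)) network$meta$name),
            class = "dbn")
}

#' @export
print.dbn <- function(x, ...) {
  cat("dbn:", length(x$species_nodes), "species nodes +",
      length(x$param_nodes), "parameter nodes,",
      length(x$grid), "time points, J =", x$J, "\n")
  invisible(x)
}

#' Build a DBN approximation of a network
#'
#' Convenience wrapper: pilot ensemble, discretisation, full coded ensemble,
#' CPT counting. A pure function of its arguments (seeded).
#'
#' @inheritParams sample_trajectories
#' @param n_var,n_param interval counts.
#' @param integrator `"rk4"` or `"lsoda"`.
#' @param pilot_J pilot ensemble size for variable-range discovery.
#' @param boundaries explicit boundary overrides (see
#'   [make_discretization()]).
#' @return a `dbn`.
#' @export
build_dbn <- function(network, prior = default_prior(network), J,
                      grid = time_grid(), seed = 1, n_var = 6, n_param = 5,
                      substeps = 10L, pilot_J = 200, boundaries = NULL,
                      integrator = "rk4", ...) {
  pil <- pilot_ensemble(network, prior, J = pilot_J, grid = grid,
                        seed = seed + 1L, substeps = substeps,
                        integrator = integrator, ...)
  disc <- make_discretization(network, pil, n_var = n_var,
                              n_param = n_param, boundaries = boundaries)
  ens <- sample_trajectories(network, prior, disc, J = J, grid = grid,
                             seed = seed, substeps = substeps,
                             integrator = integrator, ...)
  dbn <- count_cpts(ens, derive_structure(network), disc, prior, network)
  dbn$ensemble_mean <- ens$mean
  dbn$redraws <- ens$redraws
  dbn
}

#' Serialise / restore a DBN
#'
#' JSON serialisation of the full DBN (structure, boundaries, priors, CPT
#' rows with supports). The round trip reproduces CPTs exactly: counts are
#' stored as integers and probabilities re-derived on read.
#'
#' @param dbn a `dbn`.
#' @param path file path.
#' @return `read_dbn` returns the restored `dbn`.
#' @export
write_dbn <- function(dbn, path) {
  enc <- dbn
  enc$cpts <- lapply(dbn$cpts, function(nd) {
    nd$slices <- lapply(nd$slices, function(sl)
      list(rows = sl$rows,
           counts = round(sl$cpt * sl$support),
           support = sl$support))
    nd
  })
  enc$schema_version <- 1L
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_dbn
#' @export
read_dbn <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  dbn <- raw
  dbn$cpts <- lapply(raw$cpts, function(nd) {
    nd$slices <- lapply(nd$slices, function(sl) {
      nr <- length(sl$support)
      rows <- matrix(as.integer(as.matrix(sl$rows)), nrow = nr)
      counts <- matrix(as.numeric(as.matrix(sl$counts)), nrow = nr)
      list(rows = rows, cpt = counts / sl$support,
           support = as.numeric(sl$support))
    })
    nd
  })
  dbn$disc <- structure(lapply(raw$disc, function(d)
    list(boundaries = as.numeric(d$boundaries), kind = d$kind,
         degenerate = isTRUE(d$degenerate))), class = "discretization")
  dbn$structure <- structure(raw$structure, class = "dbn_structure")
  structure(dbn, class = "dbn")
}
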