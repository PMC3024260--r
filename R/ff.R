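# Factored Frontier inference: per-node marginal distributions over
# discretisation intervals are propagated one slice at a time under the
# product-of-marginals approximation of the joint frontier. Evidence is
# incorporated by filtering: at an evidence time the node's marginal is
# multiplied by the evidence indicator and renormalised before propagation.

#' Evidence for factored-frontier inference
#'
#' @param node node name (species or unknown parameter).
#' @param time grid time (s) at which the clamp applies.
#' @param interval interval index to clamp to, or
#' @param value observed numeric value, mapped to its containing interval.
#' @return an evidence entry; combine entries in a plain list.
#' @export
ff_evidence <- function(node, time, interval = NULL, value = NULL) {
  if (is.null(interval) && is.null(value))
    stop("evidence needs an interval index or a value")
  list(node = node, time = time, interval = interval, value = value)
}

prior_marginal <- function(dbn, node) {
  m <- n_intervals(dbn$disc, node)
  e <- dbn$prior[[node]]
  b <- dbn$disc[[node]]$boundaries
  if (is.null(e)) return(rep(1 / m, m))
  switch(e$type,
         point = {
           p <- numeric(m); p[code_values(dbn$disc, node, e$value)] <- 1; p
         },
         range = {
           if (m == 1) return(1)
           lo <- pmax(head(b, -1), e$lo); hi <- pmin(tail(b, -1), e$hi)
           w <- pmax(hi - lo, 0)
           ## prior mass outside the discretised range clamps to the edges
           w[1] <- w[1] + max(b[1] - e$lo, 0)
           w[m] <- w[m] + max(e$hi - b[m + 1], 0)
           if (sum(w) <= 0) stop("prior range outside discretisation: ", node)
           w / sum(w)
         },
         interval = {
           p <- e$probs
           if (length(p) != m) stop("interval prior length mismatch: ", node)
           p / sum(p)
         })
}

#' Factored Frontier forward pass
#'
#' Propagates per-node marginal distributions through the DBN. At t = 0 the
#' marginals equal the prior; the step rule sums, over the stored (observed)
#' parent-interval assignments, the CPT row weighted by the product of the
#' parents' current marginals; see `unseen` for the treatment of the
#' remaining probability mass. Parameter nodes propagate by identity.
#'
#' @param dbn a `dbn`.
#' @param evidence list of [ff_evidence()] entries (filtering only).
#' @param unseen how to treat probability mass on parent assignments never
#'   observed during counting: `"uniform"` (default) spreads the unseen
#'   mass uniformly over the child's intervals — appropriate when the
#'   ensemble covers the parent space well; `"renormalise"` conditions the
#'   frontier on the observed assignments, which keeps the propagated
#'   marginals informative when coverage is sparse (large parent sets, as
#'   in the complement sensitivity screen). The total unseen mass is
#'   reported either way.
#' @return A `marginal_series`: list with `marginals` (node -> intervals x
#'   time matrix), `fallback_mass`, `grid`, `disc`.
#' @export
ff_forward <- function(dbn, evidence = NULL,
                       unseen = c("uniform", "renormalise")) {
  unseen <- match.arg(unseen)
  nodes <- c(dbn$species_nodes, dbn$param_nodes)
  Tn <- length(dbn$grid)
  ev <- list()
  for (e in evidence %||% list()) {
    ti <- match(e$time, dbn$grid)
    if (is.na(ti)) stop("evidence time ", e$time, " not on the grid")
    if (!e$node %in% nodes) stop("evidence on unknown node: ", e$node)
    iv <- e$interval %||% code_values(dbn$disc, e$node, e$value)
    if (iv < 1 || iv > n_intervals(dbn$disc, e$node))
      stop("evidence interval out of range for node ", e$node)
    ev[[length(ev) + 1L]] <- list(node = e$node, ti = ti, iv = iv)
  }
  marg <- setNames(lapply(nodes, function(nd)
    matrix(0, n_intervals(dbn$disc, nd), Tn)), nodes)
  cur <- setNames(lapply(nodes, function(nd) prior_marginal(dbn, nd)), nodes)

  fallback <- 0
  condition_at <- function(cur, ti) {
    for (e in ev) {
      if (e$ti != ti) next
      p <- cur[[e$node]]
      ind <- numeric(length(p)); ind[e$iv] <- 1
      p <- p * ind
      z <- sum(p)
      if (z <= 0)
        stop("contradictory evidence: node ", e$node, " at t = ",
             dbn$grid[ti], " has zero posterior mass")
      cur[[e$node]] <- p / z
    }
    cur
  }

  cur <- condition_at(cur, 1L)
  for (nd in nodes) marg[[nd]][, 1L] <- cur[[nd]]
  for (ti in seq_len(Tn - 1L)) {
    nxt <- cur
    for (s in dbn$species_nodes) {
      nodecpt <- dbn$cpts[[s]]
      sl <- nodecpt$slices[[ti]]
      w <- rep(1, length(sl$support))
      for (k in seq_along(nodecpt$parents)) {
        pm <- cur[[nodecpt$parents[k]]]
        w <- w * pm[sl$rows[, k]]
      }
      p <- drop(crossprod(sl$cpt, w))
      miss <- 1 - sum(w)
      if (miss > 1e-12) {
        fallback <- fallback + miss
        if (unseen == "uniform" || sum(p) <= 0)
          p <- p + max(miss, 1 - sum(p)) / nodecpt$m
      }
      nxt[[s]] <- p / sum(p)
    }
    cur <- condition_at(nxt, ti + 1L)
    for (nd in nodes) marg[[nd]][, ti + 1L] <- cur[[nd]]
  }
  structure(list(marginals = marg, grid = dbn$grid, disc = dbn$disc,
                 fallback_mass = fallback), class = "marginal_series")
}

#' Expected-value time course from marginals
#'
#' The mean of each marginal distribution, using interval midpoints as
#' representatives (a degenerate interval uses its single value).
#'
#' @param marginals a `marginal_series` from [ff_forward()].
#' @param node node name.
#' @return numeric vector over the grid.
#' @export
expected_series <- function(marginals, node) {
  m <- marginals$marginals[[node]]
  if (is.null(m)) stop("no node named '", node, "'")
  mid <- interval_midpoints(marginals$disc, node)
  drop(crossprod(m, mid))
}
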