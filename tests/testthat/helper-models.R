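# Shared fixtures. Everything is generated in code; heavier shared objects
# (the complement DBN used by the sensitivity tests) are built once per
# session and cached.

.cache <- new.env(parent = emptyenv())

## internal helpers used by the oracles
n_intervals <- compdbn:::n_intervals
prior_marginal <- compdbn:::prior_marginal

cached <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

the_affinity <- function() cached("affinity", fit_affinity)
the_complement <- function() cached("complement", complement_model)

## a 2-species toy specification used for construction tests
toy_spec_ab <- function() {
  list(species = data.frame(name = c("A", "B"), role = "fluid-phase",
                            init = c(3, 0)),
       reactions = list(reaction("r1", "A", "B",
                                 rate_law("mass_action", k = "k"))),
       params = data.frame(name = "k", value = 2, lo = 0.1, hi = 10,
                           known = FALSE))
}

## cascade3 with an extra dummy parameter that no reaction references
## (null case for the sensitivity screen)
cascade3_with_dummy <- function() {
  net <- toy_model("cascade3")
  net$params <- rbind(net$params,
                      data.frame(name = "k_dummy", value = 1e-3, lo = 1e-4,
                                 hi = 5.1e-3, known = FALSE))
  net
}

## the parameter-recovery experiment design: three relaxation conditions
## observed densely over half an hour
recovery_design <- function() {
  list(truth = c(k1 = 2.6e-3, k2 = 1.6e-3, k3 = 1.6e-3, k4 = 2.6e-3),
       true_block = c(k1 = 3L, k2 = 2L, k3 = 2L, k4 = 3L),
       conditions = list(base = NULL,
                         bstart = c(A = 0, B = 100, C = 0),
                         cstart = c(A = 0, B = 0, C = 100)),
       grid = time_grid(1800, 100))
}

recovery_dbns <- function() {
  cached("recovery_dbns", function() {
    d <- recovery_design()
    net <- toy_model("cascade3")
    dbns <- lapply(seq_along(d$conditions), function(i)
      build_dbn(realize_condition(net, d$conditions[[i]]), J = 20000,
                grid = d$grid, seed = 10 + i, substeps = 5))
    setNames(dbns, names(d$conditions))
  })
}

## PC-initiated complement DBN for the sensitivity screen: inflammation
## pH/calcium without acute-phase CRP (the response then stays below C3
## exhaustion over the 3.5 h window); 600-sample ensemble on a 600 s
## analysis grid
complement_screen <- function() {
  cached("complement_screen", function() {
    af <- the_affinity()
    netc <- apply_condition(the_complement(),
                            condition(initiation = "PC", pH = 7.1,
                                      calcium = 2.0), af)
    dbn <- build_dbn(netc, J = 600, grid = time_grid(12600, 600), seed = 2,
                     integrator = "lsoda", pilot_J = 120,
                     rtol = 1e-4, atol = 1e-3)
    theta <- param_values(netc)[!netc$params$known]
    ds <- generate_dataset(netc, theta, conditions = list(PC = NULL),
                           observed = list(PC = c("CRP_dep", "C4_dep",
                                                  "C3_dep", "C4BP_dep")),
                           noise = noise_model(cv = 0.1), seed = 5,
                           normalise = FALSE)
    list(net = netc, dbn = dbn, data = ds)
  })
}

## generator for small synthetic DBNs with dense, concentrated CPTs — the
## regime produced by counting near-deterministic dynamics — used to
## compare factored-frontier inference against exact enumeration
random_small_dbn <- function(seed, n_nodes = 3, m = 4, n_steps = 3,
                             concentration = 0.025, deterministic = FALSE) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  disc <- structure(setNames(lapply(nodes, function(nd)
    list(boundaries = seq(0, m, by = 1), kind = "variable",
         degenerate = FALSE)), nodes), class = "discretization")
  parents <- setNames(lapply(seq_along(nodes), function(i)
    unique(c(nodes[i], sample(nodes, 1)))), nodes)
  rdirichlet <- function(n, alpha) {
    g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
                byrow = TRUE)
    g / rowSums(g)
  }
  cpts <- setNames(lapply(nodes, function(nd) {
    pa <- parents[[nd]]
    rows <- as.matrix(do.call(expand.grid, rep(list(seq_len(m)),
                                               length(pa))))
    colnames(rows) <- NULL
    ## counted CPTs inherit the continuity of the dynamics: the child
    ## interval is a smooth stochastic map of the parent intervals
    ## self-dominated maps: cross-node coupling is present but weak, the
    ## regime in which the product-of-marginals frontier is accurate
    wts <- rep(0.12 / max(1, length(pa) - 1), length(pa))
    wts[match(nd, pa)] <- if (length(pa) > 1) 0.88 else 1
    drift <- runif(1, -0.8, 0.8)
    slices <- lapply(seq_len(n_steps), function(t) {
      centre <- pmin(pmax(round(drop(rows %*% wts) + drift), 1), m)
      cpt <- matrix(0, nrow(rows), m)
      if (deterministic) {
        cpt[cbind(seq_len(nrow(rows)), centre)] <- 1
      } else {
        for (i in seq_len(nrow(rows))) {
          c0 <- centre[i]
          cpt[i, c0] <- 1 - concentration * 2
          cpt[i, min(c0 + 1, m)] <- cpt[i, min(c0 + 1, m)] + concentration
          cpt[i, max(c0 - 1, 1)] <- cpt[i, max(c0 - 1, 1)] + concentration
        }
      }
      list(rows = rows, cpt = cpt, support = rep(1, nrow(rows)))
    })
    list(parents = pa, slices = slices, m = m)
  }), nodes)
  prior <- setNames(lapply(nodes, function(nd) {
    ## counted DBNs start from sharply known initial states: a point mass
    ## under deterministic dynamics, a concentrated distribution otherwise
    ## initial states are sharply known (as for counted trajectory
    ## ensembles); one node per net carries a spread prior, playing the
    ## role of an uncertain parameter
    p <- if (deterministic || nd != nodes[1]) {
      z <- numeric(m); z[sample.int(m, 1)] <- 1; z
    } else {
      ## the uncertain node spreads over two adjacent intervals, as a
      ## parameter clamped to a block does
      z <- numeric(m); k <- sample.int(m - 1, 1)
      z[k] <- runif(1, 0.4, 0.8); z[k + 1] <- 1 - z[k]; z
    }
    list(type = "interval", probs = p,
         boundaries = disc[[nd]]$boundaries)
  }), nodes)
  structure(list(structure = structure(list(parents = parents),
                                       class = "dbn_structure"),
                 disc = disc, prior = prior, cpts = cpts,
                 grid = seq(0, n_steps) * 100, J = 1,
                 param_nodes = character(), species_nodes = nodes),
            class = "dbn")
}

## exact inference over a small DBN by full joint enumeration (the oracle
## factored-frontier inference is compared against)
exact_marginals <- function(dbn) {
  nodes <- dbn$species_nodes
  m <- vapply(nodes, function(nd) n_intervals(dbn$disc, nd), 0L)
  states <- as.matrix(do.call(expand.grid, lapply(m, seq_len)))
  colnames(states) <- nodes
  joint <- rep(1, nrow(states))
  for (nd in nodes)
    joint <- joint * prior_marginal(dbn, nd)[states[, nd]]
  Tn <- length(dbn$grid)
  out <- setNames(lapply(nodes, function(nd) matrix(0, m[nd], Tn)), nodes)
  record <- function(joint, ti) {
    for (nd in nodes)
      for (v in seq_len(m[nd]))
        out[[nd]][v, ti] <<- sum(joint[states[, nd] == v])
  }
  record(joint, 1L)
  for (t in seq_len(Tn - 1L)) {
    trans <- matrix(1, nrow(states), nrow(states))  # [from, to]
    for (nd in nodes) {
      nodecpt <- dbn$cpts[[nd]]
      sl <- nodecpt$slices[[t]]
      pa <- nodecpt$parents
      key_from <- apply(states[, pa, drop = FALSE], 1, paste,
                        collapse = ",")
      key_rows <- apply(sl$rows, 1, paste, collapse = ",")
      ridx <- match(key_from, key_rows)
      pcond <- sl$cpt[ridx, , drop = FALSE]      # [from, child value]
      trans <- trans * pcond[, states[, nd]]
    }
    joint <- drop(joint %*% trans)
    joint <- joint / sum(joint)
    record(joint, t + 1L)
  }
  out
}
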