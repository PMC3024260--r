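# Two-stage parameter estimation. Stage 1 searches the discretised space of
# interval "blocks" (one interval index per unknown parameter) scored by the
# weighted SSE between the data and the factored-frontier expected values
# under the block clamped as t=0 evidence; stage 2 searches continuously
# inside the winning block's box, scored by ODE simulation. Both stages use
# the stochastic ranking evolution strategy; small block spaces are
# enumerated exhaustively.

#' Calibration dataset container
#'
#' Observations are normalised series (each observed species series scaled
#' by its own maximum, matching the arbitrary units of densitometry);
#' weights default to 1 per observation.
#'
#' @param observations data.frame with columns `condition`, `species`,
#'   `time_s`, `value` and optionally `weight`.
#' @param conditions named list of [condition()] objects (or `NULL` entries
#'   for plain simulation), one per condition label.
#' @return a `dataset`.
#' @export
dataset <- function(observations, conditions = NULL) {
  stopifnot(all(c("condition", "species", "time_s", "value") %in%
                  names(observations)))
  if (is.null(observations$weight)) observations$weight <- 1
  if (any(!is.finite(observations$value))) stop("non-finite observation values")
  if (any(observations$weight < 0)) stop("negative weights")
  labs <- unique(observations$condition)
  if (is.null(conditions)) conditions <- setNames(vector("list", length(labs)), labs)
  structure(list(observations = observations, conditions = conditions),
            class = "dataset")
}

normalise_series <- function(x) {
  ## arbitrary-units bridge: scale each series by its mean level. The mean
  ## is an unbiased scale estimate under multiplicative noise, unlike the
  ## series maximum, whose upward noise bias mimics faster kinetics.
  m <- mean(x)
  if (m > 0) x / m else x
}

#' Stage-1 objective: weighted SSE against FF expected values
#'
#' The block is clamped as parameter-interval evidence at t = 0, the
#' factored frontier is propagated, and the expected series of every
#' observed species is compared with the data. Both sides are normalised by
#' their own series maximum over the observation times.
#'
#' @param block integer vector of interval indices, one per
#'   `dbn$param_nodes` (named or in that order).
#' @param dbn a `dbn` built under the condition the data were collected in.
#' @param data a [dataset()]; only rows whose `condition` equals
#'   `condition_label` are used (default: all rows).
#' @param condition_label optional condition filter.
#' @param unseen passed to [ff_forward()].
#' @param normalise `TRUE` (default): both sides are scaled by their own
#'   series mean (shape-only comparison for data in arbitrary units);
#'   `FALSE`: raw residuals — used when the dataset is expressed in model
#'   units (e.g. mapped through fixed calibration factors), so that
#'   scale-controlling parameters remain visible, with per-series
#'   `1/max^2`-style weights carrying the balancing.
#' @return weighted sum of squared errors (>= 0).
#' @export
objective_block <- function(block, dbn, data, condition_label = NULL,
                            normalise = TRUE, unseen = "uniform") {
  pn <- dbn$param_nodes
  if (!is.null(names(block))) block <- block[pn]
  stopifnot(length(block) == length(pn))
  ev <- lapply(seq_along(pn), function(i)
    ff_evidence(pn[i], time = dbn$grid[1], interval = as.integer(block[i])))
  marg <- ff_forward(dbn, ev, unseen = unseen)
  obs <- data$observations
  if (!is.null(condition_label)) obs <- obs[obs$condition == condition_label, ]
  sse <- 0
  for (s in unique(obs$species)) {
    o <- obs[obs$species == s, ]
    ti <- match(o$time_s, dbn$grid)
    if (anyNA(ti)) stop("observation times off the DBN grid for ", s)
    nodes_s <- if (s %in% names(dbn$observables %||% list()))
      dbn$observables[[s]] else s
    ## an observable is a sum of species, and expectation is linear
    pred <- rowSums(vapply(nodes_s, function(nd)
      expected_series(marg, nd), numeric(length(dbn$grid))))[ti]
    sse <- sse + if (normalise)
      sum(o$weight * (normalise_series(o$value) -
                        normalise_series(pred))^2)
    else sum(o$weight * (o$value - pred)^2)
  }
  sse
}

#' Stage-2 objective: weighted SSE against ODE simulation
#'
#' Simulates every condition of the dataset at the proposed parameter
#' vector and accumulates the weighted SSE between the normalised data and
#' the equally normalised simulated series. Integration failures yield the
#' configured penalty value instead of aborting the search.
#'
#' @param theta named numeric vector of unknown parameter values.
#' @param network a `reaction_network`.
#' @param data a [dataset()].
#' @param affinity_model optional `affinity_model` for conditions away from
#'   the normal reference.
#' @param penalty objective value substituted on integration failure.
#' @param normalise as in [objective_block()].
#' @return weighted sum of squared errors.
#' @export
objective_continuous <- function(theta, network, data,
                                 affinity_model = NULL, penalty = 1e6,
                                 normalise = TRUE) {
  obs <- data$observations
  sse <- 0
  for (lab in unique(obs$condition)) {
    o <- obs[obs$condition == lab, ]
    net <- realize_condition(network, data$conditions[[lab]],
                             affinity_model)
    times <- sort(unique(c(0, o$time_s)))
    traj <- tryCatch(
      simulate(net, grid = times, params = theta,
               check_conservation = FALSE),
      error = function(e) NULL)
    if (is.null(traj)) return(penalty)
    for (s in unique(o$species)) {
      oo <- o[o$species == s, ]
      pred <- series(traj, s, net)[match(oo$time_s, times)]
      sse <- sse + if (normalise)
        sum(oo$weight * (normalise_series(oo$value) -
                           normalise_series(pred))^2)
      else sum(oo$weight * (oo$value - pred)^2)
    }
  }
  sse
}

#' Stochastic ranking evolution strategy configuration
#'
#' Defaults follow the classic SRES settings: population `lambda = 200`,
#' parents `mu = 30`, ranking sweep probability `pf = 0.45`.
#'
#' @param lambda offspring population size.
#' @param mu number of parents (`mu < lambda`).
#' @param pf probability of an objective-based comparison during the
#'   stochastic-ranking bubble sort (0 < pf < 1).
#' @param generations number of generations.
#' @param seed RNG seed.
#' @return an `sres_config`.
#' @export
sres_config <- function(lambda = 200, mu = 30, pf = 0.45,
                        generations = 500, seed = 1) {
  stopifnot(mu < lambda, pf > 0, pf < 1, generations >= 1)
  structure(list(lambda = lambda, mu = mu, pf = pf,
                 generations = generations, seed = seed),
            class = "sres_config")
}

stochastic_rank <- function(f, g, pf) {
  ## bubble-sort style stochastic ranking (penalty g, zero when feasible)
  n <- length(f)
  idx <- seq_len(n)
  for (sweep in seq_len(n)) {
    swapped <- FALSE
    u <- runif(n - 1)
    for (i in seq_len(n - 1)) {
      a <- idx[i]; b <- idx[i + 1]
      use_obj <- (g[a] == 0 && g[b] == 0) || u[i] < pf
      worse <- if (use_obj) f[a] > f[b] else g[a] > g[b]
      if (worse) {
        idx[i] <- b; idx[i + 1] <- a; swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  idx
}

#' Stochastic ranking evolution strategy minimiser
#'
#' A (mu, lambda) evolution strategy with log-normal self-adaptive step
#' sizes and stochastic-ranking selection. In discrete mode the box is a
#' per-dimension index grid: mutation happens in continuous space and
#' candidate coordinates are rounded to the nearest valid index before
#' evaluation. The best point ever evaluated is returned together with the
#' per-generation history of the best-so-far objective.
#'
#' @param objective function of a numeric vector (continuous mode) or an
#'   integer index vector (discrete mode).
#' @param lower,upper box bounds (continuous mode).
#' @param levels integer vector of per-dimension level counts (discrete
#'   mode); indices run 1..levels.
#' @param config an [sres_config()].
#' @param penalty optional constraint-violation function (>= 0; 0 when
#'   feasible) used by the stochastic ranking.
#' @param initial optional matrix of points injected into the initial
#'   population (rows).
#' @return list with `par`, `value`, `history`, `evaluations`.
#' @export
sres_minimize <- function(objective, lower = NULL, upper = NULL,
                          levels = NULL, config = sres_config(),
                          penalty = NULL, initial = NULL) {
  discrete <- !is.null(levels)
  if (discrete) {
    lower <- rep(1, length(levels)); upper <- as.numeric(levels)
  }
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  n <- length(lower)
  set.seed(config$seed)
  lam <- config$lambda; mu <- config$mu
  tau <- 1 / sqrt(2 * sqrt(n)); tau2 <- 1 / sqrt(2 * n)
  X <- t(vapply(seq_len(lam), function(i) runif(n, lower, upper),
                numeric(n)))
  if (!is.null(initial)) {
    initial <- matrix(initial, ncol = n)
    k <- min(nrow(initial), lam)
    X[seq_len(k), ] <- initial[seq_len(k), , drop = FALSE]
  }
  S <- matrix(rep((upper - lower) / sqrt(n), each = lam), lam, n)
  as_point <- function(x) {
    if (discrete) pmin(pmax(round(x), 1), levels) else x
  }
  eval_all <- function(X) {
    vapply(seq_len(nrow(X)), function(i) objective(as_point(X[i, ])), 0)
  }
  f <- eval_all(X)
  if (all(!is.finite(f)))
    stop("non-finite objective at every initial individual")
  g <- if (is.null(penalty)) numeric(lam)
  else vapply(seq_len(lam), function(i) penalty(as_point(X[i, ])), 0)
  best_f <- Inf; best_x <- NULL
  history <- numeric(config$generations)
  evals <- lam
  for (gen in seq_len(config$generations)) {
    feas <- g == 0
    if (any(feas & f < best_f)) {
      i <- which(feas & f < best_f)[which.min(f[feas & f < best_f])]
      best_f <- f[i]; best_x <- as_point(X[i, ])
    }
    history[gen] <- best_f
    ord <- stochastic_rank(f, g, config$pf)
    par_idx <- ord[seq_len(mu)]
    newX <- matrix(0, lam, n); newS <- matrix(0, lam, n)
    for (k in seq_len(lam)) {
      i <- par_idx[((k - 1) %% mu) + 1]
      s <- S[i, ] * exp(tau2 * rnorm(1) + tau * rnorm(n))
      x <- X[i, ] + s * rnorm(n)
      ## reflect into the box
      for (rep_i in 1:3) {
        x <- ifelse(x < lower, 2 * lower - x, x)
        x <- ifelse(x > upper, 2 * upper - x, x)
      }
      x <- pmin(pmax(x, lower), upper)
      newX[k, ] <- x; newS[k, ] <- s
    }
    X <- newX; S <- newS
    f <- eval_all(X)
    g <- if (is.null(penalty)) numeric(lam)
    else vapply(seq_len(lam), function(i) penalty(as_point(X[i, ])), 0)
    evals <- evals + lam
  }
  feas <- g == 0
  if (any(feas & f < best_f)) {
    i <- which(feas & f < best_f)[which.min(f[feas & f < best_f])]
    best_f <- f[i]; best_x <- as_point(X[i, ])
  }
  list(par = best_x, value = best_f, history = history,
       evaluations = evals)
}

#' Two-stage DBN-guided parameter estimation
#'
#' Stage 1 finds the maximum-likelihood combination of parameter intervals
#' (block) by minimising [objective_block()] over the discrete block space
#' (exhaustively when the space has at most `exhaustive_cap` blocks,
#' otherwise by discrete-mode SRES). Stage 2 then searches the winning
#' block's box continuously with SRES scored by [objective_continuous()] —
#' a search space `prod(1/intervals)` of the original (1/5^71 for the full
#' complement model). The block's midpoint is injected into the stage-2
#' initial population, so the final objective can never exceed the
#' midpoint's.
#'
#' @param network a `reaction_network` (unknown parameter registry defines
#'   the search dimensions).
#' @param dbns named list of `dbn` objects, one per dataset condition label
#'   (a single `dbn` is accepted when the dataset has one condition).
#' @param data a [dataset()].
#' @param config1,config2 [sres_config()] for the two stages.
#' @param affinity_model passed to [objective_continuous()].
#' @param exhaustive_cap enumerate stage 1 exhaustively up to this many
#'   blocks.
#' @return A `fit_result`: best block and parameter vector, both stage
#'   objectives, histories, and the search-space ratio.
#' @export
estimate_two_stage <- function(network, dbns, data,
                               config1 = sres_config(lambda = 60, mu = 10,
                                                     generations = 50),
                               config2 = sres_config(lambda = 60, mu = 10,
                                                     generations = 80,
                                                     seed = 2),
                               affinity_model = NULL,
                               exhaustive_cap = 1e4) {
  if (inherits(dbns, "dbn")) {
    labs <- unique(data$observations$condition)
    dbns <- setNames(rep(list(dbns), length(labs)), labs)
  }
  pn <- dbns[[1]]$param_nodes
  m <- vapply(pn, function(p) n_intervals(dbns[[1]]$disc, p), 0L)
  obj1 <- function(block) {
    tot <- 0
    for (lab in names(dbns))
      tot <- tot + objective_block(block, dbns[[lab]], data,
                                   condition_label = lab)
    tot
  }
  n_blocks <- prod(m)
  if (n_blocks <= exhaustive_cap) {
    grid_idx <- as.matrix(do.call(expand.grid, lapply(m, seq_len)))
    vals <- vapply(seq_len(nrow(grid_idx)), function(i) obj1(grid_idx[i, ]), 0)
    best_block <- grid_idx[which.min(vals), ]
    stage1 <- list(par = best_block, value = min(vals),
                   history = cummin(vals), evaluations = length(vals),
                   exhaustive = TRUE)
  } else {
    stage1 <- sres_minimize(obj1, levels = m, config = config1)
    stage1$exhaustive <- FALSE
    best_block <- stage1$par
  }
  names(best_block) <- pn

  lo <- vapply(seq_along(pn), function(i)
    dbns[[1]]$disc[[pn[i]]]$boundaries[best_block[i]], 0)
  hi <- vapply(seq_along(pn), function(i)
    dbns[[1]]$disc[[pn[i]]]$boundaries[best_block[i] + 1], 0)
  obj2 <- function(x) {
    objective_continuous(setNames(x, pn), network, data,
                         affinity_model = affinity_model)
  }
  stage2 <- sres_minimize(obj2, lower = lo, upper = hi, config = config2,
                          initial = matrix((lo + hi) / 2, nrow = 1))
  structure(list(best_block = best_block,
                 best_theta = setNames(stage2$par, pn),
                 stage1_objective = stage1$value,
                 stage2_objective = stage2$value,
                 stage1 = stage1, stage2 = stage2,
                 space_ratio = prod(1 / m)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:\n  stage 1 (block) objective:", signif(x$stage1_objective, 5),
      "\n  stage 2 (continuous) objective:", signif(x$stage2_objective, 5),
      "\n  search-space ratio:", format(x$space_ratio, scientific = TRUE), "\n")
  invisible(x)
}

#' Stage-2 search-space ratio
#'
#' Volume of the stage-2 box relative to the full prior box: with
#' `n_intervals` discretisation intervals per unknown parameter, stage 1
#' reduces the continuous search space by `(1/n_intervals)^n_unknown`
#' (1/5^71 for the full complement model).
#'
#' @param network a `reaction_network`.
#' @param n_intervals intervals per parameter (default 5).
#' @return the ratio as a numeric scalar.
#' @export
search_space_ratio <- function(network, n_intervals = 5) {
  n_intervals^(-sum(!network$params$known))
}
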