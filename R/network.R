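#' @importFrom stats approx coef lm median quantile rlnorm rnorm runif sd
#'   setNames
#' @importFrom utils head read.csv tail write.csv
NULL

#' Rate law constructor
#'
#' Two kinds of rate law are supported. `mass_action` with constant `k`
#' (per s for unimolecular, per nM per s for bimolecular reactions);
#' `michaelis_menten` with catalytic constant `c` (per s) and half-saturation
#' constant `c_half` (nM). A Michaelis-Menten reaction may name an explicit
#' enzyme species as modifier (rate `c*[E]*[S]/(c_half+[S])`); without a
#' modifier the enzyme level is treated as absorbed into `c`
#' (rate `c*[S]/(c_half+[S])`), used for background proteolytic turnover
#' whose protease (e.g. factor I) is not an explicit species.
#'
#' Constants are referenced by *parameter name* so that the network keeps a
#' single flat parameter registry.
#'
#' @param kind `"mass_action"` or `"michaelis_menten"`.
#' @param k parameter name of the mass-action rate constant.
#' @param c,c_half parameter names of the Michaelis-Menten constants.
#' @return A `rate_law` object.
#' @export
rate_law <- function(kind = c("mass_action", "michaelis_menten"),
                     k = NULL, c = NULL, c_half = NULL) {
  kind <- match.arg(kind)
  if (kind == "mass_action") {
    if (is.null(k)) stop("mass_action law requires a rate constant name 'k'")
  } else {
    if (is.null(c) || is.null(c_half))
      stop("michaelis_menten law requires constant names 'c' and 'c_half'")
  }
  structure(list(kind = kind, k = k, c = c, c_half = c_half),
            class = "rate_law")
}

#' Reaction constructor
#'
#' @param id unique reaction identifier.
#' @param reactants character vector of reactant species; a species repeated
#'   `e` times has stoichiometry `e`.
#' @param products character vector of product species (possibly empty for
#'   clearance reactions).
#' @param law a [rate_law()]; for reversible reactions, the law of the
#'   forward direction.
#' @param modifiers character vector of enzyme species for Michaelis-Menten
#'   laws (at most one supported).
#' @param reversible logical; reversible reactions are stored as a single
#'   reaction carrying an extra backward constant `k_rev`, and are expanded
#'   into two irreversible mass-action reactions when the ODE right-hand side
#'   is assembled.
#' @param k_rev parameter name of the backward rate constant (reversible
#'   mass-action reactions only).
#' @param tags character vector; subset of `c("classical", "lectin",
#'   "amplification-PC", "amplification-GlcNAc", "C4BP-a", "C4BP-b",
#'   "C4BP-c", "C4BP-d", "C3-deposition")` plus free-form tags.
#' @return A `reaction` object.
#' @export
reaction <- function(id, reactants, products, law, modifiers = character(),
                     reversible = FALSE, k_rev = NULL, tags = character()) {
  if (reversible) {
    if (law$kind != "mass_action")
      stop("only mass_action reactions can be reversible: ", id)
    if (is.null(k_rev))
      stop("reversible reaction needs a backward constant name: ", id)
  }
  structure(list(id = id, reactants = as.character(reactants),
                 products = as.character(products),
                 modifiers = as.character(modifiers), law = law,
                 reversible = isTRUE(reversible), k_rev = k_rev,
                 tags = as.character(tags), active = TRUE),
            class = "reaction")
}

#' Assemble and validate a reaction network
#'
#' Builds a `reaction_network` from a model specification: species with
#' initial concentrations (nM), reactions with rate laws, and a flat
#' parameter registry with known/unknown flags and bounds. Every rate
#' constant referenced by a reaction must be registered; every species
#' referenced must be declared. Conservation groups (closed sets of species
#' whose total is invariant under the induced ODEs) and observables (named
#' sums of species, e.g. total deposited C4) are optional annotations.
#'
#' For the full complement model the declared totals (42 species,
#' 45 reactions, 85 parameters of which 71 unknown) are validated at load
#' time; a mismatch against the declared totals raises an error if
#' `strict_counts` is `TRUE` and a warning otherwise.
#'
#' @param species data.frame with columns `name`, `role`
#'   (fluid-phase/surface-bound/ligand/complex) and `init` (nM, >= 0).
#' @param reactions list of [reaction()] objects.
#' @param params data.frame with columns `name`, `value` (numeric, `NA` for
#'   unresolved unknowns), `lo`, `hi`, `known` (logical).
#' @param conservation named list of character vectors (species groups).
#' @param observables named list of character vectors (species sums).
#' @param meta free-form list (model name, affinity target parameter, ...).
#' @param expect optional list with `species`, `reactions`, `params`,
#'   `unknown` declared totals.
#' @param strict_counts logical, see above.
#' @return A `reaction_network`.
#' @export
build_network <- function(species, reactions, params,
                          conservation = list(), observables = list(),
                          meta = list(), expect = NULL,
                          strict_counts = FALSE) {
  stopifnot(is.data.frame(species), all(c("name", "init") %in% names(species)))
  if (is.null(species$role)) species$role <- "fluid-phase"
  species$name <- as.character(species$name)
  if (anyDuplicated(species$name))
    stop("duplicate species names: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  if (any(species$init < 0)) stop("negative initial concentration")

  stopifnot(is.data.frame(params),
            all(c("name", "value", "lo", "hi", "known") %in% names(params)))
  params$name <- as.character(params$name)
  if (anyDuplicated(params$name)) stop("duplicate parameter names")
  bad <- !params$known & (!is.finite(params$lo) | !is.finite(params$hi) |
                            params$lo >= params$hi)
  if (any(bad))
    stop("unknown parameters need finite bounds with lo < hi: ",
         paste(params$name[bad], collapse = ", "))
  if (any(params$value < 0, na.rm = TRUE)) stop("negative rate constant")

  ids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop("duplicate reaction id: ", paste(ids[duplicated(ids)], collapse = ", "))
  for (r in reactions) {
    refs <- c(r$reactants, r$products, r$modifiers)
    miss <- setdiff(refs, species$name)
    if (length(miss))
      stop("reaction ", r$id, " references unknown species: ",
           paste(miss, collapse = ", "))
    pn <- reaction_param_names(r)
    miss <- setdiff(pn, params$name)
    if (length(miss))
      stop("reaction ", r$id, " references unregistered parameters: ",
           paste(miss, collapse = ", "))
    if (r$law$kind == "michaelis_menten") {
      if (length(r$modifiers) > 1)
        stop("at most one Michaelis-Menten modifier supported: ", r$id)
      if (length(r$reactants) != 1)
        stop("Michaelis-Menten substrate must be a single species: ", r$id)
    }
  }
  for (g in names(conservation)) {
    miss <- setdiff(conservation[[g]], species$name)
    if (length(miss))
      stop("conservation group ", g, " references unknown species")
  }
  for (g in names(observables)) {
    miss <- setdiff(observables[[g]], species$name)
    if (length(miss))
      stop("observable ", g, " references unknown species")
  }

  net <- structure(list(species = species, reactions = reactions,
                        params = params, conservation = conservation,
                        observables = observables, meta = meta),
                   class = "reaction_network")
  if (!is.null(expect)) {
    got <- c(species = nrow(species), reactions = length(reactions),
             params = nrow(params), unknown = sum(!params$known))
    want <- unlist(expect)[names(got)]
    keep <- !is.na(want)
    if (any(got[keep] != want[keep])) {
      msg <- paste0("model counts differ from declared totals: ",
                    paste0(names(got)[keep], " ", got[keep], "/", want[keep],
                           collapse = ", "))
      if (strict_counts) stop(msg) else warning(msg)
    }
  }
  net
}

reaction_param_names <- function(r) {
  if (r$law$kind == "mass_action") c(r$law$k, if (r$reversible) r$k_rev)
  else c(r$law$c, r$law$c_half)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", x$meta$name %||% "<unnamed>", "\n")
  cat("  species:   ", nrow(x$species), "\n")
  cat("  reactions: ", length(x$reactions),
      sprintf("(%d active)", sum(vapply(x$reactions, `[[`, TRUE, "active"))), "\n")
  cat("  parameters:", nrow(x$params),
      sprintf("(%d unknown)", sum(!x$params$known)), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter vector helpers
#'
#' `param_values()` returns the named numeric vector of all registered
#' parameter values (error when unresolved unknowns remain and
#' `require_resolved` is `TRUE`); `set_params()` returns a copy of the
#' network with the named values replaced.
#'
#' @param network a `reaction_network`.
#' @param require_resolved fail on `NA` values.
#' @return named numeric vector / modified network.
#' @export
param_values <- function(network, require_resolved = TRUE) {
  v <- setNames(network$params$value, network$params$name)
  if (require_resolved && anyNA(v))
    stop("unresolved UNKNOWN parameters: ",
         paste(names(v)[is.na(v)], collapse = ", "))
  v
}

#' @rdname param_values
#' @param values named numeric vector of replacement values.
#' @export
set_params <- function(network, values) {
  i <- match(names(values), network$params$name)
  if (anyNA(i))
    stop("unknown parameter names: ",
         paste(names(values)[is.na(i)], collapse = ", "))
  network$params$value[i] <- unname(values)
  network
}

#' Initial state vector of a network
#'
#' @param network a `reaction_network`.
#' @param overrides optional named vector replacing selected initials.
#' @return named numeric vector over species.
#' @export
initial_state <- function(network, overrides = NULL) {
  x0 <- setNames(network$species$init, network$species$name)
  if (!is.null(overrides)) {
    i <- match(names(overrides), names(x0))
    if (anyNA(i)) stop("initial override for unknown species")
    x0[i] <- unname(overrides)
  }
  x0
}

# Compile the network into index structures used by both the scalar and the
# ensemble right-hand sides. Reversible reactions are expanded into explicit
# forward/backward irreversible mass-action steps here, so downstream code
# only ever sees irreversible reactions.
compile_network <- function(network) {
  sp <- network$species$name
  n <- length(sp)
  rx <- list()
  for (r in network$reactions) {
    if (!r$active) next
    rt <- table(factor(r$reactants, levels = sp))
    pt <- table(factor(r$products, levels = sp))
    ri <- which(rt > 0); pi <- which(pt > 0)
    base <- list(id = r$id, kind = r$law$kind,
                 ridx = ri, rst = as.numeric(rt[ri]),
                 pidx = pi, pst = as.numeric(pt[pi]),
                 eidx = if (length(r$modifiers)) match(r$modifiers[1], sp) else 0L,
                 tags = r$tags)
    if (r$law$kind == "mass_action") {
      base$pk <- r$law$k
      rx[[length(rx) + 1L]] <- base
      if (r$reversible) {
        rev <- base
        rev$id <- paste0(r$id, "_rev")
        rev$ridx <- pi; rev$rst <- as.numeric(pt[pi])
        rev$pidx <- ri; rev$pst <- as.numeric(rt[ri])
        rev$pk <- r$k_rev
        rx[[length(rx) + 1L]] <- rev
      }
    } else {
      base$pc <- r$law$c; base$pch <- r$law$c_half
      rx[[length(rx) + 1L]] <- base
    }
  }
  list(species = sp, n = n, rx = rx)
}

#' ODE right-hand side of a network
#'
#' Returns `function(t, x, p)` computing the rate of change of every species:
#' the sum over reactions of signed stoichiometry times the reaction rate
#' (`k * prod(reactant concentrations)` for mass action;
#' `c * [E] * [S] / (c_half + [S])` for Michaelis-Menten). The returned
#' function is suitable for [deSolve::lsoda()] (it returns a list) and is a
#' pure function of the state and the parameter vector.
#'
#' @param network a `reaction_network`; all parameters must resolve to
#'   numeric values unless `p` is supplied at call time.
#' @return derivative function `function(t, x, p = param_values(network))`.
#' @export
ode_rhs <- function(network) {
  cn <- compile_network(network)
  default_p <- setNames(network$params$value, network$params$name)
  function(t, x, p = NULL) {
    if (is.null(p)) p <- default_p
    if (anyNA(p[unlist(lapply(cn$rx, function(r)
      c(r$pk, r$pc, r$pch)))]))
      stop("unresolved UNKNOWN parameter in ode_rhs")
    dx <- numeric(cn$n)
    for (r in cn$rx) {
      if (r$kind == "mass_action") {
        rate <- p[[r$pk]] * prod(x[r$ridx]^r$rst)
      } else {
        s <- x[r$ridx]
        e <- if (r$eidx > 0L) x[r$eidx] else 1
        rate <- p[[r$pc]] * e * s / (p[[r$pch]] + s)
      }
      dx[r$ridx] <- dx[r$ridx] - r$rst * rate
      dx[r$pidx] <- dx[r$pidx] + r$pst * rate
    }
    list(dx)
  }
}

#' Conservation-group residual
#'
#' For every declared conservation group, evaluates the analytic sum of the
#' group's ODE right-hand sides at a given state; a correctly closed group
#' sums to zero identically.
#'
#' @param network a `reaction_network`.
#' @param x state vector (defaults to the initial state).
#' @param p parameter vector.
#' @return named numeric vector of group derivative sums.
#' @export
conservation_residual <- function(network, x = initial_state(network),
                                  p = param_values(network)) {
  rhs <- ode_rhs(network)
  dx <- rhs(0, x, p)[[1]]
  names(dx) <- network$species$name
  vapply(network$conservation, function(g) sum(dx[g]), 0)
}
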