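#' Experimental condition applied to a complement network
#'
#' A `condition` bundles the experimental scenario knobs of the study:
#' which surface ligand initiates the cascade (phosphorylcholine for the
#' classical arm, N-acetylglucosamine for the lectin arm, or both as on a
#' bacterial surface), the local pH and calcium level that set the
#' CRP:L-ficolin crosstalk strength, scalings of the C4BP and CRP plasma
#' pools, serum depletions, C4BP mechanism knockouts, and the
#' competitive-binding model variant.
#'
#' @param initiation `"PC"`, `"GlcNAc"` or `"both"`.
#' @param pH unitless, typically in `[5.5, 7.4]`.
#' @param calcium mM, typically 2.0-2.5.
#' @param c4bp_scale multiplier on the C4BP initial concentration (>= 0).
#' @param crp_scale multiplier on the CRP initial concentration (>= 0).
#' @param depleted subset of `c("CRP", "Lficolin")`: serum depletions, the
#'   corresponding initial concentration is set to exactly 0.
#' @param knockouts subset of `c("a", "b", "c", "d")`: C4BP mechanism
#'   knockouts, removing the reactions tagged `C4BP-a` ... `C4BP-d`.
#' @param competition_mode if `TRUE`, use the alternative model in which C1
#'   and L-ficolin (and CRP and MASP-2) compete for the same binding site on
#'   the initiator, so a CRP:L-ficolin complex cannot recruit the partner
#'   protease: the amplification arms are removed and the complex only
#'   sequesters its constituents.
#' @param initial_scales optional named vector of additional multipliers on
#'   initial concentrations (advanced use).
#' @return A `condition` object.
#' @export
condition <- function(initiation = c("both", "PC", "GlcNAc"), pH = 7.4,
                      calcium = 2.5, c4bp_scale = 1, crp_scale = 1,
                      depleted = character(), knockouts = character(),
                      competition_mode = FALSE, initial_scales = NULL) {
  initiation <- match.arg(initiation)
  stopifnot(c4bp_scale >= 0, crp_scale >= 0,
            all(depleted %in% c("CRP", "Lficolin")),
            all(knockouts %in% c("a", "b", "c", "d")))
  structure(list(initiation = initiation, pH = pH, calcium = calcium,
                 c4bp_scale = c4bp_scale, crp_scale = crp_scale,
                 depleted = depleted, knockouts = knockouts,
                 competition_mode = isTRUE(competition_mode),
                 initial_scales = initial_scales),
            class = "condition")
}

#' Apply a condition to a network
#'
#' Returns a modified copy of the network:
#' * the CRP:L-ficolin association constant (the parameter named in
#'   `network$meta$affinity_target`, `kd01_1` in the complement model) is
#'   multiplied by the affinity scale factor `affinity(pH, calcium)`;
#' * the calcium-dependent activation steps listed in
#'   `network$meta$affinity_secondary` (a named vector of exponents) are
#'   multiplied by `affinity^exponent` — in the complement model these are
#'   the C1 and MASP-2 activation constants, whose calcium/pH dependence is
#'   attenuated relative to the CRP:L-ficolin interaction;
#' * initial concentrations are scaled by `c4bp_scale` / `crp_scale` /
#'   `initial_scales` and zeroed for depleted species;
#' * branch suppression: under single-ligand initiation the other branch's
#'   ligand initial is zeroed and all reactions carrying that branch's tags
#'   are marked inactive (parameters keep their registry slots);
#' * mechanism knockouts remove (deactivate) exactly the reactions tagged
#'   with the matching `C4BP-<letter>` tag;
#' * `competition_mode` deactivates the partner-recruitment reactions of the
#'   deposited CRP:L-ficolin complexes (tag `crosstalk-recruit`).
#'
#' @param network a `reaction_network`.
#' @param cond a [condition()].
#' @param affinity_model an `affinity_model`; when `NULL` and the condition
#'   sits at the normal reference (pH 7.4, calcium 2.5) the factor is 1.
#' @return modified `reaction_network`.
#' @export
apply_condition <- function(network, cond, affinity_model = NULL) {
  stopifnot(inherits(cond, "condition"))
  net <- network
  sp <- net$species$name

  ## crosstalk affinity scaling
  target <- net$meta$affinity_target
  if (!is.null(target)) {
    if (is.null(affinity_model)) {
      if (abs(cond$pH - 7.4) > 1e-9 || abs(cond$calcium - 2.5) > 1e-9)
        stop("condition away from the normal reference needs an affinity model")
      alpha <- 1
    } else {
      alpha <- affinity(affinity_model, cond$pH, cond$calcium)
    }
    i <- match(target, net$params$name)
    if (is.na(i)) stop("affinity target parameter not registered: ", target)
    net$params$value[i] <- net$params$value[i] * alpha
    sec <- net$meta$affinity_secondary
    if (length(sec)) {
      j <- match(names(sec), net$params$name)
      if (anyNA(j)) stop("affinity_secondary names unregistered parameters")
      net$params$value[j] <- net$params$value[j] * alpha^unlist(sec)
    }
  }

  ## initial-concentration scalings and depletions
  scale_init <- function(net, species, f) {
    i <- match(species, net$species$name)
    if (is.na(i)) stop("species absent from the network: ", species)
    net$species$init[i] <- net$species$init[i] * f
    net
  }
  if (cond$c4bp_scale != 1) net <- scale_init(net, "C4BP", cond$c4bp_scale)
  if (cond$crp_scale != 1) net <- scale_init(net, "CRP", cond$crp_scale)
  for (nm in names(cond$initial_scales))
    net <- scale_init(net, nm, cond$initial_scales[[nm]])
  for (d in cond$depleted) {
    i <- match(d, net$species$name)
    if (is.na(i)) stop("depletion of a species absent from the network: ", d)
    net$species$init[i] <- 0
  }

  ## branch suppression
  deactivate_tagged <- function(net, tags) {
    hit <- FALSE
    for (k in seq_along(net$reactions)) {
      if (length(intersect(net$reactions[[k]]$tags, tags))) {
        net$reactions[[k]]$active <- FALSE
        hit <- TRUE
      }
    }
    attr(net, "last_hit") <- hit
    net
  }
  if (cond$initiation == "PC") {
    net$species$init[match("GlcNAc", sp)] <- 0
    net <- deactivate_tagged(net, c("lectin", "amplification-GlcNAc"))
  } else if (cond$initiation == "GlcNAc") {
    net$species$init[match("PC", sp)] <- 0
    net <- deactivate_tagged(net, c("classical", "amplification-PC"))
  }

  ## C4BP mechanism knockouts
  for (m in cond$knockouts) {
    net <- deactivate_tagged(net, paste0("C4BP-", m))
    if (!isTRUE(attr(net, "last_hit")))
      stop("knockout '", m, "' matches no tagged reaction")
  }

  ## competitive-binding variant: CRP:L-ficolin complexes cannot recruit the
  ## partner protease
  if (cond$competition_mode)
    net <- deactivate_tagged(net, "crosstalk-recruit")

  attr(net, "last_hit") <- NULL
  net$meta$condition <- cond
  net
}

#' Realise a dataset condition against a network
#'
#' Dataset conditions may be `NULL` (the network as-is), a [condition()]
#' object (applied via [apply_condition()]), or a named numeric vector of
#' initial-concentration overrides (a generic experimental design, e.g.
#' starting a relaxation from a different composition).
#'
#' @param network a `reaction_network`.
#' @param cond condition specification.
#' @param affinity_model optional affinity model for full conditions.
#' @return a `reaction_network`.
#' @export
realize_condition <- function(network, cond, affinity_model = NULL) {
  if (is.null(cond)) return(network)
  if (inherits(cond, "condition"))
    return(apply_condition(network, cond, affinity_model))
  if (is.numeric(cond) && !is.null(names(cond))) {
    i <- match(names(cond), network$species$name)
    if (anyNA(i)) stop("initial override for unknown species")
    network$species$init[i] <- unname(cond)
    return(network)
  }
  stop("unsupported condition specification")
}
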