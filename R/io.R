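# Model and data interchange. The native model format is a YAML dialect
# (species / reactions / params blocks); networks round-trip losslessly to
# an SBML Level 3 subset in which mass-action and Michaelis-Menten kinetic
# laws are written as MathML and package-specific metadata (bounds,
# known-flags, tags, conservation groups, observables) travels in an
# annotation element. Time-series datasets use a tidy CSV dialect.

#' Read a reaction-network model file
#'
#' Autodetects the format: files whose root element is `<sbml>` are parsed
#' as SBML Level 3 ([read_sbml()]), anything else as the native YAML
#' dialect.
#'
#' @param path model file.
#' @param strict_counts passed to [build_network()].
#' @return a `reaction_network`.
#' @export
read_model <- function(path, strict_counts = FALSE) {
  head_txt <- paste(readLines(path, n = 5, warn = FALSE), collapse = "\n")
  if (grepl("<sbml", head_txt, fixed = TRUE))
    read_sbml(path, strict_counts = strict_counts)
  else read_model_yaml(path, strict_counts = strict_counts)
}

#' @rdname read_model
#' @export
read_model_yaml <- function(path, strict_counts = FALSE) {
  y <- yaml::read_yaml(path)
  for (blk in c("species", "reactions", "params"))
    if (is.null(y[[blk]])) stop("model file lacks a '", blk, "' block")
  species <- do.call(rbind, lapply(y$species, function(s) {
    if (is.null(s$name) || is.null(s$init))
      stop("species entry needs 'name' and 'init'")
    data.frame(name = s$name, role = s$role %||% "fluid-phase",
               init = as.numeric(s$init))
  }))
  reactions <- lapply(y$reactions, function(r) {
    law <- r$law
    if (is.null(law$kind)) stop("reaction ", r$id, " lacks a law kind")
    rl <- if (law$kind == "mass_action") rate_law("mass_action", k = law$k)
    else rate_law("michaelis_menten", c = law$c, c_half = law$c_half)
    reaction(r$id,
             reactants = unlist(r$reactants) %||% character(),
             products = unlist(r$products) %||% character(),
             law = rl,
             modifiers = unlist(r$modifiers) %||% character(),
             reversible = isTRUE(r$reversible), k_rev = r$k_rev,
             tags = unlist(r$tags) %||% character())
  })
  params <- do.call(rbind, lapply(y$params, function(p)
    data.frame(name = p$name,
               value = if (is.null(p$value) ||
                           identical(p$value, "unknown")) NA_real_
               else as.numeric(p$value),
               lo = as.numeric(p$lo %||% NA), hi = as.numeric(p$hi %||% NA),
               known = isTRUE(p$known))))
  build_network(species, reactions, params,
                conservation = lapply(y$conservation %||% list(), unlist),
                observables = lapply(y$observables %||% list(), unlist),
                meta = y$meta %||% list(),
                expect = y$expect, strict_counts = strict_counts)
}

#' Write a network to the native YAML model format
#'
#' @param network a `reaction_network`.
#' @param path output file.
#' @param expect optional declared totals block to embed.
#' @return the path, invisibly.
#' @export
write_model_yaml <- function(network, path, expect = NULL) {
  y <- list(
    name = network$meta$name,
    species = lapply(seq_len(nrow(network$species)), function(i)
      list(name = network$species$name[i], role = network$species$role[i],
           init = network$species$init[i])),
    reactions = lapply(network$reactions, function(r) {
      out <- list(id = r$id, reactants = as.list(r$reactants),
                  products = as.list(r$products))
      if (length(r$modifiers)) out$modifiers <- as.list(r$modifiers)
      out$law <- if (r$law$kind == "mass_action")
        list(kind = "mass_action", k = r$law$k)
      else list(kind = "michaelis_menten", c = r$law$c,
                c_half = r$law$c_half)
      if (r$reversible) {
        out$reversible <- TRUE
        out$k_rev <- r$k_rev
      }
      if (length(r$tags)) out$tags <- as.list(r$tags)
      out
    }),
    params = lapply(seq_len(nrow(network$params)), function(i)
      list(name = network$params$name[i],
           value = network$params$value[i],
           lo = network$params$lo[i], hi = network$params$hi[i],
           known = network$params$known[i])),
    conservation = lapply(network$conservation, as.list),
    observables = lapply(network$observables, as.list),
    meta = network$meta[setdiff(names(network$meta), "condition")])
  if (!is.null(expect)) y$expect <- expect
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

sbml_ns <- "http://www.sbml.org/sbml/level3/version2/core"

mathml_ci <- function(x) paste0("<ci> ", x, " </ci>")

rate_mathml <- function(r) {
  prod_terms <- function(k, specs) {
    terms <- c(mathml_ci(k),
               unlist(lapply(specs, mathml_ci)))
    if (length(terms) == 1) terms
    else paste0("<apply><times/>", paste(terms, collapse = ""), "</apply>")
  }
  if (r$law$kind == "mass_action") {
    fwd <- prod_terms(r$law$k, r$reactants)
    if (!r$reversible) return(fwd)
    bwd <- prod_terms(r$k_rev, r$products)
    return(paste0("<apply><minus/>", fwd, bwd, "</apply>"))
  }
  s <- r$reactants[1]
  num_terms <- c(mathml_ci(r$law$c),
                 if (length(r$modifiers)) mathml_ci(r$modifiers[1]),
                 mathml_ci(s))
  num <- paste0("<apply><times/>", paste(num_terms, collapse = ""),
                "</apply>")
  den <- paste0("<apply><plus/>", mathml_ci(r$law$c_half), mathml_ci(s),
                "</apply>")
  paste0("<apply><divide/>", num, den, "</apply>")
}

#' Export a network as SBML Level 3
#'
#' Mass-action and Michaelis-Menten kinetic laws are written as MathML;
#' reversible reactions become SBML reversible reactions with a
#' forward-minus-backward rate. Package metadata that SBML core cannot
#' carry (parameter bounds and known flags, reaction tags, conservation
#' groups, observables, meta) is embedded as a JSON annotation, making the
#' round trip through [read_sbml()] lossless.
#'
#' @param network a `reaction_network`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sbml <- function(network, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="2">', sbml_ns),
    sprintf('<model id="%s">',
            esc(network$meta$name %||% "model")),
    "<annotation><compdbnMeta><![CDATA[",
    jsonlite::toJSON(list(
      params = network$params,
      tags = lapply(network$reactions, `[[`, "tags"),
      reaction_ids = vapply(network$reactions, `[[`, "", "id"),
      conservation = network$conservation,
      observables = network$observables,
      meta = network$meta,
      roles = network$species$role), auto_unbox = TRUE, digits = NA),
    "]]></compdbnMeta></annotation>",
    '<listOfCompartments><compartment id="serum" constant="true" size="1"/></listOfCompartments>',
    "<listOfSpecies>",
    sprintf(paste0('<species id="%s" compartment="serum" ',
                   'initialConcentration="%.15g" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="false" constant="false"/>'),
            network$species$name, network$species$init),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="%s" value="%.15g" constant="true"/>',
            network$params$name,
            ifelse(is.na(network$params$value), 0, network$params$value)),
    "</listOfParameters>",
    "<listOfReactions>")
  for (r in network$reactions) {
    refs <- function(tag, specs) {
      if (!length(specs)) return(character())
      tab <- table(specs)
      c(sprintf("<listOf%ss>", tag),
        sprintf('<%s species="%s" stoichiometry="%d" constant="true"/>',
                tolower(tag), names(tab), as.integer(tab)),
        sprintf("</listOf%ss>", tag))
    }
    mods <- if (length(r$modifiers))
      c("<listOfModifiers>",
        sprintf('<modifierSpeciesReference species="%s"/>', r$modifiers),
        "</listOfModifiers>") else character()
    lines <- c(lines,
               sprintf('<reaction id="%s" reversible="%s">', r$id,
                       tolower(as.character(r$reversible))),
               refs("Reactant", r$reactants), refs("Product", r$products),
               mods,
               "<kineticLaw>",
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               rate_mathml(r),
               "</math></kineticLaw></reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

parse_mathml_rate <- function(math_node, reversible) {
  ## recognise the two rate shapes this package writes; anything else is an
  ## unsupported construct
  strip <- function(node) xml2::xml_name(node)
  top <- xml2::xml_find_first(math_node, "./*")
  cis <- function(node) {
    kids <- xml2::xml_children(node)
    if (!all(xml2::xml_name(kids[-1]) == "ci")) return(NULL)
    trimws(xml2::xml_text(kids[-1]))
  }
  parse_product <- function(node) {
    if (xml2::xml_name(node) == "ci") return(trimws(xml2::xml_text(node)))
    if (xml2::xml_name(node) != "apply") return(NULL)
    op <- xml2::xml_name(xml2::xml_child(node, 1))
    if (op != "times") return(NULL)
    cis(node)
  }
  if (xml2::xml_name(top) == "apply" &&
      xml2::xml_name(xml2::xml_child(top, 1)) == "divide") {
    num <- parse_product(xml2::xml_child(top, 2))
    den_node <- xml2::xml_child(top, 3)
    if (is.null(num) || xml2::xml_name(den_node) != "apply" ||
        xml2::xml_name(xml2::xml_child(den_node, 1)) != "plus")
      stop("unsupported kinetic law construct")
    den <- cis(den_node)
    return(list(kind = "michaelis_menten", c = num[1], c_half = den[1],
                substrate = den[2],
                modifier = if (length(num) == 3) num[2]))
  }
  if (xml2::xml_name(top) == "apply" &&
      xml2::xml_name(xml2::xml_child(top, 1)) == "minus" && reversible) {
    fwd <- parse_product(xml2::xml_child(top, 2))
    bwd <- parse_product(xml2::xml_child(top, 3))
    if (is.null(fwd) || is.null(bwd))
      stop("unsupported kinetic law construct")
    return(list(kind = "mass_action", k = fwd[1], k_rev = bwd[1]))
  }
  pr <- parse_product(top)
  if (is.null(pr)) stop("unsupported kinetic law construct")
  list(kind = "mass_action", k = pr[1])
}

#' Import a network from the SBML subset written by [write_sbml()]
#'
#' @param path SBML file.
#' @param strict_counts passed to [build_network()].
#' @return a `reaction_network`.
#' @export
read_sbml <- function(path, strict_counts = FALSE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  meta_node <- xml2::xml_find_first(doc, ".//compdbnMeta")
  aux <- if (!inherits(meta_node, "xml_missing"))
    jsonlite::fromJSON(xml2::xml_text(meta_node), simplifyVector = TRUE)
  else NULL

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- data.frame(
    name = xml2::xml_attr(sp_nodes, "id"),
    role = if (!is.null(aux$roles)) aux$roles else "fluid-phase",
    init = as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")))

  if (!is.null(aux$params)) {
    params <- as.data.frame(aux$params)
  } else {
    pn <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
    params <- data.frame(name = xml2::xml_attr(pn, "id"),
                         value = as.numeric(xml2::xml_attr(pn, "value")),
                         lo = NA_real_, hi = NA_real_, known = TRUE)
    params$lo <- params$value / 10; params$hi <- params$value * 10
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    id <- xml2::xml_attr(node, "id")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    get_refs <- function(xp) {
      nn <- xml2::xml_find_all(node, xp)
      st <- xml2::xml_attr(nn, "stoichiometry")
      st[is.na(st)] <- "1"
      rep(xml2::xml_attr(nn, "species"), as.integer(st))
    }
    reac <- get_refs("./listOfReactants/*")
    prod <- get_refs("./listOfProducts/*")
    mods <- xml2::xml_attr(xml2::xml_find_all(node, "./listOfModifiers/*"),
                           "species")
    math <- xml2::xml_find_first(node, "./kineticLaw/math")
    if (inherits(math, "xml_missing")) stop("reaction ", id,
                                            " lacks a kinetic law")
    law <- parse_mathml_rate(math, rev)
    tags <- if (!is.null(aux$reaction_ids)) {
      unlist(aux$tags[match(id, aux$reaction_ids)]) %||% character()
    } else character()
    reactions[[i]] <- if (law$kind == "mass_action") {
      reaction(id, reac, prod, rate_law("mass_action", k = law$k),
               reversible = rev, k_rev = law$k_rev, tags = tags)
    } else {
      reaction(id, reac, prod,
               rate_law("michaelis_menten", c = law$c, c_half = law$c_half),
               modifiers = mods, tags = tags)
    }
  }
  conservation <- lapply(aux$conservation %||% list(), unlist)
  observables <- lapply(aux$observables %||% list(), unlist)
  meta <- aux$meta %||% list()
  if (!is.null(meta$affinity_secondary))
    meta$affinity_secondary <- as.list(meta$affinity_secondary)
  build_network(species, reactions, params, conservation = conservation,
                observables = observables, meta = meta,
                strict_counts = strict_counts)
}

#' Read / write time-series datasets as CSV
#'
#' Tidy dialect with columns `condition`, `species`, `time_s`, `value` and
#' optional `weight`; values round-trip at full double precision.
#'
#' @param path CSV file.
#' @return [read_timeseries()] returns a [dataset()].
#' @export
read_timeseries <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "species", "time_s", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$value < 0)) stop("negative concentration value in ", path)
  dataset(df)
}

#' @rdname read_timeseries
#' @param data a [dataset()].
#' @export
write_timeseries <- function(data, path) {
  df <- data$observations
  ## full precision so write -> read is lossless
  df$value <- format(df$value, digits = 17, trim = TRUE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scenario report (or any result list) as JSON
#'
#' @param report a `scenario_report` or plain list.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
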