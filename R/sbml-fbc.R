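#' Read and write constraint-based models as SBML
#'
#' Subset reader/writer for flux models. The primary dialect is SBML Level 3
#' with the `fbc` package (version 2): flux bounds as referenced parameters,
#' gene products with an association per reaction, and an active maximization
#' objective. A legacy Level 2 fallback reads COBRA-style kinetic-law
#' parameters (`LOWER_BOUND`, `UPPER_BOUND`, `OBJECTIVE_COEFFICIENT`) and
#' notes-based gene associations.
#'
#' Reactions without bounds get the defaults `[0, 1000]` (irreversible) or
#' `[-1000, 1000]` (reversible) with a warning. A model without any objective
#' is read, but [fba()] then requires an explicit `objective` argument.
#'
#' @param path File path.
#' @param model A [metabolic_network].
#' @return `read_sbml_fbc()` returns a [metabolic_network];
#'   `write_sbml_fbc()` returns `path` invisibly.
#' @name sbml_fbc
NULL

FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' @rdname sbml_fbc
#' @export
read_sbml_fbc <- function(path) {
  doc <- xml2::read_xml(path)
  nss <- unlist(xml2::xml_ns(doc))
  level <- xml2::xml_attr(doc, "level")
  sbml_ns <- if ("d1" %in% names(nss)) nss[["d1"]] else SBML_L3_NS
  ns <- c(s = sbml_ns, fbc = FBC_NS)
  if (FBC_NS %in% nss) {
    read_sbml_fbc_l3(doc, ns)
  } else if (identical(level, "2")) {
    read_sbml_l2_cobra(doc, ns)
  } else {
    stop("unsupported SBML flux model: need Level 3 + fbc or legacy Level 2",
         call. = FALSE)
  }
}

fattr <- function(nodes, name) {
  v <- xml2::xml_attr(nodes, paste0("fbc:", name))
  as.character(ifelse(is.na(v), xml2::xml_attr(nodes, name), v))
}

read_sbml_fbc_l3 <- function(doc, ns) {
  sp <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  metabolites <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           xml2::xml_attr(sp, "id")),
    compartment = xml2::xml_attr(sp, "compartment")
  )[!boundary, ]

  pars <- xml2::xml_find_all(doc, "//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  gps <- xml2::xml_find_all(doc, "//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gplabel <- stats::setNames(
    dplyr::coalesce(fattr(gps, "label"), fattr(gps, "id")), fattr(gps, "id"))

  rx <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  get_bound <- function(node, which, rid) {
    ref <- fattr(node, which)
    if (!is.na(ref) && ref %in% names(parval)) return(parval[[ref]])
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    warning("no ", which, " for reaction ", rid, "; default applied",
            call. = FALSE)
    if (which == "lowerFluxBound") (if (rev) -1000 else 0) else 1000
  }
  ids <- xml2::xml_attr(rx, "id")
  reactions <- tibble::tibble(
    id = ids,
    name = dplyr::coalesce(xml2::xml_attr(rx, "name"), ids),
    lb = vapply(seq_along(rx), function(i)
      get_bound(rx[[i]], "lowerFluxBound", ids[[i]]), 0),
    ub = vapply(seq_along(rx), function(i)
      get_bound(rx[[i]], "upperFluxBound", ids[[i]]), 0),
    genes = lapply(rx, function(r) {
      refs <- xml2::xml_find_all(
        r, ".//fbc:geneProductAssociation//fbc:geneProductRef", ns)
      if (length(refs) == 0L) return(character())
      g <- fattr(refs, "geneProduct")
      unname(ifelse(g %in% names(gplabel), gplabel[g], g))
    })
  )

  st <- do.call(rbind, lapply(seq_along(rx), function(i) {
    r <- rx[[i]]
    reac <- xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      if (length(nodes) == 0L) return(NULL)
      s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      s[is.na(s)] <- 1
      data.frame(reaction = ids[[i]],
                 metabolite = xml2::xml_attr(nodes, "species"),
                 coef = sign * s, stringsAsFactors = FALSE)
    }
    rbind(coef(reac, -1), coef(prod, 1))
  }))
  if (is.null(st)) {
    st <- data.frame(reaction = character(), metabolite = character(),
                     coef = numeric())
  }
  st <- st[st$metabolite %in% metabolites$id, ]  # drop boundary species

  active <- xml2::xml_attr(
    xml2::xml_find_first(doc, "//fbc:listOfObjectives", ns),
    "activeObjective")
  if (is.na(active)) {
    active <- fattr(xml2::xml_find_first(doc, "//fbc:listOfObjectives", ns),
                    "activeObjective")
  }
  fos <- xml2::xml_find_all(doc, "//fbc:objective//fbc:fluxObjective", ns)
  objective <- if (length(fos) == 0L) numeric() else stats::setNames(
    as.numeric(dplyr::coalesce(fattr(fos, "coefficient"), "1")),
    fattr(fos, "reaction"))
  metabolic_network(metabolites, reactions, st, objective)
}

read_sbml_l2_cobra <- function(doc, ns) {
  sp <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  metabolites <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           xml2::xml_attr(sp, "id")),
    compartment = xml2::xml_attr(sp, "compartment")
  )[!boundary, ]
  rx <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  ids <- xml2::xml_attr(rx, "id")
  kl_par <- function(node, name, default) {
    p <- xml2::xml_find_first(
      node, paste0(".//s:kineticLaw//s:parameter[@id='", name, "']"), ns)
    if (inherits(p, "xml_missing")) default
    else as.numeric(xml2::xml_attr(p, "value"))
  }
  lb <- ub <- obj <- numeric(length(rx))
  for (i in seq_along(rx)) {
    rev <- !identical(xml2::xml_attr(rx[[i]], "reversible"), "false")
    lb[i] <- kl_par(rx[[i]], "LOWER_BOUND", if (rev) -1000 else 0)
    ub[i] <- kl_par(rx[[i]], "UPPER_BOUND", 1000)
    obj[i] <- kl_par(rx[[i]], "OBJECTIVE_COEFFICIENT", 0)
  }
  reactions <- tibble::tibble(
    id = ids, name = dplyr::coalesce(xml2::xml_attr(rx, "name"), ids),
    lb = lb, ub = ub,
    genes = replicate(length(rx), character(), simplify = FALSE)
  )
  st <- do.call(rbind, lapply(seq_along(rx), function(i) {
    r <- rx[[i]]
    reac <- xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns)
    coef <- function(nodes, sign) {
      if (length(nodes) == 0L) return(NULL)
      s <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      s[is.na(s)] <- 1
      data.frame(reaction = ids[[i]],
                 metabolite = xml2::xml_attr(nodes, "species"),
                 coef = sign * s, stringsAsFactors = FALSE)
    }
    rbind(coef(reac, -1), coef(prod, 1))
  }))
  if (is.null(st)) {
    st <- data.frame(reaction = character(), metabolite = character(),
                     coef = numeric())
  }
  st <- st[st$metabolite %in% metabolites$id, ]
  objective <- stats::setNames(obj[obj != 0], ids[obj != 0])
  metabolic_network(metabolites, reactions, st, objective)
}

#' @rdname sbml_fbc
#' @export
write_sbml_fbc <- function(model, path) {
  stopifnot(inherits(model, "metabolic_network"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_L3_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  m <- xml2::xml_add_child(doc, "model", id = "metabolic_model",
                           "fbc:strict" = "true")
  lc <- xml2::xml_add_child(m, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(lc, "compartment", id = cid, constant = "true")
  }
  ls <- xml2::xml_add_child(m, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    xml2::xml_add_child(
      ls, "species",
      id = model$metabolites$id[[i]], name = model$metabolites$name[[i]],
      compartment = model$metabolites$compartment[[i]],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  lp <- xml2::xml_add_child(m, "listOfParameters")
  bid <- function(kind, rid) paste0(kind, "_", rid)
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[[i]]
    xml2::xml_add_child(lp, "parameter", id = bid("lb", rid),
                        value = format(model$reactions$lb[[i]]),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = bid("ub", rid),
                        value = format(model$reactions$ub[[i]]),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(m, "listOfReactions")
  st <- model$stoichiometry
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[[i]]
    rx <- xml2::xml_add_child(
      lr, "reaction", id = rid, name = model$reactions$name[[i]],
      reversible = if (model$reactions$lb[[i]] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid("lb", rid),
      "fbc:upperFluxBound" = bid("ub", rid))
    rows <- st[st$reaction == rid, ]
    reac <- rows[rows$coef < 0, ]
    prod <- rows[rows$coef > 0, ]
    if (nrow(reac)) {
      n <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in seq_len(nrow(reac))) {
        xml2::xml_add_child(n, "speciesReference",
                            species = reac$metabolite[[j]],
                            stoichiometry = format(-reac$coef[[j]]),
                            constant = "true")
      }
    }
    if (nrow(prod)) {
      n <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in seq_len(nrow(prod))) {
        xml2::xml_add_child(n, "speciesReference",
                            species = prod$metabolite[[j]],
                            stoichiometry = format(prod$coef[[j]]),
                            constant = "true")
      }
    }
    genes <- model$reactions$genes[[i]]
    if (length(genes)) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      parent <- if (length(genes) > 1L) {
        xml2::xml_add_child(ga, "fbc:or")
      } else ga
      for (g in genes) {
        xml2::xml_add_child(parent, "fbc:geneProductRef",
                            "fbc:geneProduct" = paste0("G_", sanitize_name(g)))
      }
    }
  }
  all_genes <- unique(unlist(model$reactions$genes, use.names = FALSE))
  if (length(all_genes)) {
    lg <- xml2::xml_add_child(m, "fbc:listOfGeneProducts")
    for (g in all_genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sanitize_name(g)),
                          "fbc:label" = g)
    }
  }
  if (length(model$objective)) {
    lo <- xml2::xml_add_child(m, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective)) {
      xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = rid,
                          "fbc:coefficient" = format(model$objective[[rid]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
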