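#' Process-description maps
#'
#' A `pd_map` holds the species/reactions/modifiers graph extracted from a
#' CellDesigner XML molecular interaction map (SBGN process-description
#' style): species with id, name, compartment and CellDesigner class;
#' reactions with reactant, product and modifier species; display aliases.
#' Species names are preserved verbatim so metabolic identifiers (BiGG-style
#' ids etc.) survive for the coupling stage.
#'
#' @name pd_map
NULL

CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"

# Modifier polarity vocabulary (conventional map-to-model semantics);
# configurable via the `polarity` argument of infer_boolean().
MODIFIER_CLASSES <- c(
  CATALYSIS = "positive",
  UNKNOWN_CATALYSIS = "positive",
  PHYSICAL_STIMULATION = "positive",
  TRIGGER = "positive",
  MODULATION = "positive",
  INHIBITION = "negative",
  UNKNOWN_INHIBITION = "negative"
)

new_pd_map <- function(species, reactions, aliases) {
  structure(list(species = species, reactions = reactions, aliases = aliases),
            class = "pd_map")
}

#' Construct a process-description map programmatically
#'
#' @param species Tibble/data frame with columns `id`, `name`, `compartment`,
#'   `class` (CellDesigner species class, e.g. `"PROTEIN"`; may be `NA`).
#' @param reactions List of lists with fields `id`, `reactants`, `products`
#'   (character vectors of species ids) and `modifiers` (tibble with columns
#'   `species`, `class`).
#' @param aliases Optional tibble with columns `species`, `alias`.
#' @return A `pd_map`.
#' @export
pd_map <- function(species, reactions, aliases = NULL) {
  species <- tibble::as_tibble(species)
  if (!"class" %in% names(species)) species$class <- NA_character_
  if (is.null(aliases)) {
    aliases <- tibble::tibble(species = character(), alias = character())
  }
  aliases <- tibble::as_tibble(aliases)
  stopifnot(all(c("id", "name", "compartment") %in% names(species)))
  if (anyDuplicated(species$id)) {
    stop("integrity error: duplicated species id", call. = FALSE)
  }
  for (r in reactions) {
    refs <- c(r$reactants, r$products, r$modifiers$species)
    dangling <- setdiff(refs, species$id)
    if (length(dangling)) {
      stop("integrity error: reaction ", r$id,
           " references unknown species: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  new_pd_map(species, reactions, aliases)
}

#' @export
print.pd_map <- function(x, ...) {
  cat("<pd_map> ", nrow(x$species), " species, ", length(x$reactions),
      " reactions\n", sep = "")
  invisible(x)
}

#' Parse a CellDesigner XML map
#'
#' Extracts the process-description content needed for Boolean inference:
#' species (with compartment and CellDesigner class), reactions with their
#' reactants, products and classified modifiers, and display aliases.
#'
#' @param path Path to a CellDesigner XML file (SBML Level 2 with the
#'   CellDesigner annotation namespace).
#' @return A `pd_map`: list with `species` (tibble: `id`, `name`,
#'   `compartment`, `class`), `reactions` (list of lists with `id`,
#'   `reactants`, `products`, `modifiers` = tibble(`species`, `class`)) and
#'   `aliases` (tibble: `species`, `alias`).
#' @export
parse_celldesigner <- function(path) {
  doc <- xml2::read_xml(path)
  nss <- unlist(xml2::xml_ns(doc))
  if (!CD_NS %in% nss) {
    stop("not a CellDesigner file: celldesigner namespace missing",
         call. = FALSE)
  }
  sbml_ns <- if ("d1" %in% names(nss)) nss[["d1"]] else
    "http://www.sbml.org/sbml/level2/version4"
  ns <- c(s = sbml_ns, cd = CD_NS)

  sp_nodes <- xml2::xml_find_all(doc, "//s:listOfSpecies/s:species", ns)
  cls <- vapply(sp_nodes, function(s) {
    c1 <- xml2::xml_find_first(
      s, ".//cd:speciesIdentity/cd:class", ns)
    if (inherits(c1, "xml_missing")) NA_character_ else xml2::xml_text(c1)
  }, "")
  species <- tibble::tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    class = cls
  )
  if (anyDuplicated(species$id)) {
    stop("integrity error: duplicated species id", call. = FALSE)
  }

  alias_nodes <- xml2::xml_find_all(doc, "//cd:speciesAlias", ns)
  aliases <- tibble::tibble(
    species = xml2::xml_attr(alias_nodes, "species"),
    alias = xml2::xml_attr(alias_nodes, "id")
  )

  rx_nodes <- xml2::xml_find_all(doc, "//s:listOfReactions/s:reaction", ns)
  reactions <- lapply(rx_nodes, function(r) {
    reactants <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//s:listOfReactants/s:speciesReference", ns),
      "species")
    products <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//s:listOfProducts/s:speciesReference", ns),
      "species")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(r, ".//s:listOfModifiers/s:modifierSpeciesReference",
                         ns),
      "species")
    # modifier classes from the CellDesigner modification annotation; a listed
    # modifier without an annotation defaults to CATALYSIS
    ann <- xml2::xml_find_all(r, ".//cd:listOfModification/cd:modification", ns)
    ann_mod <- xml2::xml_attr(ann, "modifiers")
    ann_type <- xml2::xml_attr(ann, "type")
    mclass <- vapply(mods, function(m) {
      hit <- which(ann_mod == m)
      if (length(hit)) ann_type[[hit[1]]] else "CATALYSIS"
    }, "", USE.NAMES = FALSE)
    list(
      id = xml2::xml_attr(r, "id"),
      reactants = reactants,
      products = products,
      modifiers = tibble::tibble(species = mods, class = mclass)
    )
  })

  all_refs <- unique(unlist(lapply(reactions, function(r) {
    c(r$reactants, r$products, r$modifiers$species)
  })))
  dangling <- setdiff(all_refs, species$id)
  if (length(dangling)) {
    stop("integrity error: reaction references unknown species: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  bad_alias <- setdiff(aliases$species, species$id)
  if (length(bad_alias)) {
    stop("integrity error: alias references unknown species: ",
         paste(bad_alias, collapse = ", "), call. = FALSE)
  }
  new_pd_map(species, reactions, aliases)
}

#' Write a CellDesigner XML map
#'
#' Emits the CellDesigner subset that [parse_celldesigner()] reads; used by
#' the synthetic fixture generator to produce self-contained toy maps.
#'
#' @param map A `pd_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_celldesigner <- function(map, path) {
  stopifnot(inherits(map, "pd_map"))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level2/version4",
    "xmlns:celldesigner" = CD_NS,
    level = "2", version = "4"
  )
  model <- xml2::xml_add_child(doc, "model", id = "map_model")
  ann <- xml2::xml_add_child(model, "annotation")
  ext <- xml2::xml_add_child(ann, "celldesigner:extension")
  loa <- xml2::xml_add_child(ext, "celldesigner:listOfSpeciesAliases")
  for (i in seq_len(nrow(map$aliases))) {
    xml2::xml_add_child(loa, "celldesigner:speciesAlias",
                        id = map$aliases$alias[[i]],
                        species = map$aliases$species[[i]])
  }
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  for (cid in unique(map$species$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cid)
  }
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(map$species))) {
    sp <- xml2::xml_add_child(los, "species",
                              id = map$species$id[[i]],
                              name = map$species$name[[i]],
                              compartment = map$species$compartment[[i]])
    if (!is.na(map$species$class[[i]])) {
      sann <- xml2::xml_add_child(sp, "annotation")
      sext <- xml2::xml_add_child(sann, "celldesigner:extension")
      ident <- xml2::xml_add_child(sext, "celldesigner:speciesIdentity")
      clsn <- xml2::xml_add_child(ident, "celldesigner:class")
      xml2::xml_text(clsn) <- map$species$class[[i]]
    }
  }
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (r in map$reactions) {
    rx <- xml2::xml_add_child(lor, "reaction", id = r$id, reversible = "false")
    if (nrow(r$modifiers) > 0L) {
      rann <- xml2::xml_add_child(rx, "annotation")
      rext <- xml2::xml_add_child(rann, "celldesigner:extension")
      lom <- xml2::xml_add_child(rext, "celldesigner:listOfModification")
      for (i in seq_len(nrow(r$modifiers))) {
        xml2::xml_add_child(lom, "celldesigner:modification",
                            type = r$modifiers$class[[i]],
                            modifiers = r$modifiers$species[[i]])
      }
    }
    if (length(r$reactants)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in r$reactants) {
        xml2::xml_add_child(lr, "speciesReference", species = s)
      }
    }
    if (length(r$products)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in r$products) {
        xml2::xml_add_child(lp, "speciesReference", species = s)
      }
    }
    if (nrow(r$modifiers) > 0L) {
      lm <- xml2::xml_add_child(rx, "listOfModifiers")
      for (s in r$modifiers$species) {
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = s)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
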