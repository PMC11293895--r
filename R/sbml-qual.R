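#' Read and write Boolean networks as SBML-qual
#'
#' Subset reader/writer for SBML Level 3 models using the `qual` package, the
#' standard exchange format for qualitative models. Only Boolean models are
#' supported: every qualitative species must have `maxLevel` 1 (multi-valued
#' models are rejected rather than binarized). Transition function terms are
#' MathML combinations of `and`, `or`, `not`, `eq`/`neq` comparisons of a
#' species against an integer level, bare `<ci>` references (read as
#' "species = 1") and the constants `true`/`false`. Function terms are
#' interpreted in document order with the default term as the else branch, so
#' models whose default is 1 are handled as well as the usual default-0 form.
#'
#' @param path File path.
#' @param net A [boolean_network].
#' @return `read_sbml_qual()` returns a [boolean_network]; `write_sbml_qual()`
#'   returns `path` invisibly.
#' @name sbml_qual
NULL

SBML_L3_NS <- "http://www.sbml.org/sbml/level3/version1/core"
QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

qual_ns_map <- c(s = SBML_L3_NS, q = QUAL_NS, m = MATHML_NS)

#' @rdname sbml_qual
#' @export
read_sbml_qual <- function(path) {
  doc <- xml2::read_xml(path)
  nss <- unlist(xml2::xml_ns(doc))
  if (!QUAL_NS %in% nss) {
    stop("not an SBML-qual file: qual namespace missing", call. = FALSE)
  }
  sp <- xml2::xml_find_all(doc, "//q:qualitativeSpecies", qual_ns_map)
  if (length(sp) == 0L) {
    stop("SBML-qual format error: no qualitative species", call. = FALSE)
  }
  ids <- xml2::xml_attr(sp, "id", ns = qual_ns_map)
  # the qual attributes are namespaced; fall back to plain lookup
  qattr <- function(nodes, name) {
    v <- xml2::xml_attr(nodes, paste0("qual:", name))
    ifelse(is.na(v), xml2::xml_attr(nodes, name), v)
  }
  ids <- qattr(sp, "id")
  maxlev <- qattr(sp, "maxLevel")
  if (any(!is.na(maxlev) & as.integer(maxlev) > 1L)) {
    stop("unsupported model: multi-level species (maxLevel > 1); ",
         "only Boolean models are handled", call. = FALSE)
  }
  funs <- stats::setNames(vector("list", length(ids)), ids)

  trans <- xml2::xml_find_all(doc, "//q:transition", qual_ns_map)
  for (tr in trans) {
    outs <- xml2::xml_find_all(tr, ".//q:output", qual_ns_map)
    targets <- qattr(outs, "qualitativeSpecies")
    terms <- xml2::xml_find_all(tr, ".//q:functionTerm", qual_ns_map)
    defaults <- xml2::xml_find_all(tr, ".//q:defaultTerm", qual_ns_map)
    if (length(defaults) != 1L) {
      stop("SBML-qual format error: transition without a default term",
           call. = FALSE)
    }
    default_level <- as.integer(qattr(defaults, "resultLevel"))
    lvl <- as.integer(qattr(terms, "resultLevel"))
    maths <- lapply(terms, function(t) {
      math <- xml2::xml_find_first(t, ".//m:math/*", qual_ns_map)
      parse_mathml(math)
    })
    # ordered evaluation with default as else-branch, restricted to Boolean:
    # f = OR(level-1 terms) | (default == 1 & !OR(level-0 terms))
    ones <- maths[lvl == 1L]
    zeros <- maths[lvl == 0L]
    f <- if (default_level == 1L) {
      guard <- if (length(zeros)) bx_not(bx_or(zeros)) else bx_const(1L)
      if (length(ones)) bx_or(c(ones, list(guard))) else guard
    } else {
      if (length(ones)) bx_or(ones) else bx_const(0L)
    }
    for (tg in targets) funs[[tg]] <- f
  }
  # species never targeted by a transition are inputs (identity update)
  for (id in ids) {
    if (is.null(funs[[id]])) funs[[id]] <- bx_var(id)
  }
  boolean_network(funs)
}

parse_mathml <- function(node) {
  if (inherits(node, "xml_missing") || is.null(node)) {
    stop("SBML-qual format error: function term without MathML", call. = FALSE)
  }
  name <- xml2::xml_name(node)
  if (name == "ci") return(bx_var(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    return(bx_const(as.integer(trimws(xml2::xml_text(node)))))
  }
  if (name == "true") return(bx_const(1L))
  if (name == "false") return(bx_const(0L))
  if (name != "apply") {
    stop("SBML-qual: unsupported MathML element <", name, ">", call. = FALSE)
  }
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- kids[-1]
  switch(op,
    and = bx_and(lapply(args, parse_mathml)),
    or = bx_or(lapply(args, parse_mathml)),
    not = bx_not(parse_mathml(args[[1]])),
    eq = parse_mathml_cmp(args, negate = FALSE),
    neq = parse_mathml_cmp(args, negate = TRUE),
    stop("SBML-qual: unsupported MathML operator <", op, ">", call. = FALSE)
  )
}

parse_mathml_cmp <- function(args, negate) {
  stopifnot(length(args) == 2L)
  names2 <- vapply(args, xml2::xml_name, "")
  ci <- args[[which(names2 == "ci")[1]]]
  cn <- args[[which(names2 == "cn")[1]]]
  level <- as.integer(trimws(xml2::xml_text(cn)))
  if (!level %in% c(0L, 1L)) {
    stop("unsupported model: comparison against level ", level, call. = FALSE)
  }
  e <- bx_var(trimws(xml2::xml_text(ci)))
  positive <- (level == 1L) != negate
  if (positive) e else bx_not(e)
}

#' @rdname sbml_qual
#' @export
write_sbml_qual <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  vars <- sort(net$variables)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_L3_NS, "xmlns:qual" = QUAL_NS,
    level = "3", version = "1", "qual:required" = "true"
  )
  model <- xml2::xml_add_child(doc, "model", id = "boolean_model")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "default", constant = "true")
  lqs <- xml2::xml_add_child(model, "qual:listOfQualitativeSpecies")
  for (v in vars) {
    xml2::xml_add_child(
      lqs, "qual:qualitativeSpecies",
      "qual:id" = v, "qual:compartment" = "default",
      "qual:constant" = "false", "qual:maxLevel" = "1"
    )
  }
  lot <- xml2::xml_add_child(model, "qual:listOfTransitions")
  for (v in vars) {
    f <- net$functions[[v]]
    tr <- xml2::xml_add_child(lot, "qual:transition",
                              "qual:id" = paste0("tr_", v))
    regs <- expr_vars(f)
    if (length(regs)) {
      li <- xml2::xml_add_child(tr, "qual:listOfInputs")
      for (r in regs) {
        xml2::xml_add_child(
          li, "qual:input", "qual:id" = paste0("in_", v, "_", r),
          "qual:qualitativeSpecies" = r, "qual:transitionEffect" = "none"
        )
      }
    }
    lo <- xml2::xml_add_child(tr, "qual:listOfOutputs")
    xml2::xml_add_child(
      lo, "qual:output", "qual:qualitativeSpecies" = v,
      "qual:transitionEffect" = "assignmentLevel"
    )
    lft <- xml2::xml_add_child(tr, "qual:listOfFunctionTerms")
    xml2::xml_add_child(lft, "qual:defaultTerm", "qual:resultLevel" = "0")
    ft <- xml2::xml_add_child(lft, "qual:functionTerm",
                              "qual:resultLevel" = "1")
    math <- xml2::xml_add_child(ft, "math", xmlns = MATHML_NS)
    add_mathml(math, f)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

add_mathml <- function(parent, e) {
  switch(e$op,
    var = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "eq")
      ci <- xml2::xml_add_child(ap, "ci")
      xml2::xml_text(ci) <- e$name
      cn <- xml2::xml_add_child(ap, "cn", type = "integer")
      xml2::xml_text(cn) <- "1"
    },
    const = {
      xml2::xml_add_child(parent, if (e$value == 1L) "true" else "false")
    },
    not = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "not")
      add_mathml(ap, e$arg)
    },
    and = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "and")
      for (a in e$args) add_mathml(ap, a)
    },
    or = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "or")
      for (a in e$args) add_mathml(ap, a)
    }
  )
}
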