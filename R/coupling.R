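#' Match regulatory components to metabolic reactions
#'
#' Exact, case-sensitive identifier matching of Boolean-network variables
#' against the metabolic model: a variable equal to an enzyme/gene label maps
#' with role `"enzyme"` to the reactions it catalyzes; a variable equal to a
#' metabolite id maps with role `"metabolite"` to the reactions able to
#' produce that metabolite (forward when it is a product, reverse when it is
#' a reactant of a reversible reaction). The two halves of a coupled analysis
#' are expected to share identifiers (BiGG-style ids and the like); an
#' optional synonym table bridges the inevitable leftovers.
#'
#' @param net A [boolean_network].
#' @param model A [metabolic_network].
#' @param synonyms Optional tibble/data frame with columns
#'   `network_name,model_id,role` (`role` in `enzyme`/`metabolite`) adding
#'   manual bridges; the network name is treated as if it carried the model
#'   identifier.
#' @return A tibble (class `flx_mapping`) with columns `component`, `role`,
#'   `reaction`, `direction` (`"forward"`/`"reverse"`, `NA` for enzymes).
#'   Attribute `unmatched` lists the metabolic-model identifiers (gene labels
#'   and metabolite ids) not matched by any network variable.
#' @export
match_components <- function(net, model, synonyms = NULL) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(model, "metabolic_network"))
  gene_tbl <- tibble::tibble(
    reaction = rep(model$reactions$id,
                   lengths(model$reactions$genes)),
    gene = unlist(model$reactions$genes, use.names = FALSE)
  )
  st <- model$stoichiometry
  rev_ids <- model$reactions$id[model$reactions$lb < 0]
  fwd <- st$coef > 0
  rev <- st$coef < 0 & st$reaction %in% rev_ids
  producers <- data.frame(
    metabolite = c(st$metabolite[fwd], st$metabolite[rev]),
    reaction = c(st$reaction[fwd], st$reaction[rev]),
    direction = c(rep("forward", sum(fwd)), rep("reverse", sum(rev))),
    stringsAsFactors = FALSE
  )

  lookup <- tibble::tibble(component = net$variables,
                           identifier = net$variables)
  if (!is.null(synonyms)) {
    synonyms <- tibble::as_tibble(synonyms)
    stopifnot(all(c("network_name", "model_id") %in% names(synonyms)))
    lookup <- rbind(lookup, tibble::tibble(
      component = synonyms$network_name, identifier = synonyms$model_id))
    lookup <- lookup[lookup$component %in% net$variables, ]
  }

  rows <- list()
  for (i in seq_len(nrow(lookup))) {
    cmp <- lookup$component[[i]]
    id <- lookup$identifier[[i]]
    hit_rx <- gene_tbl$reaction[gene_tbl$gene == id]
    if (length(hit_rx)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        component = cmp, role = "enzyme", reaction = unique(hit_rx),
        direction = NA_character_)
    }
    hit_pr <- producers[producers$metabolite == id, ]
    if (nrow(hit_pr)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        component = cmp, role = "metabolite", reaction = hit_pr$reaction,
        direction = hit_pr$direction)
    }
  }
  out <- if (length(rows)) dplyr::distinct(dplyr::bind_rows(rows)) else
    tibble::tibble(component = character(), role = character(),
                   reaction = character(), direction = character())
  matched_ids <- unique(lookup$identifier[lookup$component %in% out$component])
  unmatched <- setdiff(
    unique(c(gene_tbl$gene, model$metabolites$id)), matched_ids)
  if (nrow(out) == 0L) {
    warning("no regulatory component matched a metabolic identifier",
            call. = FALSE)
  }
  structure(out, class = c("flx_mapping", class(out)), unmatched = unmatched)
}

#' Trap-space projections as flux constraints
#'
#' The contextualization rule: every metabolic component whose projected
#' maximal trap-space value is 0 — proven asymptotically inactive — switches
#' its associated reactions off. An enzyme at 0 zeroes both bounds of each
#' catalyzed reaction; a metabolite at 0 zeroes each producing direction
#' (upper bound to 0 where it is a forward product, lower bound raised to 0
#' where a reversible reaction produces it in reverse). Components projected
#' to 1 induce nothing, as do mapped components missing from the projection.
#'
#' @param mapping A `flx_mapping` from [match_components()].
#' @param proj Projection tibble from [project_max()] (columns `component`,
#'   `value`).
#' @param model A [metabolic_network] (for the original bounds).
#' @param metabolite_rule `"producing"` (default: only producing directions
#'   zeroed) or `"knockout"` (both bounds of every associated reaction
#'   zeroed, like enzymes).
#' @return A tibble (class `flx_constraints`) with columns `reaction`, `lb`,
#'   `ub`, `components` (provenance, `;`-collapsed).
#' @export
extract_constraints <- function(mapping, proj, model,
                                metabolite_rule = c("producing", "knockout")) {
  metabolite_rule <- match.arg(metabolite_rule)
  stopifnot(is.data.frame(mapping), is.data.frame(proj),
            inherits(model, "metabolic_network"))
  extra <- setdiff(proj$component, mapping$component)
  if (length(extra)) {
    warning("projected component(s) absent from the mapping ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  inactive <- proj$component[proj$value == 0]
  hits <- mapping[mapping$component %in% inactive, ]
  rl <- stats::setNames(model$reactions$lb, model$reactions$id)
  ru <- stats::setNames(model$reactions$ub, model$reactions$id)
  new_lb <- rl; new_ub <- ru
  prov <- stats::setNames(vector("list", length(rl)), names(rl))
  for (i in seq_len(nrow(hits))) {
    rid <- hits$reaction[[i]]
    if (hits$role[[i]] == "enzyme" || metabolite_rule == "knockout") {
      new_lb[[rid]] <- 0; new_ub[[rid]] <- 0
    } else if (identical(hits$direction[[i]], "forward")) {
      new_ub[[rid]] <- min(new_ub[[rid]], 0)
    } else {
      new_lb[[rid]] <- max(new_lb[[rid]], 0)
    }
    prov[[rid]] <- union(prov[[rid]], hits$component[[i]])
  }
  changed <- names(rl)[new_lb != rl | new_ub != ru]
  out <- tibble::tibble(
    reaction = changed,
    lb = unname(new_lb[changed]),
    ub = unname(new_ub[changed]),
    components = unname(vapply(prov[changed], paste, "", collapse = ";"))
  )
  structure(out, class = c("flx_constraints", class(out)))
}

#' Apply a constraint set to a metabolic model
#'
#' Returns a new model with overridden bounds; the input model is unchanged.
#'
#' @param model A [metabolic_network].
#' @param constraints A `flx_constraints` tibble (columns `reaction`, `lb`,
#'   `ub`).
#' @return A contextualized [metabolic_network].
#' @export
apply_constraints <- function(model, constraints) {
  stopifnot(inherits(model, "metabolic_network"), is.data.frame(constraints))
  if (nrow(constraints) == 0L) return(model)
  idx <- match(constraints$reaction, model$reactions$id)
  if (anyNA(idx)) {
    stop("constraint for unknown reaction: ",
         paste(constraints$reaction[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  model$reactions$lb[idx] <- constraints$lb
  model$reactions$ub[idx] <- constraints$ub
  model
}

#' ATP classification
#'
#' Which reactions count as glycolytic (substrate-level phosphorylation in
#' glycolysis) versus oxidative (ATP synthase / oxidative phosphorylation)
#' ATP producers. The split is configuration, not biology baked into the
#' code: the shipped default covers the toy core-metabolism fixture and
#' common BiGG-style ids, and is explicitly provisional for other models.
#'
#' @param glycolytic,oxidative Character vectors of reaction ids. Overlap is
#'   a configuration error.
#' @return A list with elements `glycolytic` and `oxidative` (class
#'   `flx_classification`).
#' @export
atp_classification <- function(glycolytic, oxidative) {
  overlap <- intersect(glycolytic, oxidative)
  if (length(overlap)) {
    stop("classification lists overlap: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  structure(list(glycolytic = glycolytic, oxidative = oxidative),
            class = "flx_classification")
}

#' @rdname atp_classification
#' @export
default_atp_classification <- function() {
  atp_classification(
    glycolytic = c("PGK", "PYK"),
    oxidative = c("ATPS4m", "ATPS4mi", "OF_ATP_MitoCore")
  )
}

#' Read an ATP classification CSV
#'
#' Two columns `reaction,class` with `class` in
#' `glycolytic`/`oxidative`.
#'
#' @param path CSV path.
#' @return A `flx_classification`.
#' @export
read_atp_classification <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("reaction", "class") %in% names(df))) {
    stop("classification CSV needs a 'reaction,class' header", call. = FALSE)
  }
  bad <- setdiff(df$class, c("glycolytic", "oxidative"))
  if (length(bad)) {
    stop("unknown classification class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  atp_classification(df$reaction[df$class == "glycolytic"],
                     df$reaction[df$class == "oxidative"])
}

#' Pathway ratios of ATP production
#'
#' Per reaction, ATP production is the signed stoichiometric coefficient of
#' ATP times the flux, counted only when positive (a reaction consuming ATP,
#' or producing it in its unused direction, contributes nothing). The report
#' gives total production, the class sums and the dimensionless ratios
#' `ratio_glycolytic` and `ratio_oxidative`. With zero total production both
#' ratios are reported as 0 and `zero_production` is flagged. When an FVA
#' envelope is supplied, ATP-producing reactions whose interval is not a
#' point are flagged `solution_dependent`: the ratio then depends on which
#' optimal vertex FBA happened to return.
#'
#' @param fluxes A `flx_fba` tibble (or any tibble with `reaction`, `flux`).
#' @param model The [metabolic_network] the fluxes belong to.
#' @param classification A `flx_classification`; default
#'   [default_atp_classification()].
#' @param atp_ids Metabolite ids counted as cellular ATP (default: ids whose
#'   name starts `atp_`).
#' @param envelope Optional `flx_fva` tibble for the degeneracy check.
#' @return A one-row tibble (class `flx_atp_report`): `total_atp`,
#'   `glycolytic_atp`, `oxidative_atp`, `ratio_glycolytic`,
#'   `ratio_oxidative`, `zero_production`, `solution_dependent`.
#' @export
atp_ratio <- function(fluxes, model,
                      classification = default_atp_classification(),
                      atp_ids = NULL, envelope = NULL) {
  stopifnot(is.data.frame(fluxes), inherits(model, "metabolic_network"))
  if (!inherits(classification, "flx_classification")) {
    classification <- atp_classification(classification$glycolytic,
                                         classification$oxidative)
  }
  if (is.null(atp_ids)) {
    atp_ids <- model$metabolites$id[startsWith(model$metabolites$id, "atp_")]
  }
  if (length(atp_ids) == 0L) {
    stop("no ATP metabolite found; supply `atp_ids`", call. = FALSE)
  }
  # classification ids for other model families (e.g. the default's
  # MitoCore-style aliases) may be absent from this model; they simply
  # contribute nothing
  st <- model$stoichiometry
  atp_coef <- vapply(model$reactions$id, function(rid) {
    sum(st$coef[st$reaction == rid & st$metabolite %in% atp_ids])
  }, 0)
  v <- stats::setNames(fluxes$flux, fluxes$reaction)[model$reactions$id]
  production <- pmax(0, atp_coef * v)
  production[is.na(production)] <- 0
  total <- sum(production)
  gly <- sum(production[model$reactions$id %in% classification$glycolytic])
  oxi <- sum(production[model$reactions$id %in% classification$oxidative])
  zero <- total <= 0
  soldep <- FALSE
  if (!is.null(envelope)) {
    env <- tibble::as_tibble(envelope)
    producing <- model$reactions$id[atp_coef != 0 &
                                      model$reactions$id %in% env$reaction]
    width <- abs(env$max - env$min)[match(producing, env$reaction)]
    soldep <- any(width > 1e-6, na.rm = TRUE)
  }
  out <- tibble::tibble(
    total_atp = total,
    glycolytic_atp = gly,
    oxidative_atp = oxi,
    ratio_glycolytic = if (zero) 0 else gly / total,
    ratio_oxidative = if (zero) 0 else oxi / total,
    zero_production = zero,
    solution_dependent = soldep
  )
  structure(out, class = c("flx_atp_report", class(out)))
}

#' @exportS3Method generics::glance
glance.flx_atp_report <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method ggplot2::autoplot
autoplot.flx_atp_report <- function(object, ...) {
  df <- tibble::tibble(
    pathway = c("glycolytic", "oxidative", "other"),
    atp = c(object$glycolytic_atp, object$oxidative_atp,
            object$total_atp - object$glycolytic_atp - object$oxidative_atp)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pathway, y = .data$atp,
                                   fill = .data$pathway)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "ATP production flux") +
    ggplot2::theme_minimal()
}
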