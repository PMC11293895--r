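#' Sanitize component names
#'
#' CellDesigner species names may contain spaces, dashes or punctuation;
#' Boolean-network variable names are restricted to `[A-Za-z0-9_]` so that
#' BNET, SBML-qual and CSV columns stay consistent. Any other character is
#' replaced by `_`.
#'
#' @param x Character vector of names.
#' @return Sanitized names.
#' @export
sanitize_name <- function(x) {
  gsub("[^A-Za-z0-9_]", "_", x)
}

# Unique sanitized variable name per species; on collision the compartment,
# then the species id, is appended.
species_variable_names <- function(species) {
  nm <- sanitize_name(species$name)
  dup <- nm %in% nm[duplicated(nm)]
  nm[dup] <- paste0(nm[dup], "_", sanitize_name(species$compartment[dup]))
  dup2 <- nm %in% nm[duplicated(nm)]
  nm[dup2] <- paste0(nm[dup2], "_", sanitize_name(species$id[dup2]))
  stats::setNames(nm, species$id)
}

#' Infer a Boolean network from a process-description map
#'
#' One variable per map species. For each species \eqn{s}, the update function
#' is the disjunction over the reactions producing \eqn{s} of the conjunction
#' of that reaction's reactants and positive modifiers, with every negative
#' modifier negated:
#' \deqn{f_s = \bigvee_{r: s \in products(r)} \Big( \bigwedge reactants(r)
#'   \wedge \bigwedge mods^+(r) \wedge \bigwedge \neg mods^-(r) \Big)}
#' A species with no producing reaction becomes an input with identity update
#' \eqn{f_s = s}. A producing reaction with no reactants and no modifiers
#' contributes a constant-1 term (constitutive production).
#'
#' @param map A `pd_map` from [parse_celldesigner()].
#' @param polarity Named character vector mapping modifier classes to
#'   `"positive"`/`"negative"`; defaults to the conventional map-to-model semantics
#'   (CATALYSIS-like classes positive, INHIBITION-like negative).
#' @return A [boolean_network]. The species-to-variable name table is attached
#'   as attribute `"variable_names"`.
#' @export
infer_boolean <- function(map, polarity = MODIFIER_CLASSES) {
  stopifnot(inherits(map, "pd_map"))
  varname <- species_variable_names(map$species)
  funs <- stats::setNames(vector("list", nrow(map$species)), unname(varname))
  for (r in map$reactions) {
    lits <- c(
      lapply(unname(varname[r$reactants]), bx_var),
      lapply(seq_len(nrow(r$modifiers)), function(i) {
        cls <- r$modifiers$class[[i]]
        if (!cls %in% names(polarity)) {
          stop("unknown modifier class '", cls, "' in reaction ", r$id,
               call. = FALSE)
        }
        pol <- polarity[[cls]]
        v <- bx_var(varname[[r$modifiers$species[[i]]]])
        if (pol == "negative") bx_not(v) else v
      })
    )
    term <- if (length(lits)) bx_and(lits) else bx_const(1L)
    for (p in r$products) {
      v <- varname[[p]]
      funs[[v]] <- if (is.null(funs[[v]])) term else bx_or(funs[[v]], term)
    }
  }
  for (v in names(funs)) {
    if (is.null(funs[[v]])) funs[[v]] <- bx_var(v)  # input convention
  }
  net <- boolean_network(funs)
  attr(net, "variable_names") <- tibble::tibble(
    species = names(varname), variable = unname(varname)
  )
  net
}

# influence graph edges: v -> w iff v appears in f_w
influence_edges <- function(net) {
  do.call(rbind, lapply(net$variables, function(w) {
    regs <- expr_vars(net$functions[[w]])
    if (length(regs) == 0L) return(NULL)
    data.frame(from = regs, to = w, stringsAsFactors = FALSE)
  }))
}

bfs_reach <- function(adj, seeds) {
  seen <- seeds
  frontier <- seeds
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Extract a subnetwork around seed components
#'
#' Keeps the variables reachable from the seeds along influence edges
#' (\eqn{v} influences \eqn{w} when \eqn{v} appears in \eqn{f_w}):
#' `"downstream"` follows edges forward, `"upstream"` backward, `"both"`
#' takes the union. Regulators of retained variables that were dropped are
#' re-added as free inputs with identity update, so retained update functions
#' are kept verbatim rather than rewritten with unjustified constants.
#'
#' @param net A [boolean_network].
#' @param seeds Character vector of seed component names. Exact match first;
#'   a unique case-insensitive match is accepted, an ambiguous one is an
#'   error.
#' @param direction `"downstream"`, `"upstream"` or `"both"`.
#' @return A [boolean_network] over the retained variables plus boundary
#'   inputs.
#' @export
extract_subnetwork <- function(net, seeds,
                               direction = c("both", "upstream", "downstream")) {
  stopifnot(inherits(net, "boolean_network"))
  direction <- match.arg(direction)
  seeds <- vapply(seeds, function(s) resolve_name(s, net$variables), "")
  edges <- influence_edges(net)
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character())
  }
  fwd <- split(edges$to, factor(edges$from, levels = net$variables))
  bwd <- split(edges$from, factor(edges$to, levels = net$variables))
  keep <- switch(direction,
    downstream = bfs_reach(fwd, seeds),
    upstream = bfs_reach(bwd, seeds),
    both = union(bfs_reach(fwd, seeds), bfs_reach(bwd, seeds))
  )
  keep <- net$variables[net$variables %in% keep]
  funs <- stats::setNames(net$functions[keep], keep)
  boundary <- setdiff(
    unique(unlist(lapply(funs, expr_vars), use.names = FALSE)), keep)
  for (b in boundary) funs[[b]] <- bx_var(b)
  out <- boolean_network(funs)
  vn <- attr(net, "variable_names")
  if (!is.null(vn)) {
    attr(out, "variable_names") <- vn[vn$variable %in% out$variables, ]
  }
  out
}

resolve_name <- function(name, vars) {
  if (name %in% vars) return(name)
  ci <- vars[tolower(vars) == tolower(name)]
  if (length(ci) == 1L) return(ci)
  if (length(ci) > 1L) {
    stop("ambiguous component name '", name, "': matches ",
         paste(ci, collapse = ", "), call. = FALSE)
  }
  d <- utils::adist(tolower(name), tolower(vars))
  near <- vars[order(d)][seq_len(min(3L, length(vars)))]
  stop("unknown component '", name, "'; nearest matches: ",
       paste(near, collapse = ", "), call. = FALSE)
}

#' Read an initial-conditions CSV
#'
#' Two columns, `component,value`, values strictly 0/1. Component names are
#' sanitized like map species names so they line up with network variables.
#'
#' @param path CSV path.
#' @return A named integer vector (component -> 0/1).
#' @export
read_initial_conditions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("component", "value") %in% names(df))) {
    stop("initial-conditions CSV needs a 'component,value' header",
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(stats::setNames(integer(), character()))
  if (!all(df$value %in% c(0, 1))) {
    stop("initial-condition values must be 0 or 1", call. = FALSE)
  }
  stats::setNames(as.integer(df$value), sanitize_name(df$component))
}

#' Fix components to constant values
#'
#' Forcefully initializes the regulatory model: the update function of every
#' conditioned component is replaced by the constant 0/1, so all minimal trap
#' spaces of the returned network fix it to that value.
#'
#' @param net A [boolean_network].
#' @param ic Named vector of 0/1 values (component -> value), e.g. from
#'   [read_initial_conditions()].
#' @return A [boolean_network] with the conditioned functions replaced.
#' @export
apply_initial_conditions <- function(net, ic) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(ic) == 0L) return(net)
  if (!all(ic %in% c(0, 1))) {
    stop("initial-condition values must be 0 or 1", call. = FALSE)
  }
  funs <- net$functions
  for (v in names(ic)) {
    v2 <- resolve_name(v, net$variables)
    funs[[v2]] <- bx_const(as.integer(ic[[v]]))
  }
  out <- boolean_network(funs)
  attr(out, "variable_names") <- attr(net, "variable_names")
  out
}

#' Component/formula/alias table
#'
#' The first pipeline output: one row per network variable with its logic
#' formula and (when the network was inferred from a map) its CellDesigner
#' aliases.
#'
#' @param net A [boolean_network].
#' @param map Optional `pd_map` supplying aliases.
#' @return A tibble with columns `component`, `formula`, `alias`.
#' @export
components_table <- function(net, map = NULL) {
  tab <- tibble::tibble(
    component = sort(net$variables),
    formula = vapply(sort(net$variables),
                     function(v) format(net$functions[[v]]), "",
                     USE.NAMES = FALSE),
    alias = NA_character_
  )
  vn <- attr(net, "variable_names")
  if (!is.null(map) && !is.null(vn)) {
    al <- merge(vn, map$aliases, by = "species")
    collapsed <- vapply(split(al$alias, al$variable), paste,
                        "", collapse = ";")
    hit <- match(tab$component, names(collapsed))
    tab$alias <- ifelse(is.na(hit), NA_character_, unname(collapsed[hit]))
  }
  tab
}
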