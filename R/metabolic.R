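#' Constraint-based metabolic networks
#'
#' A `metabolic_network` stores metabolites, reactions with stoichiometry and
#' flux bounds, enzyme/gene associations and a linear objective — everything
#' flux balance analysis needs. Stoichiometry is kept tidy (one row per
#' reaction/metabolite pair); [stoich_matrix()] builds the dense S matrix.
#'
#' @param metabolites Tibble/data frame with columns `id`, `name`,
#'   `compartment`.
#' @param reactions Tibble/data frame with columns `id`, `name`, `lb`, `ub`
#'   and a list column `genes` (character vector of enzyme/gene labels per
#'   reaction; may be empty).
#' @param stoichiometry Tibble/data frame with columns `reaction`,
#'   `metabolite`, `coef` (signed: products positive, reactants negative).
#' @param objective Named numeric vector, reaction id -> coefficient.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, stoichiometry,
                              objective = numeric()) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  if (!"genes" %in% names(reactions)) {
    reactions$genes <- replicate(nrow(reactions), character(), simplify = FALSE)
  }
  stopifnot(all(c("id", "name", "compartment") %in% names(metabolites)),
            all(c("id", "name", "lb", "ub") %in% names(reactions)),
            all(c("reaction", "metabolite", "coef") %in% names(stoichiometry)))
  if (anyDuplicated(reactions$id) || anyDuplicated(metabolites$id)) {
    stop("duplicate reaction or metabolite id", call. = FALSE)
  }
  if (any(reactions$lb > reactions$ub)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "),
         call. = FALSE)
  }
  if (!all(stoichiometry$reaction %in% reactions$id)) {
    stop("stoichiometry references unknown reaction", call. = FALSE)
  }
  if (!all(stoichiometry$metabolite %in% metabolites$id)) {
    stop("stoichiometry references unknown metabolite", call. = FALSE)
  }
  if (length(objective) && !all(names(objective) %in% reactions$id)) {
    stop("objective references unknown reaction", call. = FALSE)
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 stoichiometry = stoichiometry, objective = objective),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions\n", sep = "")
  if (length(x$objective)) {
    cat("  objective: ",
        paste(names(x$objective), collapse = ", "), " (maximize)\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.metabolic_network <- function(x, ...) {
  tibble::tibble(
    n_metabolites = nrow(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_reversible = sum(x$reactions$lb < 0),
    objective = paste(names(x$objective), collapse = ";")
  )
}

#' Dense stoichiometric matrix
#'
#' @param model A [metabolic_network].
#' @return Numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_network"))
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(st$metabolite, st$reaction)] <- st$coef
  S
}

# ---- linear programming backend (simplex, bound-shifted standard form) ----

# maximize c'v subject to S v = beq (default 0), lb <= v <= ub, optional
# extra row a'v >= rhs. Returns list(status, value, fluxes).
solve_lp <- function(S, lb, ub, obj, maximize = TRUE,
                     extra_a = NULL, extra_rhs = NULL, beq = NULL) {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  n_all <- length(lb)
  if (is.null(beq)) beq <- numeric(nrow(S))
  # presolve: substitute out fixed variables (lb == ub) and drop equality rows
  # no remaining variable touches; zero-width columns upset the simplex tableau
  fixed <- which(ub - lb <= 0)
  if (length(fixed)) {
    vfix <- lb[fixed]
    keep <- setdiff(seq_len(n_all), fixed)
    beq2 <- beq - as.numeric(S[, fixed, drop = FALSE] %*% vfix)
    obj_fix <- sum(obj[fixed] * vfix)
    Sk <- S[, keep, drop = FALSE]
    rows_keep <- apply(Sk != 0, 1L, any)
    if (any(abs(beq2[!rows_keep]) > 1e-9)) {
      return(list(status = "infeasible", value = NA_real_,
                  fluxes = rep(NA_real_, n_all)))
    }
    inner <- solve_lp(
      Sk[rows_keep, , drop = FALSE], lb[keep], ub[keep], obj[keep],
      maximize = maximize,
      extra_a = if (is.null(extra_a)) NULL else extra_a[keep],
      extra_rhs = if (is.null(extra_rhs)) NULL else
        extra_rhs - sum(extra_a[fixed] * vfix),
      beq = beq2[rows_keep])
    fluxes <- rep(NA_real_, n_all)
    if (inner$status == "optimal") {
      fluxes[fixed] <- vfix
      fluxes[keep] <- inner$fluxes
    }
    return(list(status = inner$status,
                value = if (inner$status == "optimal")
                  inner$value + obj_fix else NA_real_,
                fluxes = fluxes))
  }
  n <- n_all
  if (n == 0L) {
    feas <- all(abs(beq) <= 1e-9) &&
      (is.null(extra_rhs) || extra_rhs <= 1e-9)
    return(list(status = if (feas) "optimal" else "infeasible",
                value = if (feas) 0 else NA_real_, fluxes = numeric()))
  }
  # shift x = v - lb >= 0; optional a'v >= rhs becomes an equality with a
  # surplus column
  A <- S
  rhs <- as.numeric(beq - S %*% lb)
  u <- ub - lb
  cvec <- obj
  if (!is.null(extra_a)) {
    A <- rbind(cbind(A, 0), c(extra_a, -1))
    rhs <- c(rhs, extra_rhs - sum(extra_a * lb))
    u <- c(u, Inf)
    cvec <- c(cvec, 0)
  }
  if (!maximize) cvec <- -cvec
  res <- simplex_bounded(A, rhs, cvec, u)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_,
                fluxes = rep(NA_real_, n)))
  }
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal",
       value = sum(obj * v),
       fluxes = v)
}

objective_vector <- function(model, objective = NULL) {
  if (is.null(objective)) {
    if (length(model$objective) == 0L) {
      stop("model declares no objective; supply `objective = ", '"<reaction id>"',
           "`", call. = FALSE)
    }
    obj <- model$objective
  } else if (is.character(objective)) {
    obj <- stats::setNames(rep(1, length(objective)), objective)
  } else {
    obj <- objective
  }
  if (!all(names(obj) %in% model$reactions$id)) {
    stop("objective references unknown reaction", call. = FALSE)
  }
  full <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
  full[names(obj)] <- obj
  full
}

#' Flux balance analysis
#'
#' Maximizes the model's linear objective (by default the declared active
#' objective, e.g. an ATP demand reaction) subject to steady state
#' \eqn{S v = 0} and the flux bounds. Returns one optimal vertex; where the
#' optimum is degenerate the individual fluxes are solver-dependent, so
#' downstream comparisons should use the objective value, class-wise ATP sums
#' or FVA envelopes.
#'
#' @param model A [metabolic_network].
#' @param objective Optional objective override: reaction id(s) or a named
#'   coefficient vector.
#' @param tol Fluxes with absolute value below `tol` are reported as exact 0.
#' @return A tibble (class `flx_fba`) with columns `reaction`, `flux`;
#'   attributes `objective_value` and `status`
#'   (`"optimal"`/`"infeasible"`/`"unbounded"`), surfaced by [glance()].
#' @export
fba <- function(model, objective = NULL, tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_network"))
  obj <- objective_vector(model, objective)
  S <- stoich_matrix(model)
  sol <- solve_lp(S, model$reactions$lb, model$reactions$ub, obj)
  fluxes <- sol$fluxes
  fluxes[!is.na(fluxes) & abs(fluxes) < tol] <- 0
  out <- tibble::tibble(reaction = model$reactions$id, flux = fluxes)
  structure(out, class = c("flx_fba", class(out)),
            objective_value = if (sol$status == "optimal") sol$value else
              NA_real_,
            status = sol$status)
}

#' @exportS3Method generics::tidy
tidy.flx_fba <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.flx_fba <- function(x, ...) {
  tibble::tibble(objective_value = attr(x, "objective_value"),
                 status = attr(x, "status"),
                 n_reactions = nrow(x))
}

#' Flux variability analysis
#'
#' For each reaction, the minimal and maximal flux subject to steady state,
#' the bounds, and the objective held at at least `fraction_of_optimum` times
#' the FBA optimum. At the default fraction 1 the envelopes describe the
#' optimal face, so every FVA interval brackets the corresponding FBA flux.
#'
#' @inheritParams fba
#' @param fraction_of_optimum Fraction of the optimal objective to retain
#'   (default 1).
#' @param reactions Reactions to analyse (default: all).
#' @return A tibble (class `flx_fva`) with columns `reaction`, `min`, `max`;
#'   attributes `objective_value` (the FBA optimum) and
#'   `fraction_of_optimum`.
#' @export
fva <- function(model, fraction_of_optimum = 1, reactions = NULL,
                objective = NULL, tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_network"))
  obj <- objective_vector(model, objective)
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  base <- solve_lp(S, lb, ub, obj)
  if (base$status != "optimal") {
    stop("FVA base problem is ", base$status, call. = FALSE)
  }
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- match(reactions, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction(s): ",
         paste(reactions[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  # hair of numerical slack so the optimal face stays feasible at fraction 1
  target <- fraction_of_optimum * base$value -
    1e-9 * max(1, abs(base$value))
  bounds <- vapply(idx, function(i) {
    unit <- stats::setNames(numeric(length(lb)), model$reactions$id)
    unit[i] <- 1
    lo <- solve_lp(S, lb, ub, unit, maximize = FALSE,
                   extra_a = obj, extra_rhs = target)
    hi <- solve_lp(S, lb, ub, unit, maximize = TRUE,
                   extra_a = obj, extra_rhs = target)
    c(lo$value, hi$value)
  }, numeric(2))
  mn <- bounds[1, ]; mx <- bounds[2, ]
  mn[abs(mn) < tol] <- 0; mx[abs(mx) < tol] <- 0
  # numerical guard: envelopes may cross by solver tolerance only
  swap <- mn > mx
  if (any(swap & (mn - mx) > 1e-6)) {
    stop("FVA produced inverted interval beyond tolerance", call. = FALSE)
  }
  mid <- (mn[swap] + mx[swap]) / 2
  mn[swap] <- mid; mx[swap] <- mid
  out <- tibble::tibble(reaction = reactions, min = mn, max = mx)
  structure(out, class = c("flx_fva", class(out)),
            objective_value = base$value,
            fraction_of_optimum = fraction_of_optimum)
}

#' @exportS3Method generics::tidy
tidy.flx_fva <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.flx_fva <- function(x, ...) {
  tibble::tibble(objective_value = attr(x, "objective_value"),
                 fraction_of_optimum = attr(x, "fraction_of_optimum"),
                 n_reactions = nrow(x))
}

#' @exportS3Method ggplot2::autoplot
autoplot.flx_fva <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(y = stats::reorder(.data$reaction,
                                                      .data$max))) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$min, xmax = .data$max), height = 0.3) +
    ggplot2::geom_point(ggplot2::aes(x = (.data$min + .data$max) / 2),
                        size = 0.8) +
    ggplot2::labs(x = "flux", y = NULL,
                  title = "Flux variability envelopes") +
    ggplot2::theme_minimal()
}

#' Write FBA/FVA results as CSV
#'
#' `reaction,flux` for FBA results, `reaction,min,max` for FVA results.
#'
#' @param result A `flx_fba` or `flx_fva` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(result, path) {
  readr::write_csv(tibble::as_tibble(result), path)
  invisible(path)
}
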