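#' Trap spaces of a Boolean network
#'
#' A subspace (partial assignment of variables to 0/1, the rest free) is a
#' trap space when no trajectory can leave it: for every fixed variable
#' \eqn{v = b}, the update function \eqn{f_v} evaluates to \eqn{b} on every
#' complete state inside the subspace. Minimal trap spaces over-approximate
#' the asynchronous attractors and stand for the model's asymptotic behaviour;
#' components fixed at 0 in every minimal trap space are proven asymptotically
#' inactive and are the source of the metabolic zero-flux constraints.
#'
#' @name trap_spaces
NULL

#' Test whether a subspace is a trap space
#'
#' @param net A [boolean_network].
#' @param m Named vector over (a subset of) the network's variables with
#'   values 0/1; variables absent or `NA` are free.
#' @return `TRUE` iff `m` is closed under the dynamics: every implicant of
#'   \eqn{f_v} toward the value opposite to `m[v]` is contradicted by `m`,
#'   for every fixed `v`.
#' @examples
#' net <- parse_bnet("x, !y\ny, !x")
#' is_trap_space(net, c(x = 1, y = 0))
#' @export
is_trap_space <- function(net, m) {
  stopifnot(inherits(net, "boolean_network"))
  m <- m[!is.na(m)]
  bad <- setdiff(names(m), net$variables)
  if (length(bad)) {
    stop("subspace fixes undeclared variable(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) stop("subspace values must be 0/1", call. = FALSE)
  pis <- network_prime_implicants(net)
  for (v in names(m)) {
    b <- as.integer(m[[v]])
    opp <- if (b == 1L) pis[[v]]$toward0 else pis[[v]]$toward1
    for (imp in opp) {
      # blocked iff some literal (w = x) is contradicted: m fixes w to 1-x
      lits <- names(imp)
      fixed <- lits[lits %in% names(m)]
      if (!any(m[fixed] == 1L - imp[fixed])) return(FALSE)
    }
  }
  TRUE
}

#' Compute all minimal trap spaces
#'
#' Complete search over partial assignments in \{0, 1, free\} with
#' unit-propagation on the prime-implicant closure constraints (the
#' place/negated-place siphon encoding of the implicants, explored as an
#' iterative constraint search), followed by inclusion-minimality filtering.
#' Exact: returns precisely the inclusion-minimal trap spaces; every complete
#' fixed point appears among them, and the all-free subspace is returned when
#' it is the only trap space.
#'
#' @param net A [boolean_network].
#' @return A tibble with one row per minimal trap space and one column per
#'   variable; cells are `"0"`, `"1"` or `"-"` (free). Rows are ordered
#'   lexicographically for reproducible output. Class `flx_trap_spaces`.
#' @examples
#' minimal_trap_spaces(parse_bnet("x, !y\ny, !x"))
#' @export
minimal_trap_spaces <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  vars <- net$variables
  n <- length(vars)
  if (n == 0L) {
    out <- tibble::as_tibble(matrix(character(), 1L, 0L))
    return(structure(out, class = c("flx_trap_spaces", class(out))))
  }
  pis <- network_prime_implicants(net)
  # index implicants by variable id; literals as integer var ids
  opp <- vector("list", n)  # opp[[v]][[b+1]] = implicants toward 1-b ... see below
  for (i in seq_len(n)) {
    tow <- pis[[vars[[i]]]]
    conv <- function(lst) lapply(lst, function(imp) {
      list(vars = match(names(imp), vars), vals = as.integer(imp))
    })
    # when v is fixed to 0 we must block implicants toward 1; to 1 -> toward 0
    opp[[i]] <- list(conv(tow$toward1), conv(tow$toward0))
  }

  UNDEC <- -1L; FREE <- 2L
  traps <- list()

  # propagate: returns updated assignment or NULL on contradiction
  propagate <- function(a) {
    repeat {
      changed <- FALSE
      for (v in which(a == 0L | a == 1L)) {
        for (imp in opp[[v]][[a[v] + 1L]]) {
          w <- imp$vars; x <- imp$vals
          if (any(a[w] == 1L - x)) next            # blocked
          cand <- w[a[w] == UNDEC]
          if (length(cand) == 0L) return(NULL)     # unblockable -> contradiction
          if (length(cand) == 1L) {
            xi <- x[match(cand, w)]
            a[cand] <- 1L - xi                     # forced blocker
            changed <- TRUE
          }
        }
      }
      if (!changed) return(a)
    }
  }

  search <- function(a) {
    a <- propagate(a)
    if (is.null(a)) return(invisible())
    j <- which(a == UNDEC)[1]
    if (is.na(j)) {
      traps[[length(traps) + 1L]] <<- a
      return(invisible())
    }
    for (val in c(0L, 1L, FREE)) {
      a2 <- a
      a2[j] <- val
      search(a2)
    }
  }
  search(rep(UNDEC, n))

  # minimality: process by decreasing number of fixed variables; a candidate is
  # minimal unless an accepted (more-fixed) trap space extends its assignment.
  nfixed <- vapply(traps, function(a) sum(a != FREE), 0L)
  ord <- order(-nfixed)
  accepted <- list()
  for (idx in ord) {
    a <- traps[[idx]]
    fixed <- which(a != FREE)
    contained <- FALSE
    for (t in accepted) {
      if (all(t[fixed] == a[fixed])) { contained <- TRUE; break }
    }
    if (!contained) accepted[[length(accepted) + 1L]] <- a
  }

  rows <- vapply(accepted, function(a) {
    ifelse(a == FREE, "-", as.character(a))
  }, character(n))
  mat <- if (n == 1L) matrix(rows, ncol = 1L) else t(rows)
  colnames(mat) <- vars
  mat <- mat[order(apply(mat, 1L, paste, collapse = "")), , drop = FALSE]
  out <- tibble::as_tibble(mat)
  structure(out, class = c("flx_trap_spaces", class(out)))
}

#' Project the maximal trap-space value of components
#'
#' For each requested component, the projected value is 0 only when **every**
#' minimal trap space fixes it to 0 — the component is then proven
#' asymptotically inactive. A component that reaches 1 in some trap space, or
#' is left free in one (possibly active), projects to 1.
#'
#' @param traps A `flx_trap_spaces` tibble from [minimal_trap_spaces()].
#' @param components Character vector of component names (must be columns of
#'   `traps`).
#' @return A tibble with columns `component` and `value` (integer 0/1).
#' @export
project_max <- function(traps, components) {
  stopifnot(is.data.frame(traps))
  if (nrow(traps) == 0L) {
    stop("cannot project over an empty trap-space set", call. = FALSE)
  }
  bad <- setdiff(components, colnames(traps))
  if (length(bad)) {
    stop("unknown component(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  value <- vapply(components, function(cmp) {
    if (all(traps[[cmp]] == "0")) 0L else 1L
  }, integer(1))
  tibble::tibble(component = components, value = unname(value))
}

#' Write trap spaces as CSV
#'
#' One row per trap space, one column per variable, cells in `{0, 1, -}`.
#'
#' @param traps A `flx_trap_spaces` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trap_spaces <- function(traps, path) {
  readr::write_csv(tibble::as_tibble(traps), path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.flx_trap_spaces <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$`.trap` <- factor(seq_len(nrow(df)))
  long <- tidyr_pivot_longer(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variable, y = .data$.trap,
                                     fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`0` = "#4575b4", `1` = "#d73027",
                                          `-` = "grey85")) +
    ggplot2::labs(x = NULL, y = "minimal trap space", fill = "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# minimal local pivot (avoids a tidyr dependency for one reshape)
tidyr_pivot_longer <- function(df) {
  vars <- setdiff(names(df), ".trap")
  tibble::tibble(
    .trap = rep(df$`.trap`, times = length(vars)),
    variable = rep(vars, each = nrow(df)),
    value = unlist(lapply(vars, function(v) as.character(df[[v]])),
                   use.names = FALSE)
  )
}
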