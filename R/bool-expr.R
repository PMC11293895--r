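#' Boolean expression trees
#'
#' Update functions of a Boolean network are stored as small expression trees
#' built from variable references, the constants 0/1, negation, conjunction and
#' disjunction. Constructors are exported so networks can be assembled
#' programmatically; most users will obtain expressions by parsing BNET text
#' ([parse_bnet()]) or SBML-qual files ([read_sbml_qual()]).
#'
#' @param name Variable name (single string, `[A-Za-z0-9_]+`).
#' @param value Constant value, 0 or 1.
#' @param x,... Child expressions.
#' @return An object of class `bool_expr`.
#' @examples
#' e <- bx_or(bx_and(bx_var("A"), bx_not(bx_var("B"))), bx_const(1))
#' format(e)
#' @name bool_expr
NULL

new_bool_expr <- function(op, ...) {
  structure(list(op = op, ...), class = "bool_expr")
}

#' @rdname bool_expr
#' @export
bx_var <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("^[A-Za-z0-9_]+$", name) || name %in% c("0", "1")) {
    stop("invalid variable name: '", name, "'", call. = FALSE)
  }
  new_bool_expr("var", name = name)
}

#' @rdname bool_expr
#' @export
bx_const <- function(value) {
  value <- as.integer(value)
  stopifnot(length(value) == 1L, value %in% c(0L, 1L))
  new_bool_expr("const", value = value)
}

#' @rdname bool_expr
#' @export
bx_not <- function(x) {
  stopifnot(inherits(x, "bool_expr"))
  new_bool_expr("not", arg = x)
}

#' @rdname bool_expr
#' @export
bx_and <- function(...) {
  args <- flatten_args(list(...))
  stopifnot(length(args) >= 1L)
  if (length(args) == 1L) return(args[[1L]])
  new_bool_expr("and", args = args)
}

#' @rdname bool_expr
#' @export
bx_or <- function(...) {
  args <- flatten_args(list(...))
  stopifnot(length(args) >= 1L)
  if (length(args) == 1L) return(args[[1L]])
  new_bool_expr("or", args = args)
}

flatten_args <- function(args) {
  out <- list()
  for (a in args) {
    if (inherits(a, "bool_expr")) out <- c(out, list(a))
    else if (is.list(a)) out <- c(out, flatten_args(a))
    else stop("expected bool_expr arguments", call. = FALSE)
  }
  out
}

#' Variables referenced by an expression
#'
#' @param expr A `bool_expr`.
#' @return Character vector of distinct variable names, sorted.
#' @export
expr_vars <- function(expr) {
  stopifnot(inherits(expr, "bool_expr"))
  collect <- function(e) {
    switch(e$op,
      var = e$name,
      const = character(),
      not = collect(e$arg),
      and = ,
      or = unlist(lapply(e$args, collect))
    )
  }
  sort(unique(collect(expr)))
}

#' Evaluate a Boolean expression on a complete state
#'
#' Standard Boolean semantics; evaluation is total and deterministic on any
#' state that assigns every referenced variable.
#'
#' @param expr A `bool_expr`.
#' @param state Named vector (0/1 or logical) assigning every variable
#'   referenced by `expr`.
#' @return Integer 0 or 1.
#' @examples
#' evaluate_expr(bx_not(bx_var("B")), c(B = 1))
#' @export
evaluate_expr <- function(expr, state) {
  stopifnot(inherits(expr, "bool_expr"))
  state <- as.integer(state[!is.na(names(state))] != 0) |>
    stats::setNames(names(state))
  missing_vars <- setdiff(expr_vars(expr), names(state))
  if (length(missing_vars)) {
    stop("variable '", missing_vars[[1]], "' is not assigned in the state",
         call. = FALSE)
  }
  rec <- function(e) {
    switch(e$op,
      var = {
        v <- state[[e$name]] %||% NA_integer_
        if (is.na(v)) {
          stop("variable '", e$name, "' is not assigned in the state",
               call. = FALSE)
        }
        v
      },
      const = e$value,
      not = 1L - rec(e$arg),
      and = { for (a in e$args) if (rec(a) == 0L) return(0L); 1L },
      or = { for (a in e$args) if (rec(a) == 1L) return(1L); 0L }
    )
  }
  rec(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorised evaluation over a 0/1 state matrix (columns named by variable).
# Used by truth-table utilities and the map-inference checks.
eval_expr_matrix <- function(expr, states) {
  rec <- function(e) {
    switch(e$op,
      var = {
        if (!e$name %in% colnames(states)) {
          stop("variable '", e$name, "' missing from state matrix", call. = FALSE)
        }
        states[, e$name] != 0
      },
      const = rep(e$value == 1L, nrow(states)),
      not = !rec(e$arg),
      and = Reduce(`&`, lapply(e$args, rec)),
      or = Reduce(`|`, lapply(e$args, rec))
    )
  }
  as.integer(rec(expr))
}

#' @export
format.bool_expr <- function(x, ...) {
  fmt <- function(e, parent) {
    switch(e$op,
      var = e$name,
      const = as.character(e$value),
      not = {
        inner <- fmt(e$arg, "not")
        if (e$arg$op %in% c("and", "or")) paste0("!(", inner, ")")
        else paste0("!", inner)
      },
      and = {
        s <- paste(vapply(e$args, fmt, "", parent = "and"), collapse = " & ")
        if (parent == "not") paste0("(", s, ")") else s
      },
      or = {
        s <- paste(vapply(e$args, fmt, "", parent = "or"), collapse = " | ")
        if (parent %in% c("and", "not")) paste0("(", s, ")") else s
      }
    )
  }
  fmt(x, "top")
}

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr> ", format(x), "\n", sep = "")
  invisible(x)
}

# All 2^n complete states over `vars`, as a 0/1 matrix with named columns.
# Row order: first variable varies slowest (row i encodes i-1 in binary,
# most-significant bit = first variable).
state_matrix <- function(vars) {
  n <- length(vars)
  if (n == 0L) {
    return(matrix(integer(), nrow = 1L, ncol = 0L,
                  dimnames = list(NULL, character())))
  }
  idx <- 0:(2L^n - 1L)
  m <- vapply(seq_len(n), function(j) {
    bitwAnd(bitwShiftR(idx, n - j), 1L)
  }, integer(length(idx)))
  colnames(m) <- vars
  m
}
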