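#' Boolean networks
#'
#' A Boolean network is an ordered set of uniquely named binary variables, each
#' carrying an update function over the network's variables. It is the
#' regulatory half of the regulatory-metabolic coupling pipeline.
#'
#' @param functions Named list of [bool_expr] objects; names are the variables.
#' @return An object of class `boolean_network` with fields `variables`
#'   (character) and `functions` (named list of `bool_expr`).
#' @examples
#' net <- boolean_network(list(A = bx_not(bx_var("B")), B = bx_var("A")))
#' net
#' @export
boolean_network <- function(functions) {
  stopifnot(is.list(functions))
  vars <- names(functions)
  if (is.null(vars) || any(vars == "") ) {
    stop("every update function must be named", call. = FALSE)
  }
  if (anyDuplicated(vars)) {
    stop("duplicate variable definition: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "), call. = FALSE)
  }
  for (v in vars) {
    if (!inherits(functions[[v]], "bool_expr")) {
      stop("update function of '", v, "' is not a bool_expr", call. = FALSE)
    }
    bad <- setdiff(expr_vars(functions[[v]]), vars)
    if (length(bad)) {
      stop("update function of '", v, "' references undeclared variable(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(variables = vars, functions = functions),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("<boolean_network> ", length(x$variables), " variables\n", sep = "")
  for (v in x$variables) {
    cat("  ", v, " <- ", format(x$functions[[v]]), "\n", sep = "")
  }
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.boolean_network <- function(x, ...) {
  tibble::tibble(
    target = x$variables,
    factors = vapply(x$functions, format, "", USE.NAMES = FALSE)
  )
}

#' @exportS3Method generics::glance
glance.boolean_network <- function(x, ...) {
  indeg <- vapply(x$functions, function(f) length(expr_vars(f)), 0L)
  inputs <- vapply(x$variables, function(v) {
    f <- x$functions[[v]]
    f$op == "var" && f$name == v
  }, logical(1))
  tibble::tibble(
    n_variables = length(x$variables),
    n_inputs = sum(inputs),
    max_in_degree = if (length(indeg)) max(indeg) else 0L
  )
}

#' Parse the BNET text format
#'
#' The BNET dialect consumed by trap-space tools: one `target, factors` line
#' per variable, operators `&` (and), `|` (or), `!` (not), parentheses and the
#' constants `0` and `1`. Lines starting with `#` and the conventional header
#' `targets, factors` are ignored. Variable names are case-sensitive and match
#' `[A-Za-z0-9_]+`.
#'
#' @param text BNET source, either a single string (possibly with newlines) or
#'   a character vector of lines.
#' @return A [boolean_network].
#' @examples
#' parse_bnet("A, !B\nB, A")
#' @seealso [write_bnet()], [read_bnet()]
#' @export
parse_bnet <- function(text) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  funs <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^targets\\s*,\\s*factors$", line, ignore.case = TRUE)) next
    comma <- regexpr(",", line, fixed = TRUE)
    if (comma < 0) {
      stop("BNET parse error at line ", i, ": expected 'target, expression'",
           call. = FALSE)
    }
    target <- trimws(substr(line, 1L, comma - 1L))
    rhs <- trimws(substr(line, comma + 1L, nchar(line)))
    if (!grepl("^[A-Za-z0-9_]+$", target) || target %in% c("0", "1")) {
      stop("BNET parse error at line ", i, ": invalid target name '",
           target, "'", call. = FALSE)
    }
    if (!is.null(funs[[target]])) {
      stop("duplicate definition of target '", target, "' at line ", i,
           call. = FALSE)
    }
    funs[[target]] <- parse_bool_formula(rhs, line = i)
  }
  boolean_network(funs)
}

#' Parse a single Boolean formula
#'
#' Recursive-descent parser for the BNET expression dialect (`& | !`,
#' parentheses, constants `0`/`1`); precedence `!` > `&` > `|`.
#'
#' @param src Formula source string, e.g. `"A & !B | C"`.
#' @param line Line number used in error messages (internal).
#' @return A [bool_expr].
#' @export
parse_bool_formula <- function(src, line = NA) {
  toks <- tokenize_formula(src, line)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { pos <<- pos + 1L }
  perr <- function(msg) {
    where <- if (is.na(line)) "" else paste0(" at line ", line)
    stop("BNET parse error", where, ": ", msg, call. = FALSE)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "|")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else new_bool_expr("or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_unary())
    while (identical(peek(), "&")) {
      advance()
      args <- c(args, list(parse_unary()))
    }
    if (length(args) == 1L) args[[1L]] else new_bool_expr("and", args = args)
  }
  parse_unary <- function() {
    t <- peek()
    if (is.null(t)) perr("unexpected end of expression")
    if (t == "!") {
      advance()
      return(bx_not(parse_unary()))
    }
    if (t == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) perr("missing closing parenthesis")
      advance()
      return(e)
    }
    if (t %in% c("0", "1")) {
      advance()
      return(bx_const(as.integer(t)))
    }
    if (grepl("^[A-Za-z0-9_]+$", t)) {
      advance()
      return(bx_var(t))
    }
    perr(paste0("unexpected token '", t, "'"))
  }
  e <- parse_or()
  if (!is.null(peek())) perr(paste0("trailing input '", peek(), "'"))
  e
}

tokenize_formula <- function(src, line = NA) {
  rest <- src
  toks <- character()
  while (nchar(rest <- sub("^\\s+", "", rest)) > 0L) {
    m <- regmatches(rest, regexpr("^([A-Za-z0-9_]+|[&|!()])", rest))
    if (length(m) == 0L) {
      where <- if (is.na(line)) "" else paste0(" at line ", line)
      stop("BNET parse error", where, ": cannot tokenize near '",
           substr(rest, 1, 10), "'", call. = FALSE)
    }
    toks <- c(toks, m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  as.list(toks)
}

#' Serialize a Boolean network to BNET text
#'
#' Output is deterministic (alphabetical by variable) and re-parseable by
#' [parse_bnet()]; round trips preserve every update function's truth table.
#'
#' @param net A [boolean_network].
#' @param path Optional file path; when given the text is also written there.
#' @return The BNET text, invisibly when `path` is given.
#' @export
write_bnet <- function(net, path = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  vars <- sort(net$variables)
  lines <- vapply(vars, function(v) {
    paste0(v, ", ", format(net$functions[[v]]))
  }, "")
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(c("targets, factors", lines), path)
    return(invisible(text))
  }
  text
}

#' @rdname parse_bnet
#' @param path Path to a BNET file.
#' @export
read_bnet <- function(path) {
  parse_bnet(readLines(path, warn = FALSE))
}

#' Full synchronous truth table of a network
#'
#' One row per complete state (all \eqn{2^n}), one column per variable plus
#' the image columns `<var>_next`. Exact at small n; intended for desk-scale
#' inspection and tests.
#'
#' @param net A [boolean_network] (n of at most ~20).
#' @return A tibble with `2^n` rows.
#' @export
truth_table <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  states <- state_matrix(net$variables)
  nxt <- vapply(net$variables, function(v) {
    eval_expr_matrix(net$functions[[v]], states)
  }, integer(nrow(states)))
  if (is.null(dim(nxt))) nxt <- matrix(nxt, nrow = 1L)
  colnames(nxt) <- paste0(net$variables, "_next")
  tibble::as_tibble(cbind(states, nxt))
}
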