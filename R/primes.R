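#' Prime implicants of an update function
#'
#' A prime implicant toward a value \eqn{b} is a minimal partial assignment of
#' the function's regulators that forces the function to \eqn{b}: the
#' assignment implies \eqn{f = b}, and dropping any literal breaks that.
#' Implicants toward 0 are the prime implicants of the negated function. They
#' are the building blocks of the trap-space constraint encoding: a subspace
#' fixing \eqn{v} to \eqn{b} is closed for \eqn{v} exactly when every implicant
#' of \eqn{f_v} toward \eqn{1-b} is contradicted by the subspace.
#'
#' Computed by Quine-McCluskey merging over the truth table restricted to the
#' function's support, so functions are limited to ~16 regulators; the update
#' functions of curated maps are far sparser.
#'
#' @param f A [bool_expr].
#' @param value Target value, 0 or 1.
#' @return A list of named integer vectors; each vector is one prime implicant
#'   (names = regulators, values = required 0/1). A constant function equal to
#'   `value` yields a single empty implicant; a constant unequal to `value`
#'   yields an empty list.
#' @examples
#' prime_implicants(parse_bool_formula("A & B"), 1)
#' prime_implicants(parse_bool_formula("(A & B) | (!A & C)"), 1)
#' @export
prime_implicants <- function(f, value) {
  stopifnot(inherits(f, "bool_expr"), value %in% c(0, 1))
  value <- as.integer(value)
  support <- expr_vars(f)
  k <- length(support)
  if (k > 16L) {
    stop("prime_implicants: function has ", k,
         " regulators; the truth-table method supports at most 16",
         call. = FALSE)
  }
  states <- state_matrix(support)
  tt <- eval_expr_matrix(f, states)
  rows <- which(tt == value)
  if (length(rows) == 0L) return(list())
  if (k == 0L) return(list(stats::setNames(integer(), character())))

  # Quine-McCluskey: implicants are rows in {0,1,NA}^k; merge pairs that agree
  # everywhere except one determined position. Uncombined implicants are prime.
  level <- unique(lapply(rows, function(r) states[r, ]))
  primes <- list()
  while (length(level) > 0L) {
    mat <- do.call(rbind, lapply(level, function(x) ifelse(is.na(x), 2L, x)))
    combined <- logical(length(level))
    nxt <- list()
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        diffpos <- which(mat[i, ] != mat[j, ])
        if (length(diffpos) == 1L && mat[i, diffpos] != 2L &&
            mat[j, diffpos] != 2L) {
          merged <- level[[i]]
          merged[diffpos] <- NA_integer_
          nxt <- c(nxt, list(merged))
          combined[i] <- TRUE
          combined[j] <- TRUE
        }
      }
    }
    primes <- c(primes, level[!combined])
    level <- unique(nxt)
  }
  primes <- unique(primes)
  out <- lapply(primes, function(p) {
    keep <- !is.na(p)
    stats::setNames(as.integer(p[keep]), support[keep])
  })
  # deterministic order: fewest literals first, then lexicographic
  key <- vapply(out, function(p) {
    paste(sprintf("%02d", length(p)),
          paste(names(p), p, sep = "=", collapse = ","))
  }, "")
  out[order(key)]
}

# Prime implicants of every update function, both polarities.
# Returns list with elements [[v]]$toward1 / $toward0 (lists of named vectors).
network_prime_implicants <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  out <- lapply(net$variables, function(v) {
    list(
      toward1 = prime_implicants(net$functions[[v]], 1L),
      toward0 = prime_implicants(net$functions[[v]], 0L)
    )
  })
  stats::setNames(out, net$variables)
}
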