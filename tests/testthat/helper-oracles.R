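# Independent oracles used across the suite. They deliberately avoid the
# package's own evaluator, implicant and trap-space machinery: formulas are
# evaluated by R's parser on logical vectors (the BNET operators ! & | are
# valid R syntax), trap spaces are found by exhaustive closure checks on full
# truth tables, and attractors come from the asynchronous state-transition
# graph via igraph.

# formulas as strings, e.g. from the second column of a BNET file
oracle_formulas <- function(net) {
  vapply(net$variables, function(v) format(net$functions[[v]]), "")
}

# all 2^n states as a data.frame of logicals, first variable = MSB
oracle_states <- function(vars) {
  n <- length(vars)
  idx <- 0:(2^n - 1)
  df <- as.data.frame(lapply(seq_len(n), function(j) {
    bitwAnd(bitwShiftR(idx, n - j), 1) == 1
  }))
  names(df) <- vars
  df
}

# truth tables via R's own parser/evaluator: list var -> logical vector
oracle_truth_tables <- function(formulas, states) {
  lapply(formulas, function(f) {
    res <- eval(parse(text = f), envir = states)
    if (length(res) == 1L) res <- rep(res, nrow(states))
    as.logical(res)
  })
}

# exhaustive trap-space enumeration: all 3^n subspaces, closure checked
# against the truth tables state by state. Returns a character matrix in
# {0,1,-} with one row per trap space (unsorted).
oracle_trap_spaces <- function(net) {
  vars <- net$variables
  n <- length(vars)
  states <- oracle_states(vars)
  tts <- oracle_truth_tables(oracle_formulas(net), states)
  smat <- as.matrix(states)
  combos <- expand.grid(rep(list(c("0", "1", "-")), n),
                        stringsAsFactors = FALSE)
  names(combos) <- vars
  keep <- logical(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    m <- unlist(combos[r, , drop = TRUE])
    fixed <- which(m != "-")
    inside <- rep(TRUE, nrow(states))
    for (j in fixed) inside <- inside & (smat[, j] == (m[[j]] == "1"))
    ok <- TRUE
    for (j in fixed) {
      if (any(tts[[vars[j]]][inside] != (m[[j]] == "1"))) { ok <- FALSE; break }
    }
    keep[r] <- ok
  }
  as.matrix(combos[keep, , drop = FALSE])
}

# Same enumeration, vectorised for n up to ~10: subspaces are base-3 codes
# (coord 0/1 = fixed, 2 = free, first variable most significant). For each
# (variable j, value b) a lattice OR-propagation marks every subspace whose
# interior contains a state violating closure of j at b; a subspace is a trap
# space iff unmarked for all its fixed coordinates. Cross-validated against
# oracle_trap_spaces at small n.
oracle_trap_spaces_fast <- function(net) {
  vars <- net$variables
  n <- length(vars)
  states <- oracle_states(vars)
  tts <- oracle_truth_tables(oracle_formulas(net), states)
  n3 <- 3L^n
  idx <- 0:(2^n - 1)
  pos <- integer(length(idx))   # base-3 position of each complete state
  for (i in seq_len(n)) {
    pos <- pos + bitwAnd(bitwShiftR(idx, n - i), 1L) * 3L^(n - i)
  }
  codes <- 0:(n3 - 1)
  coord <- function(j) (codes %/% 3L^(n - j)) %% 3L
  ok <- rep(TRUE, n3)
  for (j in seq_len(n)) {
    for (b in c(0L, 1L)) {
      bad <- tts[[vars[j]]] != (b == 1L)
      T <- logical(n3)
      T[pos + 1L] <- bad
      for (i in seq_len(n)) {
        dim(T) <- c(3L^(n - i), 3L, 3L^(i - 1L))
        T[, 3L, ] <- T[, 1L, ] | T[, 2L, ]
        T <- as.logical(T)
      }
      ok <- ok & !(coord(j) == b & T)
    }
  }
  traps <- codes[ok]
  mat <- matrix("", length(traps), n, dimnames = list(NULL, vars))
  for (j in seq_len(n)) {
    cj <- (traps %/% 3L^(n - j)) %% 3L
    mat[, j] <- c("0", "1", "-")[cj + 1L]
  }
  mat
}

# minimal members of a trap-space matrix (subspace inclusion)
oracle_minimal <- function(traps) {
  if (nrow(traps) == 0L) return(traps)
  contains <- function(outer, inner) {
    fixed <- outer != "-"
    all(inner[fixed] == outer[fixed])
  }
  minimal <- vapply(seq_len(nrow(traps)), function(i) {
    !any(vapply(seq_len(nrow(traps)), function(j) {
      j != i && contains(traps[i, ], traps[j, ])
    }, logical(1)))
  }, logical(1))
  traps[minimal, , drop = FALSE]
}

# canonical sorted key for set comparison of trap-space matrices
trap_keys <- function(mat) {
  if (nrow(mat) == 0L) return(character())
  unname(sort(apply(mat, 1L, paste, collapse = "")))
}

# attractors of the fully asynchronous state-transition graph: terminal
# strongly connected components, as lists of state index vectors (1-based
# rows of oracle_states)
oracle_async_attractors <- function(net) {
  vars <- net$variables
  n <- length(vars)
  states <- oracle_states(vars)
  tts <- oracle_truth_tables(oracle_formulas(net), states)
  n_states <- nrow(states)
  from <- integer(); to <- integer()
  for (j in seq_len(n)) {
    cur <- states[[vars[j]]]
    nxt <- tts[[vars[j]]]
    moved <- which(cur != nxt)
    # flipping bit j of state i-1: bit j has weight 2^(n-j)
    from <- c(from, moved)
    to <- c(to, moved + ifelse(cur[moved], -1L, 1L) * 2L^(n - j))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), vertices = data.frame(name = 1:n_states))
  comp <- igraph::components(g, mode = "strong")
  cond_edges <- unique(data.frame(
    from = comp$membership[from], to = comp$membership[to]))
  cond_edges <- cond_edges[cond_edges$from != cond_edges$to, ]
  terminal <- setdiff(seq_len(comp$no), cond_edges$from)
  lapply(terminal, function(k) which(comp$membership == k))
}

# brute-force prime implicants of a formula toward `value`: all partial
# assignments over the support that force the value, filtered to minimal
oracle_prime_implicants <- function(formula, value) {
  vars <- sort(setdiff(all.vars(parse(text = formula)), c("0", "1")))
  k <- length(vars)
  if (k == 0L) {
    val <- as.logical(eval(parse(text = formula)))
    return(if (val == (value == 1)) {
      list(stats::setNames(integer(), character()))
    } else list())
  }
  states <- oracle_states(vars)
  tt <- oracle_truth_tables(stats::setNames(formula, "f"), states)[[1]]
  smat <- as.matrix(states)
  combos <- expand.grid(rep(list(c("0", "1", "-")), k),
                        stringsAsFactors = FALSE)
  names(combos) <- vars
  forces <- logical(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    m <- unlist(combos[r, , drop = TRUE])
    fixed <- which(m != "-")
    inside <- rep(TRUE, nrow(states))
    for (j in fixed) inside <- inside & (smat[, j] == (m[[j]] == "1"))
    forces[r] <- all(tt[inside] == (value == 1))
  }
  cand <- as.matrix(combos[forces, , drop = FALSE])
  if (k == 0L) {
    return(if (all(tt == (value == 1))) list(stats::setNames(integer(), character()))
           else list())
  }
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    fixed_i <- cand[i, ] != "-"
    !any(vapply(seq_len(nrow(cand)), function(j) {
      if (j == i) return(FALSE)
      fixed_j <- cand[j, ] != "-"
      # j strictly more general than i and still forcing
      all(!fixed_j | (fixed_i & cand[j, ] == cand[i, ])) && sum(fixed_j) < sum(fixed_i)
    }, logical(1)))
  }, logical(1))
  out <- lapply(which(keep), function(i) {
    fixed <- cand[i, ] != "-"
    stats::setNames(as.integer(cand[i, fixed]), vars[fixed])
  })
  out
}

# canonical key for an implicant list (set comparison)
implicant_keys <- function(lst) {
  sort(vapply(lst, function(p) {
    p <- p[order(names(p))]
    paste(names(p), p, sep = "=", collapse = ",")
  }, ""))
}

# subspace membership: is every state of `state_idx` (1-based) inside the
# trap-space row `row` (named character vector over the net's variables)?
states_in_subspace <- function(state_idx, row, vars) {
  n <- length(vars)
  fixed <- which(row != "-")
  all(vapply(state_idx, function(i) {
    bits <- bitwAnd(bitwShiftR(i - 1L, n - fixed), 1L)
    all(bits == as.integer(row[fixed]))
  }, logical(1)))
}
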