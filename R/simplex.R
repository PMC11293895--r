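# Bounded-variable two-phase primal simplex with Bland's rule.
#
# Solves max c'x subject to A x = b, 0 <= x <= u (u may be Inf), the exact
# form flux problems reduce to after shifting by the lower bounds. Dense and
# deliberately simple: basis systems are re-solved each iteration, Bland's
# pivoting rule guarantees termination on the degenerate bases that
# knockout-style models produce. Intended for desk-scale models (tens to a
# few hundred reactions).

simplex_bounded <- function(A, b, cvec, u, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    # no constraints: push each variable to whichever bound its cost prefers
    x <- ifelse(cvec > 0, u, 0)
    if (any(!is.finite(x))) return(list(status = "unbounded"))
    return(list(status = "optimal", x = x, value = sum(cvec * x)))
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  Aext <- cbind(A, diag(m))
  uext <- c(u, rep(Inf, m))
  art <- n + seq_len(m)

  basis <- art
  at_ub <- rep(FALSE, n + m)   # status of nonbasic variables

  run_phase <- function(cost, basis, at_ub, max_iter) {
    for (iter in seq_len(max_iter)) {
      nonbasic <- setdiff(seq_len(n + m), basis)
      B <- Aext[, basis, drop = FALSE]
      ub_nb <- nonbasic[at_ub[nonbasic]]
      rhs <- b
      if (length(ub_nb)) {
        rhs <- rhs - as.numeric(Aext[, ub_nb, drop = FALSE] %*% uext[ub_nb])
      }
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular"))
      y <- solve(t(B), cost[basis])
      d <- cost[nonbasic] - as.numeric(crossprod(Aext[, nonbasic, drop = FALSE], y))
      enter_lb <- nonbasic[!at_ub[nonbasic] & d > tol]
      enter_ub <- nonbasic[at_ub[nonbasic] & d < -tol]
      cand <- sort(c(enter_lb, enter_ub))
      if (length(cand) == 0L) {
        return(list(status = "optimal", basis = basis, at_ub = at_ub,
                    xB = xB))
      }
      j <- cand[[1L]]                       # Bland: smallest index
      up <- !at_ub[j]                       # entering increases from 0?
      dir <- solve(B, Aext[, j])
      if (!up) dir <- -dir
      # entering moves by t >= 0; basic values change by -t * dir
      lim_dn <- which(dir > tol)            # basic decreasing toward 0
      lim_up <- which(dir < -tol)           # basic increasing toward its ub
      t1 <- if (length(lim_dn)) min(xB[lim_dn] / dir[lim_dn]) else Inf
      t2 <- if (length(lim_up)) {
        min((uext[basis[lim_up]] - xB[lim_up]) / (-dir[lim_up]))
      } else Inf
      t3 <- uext[j]
      t <- min(t1, t2, t3)
      if (!is.finite(t)) return(list(status = "unbounded"))
      if (t3 <= t1 && t3 <= t2) {
        at_ub[j] <- !at_ub[j]               # bound flip, basis unchanged
        next
      }
      if (t1 <= t2) {
        leave_pos <- lim_dn[xB[lim_dn] / dir[lim_dn] <= t1 + tol]
        leave_pos <- leave_pos[which.min(basis[leave_pos])]
        at_ub[basis[leave_pos]] <- FALSE
      } else {
        leave_pos <- lim_up[(uext[basis[lim_up]] - xB[lim_up]) /
                              (-dir[lim_up]) <= t2 + tol]
        leave_pos <- leave_pos[which.min(basis[leave_pos])]
        at_ub[basis[leave_pos]] <- TRUE
      }
      at_ub[j] <- FALSE
      basis[leave_pos] <- j
    }
    list(status = "iteration_limit")
  }

  max_iter <- 500L * (n + m + 1L)
  cost1 <- c(rep(0, n), rep(-1, m))        # maximize -sum(artificials)
  ph1 <- run_phase(cost1, basis, at_ub, max_iter)
  if (ph1$status != "optimal") return(list(status = "infeasible"))
  x <- full_solution(ph1, Aext, uext, b, n, m)
  if (sum(x[art]) > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible"))
  }
  uext[art] <- 0                            # lock artificials at 0
  cost2 <- c(cvec, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, ph1$at_ub, max_iter)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  if (ph2$status != "optimal") return(list(status = "infeasible"))
  x <- full_solution(ph2, Aext, uext, b, n, m)
  xs <- x[seq_len(n)]
  list(status = "optimal", x = xs, value = sum(cvec * xs))
}

full_solution <- function(ph, Aext, uext, b, n, m) {
  x <- numeric(n + m)
  nonbasic <- setdiff(seq_len(n + m), ph$basis)
  x[nonbasic[ph$at_ub[nonbasic]]] <- uext[nonbasic[ph$at_ub[nonbasic]]]
  x[ph$basis] <- ph$xB
  # recompute basic values against the final nonbasic pattern
  rhs <- b
  ub_nb <- nonbasic[ph$at_ub[nonbasic]]
  if (length(ub_nb)) {
    rhs <- rhs - as.numeric(Aext[, ub_nb, drop = FALSE] %*% uext[ub_nb])
  }
  x[ph$basis] <- solve(Aext[, ph$basis, drop = FALSE], rhs)
  x
}
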