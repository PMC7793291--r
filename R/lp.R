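# Minimal dense two-phase primal simplex for the small exact LPs used in
# supported/unsupported classification (a handful of rows and at most a few
# hundred columns). Bland's rule guarantees termination on the degenerate
# instances that arise when frontier points are exactly coplanar.
#
# Solves: min c'x  s.t.  A x = b, x >= 0, with b >= 0 required.
# Returns list(status = "optimal" | "infeasible" | "unbounded", x, value).
lp_simplex <- function(A, b, c, tol = 1e-11) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(c) == n, all(b >= -tol))
  b <- pmax(b, 0)

  # phase 1: artificial basis
  T_ <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  res <- simplex_iterate(T_, basis, cost1, tol)
  if (res$status != "optimal" || res$value > 1e-8)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  T_ <- res$T_; basis <- res$basis

  # drive any artificial variables out of the basis (degenerate rows)
  for (r in which(basis > n)) {
    piv <- which(abs(T_[r, seq_len(n)]) > tol)
    if (length(piv)) {
      T_ <- pivot_tableau(T_, r, piv[1])
      basis[r] <- piv[1]
    }
  }
  keep_rows <- basis <= n
  T_ <- T_[keep_rows, , drop = FALSE]
  basis <- basis[keep_rows]
  T_ <- T_[, c(seq_len(n), ncol(T_)), drop = FALSE]

  # phase 2
  res <- simplex_iterate(T_, basis, c, tol)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, value = NA_real_))
  x <- numeric(n)
  x[res$basis] <- res$T_[, ncol(res$T_)]
  list(status = "optimal", x = x, value = sum(c * x))
}

simplex_iterate <- function(T_, basis, cost, tol) {
  m <- nrow(T_); n <- ncol(T_) - 1L
  repeat {
    cb <- cost[basis]
    # reduced costs (computed from the current tableau rows)
    red <- cost[seq_len(n)] - as.numeric(crossprod(T_[, seq_len(n), drop = FALSE], cb))
    enter_cands <- which(red < -tol)
    if (!length(enter_cands)) {
      return(list(status = "optimal", T_ = T_, basis = basis,
                  value = sum(cb * T_[, n + 1L])))
    }
    j <- min(enter_cands)                      # Bland: smallest index enters
    col <- T_[, j]
    pos <- which(col > tol)
    if (!length(pos))
      return(list(status = "unbounded", T_ = T_, basis = basis,
                  value = -Inf))
    ratio <- T_[pos, n + 1L] / col[pos]
    rmin <- min(ratio)
    leave_cands <- pos[ratio <= rmin + tol]
    r <- leave_cands[which.min(basis[leave_cands])]  # Bland: smallest basis leaves
    T_ <- pivot_tableau(T_, r, j)
    basis[r] <- j
  }
}

pivot_tableau <- function(T_, r, j) {
  T_[r, ] <- T_[r, ] / T_[r, j]
  for (i in seq_len(nrow(T_))) {
    if (i != r && abs(T_[i, j]) > 0)
      T_[i, ] <- T_[i, ] - T_[i, j] * T_[r, ]
  }
  T_
}
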