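#' Brute-force LP oracle by basic-solution enumeration
#'
#' An independent check on the simplex engine: for small problems, every
#' basic solution of \{A x = b, lb <= x <= ub\} is enumerated (choose a
#' column basis, pin the remaining variables at a bound, solve the square
#' system) and feasible ones are collected as candidate vertices. A linear
#' objective over a polytope with finite bounds attains its optimum at such
#' a point, so the exact optimum is the maximum over the candidate set.
#' This is exponential in the number of variables and is only meant for
#' problems with at most a dozen or so columns; it shares no code with the
#' simplex in [lp_run()].
#'
#' Infinite bounds are clamped to a big-M value derived from the finite
#' data; this is only valid when the optimum does not escape that box,
#' which holds for the stoichiometric test problems this oracle is used on.
#'
#' @param A,b,lb,ub equality-constrained LP data as in [lp_prepare()].
#' @return matrix with one column per feasible basic solution (possibly
#'   zero columns when the polytope is empty).
#' @export
lp_enumerate_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  finite_mag <- c(abs(b), abs(lb[is.finite(lb)]), abs(ub[is.finite(ub)]), 1)
  bigM <- 100 * max(finite_mag) * max(1, max(abs(A)))
  lb2 <- ifelse(is.finite(lb), lb, -bigM)
  ub2 <- ifelse(is.finite(ub), ub, bigM)

  qa <- qr(A)
  r <- qa$rank
  # independent row subset (via QR of the transpose)
  qt <- qr(t(A))
  rows <- sort(qt$pivot[seq_len(r)])
  Ar <- A[rows, , drop = FALSE]
  br <- b[rows]

  sols <- list()
  if (r == 0L) {
    # box only: all bound corners (tiny n by assumption)
    stopifnot(n <= 16L)
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    return(apply(grid, 1, function(g) ifelse(g, ub2, lb2)))
  }
  bases <- utils::combn(n, r)
  for (k in seq_len(ncol(bases))) {
    B <- bases[, k]
    AB <- Ar[, B, drop = FALSE]
    qb <- qr(AB)
    if (qb$rank < r) next
    Nn <- setdiff(seq_len(n), B)
    nf <- length(Nn)
    grid <- if (nf == 0L) matrix(0, nrow = 0, ncol = 1) else
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nf)))
    if (nf > 0L) grid <- t(grid)
    for (g in seq_len(max(1L, ncol(grid)))) {
      xN <- if (nf == 0L) numeric(0) else ifelse(grid[, g], ub2[Nn], lb2[Nn])
      rhs <- br - if (nf == 0L) 0 else as.vector(Ar[, Nn, drop = FALSE] %*% xN)
      xB <- qr.coef(qb, rhs)
      if (any(!is.finite(xB))) next
      x <- numeric(n)
      x[B] <- xB
      x[Nn] <- xN
      if (any(x < lb2 - tol) || any(x > ub2 + tol)) next
      if (max(abs(as.vector(A %*% x) - b)) > tol) next
      sols[[length(sols) + 1L]] <- x
    }
  }
  if (length(sols) == 0L) return(matrix(0, nrow = n, ncol = 0))
  do.call(cbind, sols)
}

#' Brute-force LP solve
#'
#' @inheritParams lp_enumerate_vertices
#' @param obj objective coefficients.
#' @param sense `"max"` or `"min"`.
#' @return list with `status` and `objective` (and `x`, a maximiser).
#' @export
lp_enumerate_solve <- function(A, b, obj, lb, ub, sense = c("max", "min"),
                               tol = 1e-7) {
  sense <- match.arg(sense)
  V <- lp_enumerate_vertices(A, b, lb, ub, tol = tol)
  if (ncol(V) == 0L) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  vals <- as.vector(crossprod(obj, V))
  i <- if (sense == "max") which.max(vals) else which.min(vals)
  list(status = "optimal", objective = vals[i], x = V[, i])
}

#' Brute-force FVA over a vertex set
#'
#' Computes per-variable min/max over the enumerated feasible basic
#' solutions; equals the true FVA range for polytopes with finite bounds.
#'
#' @inheritParams lp_enumerate_vertices
#' @param idx variable indices to range over (default all).
#' @return data.frame with columns `index`, `min`, `max`.
#' @export
lp_enumerate_fva <- function(A, b, lb, ub, idx = NULL, tol = 1e-7) {
  n <- ncol(as.matrix(A))
  if (is.null(idx)) idx <- seq_len(n)
  V <- lp_enumerate_vertices(A, b, lb, ub, tol = tol)
  if (ncol(V) == 0L) stop("infeasible LP: no feasible basic solution")
  data.frame(index = idx,
             min = apply(V[idx, , drop = FALSE], 1, min),
             max = apply(V[idx, , drop = FALSE], 1, max))
}
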