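#' Linear programming engine
#'
#' A self-contained bounded-variable primal simplex solver used for all
#' flux-balance (FBA) and flux-variability (FVA) computations in the package.
#' Problems are stated as
#'
#'   max / min  c'x   subject to   A x = b,   lb <= x <= ub
#'
#' Inequality rows (e.g. flux-coupling constraints) are converted to
#' equalities with nonnegative slack variables before reaching this layer.
#' Phase I uses artificial variables; Phase II prices with Dantzig's rule and
#' falls back to Bland's rule after an iteration threshold so termination is
#' guaranteed under degeneracy. The basis inverse is maintained by product
#' updates and refactorised periodically.
#'
#' @name lp_engine
#' @keywords internal
NULL

#' Prepare a bounded LP for (repeated) solution
#'
#' Builds the internal problem representation once so that several objectives
#' can be solved over the same feasible region (as FVA requires), with warm
#' starts between solves.
#'
#' @param A constraint matrix (m x n), dense or sparse; equality rows.
#' @param b right-hand side, length m.
#' @param lb,ub variable bounds, length n; may contain -Inf/Inf.
#' @return an object of class `lp_problem`.
#' @export
lp_prepare <- function(A, b, lb, ub) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  b <- as.double(b)
  lb <- as.double(lb); ub <- as.double(ub)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    bad <- which(lb > ub + 1e-12)[1]
    stop("invalid bounds: lb > ub at variable ", bad)
  }
  structure(list(A = A, b = b, lb = lb, ub = ub, m = m, n = n),
            class = "lp_problem")
}

# Starting value for a nonbasic variable: finite lower bound preferred,
# then finite upper bound, else 0 (free variable).
.nb_value <- function(lb, ub, at_upper) {
  v <- ifelse(at_upper & is.finite(ub), ub,
              ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0)))
  v
}

#' Solve a prepared LP
#'
#' @param prob an `lp_problem` from [lp_prepare()].
#' @param obj objective coefficients, length n.
#' @param sense `"max"` or `"min"`.
#' @param start optional warm start: the `state` element of a previous
#'   solution over the same feasible region.
#' @param tol numerical tolerance (default 1e-9).
#' @param max_iter simplex iteration cap.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective`, `x` (length n), and `state` for warm starting.
#' @export
lp_run <- function(prob, obj, sense = c("max", "min"), start = NULL,
                   tol = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  m <- prob$m; n <- prob$n
  cvec <- as.double(obj)
  stopifnot(length(cvec) == n)
  if (sense == "min") cvec <- -cvec

  if (m == 0L) {
    # pure bound-constrained: optimum at bounds
    x <- ifelse(cvec > tol, prob$ub, ifelse(cvec < -tol, prob$lb,
                ifelse(is.finite(prob$lb), prob$lb,
                       ifelse(is.finite(prob$ub), prob$ub, 0))))
    if (any(!is.finite(x) & abs(cvec) > tol)) {
      return(list(status = "unbounded", objective = NA_real_, x = NULL,
                  state = NULL))
    }
    x[!is.finite(x)] <- 0
    objv <- sum(cvec * x)
    if (sense == "min") objv <- -objv
    return(list(status = "optimal", objective = objv, x = x, state = NULL))
  }

  # extended problem: n structural + m artificial columns
  N <- n + m
  lbx <- c(prob$lb, rep(0, m))
  ubx <- c(prob$ub, rep(Inf, m))

  res <- NULL
  if (!is.null(start)) {
    res <- .simplex_warm(prob, cvec, start, lbx, ubx, tol, max_iter)
  }
  if (is.null(res)) {
    res <- .simplex_cold(prob, cvec, lbx, ubx, tol, max_iter)
  }
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = NULL,
                state = NULL))
  }
  x <- res$x[seq_len(n)]
  objv <- sum(cvec * x)
  if (sense == "min") objv <- -objv
  list(status = "optimal", objective = objv, x = x,
       state = list(basis = res$basis, at_upper = res$at_upper,
                    art_sign = res$art_sign))
}

#' One-shot LP solve
#'
#' Convenience wrapper around [lp_prepare()] and [lp_run()].
#' @inheritParams lp_prepare
#' @inheritParams lp_run
#' @export
lp_solve <- function(A, b, obj, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, max_iter = 20000L) {
  prob <- lp_prepare(A, b, lb, ub)
  lp_run(prob, obj, sense = match.arg(sense), tol = tol, max_iter = max_iter)
}

# Cold start: Phase I with artificial basis, then Phase II.
.simplex_cold <- function(prob, cvec, lbx, ubx, tol, max_iter) {
  m <- prob$m; n <- prob$n; N <- n + m
  at_upper <- rep(FALSE, N)
  # nonbasic structural variables sit at a finite bound (lb preferred)
  at_upper[seq_len(n)] <- !is.finite(prob$lb) & is.finite(prob$ub)
  xN <- .nb_value(lbx[seq_len(n)], ubx[seq_len(n)], at_upper[seq_len(n)])
  r <- prob$b - as.vector(prob$A %*% xN)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(prob$A, diag(sgn, nrow = m))
  basis <- n + seq_len(m)

  # Phase I: maximize -(sum of artificials)
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- .simplex_iter(Afull, prob$b, c1, lbx, ubx, basis, at_upper,
                       tol, max_iter)
  if (ph1$status == "unbounded") stop("internal LP error: phase I unbounded")
  if (-ph1$objective > 1e-7) {
    return(list(status = "infeasible"))
  }
  # freeze artificials at zero and optimise the real objective
  lbx2 <- lbx; ubx2 <- ubx
  ubx2[n + seq_len(m)] <- 0
  c2 <- c(cvec, rep(0, m))
  ph2 <- .simplex_iter(Afull, prob$b, c2, lbx2, ubx2, ph1$basis, ph1$at_upper,
                       tol, max_iter)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  list(status = "optimal", x = ph2$x, basis = ph2$basis,
       at_upper = ph2$at_upper, objective = ph2$objective, art_sign = sgn)
}

# Warm start from a previous basis over the same feasible region; returns
# NULL if the start is unusable so the caller can fall back to a cold start.
.simplex_warm <- function(prob, cvec, start, lbx, ubx, tol, max_iter) {
  m <- prob$m; n <- prob$n
  basis <- start$basis; at_upper <- start$at_upper
  if (length(basis) != m || length(at_upper) != n + m) return(NULL)
  sgn <- start$art_sign
  if (is.null(sgn) || length(sgn) != m) sgn <- rep(1, m)
  Afull <- cbind(prob$A, diag(sgn, nrow = m))
  # basis feasibility check
  ok <- tryCatch({
    Binv <- solve(Afull[, basis, drop = FALSE])
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(NULL)
  nb <- setdiff(seq_len(n + m), basis)
  ubx2 <- ubx; ubx2[n + seq_len(m)] <- 0
  xN <- .nb_value(lbx[nb], ubx2[nb], at_upper[nb])
  xB <- as.vector(Binv %*% (prob$b - Afull[, nb, drop = FALSE] %*% xN))
  if (any(xB < lbx[basis] - 1e-7) || any(xB > ubx2[basis] + 1e-7)) {
    return(NULL)
  }
  c2 <- c(cvec, rep(0, m))
  ph2 <- .simplex_iter(Afull, prob$b, c2, lbx, ubx2, basis, at_upper,
                       tol, max_iter)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  list(status = "optimal", x = ph2$x, basis = ph2$basis,
       at_upper = ph2$at_upper, objective = ph2$objective, art_sign = sgn)
}

# Core bounded-variable primal simplex (maximisation).
.simplex_iter <- function(A, b, cvec, lb, ub, basis, at_upper, tol, max_iter) {
  m <- nrow(A); N <- ncol(A)
  refresh_every <- 150L
  bland_after <- max(500L, 10L * N)

  is_basic <- rep(FALSE, N); is_basic[basis] <- TRUE
  Binv <- solve(A[, basis, drop = FALSE])
  nbv <- function() which(!is_basic)
  recompute_xB <- function() {
    nb <- which(!is_basic)
    xN <- .nb_value(lb[nb], ub[nb], at_upper[nb])
    as.vector(Binv %*% (b - A[, nb, drop = FALSE] %*% xN))
  }
  xB <- recompute_xB()

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex iteration limit exceeded")
    if (iter %% refresh_every == 0L) {
      Binv <- solve(A[, basis, drop = FALSE])
      xB <- recompute_xB()
    }
    y <- as.vector(crossprod(Binv, cvec[basis]))
    d <- cvec - as.vector(crossprod(A, y))
    nb <- which(!is_basic)
    dn <- d[nb]
    fixed <- lb[nb] == ub[nb]
    up_ok <- !at_upper[nb] & !fixed & dn > tol     # can increase
    dn_ok <- (at_upper[nb] | (!is.finite(lb[nb]) & !is.finite(ub[nb]))) &
      !fixed & dn < -tol                            # can decrease
    cand <- which(up_ok | dn_ok)
    if (length(cand) == 0L) break # optimal

    if (iter > bland_after) {
      k <- cand[which.min(nb[cand])]
    } else {
      k <- cand[which.max(abs(dn[cand]))]
    }
    q <- nb[k]
    sigma <- if (dn[k] > 0) 1 else -1
    w <- as.vector(Binv %*% A[, q])

    # ratio test
    t_own <- if (is.finite(lb[q]) && is.finite(ub[q])) ub[q] - lb[q] else Inf
    sw <- sigma * w
    lim <- rep(Inf, m)
    dec <- sw > tol     # basic value decreases
    inc <- sw < -tol    # basic value increases
    lim[dec] <- (xB[dec] - lb[basis[dec]]) / sw[dec]
    lim[inc] <- (ub[basis[inc]] - xB[inc]) / (-sw[inc])
    lim[lim < 0] <- 0
    tmin <- min(t_own, lim)
    if (!is.finite(tmin)) {
      return(list(status = "unbounded"))
    }
    if (is.finite(t_own) && t_own <= min(lim) + 1e-12) {
      # bound flip: q moves to its opposite bound, basis unchanged
      xB <- xB - sigma * t_own * w
      at_upper[q] <- !at_upper[q]
      next
    }
    # leaving variable: among near-minimal ratios choose largest |pivot|
    near <- which(lim <= tmin + 1e-9)
    rI <- near[which.max(abs(w[near]))]
    leave <- basis[rI]
    # entering value
    q_start <- if (at_upper[q] && is.finite(ub[q])) ub[q]
               else if (is.finite(lb[q])) lb[q]
               else if (is.finite(ub[q])) ub[q] else 0
    xB <- xB - sigma * tmin * w
    xB[rI] <- q_start + sigma * tmin
    at_upper[leave] <- sw[rI] < 0   # left at upper bound if it was increasing
    is_basic[leave] <- FALSE
    is_basic[q] <- TRUE
    basis[rI] <- q
    # product-form update of the basis inverse
    Brow <- Binv[rI, ] / w[rI]
    Binv <- Binv - outer(w, Brow)
    Binv[rI, ] <- Brow
  }

  nb <- which(!is_basic)
  x <- numeric(N)
  x[nb] <- .nb_value(lb[nb], ub[nb], at_upper[nb])
  x[basis] <- xB
  list(status = "optimal", x = x, basis = basis, at_upper = at_upper,
       objective = sum(cvec * x))
}
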