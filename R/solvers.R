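# Internal optimisation kernels.
#
# LP: a two-phase bounded-variable revised simplex written for this package
#     (dense basis inverse with eta updates, Bland's rule fallback against
#     cycling, periodic refactorization).
# QP: Euclidean projection onto {v : S v = 0, lb <= v <= ub} via Dykstra's
#     alternating projections, refined by an exact KKT solve on the active set.

#' @keywords internal
.finite_bounds <- function(lb, ub, big = 1e4) {
  lb[!is.finite(lb)] <- -big
  ub[!is.finite(ub)] <- big
  list(lb = lb, ub = ub)
}

# Core: maximize obj'x subject to A x = b, lb <= x <= ub (all finite).
# Returns list(status, x, objective). Assumes nothing about the rank of A.
.simplex_bounded <- function(obj, A, b, lb, ub, tol = 1e-9, max_iter = NULL) {
  n <- ncol(A)
  m0 <- nrow(A)
  # keep a maximal independent row set (consistency is re-checked at the end)
  if (m0 > 1L) {
    qt <- qr(t(A))
    keep <- qt$pivot[seq_len(qt$rank)]
    A_full <- A
    b_full <- b
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
  } else {
    A_full <- A
    b_full <- b
  }
  m <- nrow(A)
  if (is.null(max_iter)) max_iter <- 2000L + 200L * (n + m)
  # augment with artificial variables for phase 1
  N <- n + m
  x <- numeric(N)
  lbx <- c(lb, rep(0, m))
  ubx <- c(ub, rep(Inf, m))
  # nonbasic structural variables start at the bound nearer zero
  at_ub <- abs(ub) < abs(lb)
  status <- c(ifelse(at_ub, 2L, 1L), rep(0L, m)) # 1 = at lb, 2 = at ub, 0 = basic
  x[seq_len(n)] <- ifelse(at_ub, ub, lb)
  r <- b - as.vector(A %*% x[seq_len(n)])
  sgn <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  x[n + seq_len(m)] <- abs(r)
  basis <- n + seq_len(m)
  Binv <- diag(1 / sgn, m) # inverse of the artificial basis
  run_phase <- function(cost, basis, status, x, Binv, allow = rep(TRUE, N)) {
    degenerate_streak <- 0L
    for (it in seq_len(max_iter)) {
      if (it %% 100L == 0L) {
        Binv_try <- tryCatch(solve(Aall[, basis, drop = FALSE]), error = function(e) NULL)
        if (!is.null(Binv_try)) {
          Binv <- Binv_try
          xb <- as.vector(Binv %*% (b - Aall[, -basis, drop = FALSE] %*% x[-basis]))
          x[basis] <- xb
        }
      }
      y <- as.vector(crossprod(Binv, cost[basis]))
      d <- cost - as.vector(crossprod(Aall, y))
      cand <- which(status != 0L & allow &
                      ((status == 1L & d > tol) | (status == 2L & d < -tol)) &
                      (ubx - lbx) > tol)
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, st = status, x = x, Binv = Binv))
      }
      j <- if (degenerate_streak > 30L) cand[1] else cand[which.max(abs(d[cand]))]
      sigma <- if (status[j] == 1L) 1 else -1
      w <- as.vector(Binv %*% Aall[, j])
      # max step t >= 0 for x_j moving by sigma * t; x_basis moves by -sigma*w*t
      dirw <- -sigma * w
      t_best <- ubx[j] - lbx[j]
      leave <- 0L
      leave_to <- 0L
      for (i in seq_len(m)) {
        if (dirw[i] < -tol) {
          ti <- (x[basis[i]] - lbx[basis[i]]) / (-dirw[i])
          if (ti < t_best - 1e-12) {
            t_best <- ti
            leave <- i
            leave_to <- 1L
          }
        } else if (dirw[i] > tol) {
          ti <- (ubx[basis[i]] - x[basis[i]]) / dirw[i]
          if (ti < t_best - 1e-12) {
            t_best <- ti
            leave <- i
            leave_to <- 2L
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis, st = status, x = x, Binv = Binv))
      }
      t_best <- max(t_best, 0)
      degenerate_streak <- if (t_best <= 1e-11) degenerate_streak + 1L else 0L
      x[basis] <- x[basis] + dirw * t_best
      x[j] <- x[j] + sigma * t_best
      if (leave == 0L) {
        status[j] <- if (status[j] == 1L) 2L else 1L # bound flip
      } else {
        lv <- basis[leave]
        status[lv] <- leave_to
        x[lv] <- if (leave_to == 1L) lbx[lv] else ubx[lv]
        basis[leave] <- j
        status[j] <- 0L
        piv <- w[leave]
        if (abs(piv) < 1e-12) {
          Binv_try <- tryCatch(solve(Aall[, basis, drop = FALSE]), error = function(e) NULL)
          if (is.null(Binv_try)) {
            return(list(status = "failed", basis = basis, st = status, x = x, Binv = Binv))
          }
          Binv <- Binv_try
        } else {
          Binv[leave, ] <- Binv[leave, ] / piv
          for (i in seq_len(m)) {
            if (i != leave && abs(w[i]) > 0) {
              Binv[i, ] <- Binv[i, ] - w[i] * Binv[leave, ]
            }
          }
        }
      }
    }
    list(status = "iteration_limit", basis = basis, st = status, x = x, Binv = Binv)
  }
  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, basis, status, x, Binv)
  if (ph1$status != "optimal" || sum(ph1$x[n + seq_len(m)]) > 1e-7) {
    st <- if (ph1$status == "optimal") "infeasible" else ph1$status
    return(list(status = st, x = rep(NA_real_, n), objective = NA_real_))
  }
  # phase 2: pin artificials at zero and optimize the true objective
  ubx2 <- ubx
  ubx2[n + seq_len(m)] <- 0
  cost2 <- c(obj, rep(0, m))
  ubx <- ubx2
  ph2 <- run_phase(cost2, ph1$basis, ph1$st, ph1$x, ph1$Binv,
                   allow = c(rep(TRUE, n), rep(FALSE, m)))
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, x = rep(NA_real_, n), objective = NA_real_))
  }
  xout <- ph2$x[seq_len(n)]
  # consistency on the full (possibly rank-deficient) system
  if (max(abs(A_full %*% xout - b_full)) > 1e-6) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  list(status = "optimal", x = xout, objective = sum(obj * xout))
}

#' Solve a bounded linear program with equality and inequality constraints
#'
#' Minimises or maximises `obj %*% v` subject to `Aeq v = beq`,
#' `Aub v <= bub` and `lb <= v <= ub`. Inequality rows get bounded slack
#' variables and the whole system is handed to the bounded-variable simplex.
#'
#' @keywords internal
solve_lp_general <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                             lb, ub, maximize = TRUE) {
  n <- length(obj)
  fb <- .finite_bounds(lb, ub)
  lb <- fb$lb
  ub <- fb$ub
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", flux = rep(NA_real_, n), objective = NA_real_))
  }
  A <- NULL
  b <- numeric(0)
  if (!is.null(Aeq) && nrow(Aeq)) {
    A <- Aeq
    b <- beq
  }
  n_slack <- 0L
  if (!is.null(Aub) && nrow(Aub)) {
    n_slack <- nrow(Aub)
    if (is.null(A)) {
      A <- cbind(Aub, diag(n_slack))
      b <- bub
    } else {
      A <- rbind(cbind(A, matrix(0, nrow(A), n_slack)),
                 cbind(Aub, diag(n_slack)))
      b <- c(b, bub)
    }
    # generous finite slack range
    slack_ub <- abs(bub) + sum(pmax(abs(lb), abs(ub))) * apply(abs(Aub), 1, max) + 1
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, slack_ub)
  } else if (is.null(A)) {
    A <- matrix(0, 1, n)
    b <- 0
  }
  cost <- c(if (maximize) obj else -obj, rep(0, n_slack))
  res <- .simplex_bounded(cost, A, b, lb, ub)
  if (res$status != "optimal") {
    return(list(status = res$status, flux = rep(NA_real_, n), objective = NA_real_))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", flux = v, objective = sum(obj * v))
}

#' Solve the steady-state LP max/min obj'v s.t. S v = 0, lb <= v <= ub
#' @keywords internal
solve_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  solve_lp_general(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                   maximize = maximize)
}

#' Orthonormal basis of the nullspace of a matrix
#' @keywords internal
.nullspace <- function(S, tol = 1e-10) {
  n <- ncol(S)
  if (!nrow(S) || all(S == 0)) return(diag(n))
  qt <- qr(t(S))
  r <- qt$rank
  if (r >= n) return(matrix(0, n, 0))
  qr.Q(qt, complete = TRUE)[, seq(r + 1, n), drop = FALSE]
}

#' Minimum-norm least-squares solution of C x = d (via SVD)
#' @keywords internal
.lsq_min_norm <- function(C, d, tol = 1e-10) {
  sv <- svd(C)
  r <- sum(sv$d > tol * max(sv$d[1], 1))
  if (r == 0) return(rep(0, ncol(C)))
  u <- sv$u[, seq_len(r), drop = FALSE]
  v <- sv$v[, seq_len(r), drop = FALSE]
  as.vector(v %*% ((crossprod(u, d)) / sv$d[seq_len(r)]))
}

#' Primal active-set solve of the box/steady-state projection
#'
#' Exact minimiser of ||v - ref||^2 over {S v = 0, lb <= v <= ub}, starting
#' from a feasible point: at each iteration the equality-constrained
#' projection with the working set of pinned bounds gives a step direction;
#' the step is cut at the first blocking bound (which joins the working set),
#' and at stationary points bounds whose KKT multiplier has the wrong sign are
#' released. Finite for this strictly convex objective.
#'
#' @keywords internal
.qp_active_set <- function(ref, S, lb, ub, x0, tol = 1e-10) {
  n <- length(ref)
  x <- x0
  fixed <- (ub - lb) <= tol
  at_l <- fixed | (x - lb) <= tol
  at_u <- !at_l & (ub - x) <= tol
  for (k in seq_len(200L + 20L * n)) {
    idx <- which(at_l | at_u)
    E <- matrix(0, length(idx), n)
    if (length(idx)) E[cbind(seq_along(idx), idx)] <- 1
    C <- rbind(S, E)
    d <- c(rep(0, nrow(S)), x[idx])
    v_p <- .lsq_min_norm(C, d)
    Z <- .nullspace(C)
    v_star <- v_p + if (ncol(Z)) as.vector(Z %*% crossprod(Z, ref - v_p)) else 0
    p <- v_star - x
    if (max(abs(p)) <= 1e-10) {
      if (!length(idx)) break
      theta <- .lsq_min_norm(t(C), 2 * (x - ref))
      mult <- theta[nrow(S) + seq_along(idx)]
      # lower-bound multipliers must be >= 0, upper-bound ones <= 0
      score <- ifelse(at_l[idx] & !fixed[idx], -mult,
                      ifelse(at_u[idx], mult, -Inf))
      worst <- which.max(score)
      if (score[worst] <= 1e-9) break
      i <- idx[worst]
      at_l[i] <- FALSE
      at_u[i] <- FALSE
      next
    }
    # longest feasible step along p, cut at the first blocking bound
    alpha <- 1
    block <- 0L
    block_side <- 0L
    for (i in seq_len(n)) {
      if (p[i] > tol) {
        ai <- (ub[i] - x[i]) / p[i]
        if (ai < alpha - 1e-12) {
          alpha <- ai
          block <- i
          block_side <- 2L
        }
      } else if (p[i] < -tol) {
        ai <- (lb[i] - x[i]) / p[i]
        if (ai < alpha - 1e-12) {
          alpha <- ai
          block <- i
          block_side <- 1L
        }
      }
    }
    alpha <- max(alpha, 0)
    x <- x + alpha * p
    if (block > 0L) {
      x[block] <- if (block_side == 1L) lb[block] else ub[block]
      if (block_side == 1L) at_l[block] <- TRUE else at_u[block] <- TRUE
    }
  }
  pmin(pmax(x, lb), ub)
}

#' Euclidean projection onto {v : S v = 0, lb <= v <= ub}
#'
#' The quadratic kernel behind the minimal-metabolic-adjustment (MOMA) step:
#' a feasible starting vertex is found by the LP kernel, then the primal
#' active-set iteration projects onto the intersection of the steady-state
#' subspace and the bound box.
#'
#' @keywords internal
solve_qp_box <- function(ref, S, lb, ub) {
  n <- length(ref)
  fb <- .finite_bounds(lb, ub)
  lb <- fb$lb
  ub <- fb$ub
  if (any(lb > ub + 1e-12)) {
    return(list(flux = rep(NA_real_, n), distance = NA_real_, status = "infeasible"))
  }
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  if (all(ref >= lb - 1e-12) && all(ref <= ub + 1e-12) &&
      max(abs(S %*% ref)) <= 1e-9) {
    # the reference itself is feasible: zero adjustment
    x <- pmin(pmax(ref, lb), ub)
    return(list(flux = x, distance = sqrt(sum((x - ref)^2)), status = "optimal"))
  }
  feas <- solve_lp(rep(0, n), S, lb, ub)
  if (feas$status != "optimal") {
    return(list(flux = rep(NA_real_, n), distance = NA_real_, status = "infeasible"))
  }
  x <- .qp_active_set(ref, S, lb, ub, feas$flux)
  list(flux = x, distance = sqrt(sum((x - ref)^2)), status = "optimal")
}
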