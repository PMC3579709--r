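#' Solve a bounded linear program
#'
#' Minimises (or maximises) `obj %*% x` subject to `Aeq %*% x == beq`,
#' optional extra inequality rows, and box constraints `lb <= x <= ub`.
#' This is the engine behind [fba_max()] and [gimme()]: flux-balance
#' problems are equality-constrained LPs over box-bounded fluxes, so the
#' solver implements a two-phase revised simplex with bounded variables
#' (variables may be nonbasic at either bound; a ratio test limit at the
#' entering variable's opposite bound produces a bound flip instead of a
#' pivot).
#'
#' @param obj numeric objective coefficients (length n).
#' @param Aeq equality constraint matrix (m x n), dense or `Matrix` sparse.
#' @param beq equality right-hand sides (length m).
#' @param lb,ub box bounds, recycled to length n; `ub` may be `Inf`.
#' @param maximize maximise instead of minimise.
#' @param ineq optional inequality block: a list with elements `A` (k x n
#'   matrix), `dir` (character vector of `">="`/`"<="`), `rhs` (length k).
#'   Converted internally to equalities with slack variables.
#' @param tol numeric tolerance for pivoting and feasibility tests.
#' @param max_iter simplex iteration cap.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (solution, length n) and `objval`.
#' @examples
#' # max x2 s.t. x1 - x2 = 0, 0 <= x <= c(5, 10): optimum 5
#' solve_lp(c(0, 1), matrix(c(1, -1), 1), 0, ub = c(5, 10), maximize = TRUE)
#' @export
solve_lp <- function(obj, Aeq, beq, lb = 0, ub = Inf, maximize = FALSE,
                     ineq = NULL, tol = 1e-9, max_iter = 20000L) {
  Aeq <- as.matrix(Aeq)
  n <- ncol(Aeq)
  stopifnot(length(obj) == n, length(beq) == nrow(Aeq))
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub)) stop("lp: lb > ub")
  A <- Aeq
  b <- as.numeric(beq)
  cost <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  n_slack <- 0L
  if (!is.null(ineq)) {
    Ai <- as.matrix(ineq$A)
    k <- nrow(Ai)
    stopifnot(ncol(Ai) == n, length(ineq$dir) == k, length(ineq$rhs) == k)
    # a'x <= r  ->  a'x + s = r ;  a'x >= r  ->  a'x - s = r  (s >= 0)
    sgn <- ifelse(ineq$dir == "<=", 1, -1)
    Slk <- matrix(0, nrow(A) + k, k)
    Slk[nrow(A) + seq_len(k), ] <- diag(sgn, k)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)), cbind(Ai, matrix(0, k, k)))
    A[, n + seq_len(k)] <- Slk[, seq_len(k)]
    b <- c(b, as.numeric(ineq$rhs))
    cost <- c(cost, rep(0, k))
    lb <- c(lb, rep(0, k))
    ub <- c(ub, rep(Inf, k))
    n_slack <- k
  }

  # shift to lb = 0: x = lb + z, 0 <= z <= ub - lb
  finite_lb <- lb
  finite_lb[!is.finite(finite_lb)] <- 0  # -Inf lower bounds unsupported
  if (any(!is.finite(lb))) stop("lp: -Inf lower bounds unsupported; split the variable")
  b <- b - as.vector(A %*% finite_lb)
  ubz <- ub - finite_lb

  res <- .lp_simplex_core(cost, A, b, ubz, tol = tol, max_iter = max_iter)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(NA_real_, n), objval = NA_real_))
  }
  x <- res$x[seq_len(n)] + finite_lb[seq_len(n)]
  objval <- sum(as.numeric(obj) * x)
  list(status = "optimal", x = x, objval = objval)
}

# Two-phase bounded-variable simplex with explicit basis inverse.
# min cost'x  s.t.  A x = b,  0 <= x <= ub.
.lp_simplex_core <- function(cost, A, b, ub, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  Af <- cbind(A, diag(m))
  ubf <- c(ub, rep(Inf, m))
  ntot <- n + m
  basis <- n + seq_len(m)
  # status: 0 nonbasic at lower, 1 nonbasic at upper, 2 basic
  vstat <- c(rep(0L, n), rep(2L, m))
  Binv <- diag(m)
  xB <- b

  run_phase <- function(cvec, allowed, basis, vstat, Binv, xB) {
    it <- 0L
    bland_after <- 2000L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("lp: iteration limit reached")
      if (it %% 200L == 0L) {  # refactorise to contain drift
        Bmat <- Af[, basis, drop = FALSE]
        Binv <- tryCatch(solve(Bmat), error = function(e) Binv)
        nb <- setdiff(seq_len(ntot), basis)
        x_nb <- numeric(ntot)
        x_nb[nb[vstat[nb] == 1L]] <- ubf[nb[vstat[nb] == 1L]]
        xB <- as.vector(Binv %*% (b - Af[, nb, drop = FALSE] %*% x_nb[nb]))
      }
      yB <- as.vector(crossprod(Binv, cvec[basis]))   # Binv' cB
      d <- cvec - as.vector(crossprod(Af, yB))
      d[basis] <- 0
      cand <- which(allowed & vstat != 2L &
                      ((vstat == 0L & d < -tol) | (vstat == 1L & d > tol)))
      if (!length(cand)) {
        return(list(basis = basis, vstat = vstat, Binv = Binv, xB = xB,
                    obj = sum(cvec[basis] * xB) +
                      sum(cvec[vstat == 1L] * ubf[vstat == 1L])))
      }
      j <- if (it > bland_after) cand[1L] else cand[which.max(abs(d[cand]))]
      dir <- if (vstat[j] == 0L) 1 else -1
      w <- as.vector(Binv %*% Af[, j])
      incr <- -dir * w                     # d xB / d t
      t_bound <- ubf[j]
      t_dec <- ifelse(incr < -tol, xB / pmax(-incr, .Machine$double.eps), Inf)
      room <- ubf[basis] - xB
      t_inc <- ifelse(incr > tol & is.finite(ubf[basis]),
                      room / pmax(incr, .Machine$double.eps), Inf)
      t_dec[t_dec < 0] <- 0
      t_inc[t_inc < 0] <- 0
      t_row <- pmin(t_dec, t_inc)
      r <- which.min(t_row)
      t_star <- min(t_bound, t_row[r])
      if (!is.finite(t_star)) return(list(unbounded = TRUE))
      xB <- xB + incr * t_star
      if (is.finite(t_bound) && t_bound <= t_row[r] + tol) {
        vstat[j] <- 1L - vstat[j]          # bound flip, no pivot
      } else {
        # among ties pick the row with largest |w| for stability
        ties <- which(t_row <= t_star + tol)
        r <- ties[which.max(abs(w[ties]))]
        leave <- basis[r]
        vstat[leave] <- if (t_inc[r] <= t_dec[r]) 1L else 0L
        basis[r] <- j
        vstat[j] <- 2L
        xB[r] <- if (dir > 0) t_star else ubf[j] - t_star
        piv <- w[r]
        Binv[r, ] <- Binv[r, ] / piv
        if (m > 1L) {
          other <- setdiff(seq_len(m), r)
          Binv[other, ] <- Binv[other, , drop = FALSE] -
            outer(w[other], Binv[r, ])
        }
      }
      xB[xB < 0 & xB > -1e-7] <- 0
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- run_phase(c1, allowed = rep(TRUE, ntot), basis, vstat, Binv, xB)
  if (isTRUE(p1$unbounded)) return(list(status = "unbounded"))
  if (p1$obj > 1e-7) return(list(status = "infeasible"))
  # phase 2: artificials may stay basic but are pinned to zero (ub = 0)
  # and never re-enter; without the pin a basic artificial at zero could
  # grow again during phase-2 pivots and fake feasibility
  ubf[n + seq_len(m)] <- 0
  allowed <- c(rep(TRUE, n), rep(FALSE, m))
  c2 <- c(cost, rep(0, m))
  p2 <- run_phase(c2, allowed, p1$basis, p1$vstat, p1$Binv, p1$xB)
  if (isTRUE(p2$unbounded)) return(list(status = "unbounded"))
  x <- numeric(ntot)
  x[p2$vstat == 1L] <- ubf[p2$vstat == 1L]
  x[p2$basis] <- p2$xB
  x <- pmin(pmax(x, 0), ifelse(is.finite(ubf), ubf, Inf))
  list(status = "optimal", x = x[seq_len(n)], objval = sum(cost * x[seq_len(n)]))
}
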