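#' Solve a bounded linear programme
#'
#' Dense two-phase revised simplex for problems of the form
#' \deqn{\min c'x \quad \textrm{s.t.} \quad A x = b,\; l \le x \le u,}
#' the canonical shape of flux balance analysis. Written for the small,
#' dense systems that arise from desk-scale stoichiometric models; every
#' pivot refactorises the basis, trading speed for numerical robustness,
#' and the pricing rule falls back to Bland's rule to break cycles.
#'
#' @param obj objective coefficient vector (length n)
#' @param A constraint matrix (m x n), dense or a Matrix object
#' @param b right-hand side (length m)
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed
#' @param maximize maximise instead of minimise
#' @param tol optimality tolerance on reduced costs
#' @param maxit iteration cap (per phase)
#' @return list with \code{status} ("optimal", "infeasible", "unbounded",
#'   "maxit"), \code{objective}, and the primal solution \code{x}
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = FALSE,
                     tol = 1e-9, maxit = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  sense <- if (maximize) -1 else 1
  cc <- sense * as.numeric(obj)

  ## Start every structural variable at a finite bound (0 if free), then add
  ## one artificial per row to absorb the residual; basis = the artificials.
  x0 <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  r <- b - as.numeric(A %*% x0)
  sg <- ifelse(r >= 0, 1, -1)
  Aful <- cbind(A, diag(sg, m))
  lful <- c(lb, rep(0, m))
  uful <- c(ub, rep(Inf, m))
  ntot <- n + m
  art <- seq.int(n + 1L, ntot)

  basis <- art
  ## nonbasic status: -1 at lower, +1 at upper, 0 free-at-zero
  nbstat <- integer(ntot)
  nbstat[seq_len(n)] <- ifelse(is.finite(lb), -1L, ifelse(is.finite(ub), 1L, 0L))
  x <- c(x0, abs(r))

  run_phase <- function(cost, stop_at_zero = FALSE) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return("maxit")
      ## phase 1 is done the moment the artificials reach zero
      if (stop_at_zero && sum(abs(x[art])) <= 1e-9) return("optimal")
      bland <- it > 0.6 * maxit
      B <- Aful[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return("singular")
      nonbasic <- setdiff(seq_len(ntot), basis)
      d <- cost[nonbasic] - as.numeric(crossprod(Aful[, nonbasic, drop = FALSE], y))
      stat <- nbstat[nonbasic]
      ## variables pinned to a point (lb == ub) can never usefully enter
      movable <- (uful[nonbasic] - lful[nonbasic]) > 0
      elig <- which(movable &
                      ((stat == -1L & d < -tol) | (stat == 1L & d > tol) |
                         (stat == 0L & abs(d) > tol)))
      if (!length(elig)) return("optimal")
      pick <- if (bland) elig[which.min(nonbasic[elig])] else elig[which.max(abs(d[elig]))]
      j <- nonbasic[pick]
      ## direction of travel for the entering variable
      sigma <- if (nbstat[j] == -1L) 1 else if (nbstat[j] == 1L) -1 else if (d[pick] < 0) 1 else -1
      w <- tryCatch(solve(B, Aful[, j]), error = function(e) NULL)
      if (is.null(w)) return("singular")
      delta <- -sigma * w            # change in x_B per unit step t >= 0
      xB <- x[basis]
      tmax <- Inf; leave <- 0L; leave_bound <- NA_real_
      for (i in seq_len(m)) {
        ti <- Inf; bnd <- NA_real_
        if (delta[i] > 1e-10) {
          bnd <- uful[basis[i]]; ti <- (bnd - xB[i]) / delta[i]
        } else if (delta[i] < -1e-10) {
          bnd <- lful[basis[i]]; ti <- (xB[i] - bnd) / (-delta[i])
        }
        if (ti < tmax - 1e-12 ||
            (ti < tmax + 1e-12 && leave > 0L &&
             (if (bland) basis[i] < basis[leave] else abs(delta[i]) > abs(delta[leave])))) {
          tmax <- ti; leave <- i; leave_bound <- bnd
        }
      }
      ## bound-to-bound flip of the entering variable
      span <- uful[j] - lful[j]
      flip <- is.finite(span) && span < tmax
      if (flip) tmax <- span
      if (!is.finite(tmax)) return("unbounded")
      tmax <- max(tmax, 0)
      x[j] <<- x[j] + sigma * tmax
      x[basis] <<- x[basis] + delta * tmax
      if (flip) {
        nbstat[j] <<- -nbstat[j]
      } else {
        out <- basis[leave]
        nbstat[out] <<- if (abs(leave_bound - lful[out]) <= abs(leave_bound - uful[out])) -1L else 1L
        x[out] <<- leave_bound
        basis[leave] <<- j
        ## refresh basic values from scratch for accuracy
        nb <- setdiff(seq_len(ntot), basis)
        rhs <- b - as.numeric(Aful[, nb, drop = FALSE] %*% x[nb])
        xb <- tryCatch(solve(Aful[, basis, drop = FALSE], rhs),
                       error = function(e) NULL)
        if (!is.null(xb)) x[basis] <<- xb
      }
    }
  }

  ## Phase 1: drive artificials to zero
  s1 <- run_phase(c(rep(0, n), rep(1, m)), stop_at_zero = TRUE)
  if (s1 %in% c("maxit", "singular")) {
    return(list(status = "maxit", objective = NA_real_, x = NULL))
  }
  if (sum(abs(x[art])) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  ## Phase 2: pin artificials at zero and optimise the true objective
  uful[art] <- 0
  x[art] <- 0
  s2 <- run_phase(c(cc, rep(0, m)))
  if (s2 == "unbounded") {
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf, x = NULL))
  }
  if (s2 %in% c("maxit", "singular")) {
    return(list(status = "maxit", objective = NA_real_, x = NULL))
  }
  xs <- x[seq_len(n)]
  list(status = "optimal", objective = sum(sense * cc * xs), x = xs)
}
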