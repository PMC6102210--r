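# Independent oracles and random-fixture generators used across the suite.
# The LP oracle is deliberately a different algorithm from the package's
# simplex: brute-force enumeration of basic solutions (vertices) of
# {v : N v = 0, lb <= v <= ub}, exact for bounded problems of <= 8 reactions.

# Maximise / minimise cc'v by vertex enumeration. All bounds must be finite.
oracle_lp <- function(cc, N, lb, ub, maximize = TRUE) {
  N <- as.matrix(N)
  n <- ncol(N)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  qa <- qr(t(N))
  r <- qa$rank
  if (r > 0) N <- N[qa$pivot[seq_len(r)], , drop = FALSE] else N <- NULL
  best <- NULL
  consider <- function(v) {
    if (any(v < lb - 1e-8) || any(v > ub + 1e-8)) return()
    obj <- sum(cc * v)
    if (is.null(best) || (maximize && obj > best) || (!maximize && obj < best)) {
      best <<- obj
    }
  }
  if (r == 0) {
    v <- ifelse((maximize & cc > 0) | (!maximize & cc < 0), ub, lb)
    consider(v)
    return(list(status = if (is.null(best)) "infeasible" else "optimal",
                objective = best))
  }
  nonbasic_count <- n - r
  for (basic in utils::combn(n, r, simplify = FALSE)) {
    B <- N[, basic, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    free <- setdiff(seq_len(n), basic)
    # all 2^(n-r) lower/upper assignments of the nonbasic variables at once
    if (nonbasic_count > 0) {
      combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nonbasic_count)))
      G <- matrix(lb[free], nonbasic_count, nrow(combos))
      G[t(combos)] <- matrix(ub[free], nonbasic_count, nrow(combos))[t(combos)]
      Xb <- solve(B, -N[, free, drop = FALSE] %*% G)
      for (j in seq_len(ncol(G))) {
        v <- numeric(n); v[basic] <- Xb[, j]; v[free] <- G[, j]
        consider(v)
      }
    } else {
      v <- numeric(n); v[basic] <- solve(B, rep(0, r))
      consider(v)
    }
  }
  list(status = if (is.null(best)) "infeasible" else "optimal",
       objective = best)
}

oracle_fva <- function(N, lb, ub, i) {
  cc <- numeric(ncol(N)); cc[i] <- 1
  c(vmin = oracle_lp(cc, N, lb, ub, maximize = FALSE)$objective,
    vmax = oracle_lp(cc, N, lb, ub, maximize = TRUE)$objective)
}

# Random small stoichiometric networks. With lb <= 0 <= ub the zero flux is
# always feasible, so every draw has a well-defined optimum.
random_network <- function(seed) {
  withr::with_seed(seed, {
    m <- sample(1:5, 1)
    n <- m + sample(2:4, 1)
    n <- min(n, 8)
    N <- matrix(sample(c(-2:-1, 0, 0, 1:2), m * n, replace = TRUE), m, n)
    dimnames(N) <- list(paste0("M", seq_len(m)), paste0("R", seq_len(n)))
    lb <- -sample(0:5, n, replace = TRUE)
    ub <- sample(1:5, n, replace = TRUE)
    list(N = N, lb = lb, ub = ub, obj = sample(n, 1))
  })
}

as_model <- function(net) {
  metabolic_model(net$N, net$lb, net$ub)
}

# Hand-rolled Clopper-Pearson-free exact band for a binomial fraction
binom_band <- function(n, p, level = 0.95) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}
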