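#' @title Michaelis-Menten depletion: closed form and parameter recovery
#' @description
#' A substrate consumed from a well-mixed medium at Michaelis-Menten rate,
#' `dS/dt = -Vmax S / (Km + S)` (Vmax here in mM/h, i.e. already converted
#' to a medium-concentration rate), has the closed-form solution
#' `S(t) = Km W((S0/Km) exp((S0 - Vmax t)/Km))` with W the Lambert W
#' function. [fit_mm()] recovers (Vmax, Km) from an observed depletion
#' time course by nonlinear least squares on this integrated model —
#' a validation utility for synthetic uptake data, not a calibration step
#' of the simulator.
#' @name mm_depletion
NULL

lambert_w_exp <- function(L) {
  ## W(exp(L)) without forming exp(L): solve e^u + u = L for u = log(w).
  ## g(u) = e^u + u - L is convex and strictly increasing, so Newton
  ## converges globally; works for the full range of L the depletion
  ## model can produce (L ~ -S/Km to +S/Km with Km down to ~1e-6).
  vapply(L, function(l) {
    if (!is.finite(l)) return(if (l < 0) 0 else NaN)
    if (l < -36) return(exp(l))               # w = e^l to machine precision
    u <- if (l > 1) log(l - log(l) + 0.5) else l - exp(l) / (1 + exp(l))
    for (i in 1:100) {
      eu <- exp(u)
      du <- (eu + u - l) / (eu + 1)
      u <- u - du
      if (abs(du) < 1e-15 * max(1, abs(u))) break
    }
    exp(u)
  }, 0)
}

#' Closed-form Michaelis-Menten depletion curve
#'
#' @param t time(s), hours
#' @param S0 initial concentration, mM
#' @param Vmax maximal depletion rate, mM/h
#' @param Km half-saturation, mM
#' @return concentration(s), mM (exactly 0 once the substrate is exhausted
#'   to numerical precision)
#' @export
mm_depletion <- function(t, S0, Vmax, Km) {
  if (any(c(S0, Vmax, Km) < 0)) stop("parameters must be non-negative")
  if (S0 == 0) return(rep(0, length(t)))
  L <- log(S0 / Km) + (S0 - Vmax * t) / Km
  pmax(Km * lambert_w_exp(L), 0)
}

#' Fit the integrated Michaelis-Menten uptake model
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the closed-form
#' depletion curve to an observed medium time course. At least 5 points
#' are required. A time course whose total relative drop is under 2% is
#' declared non-identifiable: the fit is flagged and no estimates are
#' returned, rather than reporting meaningless numbers.
#'
#' @param data data frame with columns `time` (h) and `concentration` (mM);
#'   replicate columns are ignored
#' @param start optional named list of starting values (`S0`, `Vmax`, `Km`)
#' @return an `mm_fit`: list with `identifiable`, `estimate` (named vector
#'   S0, Vmax, Km), `se` (standard errors), and the underlying `nls` fit
#' @export
fit_mm <- function(data, start = NULL) {
  stopifnot(all(c("time", "concentration") %in% names(data)))
  d <- data[stats::complete.cases(data[c("time", "concentration")]), ]
  if (nrow(d) < 5) stop("need at least 5 time points")
  rng <- range(d$concentration)
  if (rng[1] > (1 - 0.02) * rng[2] || rng[2] <= 0) {
    return(structure(list(identifiable = FALSE, estimate = NULL, se = NULL,
                          fit = NULL, reason = "time course is flat"),
                     class = "mm_fit"))
  }
  if (is.null(start)) {
    S0g <- max(d$concentration)
    rate0 <- -stats::coef(stats::lm(concentration ~ time, d))[["time"]]
    start <- list(S0 = S0g, Vmax = max(rate0, 1e-3) * 1.5, Km = S0g / 4)
  }
  fit <- minpack.lm::nlsLM(
    concentration ~ mm_depletion(time, S0, Vmax, Km),
    data = d, start = start,
    lower = c(S0 = 1e-6, Vmax = 1e-9, Km = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  sm <- summary(fit)
  structure(list(identifiable = TRUE,
                 estimate = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 fit = fit, reason = NULL),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("<mm_fit> non-identifiable:", x$reason, "\n")
  } else {
    cat("<mm_fit> Vmax =", signif(x$estimate[["Vmax"]], 4), "mM/h, Km =",
        signif(x$estimate[["Km"]], 4), "mM\n")
  }
  invisible(x)
}
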