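#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dFVA result
#'
#' @param x a [run_dfva()] result
#' @param ... unused
#' @return the trajectory tibble: `time`, `direction`, `flux`, `status`,
#'   plus one column per tracked place
#' @export
tidy.dfva_result <- function(x, ...) x$trajectory

#' One-row-per-direction summary of a dFVA result
#'
#' @param x a [run_dfva()] result
#' @param ... unused
#' @return tibble with `direction`, `flux_initial`, `flux_final` (last
#'   feasible step), `flux_auc` (trapezoidal, over the feasible span),
#'   `n_infeasible`
#' @export
glance.dfva_result <- function(x, ...) {
  x$trajectory |>
    dplyr::filter(.data$status != "end") |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(
      flux_initial = dplyr::first(stats::na.omit(.data$flux)),
      flux_final = dplyr::last(stats::na.omit(.data$flux)),
      flux_auc = if (sum(!is.na(.data$flux)) >= 2)
        auc(.data$time[!is.na(.data$flux)], .data$flux[!is.na(.data$flux)])
        else NA_real_,
      n_infeasible = sum(.data$status == "infeasible"),
      .groups = "drop")
}

#' Tidy a trajectory
#'
#' @param x a [run_trajectory()] result
#' @param ... unused
#' @return long tibble: `step`, `transition` (NA for the initial state),
#'   `reaction`, `flux`
#' @export
tidy.trajectory <- function(x, ...) {
  steps <- seq_len(nrow(x$fluxes)) - 1L
  trans <- c(NA_character_, x$events$transition)
  tidyr::expand_grid(i = seq_along(steps), reaction = x$monitored) |>
    dplyr::mutate(step = steps[.data$i], transition = trans[.data$i],
                  flux = x$fluxes[cbind(.data$i, match(.data$reaction,
                                                       x$monitored))]) |>
    dplyr::select("step", "transition", "reaction", "flux")
}

#' Tidy a trajectory ensemble
#'
#' @param x a [run_ensemble()] result
#' @param ... unused
#' @return long tibble: `trajectory`, `step`, `reaction`, `flux`
#' @export
tidy.trajectory_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$trajectories, function(tr, i) {
    dplyr::mutate(tidy(tr), trajectory = i, .before = 1)
  })
}

#' Ensemble summary
#'
#' @param x a [run_ensemble()] result
#' @param ... unused
#' @return tibble with `n`, `master_seed`, `mean_events`, `max_events`
#' @export
glance.trajectory_ensemble <- function(x, ...) {
  ev <- vapply(x$trajectories, function(tr) nrow(tr$events), 0L)
  tibble::tibble(n = x$n, master_seed = x$master_seed,
                 mean_events = mean(ev), max_events = max(ev))
}

#' Tidy a fraction statistic
#' @param x a [fraction_increased_flux()] result
#' @param ... unused
#' @export
tidy.fraction_statistic <- function(x, ...) {
  tibble::tibble(reaction = x$reaction, fraction = x$fraction, n = x$n,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 baseline = x$baseline)
}

#' Tidy a Michaelis-Menten fit
#' @param x an [fit_mm()] result
#' @param ... unused
#' @return tibble with `term`, `estimate`, `std_error` (empty when the
#'   fit was non-identifiable)
#' @export
tidy.mm_fit <- function(x, ...) {
  if (!x$identifiable) {
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          std_error = numeric(0)))
  }
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                 std_error = unname(x$se))
}

#' @export
glance.mm_fit <- function(x, ...) {
  if (!x$identifiable) {
    return(tibble::tibble(identifiable = FALSE, sigma = NA_real_,
                          df_residual = NA_integer_))
  }
  sm <- summary(x$fit)
  tibble::tibble(identifiable = TRUE, sigma = sm$sigma,
                 df_residual = sm$df[2])
}
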