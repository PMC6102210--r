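#' Kinetic rate laws
#'
#' A kinetic law maps markings to a rate or flux magnitude. Three forms are
#' supported: Michaelis–Menten (`Vmax`, `Km`, substrate), mass action (`k`),
#' and constant. Modifiers multiply the base rate by a factor computed from
#' another place's marking — the mechanism used to couple e.g. an insulin
#' signal to a transporter's Vmax. Modifier types:
#'
#' * `"scale_if_present"`: factor while the modifier place is present, 1
#'   otherwise (a switch).
#' * `"saturating"`: `1 + (factor - 1) * M / (K + M)`, a graded dose
#'   response in the modifier marking M.
#'
#' @param form "michaelis_menten", "mass_action" or "constant"
#' @param Vmax maximal rate, mmol/g DW/h (Michaelis–Menten; > 0)
#' @param Km half-saturation concentration, mM (Michaelis–Menten; > 0)
#' @param k mass-action rate constant (>= 0)
#' @param rate constant-form rate
#' @param substrate place id supplying S for Michaelis–Menten (defaults to
#'   the transition's first consume arc)
#' @param modifiers list of modifier specs, each a list with `place`,
#'   `type`, `factor`, and `K` (saturating type only)
#' @return a `kinetic_law` object
#' @export
kinetic_law <- function(form = c("michaelis_menten", "mass_action", "constant"),
                        Vmax = NULL, Km = NULL, k = NULL, rate = NULL,
                        substrate = NULL, modifiers = list()) {
  form <- match.arg(form)
  if (form == "michaelis_menten") {
    stopifnot(is.numeric(Vmax), Vmax > 0, is.numeric(Km), Km > 0)
  } else if (form == "mass_action") {
    stopifnot(is.numeric(k), k >= 0)
  } else {
    stopifnot(is.numeric(rate))
  }
  for (m in modifiers) {
    stopifnot(is.character(m$place),
              m$type %in% c("scale_if_present", "saturating"),
              is.numeric(m$factor), m$factor >= 0)
    if (m$type == "saturating") stopifnot(is.numeric(m$K), m$K > 0)
  }
  structure(list(form = form, Vmax = Vmax, Km = Km, k = k, rate = rate,
                 substrate = substrate, modifiers = modifiers),
            class = "kinetic_law")
}

modifier_scale <- function(law, marking) {
  sc <- 1
  for (m in law$modifiers) {
    M <- marking[[m$place]]
    if (is.null(M)) stop("modifier references unknown place '", m$place, "'")
    sc <- sc * switch(m$type,
      scale_if_present = if (M > 0) m$factor else 1,
      saturating = 1 + (m$factor - 1) * M / (m$K + M))
  }
  sc
}

#' Michaelis–Menten rate
#'
#' `Vmax * S / (Km + S)`, optionally scaled by the law's modifiers evaluated
#' at a marking. The rate is finite and non-negative for any S >= 0; S = Km
#' gives exactly Vmax/2.
#'
#' @param S substrate concentration, mM (>= 0)
#' @param law a Michaelis–Menten [kinetic_law()]
#' @param marking marking used to evaluate modifiers (optional when the law
#'   has none)
#' @param apply_modifiers set FALSE to return the unscaled rate
#' @return flux, mmol/g DW/h
#' @export
mm_rate <- function(S, law, marking = NULL, apply_modifiers = TRUE) {
  if (any(S < 0)) stop("substrate concentration must be >= 0")
  if (law$form != "michaelis_menten") stop("law is not Michaelis-Menten")
  r <- law$Vmax * S / (law$Km + S)
  if (apply_modifiers && length(law$modifiers)) {
    if (is.null(marking)) stop("marking required to evaluate modifiers")
    r <- r * modifier_scale(law, marking)
  }
  r
}
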