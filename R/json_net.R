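#' @title JSON Petri-net schema
#' @description
#' The native serialisation for Petri nets is a small, versioned JSON
#' schema (`"pnjson-1"`): an object with `schema`, `places` (id, kind,
#' marking, discrete, level_range, units), and `transitions` (id, mode,
#' arcs, guard conditions, kinetic law including modifiers). Guards and
#' laws are declarative, so a net round-trips losslessly.
#' @name json_net
NULL

law_to_list <- function(law) {
  if (is.null(law)) return(NULL)
  Filter(Negate(is.null), list(
    form = law$form, Vmax = law$Vmax, Km = law$Km, k = law$k,
    rate = law$rate, substrate = law$substrate,
    modifiers = if (length(law$modifiers)) law$modifiers else NULL))
}

law_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  kinetic_law(x$form, Vmax = x$Vmax, Km = x$Km, k = x$k, rate = x$rate,
              substrate = x$substrate,
              modifiers = if (is.null(x$modifiers)) list() else x$modifiers)
}

#' Write a Petri net to JSON
#' @param net a [petri_net()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_petri_json <- function(net, path) {
  obj <- list(
    schema = "pnjson-1",
    places = lapply(unname(net$places), function(p) {
      list(id = p$id, kind = p$kind, marking = p$marking,
           discrete = p$discrete, level_range = p$level_range,
           units = p$units)
    }),
    transitions = lapply(unname(net$transitions), function(tr) {
      Filter(Negate(is.null), list(
        id = tr$id, mode = tr$mode,
        arcs = tr$arcs,
        guard = if (length(tr$guard))
          lapply(tr$guard, function(g) list(place = g$place, test = g$test,
                                            value = g$value)) else NULL,
        rate_law = law_to_list(tr$rate_law)))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a Petri net from JSON
#' @param path file written by [write_petri_json()]
#' @return a [petri_net()]
#' @export
read_petri_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "pnjson-1")) {
    stop("unrecognised net schema: ", obj$schema %||% "<missing>")
  }
  places <- lapply(obj$places, function(p) {
    pn_place(p$id, kind = p$kind, marking = p$marking,
             discrete = isTRUE(p$discrete),
             level_range = unlist(p$level_range), units = p$units %||% "")
  })
  transitions <- lapply(obj$transitions, function(tr) {
    arcs <- do.call(rbind, lapply(tr$arcs, function(a) {
      pn_arcs(a$place, a$weight, a$kind)
    }))
    guard <- lapply(tr$guard %||% list(), function(g) {
      pn_guard(g$place, g$test, g$value %||% NA_real_)
    })
    pn_transition(tr$id, tr$mode, arcs,
                  rate_law = law_from_list(tr$rate_law), guard = guard)
  })
  petri_net(places, transitions)
}
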