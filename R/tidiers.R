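#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Fitch reconstruction
#'
#' One row per node with its label (tips) or index, the Fitch state
#' set, and ambiguity.
#'
#' @param x a `fitch_fit`.
#' @param ... unused.
#' @return a tibble with `node`, `label`, `is_tip`, `states`
#'   (list-column), `n_states`.
#' @export
tidy.fitch_fit <- function(x, ...) {
  ntip <- ape::Ntip(x$tree)
  n_all <- ntip + x$tree$Nnode
  tibble::tibble(
    node = seq_len(n_all),
    label = c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode)),
    is_tip = seq_len(n_all) <= ntip,
    states = x$sets,
    n_states = lengths(x$sets)
  )
}

#' @rdname tidy.fitch_fit
#' @export
glance.fitch_fit <- function(x, ...) {
  tibble::tibble(
    n_tips = ape::Ntip(x$tree),
    n_states = length(unique(unname(x$states))),
    score = x$score,
    root_forced = !is.null(x$root_state)
  )
}

#' Tidy a resolved reconstruction
#'
#' @param x a `fitch_resolved`.
#' @param ... unused.
#' @return a tibble with `node`, `label`, `is_tip`, `state`.
#' @export
tidy.fitch_resolved <- function(x, ...) {
  ntip <- ape::Ntip(x$tree)
  n_all <- ntip + x$tree$Nnode
  tibble::tibble(
    node = seq_len(n_all),
    label = c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode)),
    is_tip = seq_len(n_all) <= ntip,
    state = x$node_state
  )
}

#' @rdname tidy.fitch_resolved
#' @export
glance.fitch_resolved <- function(x, ...) {
  tr <- transitions(x)
  tibble::tibble(
    n_tips = ape::Ntip(x$tree),
    score = x$score,
    n_transitions = nrow(tr),
    mode = x$mode
  )
}

#' Tidy a derivation graph
#'
#' @param x a `derivation_graph`.
#' @param ... unused.
#' @return the edge tibble with one row per event per transition.
#' @export
tidy.derivation_graph <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(x$edges, "from", "to", "n_transitions", "events"),
    "events")
}
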