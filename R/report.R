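#' Pipeline configuration
#'
#' Central knobs of the pipeline with their defaults: the minimum size
#' for an unannotated gap to become an NC token (50 bp — typical
#' intergenic spacers are under ~30 bp while the smallest diagnostic
#' insertion is 342 bp), the control-region asymmetry ratio (1.2 —
#' concerted near-identical CRs sit near 1.0 while the smallest
#' diagnostic asymmetry is ~1.43), the linearization anchor, and the
#' ancestral-state resolution mode.
#'
#' @param nc_threshold_bp minimum NC gap size in bp.
#' @param cr_asymmetry_ratio max/min CR length ratio above which a pair
#'   of control regions is called asymmetric.
#' @param anchor linearization anchor gene.
#' @param resolution `"deltran"` or `"acctran"`.
#' @param seed integer seed for generators.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(nc_threshold_bp = 50L, cr_asymmetry_ratio = 1.2,
                            anchor = "F", resolution = c("deltran", "acctran"),
                            seed = 1L) {
  stopifnot(nc_threshold_bp > 0, cr_asymmetry_ratio > 0)
  structure(list(nc_threshold_bp = as.integer(nc_threshold_bp),
                 cr_asymmetry_ratio = cr_asymmetry_ratio,
                 anchor = anchor, resolution = match.arg(resolution),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

binary_charmap <- function(tip_types, predicate_types) {
  stats::setNames(ifelse(tip_types$type %in% predicate_types, "present", "absent"),
                  tip_types$taxon_id)
}

#' Headline comparative counts for a fixture set
#'
#' Recomputes, from the records, registry and tree of a fixture set,
#' the headline quantities of the comparative analysis: the number of
#' distinct arrangement types, species and family counts, independent
#' origins of the III-C arrangement and of pseudo-Pro presence,
#' independent losses of OL (with the root constrained to OL-present,
#' the outgroup condition in squamates), the number of types with
#' control-region-flank rearrangements, and the number of types novel
#' relative to the prior six-arrangement registry.
#'
#' @param fixtures a `fixture_set` ([build_fixture_set()]).
#' @param config a [pipeline_config()].
#' @return a tibble with `metric`, `value`, `module`.
#' @export
headline_report <- function(fixtures, config = pipeline_config()) {
  registry <- fixtures$registry
  classified <- classify_records(fixtures$records, registry,
                                 asymmetry_ratio = config$cr_asymmetry_ratio)
  census <- type_census(classified)

  tip_types <- tibble::tibble(taxon_id = classified$taxon_id,
                              type = classified$type)

  fit_iiic <- fitch_reconstruct(fixtures$tree,
                                binary_charmap(tip_types, "III-C"),
                                root_state = "absent")
  iiic_origins <- count_origins(resolve_states(fit_iiic, config$resolution),
                                "present")

  # pseudo-Pro presence: the III-C tips plus the III-B1 genome, whose
  # pseudo-Pro sits by CR1 instead of CR2
  pstar_tips <- classified$taxon_id[vapply(classified$order, function(o) {
    any(o$name == "P*")
  }, TRUE)]
  pstar_states <- stats::setNames(
    ifelse(tip_types$taxon_id %in% pstar_tips, "present", "absent"),
    tip_types$taxon_id)
  fit_pstar <- fitch_reconstruct(fixtures$tree, pstar_states,
                                 root_state = "absent")
  pstar_origins <- count_origins(resolve_states(fit_pstar, config$resolution),
                                 "present")

  ol_states <- stats::setNames(
    ifelse(vapply(classified$order, function(o) detect_ol(o)$present, TRUE),
           "present", "absent"),
    classified$taxon_id)
  fit_ol <- fitch_reconstruct(fixtures$tree, ol_states, root_state = "present")
  ol_losses <- count_losses(resolve_states(fit_ol, config$resolution), "present")

  hs <- hotspot_assignment(registry)
  cr_flank_types <- dplyr::n_distinct(hs$label[hs$locus == "CR-flank"])

  tibble::tibble(
    metric = c("distinct_types", "species", "families", "iii_c_origins",
               "pstar_origins", "ol_losses", "cr_flank_types", "new_vs_prior"),
    value = c(n_distinct_types(census),
              nrow(fixtures$records),
              dplyr::n_distinct(fixtures$taxa$family),
              iiic_origins,
              pstar_origins,
              ol_losses,
              cr_flank_types,
              length(novel_types(registry, fixtures$prior))),
    module = c("classify", "fixture", "fixture", "parsimony", "parsimony",
               "parsimony", "hotspot", "classify")
  )
}

#' Write a headline report as TSV or JSON
#'
#' @param report output of [headline_report()].
#' @param path output path (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_headline_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    obj <- stats::setNames(as.list(report$value), report$metric)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    readr::write_tsv(report, path)
  }
  invisible(path)
}
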