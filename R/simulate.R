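# deterministic integer stream from a seed (no global RNG state)
lcg_stream <- function(seed, n, modulo) {
  s <- as.double(abs(as.integer(seed)) %% 2147483647L)
  if (s <= 0) s <- 1
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- as.integer(floor(s) %% modulo)
  }
  out
}

#' Generate an annotated mitogenome record of a given arrangement type
#'
#' Produces a fully annotated synthetic record whose token sequence
#' equals the registry reference order for `type_label`. Diagnostic
#' control-region and non-coding lengths are taken from the reference
#' order (overridable); all other feature lengths are drawn from the
#' package's table of typical vertebrate gene sizes with a small
#' deterministic per-seed jitter, so that two calls with the same seed
#' are identical and different seeds give plausibly different genomes.
#' Lengths never affect arrangement identity.
#'
#' @param type_label one of the registry labels.
#' @param seed integer seed fixing all randomness.
#' @param registry an arrangement registry.
#' @param cr_lengths optional numeric vector overriding control-region
#'   lengths: in linear order from tRNA-Phe, i.e. for duplicate-CR
#'   types the first element is CR2 (the ND1..ND2 copy) and the last is
#'   CR1 (the copy upstream of tRNA-Phe).
#' @param nc_lengths optional numeric vector overriding NC token
#'   lengths in order of appearance.
#' @param taxon_id,species,family record metadata.
#' @return a one-row record tibble with `source = "generated"`.
#' @export
generate_record <- function(type_label, seed = 1L,
                            registry = arrangement_registry(),
                            cr_lengths = NULL, nc_lengths = NULL,
                            taxon_id = paste0("sim_", type_label),
                            species = paste("Synthetica", type_label),
                            family = "Synthetidae") {
  row <- registry[registry$label == type_label, ]
  if (nrow(row) == 0L) stop("unknown arrangement type label: ", type_label,
                            call. = FALSE)
  ord <- row$order[[1]]
  len <- ord$length_bp
  base <- default_token_length(ord$name)
  jitter <- lcg_stream(seed + 7L * match(type_label, registry$label), nrow(ord), 5L)
  fill <- is.na(len)
  len[fill] <- base[fill] + jitter[fill]
  if (!is.null(cr_lengths)) {
    idx <- which(ord$category == "CR")
    stopifnot(length(cr_lengths) == length(idx))
    len[idx] <- as.integer(cr_lengths)
  }
  if (!is.null(nc_lengths)) {
    idx <- which(ord$category == "NC")
    stopifnot(length(nc_lengths) == length(idx))
    len[idx] <- as.integer(nc_lengths)
  }
  ord$length_bp <- as.integer(len)
  mito_records(taxon_id, species, family, list(ord),
               genome_length_bp = sum(len), source = "generated")
}

#' Generate records for several types, optionally writing GenBank files
#'
#' @param type_labels labels to generate (default: all registry types).
#' @param n records per type.
#' @param seed base seed; record i of type t uses a seed derived
#'   deterministically from it.
#' @param dir if non-NULL, write one GenBank flat file per record here.
#' @param registry an arrangement registry.
#' @return a record tibble (one row per generated record).
#' @export
simulate_types <- function(type_labels = NULL, n = 1L, seed = 1L, dir = NULL,
                           registry = arrangement_registry()) {
  if (is.null(type_labels)) type_labels <- registry$label
  if (n < 1L) {
    warning("n = 0: nothing generated")
    return(mito_records(character(), order = list())[0, ])
  }
  combos <- tidyr::expand_grid(type = type_labels, rep = seq_len(n))
  recs <- purrr::map2_dfr(combos$type, combos$rep, function(t, r) {
    generate_record(t, seed = seed + 131L * r,
                    registry = registry,
                    taxon_id = sprintf("sim_%s_%d", t, r))
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nrow(recs))) {
      write_genbank(recs[i, ],
                    file.path(dir, paste0(recs$taxon_id[i], ".gb")),
                    emit_sequence = FALSE)
    }
  }
  recs
}

#' Load the bundled 65-taxon synthetic study fixture
#'
#' A constructed stand-in for the published 65-species, 14-family snake
#' mitogenome panel: a taxon registry with per-tip arrangement-type
#' assignments, a rooted phylogeny whose topology reproduces the
#' published family-level relationships (Leptotyphlopidae basal,
#' Scolecophidia paraphyletic, Caenophidia ladder Acrochordidae →
#' Xenodermatidae → Viperidae → Homalopsidae → Elapidae → Colubridae),
#' a generated annotated record per taxon, and the prior six-type
#' registry. Integrity violations (taxon/tip mismatch, wrong counts)
#' raise a hard error at load.
#'
#' @param seed base seed for per-taxon record generation.
#' @param registry an arrangement registry.
#' @return an object of class `fixture_set`: list with `records`
#'   (record tibble incl. assigned `type`), `tree` (`phylo`),
#'   `tip_types` (tibble `taxon_id`, `type`), `taxa` (full taxon
#'   table), `prior` (prior registry), `registry`.
#' @export
build_fixture_set <- function(seed = 1L, registry = arrangement_registry()) {
  taxa <- readr::read_tsv(mitorder_extdata("snake_taxa_synthetic.tsv"),
                          comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  tree <- read_phylogeny(mitorder_extdata("snake_tree_synthetic.nwk"))

  if (nrow(taxa) != 65L) stop("fixture integrity: expected 65 taxa, got ",
                              nrow(taxa), call. = FALSE)
  if (dplyr::n_distinct(taxa$family) != 14L) {
    stop("fixture integrity: expected 14 families", call. = FALSE)
  }
  if (!setequal(tree$tip.label, taxa$taxon_id)) {
    stop("fixture integrity: tree tips do not match taxon registry", call. = FALSE)
  }
  if (!all(taxa$type %in% registry$label)) {
    stop("fixture integrity: unknown type label(s) ",
         paste(setdiff(taxa$type, registry$label), collapse = ", "), call. = FALSE)
  }

  recs <- purrr::map_dfr(seq_len(nrow(taxa)), function(i) {
    generate_record(taxa$type[i], seed = seed + i,
                    registry = registry,
                    taxon_id = taxa$taxon_id[i],
                    species = taxa$species[i],
                    family = taxa$family[i])
  })
  recs$type <- taxa$type

  structure(list(records = recs, tree = tree,
                 tip_types = dplyr::select(taxa, "taxon_id", "type"),
                 taxa = taxa, prior = prior_registry(), registry = registry),
            class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("<fixture_set>", nrow(x$records), "records,",
      dplyr::n_distinct(x$taxa$family), "families,",
      dplyr::n_distinct(x$tip_types$type), "arrangement types\n")
  invisible(x)
}

find_adjacent_pair <- function(order, prev, next_) {
  n <- nrow(order)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (order$name[i] == prev && order$name[j] == next_) return(i)
  }
  NA_integer_
}

insert_token <- function(order, after, name, strand = NULL, length_bp = NA) {
  newtok <- gene_order(name, strand, if (is.na(length_bp)) NULL else length_bp)
  if (token_category(name) != "NC" && is.na(length_bp)) {
    newtok$length_bp <- default_token_length(name)
  }
  n <- nrow(order)
  out <- dplyr::bind_rows(
    order[seq_len(after), ], newtok,
    if (after < n) order[(after + 1L):n, ]
  )
  class(out) <- class(order)
  out
}

#' Apply a single rearrangement event to a record
#'
#' Property-test driver for the three rearrangement processes (loss,
#' translocation, duplication) plus insertions, pseudogenizations and
#' control-region asymmetry: returns a new record differing from the
#' input by exactly the given event, so that
#' `infer_event_path(before, after)` recovers it.
#'
#' @param record a one-row record tibble.
#' @param event a one-row event tibble ([event_annotation()]).
#' @param seed unused at present (kept for interface stability).
#' @return a one-row record tibble.
#' @export
perturb <- function(record, event, seed = 1L) {
  stopifnot(nrow(record) == 1L)
  ord <- record$order[[1]]
  kind <- event$kind
  subj <- event$subject

  if (kind == "LOSS") {
    pos <- which(ord$name == subj)
    if (!is.na(event$from_prev)) {
      ctx <- vapply(pos, function(i) {
        nb <- circular_neighbors(nrow(ord), i)
        ord$name[nb[1]] == event$from_prev && ord$name[nb[2]] == event$from_next
      }, TRUE)
      pos <- pos[ctx]
    }
    if (length(pos) == 0L) stop("LOSS inapplicable: ", subj,
                                " not found in the given context", call. = FALSE)
    out <- ord[-pos[1], ]
    class(out) <- class(ord)
  } else if (kind %in% c("INSERTION", "PSEUDOGENIZATION", "DUPLICATION")) {
    at <- find_adjacent_pair(ord, event$to_prev, event$to_next)
    if (is.na(at)) stop(kind, " inapplicable: context (", event$to_prev, ", ",
                        event$to_next, ") not adjacent", call. = FALSE)
    if (kind == "DUPLICATION" && !subj %in% ord$name) {
      stop("DUPLICATION inapplicable: ", subj, " absent from order", call. = FALSE)
    }
    len <- if (!is.na(event$length_bp)) event$length_bp
           else if (kind == "INSERTION") 342L else NA
    out <- insert_token(ord, at, subj, length_bp = len)
  } else if (kind == "TRANSLOCATION") {
    pos <- which(ord$name == subj)
    if (length(pos) != 1L) stop("TRANSLOCATION inapplicable: ", subj,
                                " must occur exactly once", call. = FALSE)
    tok <- ord[pos, ]
    rest <- ord[-pos, ]
    class(rest) <- class(ord)
    at <- find_adjacent_pair(rest, event$to_prev, event$to_next)
    if (is.na(at)) stop("TRANSLOCATION inapplicable: destination context (",
                        event$to_prev, ", ", event$to_next, ") not adjacent",
                        call. = FALSE)
    out <- dplyr::bind_rows(rest[seq_len(at), ], tok,
                            if (at < nrow(rest)) rest[(at + 1L):nrow(rest), ])
    class(out) <- class(ord)
  } else if (kind == "CR_ASYMMETRY") {
    idx <- which(ord$category == "CR")
    if (length(idx) < 2L) stop("CR_ASYMMETRY inapplicable: fewer than two CRs",
                               call. = FALSE)
    out <- ord
    lens <- out$length_bp[idx]
    lens[is.na(lens)] <- default_token_length("CR")
    # stretch the last CR well past the asymmetry threshold
    lens[length(lens)] <- as.integer(max(lens) * 2L)
    out$length_bp[idx] <- lens
  } else {
    stop("unknown event kind: ", kind, call. = FALSE)
  }

  rec <- record
  rec$order <- list(out)
  rec$genome_length_bp <- if (anyNA(out$length_bp)) NA_integer_
                          else sum(out$length_bp)
  rec
}
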