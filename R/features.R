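circular_neighbors <- function(n, i) {
  c(if (i == 1L) n else i - 1L, if (i == n) 1L else i + 1L)
}

#' Detect the light-strand replication origin
#'
#' @param order an `mt_order`.
#' @return a list with `present` (logical) and, when present,
#'   `neighbors`: the names of the two circularly flanking tokens.
#'   Two OL tokens (seen in no known arrangement) raise an integrity
#'   error.
#' @export
detect_ol <- function(order) {
  hits <- which(order$name == "OL")
  if (length(hits) > 1L) stop("integrity error: more than one OL token", call. = FALSE)
  if (length(hits) == 0L) return(list(present = FALSE, neighbors = NULL))
  nb <- circular_neighbors(nrow(order), hits)
  list(present = TRUE, neighbors = order$name[nb])
}

#' Count control regions and assess their length asymmetry
#'
#' Two control regions whose length ratio (max/min) exceeds the
#' asymmetry threshold are flagged asymmetric; near-identical lengths —
#' the signature of concerted evolution of the duplicates — sit at a
#' ratio close to 1.
#'
#' @param order an `mt_order`.
#' @param asymmetry_ratio threshold on max/min CR length (default 1.2).
#' @return a list with `cr_count`, `cr_lengths` (NA where unknown) and
#'   `cr_asymmetric` (FALSE, with a message, when lengths are missing).
#' @export
count_control_regions <- function(order, asymmetry_ratio = 1.2) {
  hits <- which(order$category == "CR")
  lens <- order$length_bp[hits]
  asym <- FALSE
  if (length(hits) >= 2L) {
    if (anyNA(lens)) {
      rlang::inform("CR lengths unknown; asymmetry undefined, reported as FALSE",
                    class = "mitorder_cr_caveat")
    } else {
      asym <- max(lens) / min(lens) > asymmetry_ratio
    }
  }
  list(cr_count = length(hits), cr_lengths = lens, cr_asymmetric = asym)
}

# restrict an order to the identity strings occurring exactly once in
# both orders; returns the id vectors in circular order
shared_single_copy <- function(a, b) {
  ida <- token_id(a); idb <- token_id(b)
  ca <- table(ida); cb <- table(idb)
  shared <- intersect(names(ca)[ca == 1L], names(cb)[cb == 1L])
  list(a = ida[ida %in% shared], b = idb[idb %in% shared])
}

circ_equal <- function(x, y) {
  if (length(x) != length(y)) return(FALSE)
  if (length(x) == 0L) return(TRUE)
  kx <- min_rotation_index(x); ky <- min_rotation_index(y)
  rx <- c(x[kx:length(x)], if (kx > 1L) x[seq_len(kx - 1L)])
  ry <- c(y[ky:length(y)], if (ky > 1L) y[seq_len(ky - 1L)])
  identical(rx, ry)
}

circ_prev_next <- function(ids, i) {
  n <- length(ids)
  c(ids[if (i == 1L) n else i - 1L], ids[if (i == n) 1L else i + 1L])
}

strip_strand <- function(id) sub("^-", "", id)

#' Detect translocated genes relative to a reference order
#'
#' A gene is a translocation candidate when it occurs exactly once in
#' both orders and both of its circular neighbors differ between them;
#' tokens absent from either order are deleted before comparing flanks,
#' so an insertion or loss elsewhere does not cascade into spurious
#' calls. Because a single move of gene X past its neighbor can equally
#' be described as a move of the neighbor, the reported set is the
#' smallest candidate subset whose removal reconciles the two circular
#' orders, preferring mobile elements (tRNAs) over rRNA/protein genes
#' when several minimal explanations exist.
#'
#' @param order an `mt_order` to examine.
#' @param reference_order the baseline `mt_order` (e.g. the canonical
#'   squamate order, or the parent arrangement).
#' @return a tibble with columns `gene`, `ref_prev`, `ref_next`,
#'   `obs_prev`, `obs_next`, sorted by gene name.
#' @export
detect_translocations <- function(order, reference_order) {
  res <- shared_single_copy(reference_order, order)
  ref_ids <- res$a; obs_ids <- res$b
  empty <- tibble::tibble(gene = character(), ref_prev = character(),
                          ref_next = character(), obs_prev = character(),
                          obs_next = character())
  if (circ_equal(ref_ids, obs_ids)) return(empty)

  cand <- character()
  for (id in obs_ids) {
    i_ref <- match(id, ref_ids); i_obs <- match(id, obs_ids)
    nb_ref <- circ_prev_next(ref_ids, i_ref)
    nb_obs <- circ_prev_next(obs_ids, i_obs)
    if (nb_ref[1] != nb_obs[1] && nb_ref[2] != nb_obs[2]) cand <- c(cand, id)
  }
  if (length(cand) == 0L) return(empty)

  # preference: tRNAs (and OL) are the usual mobile elements
  cat_of <- token_category(strip_strand(cand))
  pref <- order(ifelse(cat_of %in% c("tRNA", "OL", "pseudo"), 0L, 1L),
                strip_strand(cand))
  cand <- cand[pref]

  chosen <- cand
  found <- FALSE
  for (s in seq_len(min(length(cand), 6L))) {
    for (combo in utils::combn(seq_along(cand), s, simplify = FALSE)) {
      sub <- cand[combo]
      if (circ_equal(setdiff_keep(ref_ids, sub), setdiff_keep(obs_ids, sub))) {
        chosen <- sub; found <- TRUE; break
      }
    }
    if (found) break
  }

  out <- purrr::map_dfr(sort(strip_strand(chosen)), function(g) {
    id <- chosen[strip_strand(chosen) == g]
    nb_ref <- strip_strand(circ_prev_next(ref_ids, match(id, ref_ids)))
    nb_obs <- strip_strand(circ_prev_next(obs_ids, match(id, obs_ids)))
    tibble::tibble(gene = g, ref_prev = nb_ref[1], ref_next = nb_ref[2],
                   obs_prev = nb_obs[1], obs_next = nb_obs[2])
  })
  dplyr::arrange(out, .data$gene)
}

setdiff_keep <- function(x, drop) x[!x %in% drop]

#' Detect pseudogene tokens and their flanks
#'
#' @param order an `mt_order`.
#' @return a tibble with `symbol`, `prev`, `next_` (circular neighbors).
#' @export
detect_pseudogenes <- function(order) {
  hits <- which(order$category == "pseudo")
  out <- purrr::map_dfr(hits, function(i) {
    nb <- circular_neighbors(nrow(order), i)
    tibble::tibble(symbol = order$name[i],
                   prev = order$name[nb[1]], next_ = order$name[nb[2]])
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(symbol = character(), prev = character(),
                          next_ = character())
  }
  out
}

#' Detect duplicated functional genes
#'
#' Functional gene names occurring two or more times (control regions
#' are counted separately by [count_control_regions()]; pseudo and NC
#' tokens are excluded).
#'
#' @param order an `mt_order`.
#' @return a tibble with `gene` and `n_copies`.
#' @export
detect_extra_copies <- function(order) {
  keep <- !order$category %in% c("CR", "NC", "pseudo")
  counts <- table(order$name[keep])
  dup <- counts[counts >= 2L]
  tibble::tibble(gene = names(dup), n_copies = as.integer(dup))
}

#' Detect non-coding insertions
#'
#' All `NC` tokens with their lengths and circular flanks, sorted by
#' length descending.
#'
#' @param order an `mt_order`.
#' @return a tibble with `length_bp`, `prev`, `next_`.
#' @export
detect_nc_insertions <- function(order) {
  hits <- which(order$category == "NC")
  out <- purrr::map_dfr(hits, function(i) {
    nb <- circular_neighbors(nrow(order), i)
    tibble::tibble(length_bp = order$length_bp[i],
                   prev = order$name[nb[1]], next_ = order$name[nb[2]])
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(length_bp = integer(), prev = character(),
                          next_ = character()))
  }
  dplyr::arrange(out, dplyr::desc(.data$length_bp))
}

#' Per-record rearrangement feature report
#'
#' Runs every detector over a record table and returns one row per
#' taxon. Translocations are scored against the canonical squamate
#' reference order unless another reference is supplied.
#'
#' @param records a record tibble ([mito_records()]).
#' @param reference_order baseline for translocation calls (default
#'   [canonical_reference_order()]).
#' @param asymmetry_ratio CR length-ratio threshold (default 1.2).
#' @return a tibble with per-taxon columns `ol_present`, `cr_count`,
#'   `cr_lengths` (list), `cr_asymmetric`, `translocations`,
#'   `pseudogenes`, `nc_insertions`, `extra_copies` (list-columns).
#' @export
feature_report <- function(records, reference_order = canonical_reference_order(),
                           asymmetry_ratio = 1.2) {
  rows <- purrr::map2_dfr(records$taxon_id, records$order, function(tid, ord) {
    ol <- detect_ol(ord)
    cr <- count_control_regions(ord, asymmetry_ratio)
    tibble::tibble(
      taxon_id = tid,
      ol_present = ol$present,
      cr_count = cr$cr_count,
      cr_lengths = list(cr$cr_lengths),
      cr_asymmetric = cr$cr_asymmetric,
      translocations = list(detect_translocations(ord, reference_order)),
      pseudogenes = list(detect_pseudogenes(ord)),
      nc_insertions = list(detect_nc_insertions(ord)),
      extra_copies = list(detect_extra_copies(ord))
    )
  })
  rows
}

#' Write a feature report to JSON or TSV
#'
#' @param report output of [feature_report()].
#' @param path output path; format chosen by extension (`.json` or
#'   `.tsv`).
#' @return `path`, invisibly.
#' @export
write_feature_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    flat <- dplyr::mutate(
      report,
      cr_lengths = vapply(.data$cr_lengths, paste, "", collapse = ","),
      translocations = vapply(.data$translocations,
                              function(x) paste(x$gene, collapse = ","), ""),
      pseudogenes = vapply(.data$pseudogenes,
                           function(x) paste(x$symbol, collapse = ","), ""),
      nc_insertions = vapply(.data$nc_insertions,
                             function(x) paste(x$length_bp, collapse = ","), ""),
      extra_copies = vapply(.data$extra_copies,
                            function(x) paste(x$gene, collapse = ","), "")
    )
    readr::write_tsv(flat, path)
  }
  invisible(path)
}

# positions of the WANCY span (W..Y walking forward) in an order; NULL
# when W or Y is absent
wancy_span <- function(order) {
  iw <- match("W", order$name); iy <- match("Y", order$name)
  if (is.na(iw) || is.na(iy)) return(NULL)
  if (iw <= iy) iw:iy else c(iw:nrow(order), 1:iy)
}

locus_of_event <- function(event, type_order) {
  if (event$kind == "CR_ASYMMETRY") return("CR-flank")
  ctx <- unlist(event[c("from_prev", "from_next", "to_prev", "to_next")],
                use.names = FALSE)
  ctx <- ctx[!is.na(ctx)]
  subj <- event$subject
  subj_pos <- which(type_order$name == subj)
  # CR-flank: the token the event creates/moves/removes is a CR, sits
  # next to a CR in the type's own order, or the event junction touches
  # a CR
  if (subj == "CR" || "CR" %in% ctx) return("CR-flank")
  for (i in subj_pos) {
    nb <- circular_neighbors(nrow(type_order), i)
    if (any(type_order$category[nb] == "CR")) return("CR-flank")
  }
  span <- wancy_span(type_order)
  if (!is.null(span)) {
    loci <- c(subj_pos, match(ctx, type_order$name))
    loci <- loci[!is.na(loci)]
    # OL counts as inside the cluster even in orders that lost it
    if (length(loci) && all(loci %in% span)) return("WANCY")
  }
  "other"
}

#' Assign hotspot loci to the diagnostic events of arrangement types
#'
#' Each diagnostic rearrangement event of each type is assigned a locus:
#' `CR-flank` when the token it creates, moves or removes is a control
#' region or is circularly adjacent to one in the type's own order
#' (control-region asymmetry is CR-flank by definition); `WANCY` when
#' all its loci fall inside the Trp..Tyr tRNA cluster (inclusive of OL);
#' `other` otherwise.
#'
#' @param registry an arrangement registry ([arrangement_registry()]).
#' @param labels types to score (default: every type in the registry).
#' @return a tibble with `label`, `kind`, `subject`, `locus`.
#' @export
hotspot_assignment <- function(registry, labels = registry$label) {
  purrr::map_dfr(labels, function(lab) {
    row <- registry[registry$label == lab, ]
    if (nrow(row) == 0L) stop("unknown type label: ", lab, call. = FALSE)
    ev <- row$events[[1]]
    if (is.null(ev) || nrow(ev) == 0L) {
      stop("type ", lab, " has no diagnostic events", call. = FALSE)
    }
    ord <- row$order[[1]]
    ev$locus <- vapply(seq_len(nrow(ev)),
                       function(i) locus_of_event(ev[i, ], ord), "")
    dplyr::select(dplyr::mutate(ev, label = lab),
                  "label", "kind", "subject", "locus")
  })
}

#' Hotspot census over a registry
#'
#' Counts, per locus, how many arrangement types have at least one
#' diagnostic event assigned there.
#'
#' @param registry an arrangement registry.
#' @return a tibble with `locus` and `n_types`.
#' @export
hotspot_census <- function(registry) {
  hs <- hotspot_assignment(registry)
  dplyr::summarise(dplyr::group_by(hs, .data$locus),
                   n_types = dplyr::n_distinct(.data$label), .groups = "drop")
}
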