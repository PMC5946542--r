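mitorder_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mitorder")
  if (!nzchar(path)) {
    # during development (package not installed) fall back to source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("cannot find data file ", file, call. = FALSE)
  path
}

#' The canonical squamate reference gene order
#'
#' The typical vertebrate/squamate mitochondrial arrangement used as the
#' comparison baseline: the IQM tRNA cluster between ND1 and ND2, the
#' WAN-OL-CY cluster, Leu(UUR) between 16S and ND1, and a single
#' control region between Pro and Phe.
#'
#' @return an `mt_order`.
#' @export
canonical_reference_order <- function() {
  parse_order_string(paste0(
    "F,12S,V,16S,L2,ND1,I,-Q,M,ND2,W,-A,-N,OL,-C,-Y,COX1,-S2,D,COX2,K,",
    "ATP8,ATP6,COX3,G,ND3,R,ND4L,ND4,H,S1,L1,ND5,-ND6,-E,CYTB,T,-P,CR:1100"))
}

read_type_table <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  raw$order <- lapply(raw$order, parse_order_string)
  if ("asym_required" %in% names(raw)) {
    raw$asym_required <- as.logical(raw$asym_required)
  } else {
    raw$asym_required <- FALSE
  }
  raw$key <- vapply(raw$order, canonical_key, "")
  raw
}

#' The arrangement-type registry
#'
#' Loads the eleven reference snake arrangement types (labels I, II,
#' III, III-A ... III-G) with their reference orders, derivation
#' parents and diagnostic rearrangement events. Diagnostic events are
#' computed by [infer_event_path()] against each type's parent
#' arrangement; for the three basal types (I, II, III), whose true
#' ancestor is indeterminate, the canonical squamate order serves as
#' the baseline for describing the events without implying it is the
#' actual ancestor.
#'
#' @param asymmetry_ratio CR length-ratio threshold used when deriving
#'   diagnostic events (default 1.2).
#' @return a tibble of class `mt_registry` with columns `label`,
#'   `parent`, `asym_required`, `description`, `order` (list),
#'   `key`, `events` (list); the canonical baseline is attached as
#'   attribute `reference`.
#' @export
arrangement_registry <- function(asymmetry_ratio = 1.2) {
  tab <- read_type_table(mitorder_extdata("arrangement_types.tsv"))
  reference <- canonical_reference_order()
  tab$events <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parent_order <- if (tab$parent[i] == "UNKNOWN") {
      reference
    } else {
      j <- match(tab$parent[i], tab$label)
      if (is.na(j)) stop("registry parent not found: ", tab$parent[i], call. = FALSE)
      tab$order[[j]]
    }
    tab$events[[i]] <- infer_event_path(parent_order, tab$order[[i]],
                                        asymmetry_ratio = asymmetry_ratio)
  }
  validate_registry(tab)
  attr(tab, "reference") <- reference
  class(tab) <- c("mt_registry", class(tab))
  tab
}

validate_registry <- function(tab) {
  if (anyDuplicated(tab$label)) stop("duplicate registry labels", call. = FALSE)
  dup_keys <- tab$key[duplicated(tab$key)]
  for (k in unique(dup_keys)) {
    rows <- tab[tab$key == k, ]
    # the one sanctioned collision: a token-identical pair distinguished
    # by the CR-asymmetry marker
    if (!(nrow(rows) == 2L && sum(rows$asym_required) == 1L)) {
      stop("registry integrity error: types ",
           paste(rows$label, collapse = ", "),
           " share one arrangement without a distinguishing marker",
           call. = FALSE)
    }
  }
  invisible(tab)
}

#' The previously reported six-arrangement registry
#'
#' The six snake mitogenome arrangements known before the eleven-type
#' comparison, used by [novel_types()] to determine which of the eleven
#' types are new.
#'
#' @return a tibble with `label`, `description`, `order` (list), `key`,
#'   `asym_required` (all `FALSE`; none of the prior arrangements was
#'   diagnosed by control-region asymmetry).
#' @export
prior_registry <- function() {
  read_type_table(mitorder_extdata("prior_arrangement_types.tsv"))
}

registry_match_label <- function(key, is_asym, registry) {
  rows <- registry[registry$key == key, ]
  if (nrow(rows) == 0L) return(NA_character_)
  if (nrow(rows) == 1L) {
    # a type whose sole diagnostic is CR asymmetry only matches
    # asymmetric records; without the marker the record keeps the
    # token-identical base label, which cannot exist here (the base
    # would share the key) - so accept directly
    return(rows$label)
  }
  if (nrow(rows) == 2L && sum(rows$asym_required) == 1L) {
    return(if (isTRUE(is_asym)) rows$label[rows$asym_required]
           else rows$label[!rows$asym_required])
  }
  stop("registry integrity error: record matches types ",
       paste(rows$label, collapse = ", "), call. = FALSE)
}

#' Classify records into arrangement types
#'
#' Assigns each record the label of the registry type with the same
#' circular arrangement (same components and order, lengths abstracted).
#' A record token-identical to a type that is distinguished only by
#' control-region asymmetry is promoted to that type when its CR length
#' ratio exceeds the threshold. Records matching no registry type
#' receive fresh deterministic labels `NEW-1`, `NEW-2`, ... in input
#' order (repeated novel arrangements share their label); no record is
#' left unlabeled.
#'
#' @param records a record tibble.
#' @param registry an arrangement registry (default
#'   [arrangement_registry()]).
#' @param asymmetry_ratio CR length-ratio threshold (default 1.2).
#' @return `records` with a `type` column appended; novel keys are
#'   recorded in attribute `new_types` (tibble `type`, `key`).
#' @export
classify_records <- function(records, registry = arrangement_registry(),
                             asymmetry_ratio = 1.2) {
  new_keys <- character()
  labels <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    ord <- records$order[[i]]
    key <- canonical_key(ord)
    cr <- suppressMessages(count_control_regions(ord, asymmetry_ratio))
    lab <- registry_match_label(key, cr$cr_asymmetric, registry)
    if (is.na(lab)) {
      k <- match(key, new_keys)
      if (is.na(k)) {
        new_keys <- c(new_keys, key)
        k <- length(new_keys)
      }
      lab <- paste0("NEW-", k)
    }
    labels[i] <- lab
  }
  out <- dplyr::mutate(records, type = labels)
  attr(out, "new_types") <- tibble::tibble(
    type = paste0("NEW-", seq_along(new_keys)), key = new_keys)
  out
}

#' Classify a single gene order
#'
#' @param order an `mt_order`.
#' @inheritParams classify_records
#' @return a single type label (or `"NEW-1"` for an arrangement absent
#'   from the registry).
#' @export
classify_order <- function(order, registry = arrangement_registry(),
                           asymmetry_ratio = 1.2) {
  rec <- mito_records("x", order = list(order), source = "parsed")
  classify_records(rec, registry, asymmetry_ratio)$type
}

#' Arrangement-type census
#'
#' @param records a record tibble with a `type` column (from
#'   [classify_records()]); records without one are classified first.
#' @param registry used only when classification is still needed.
#' @return a tibble of class `mt_census` with `type`, `n`, sorted by
#'   label; the number of distinct types is attribute `n_types` and is
#'   also available via [n_distinct_types()].
#' @export
type_census <- function(records, registry = arrangement_registry()) {
  if (!"type" %in% names(records)) records <- classify_records(records, registry)
  out <- dplyr::count(records, .data$type, name = "n")
  out <- dplyr::arrange(out, .data$type)
  attr(out, "n_types") <- nrow(out)
  class(out) <- c("mt_census", class(out))
  out
}

#' @rdname type_census
#' @param census an `mt_census`.
#' @export
n_distinct_types <- function(census) {
  sum(census$n >= 1L)
}

#' Types absent from a prior registry
#'
#' Compares two registries under the arrangement-identity rule
#' (canonical key, plus the CR-asymmetry marker for the type diagnosed
#' by it alone) and returns the labels in `registry_now` with no
#' arrangement-identical member in `registry_prior`, sorted by label.
#'
#' @param registry_now,registry_prior registry tibbles with `key` and
#'   `asym_required` columns.
#' @return character vector of labels.
#' @export
novel_types <- function(registry_now, registry_prior) {
  prior_id <- paste(registry_prior$key, registry_prior$asym_required)
  now_id <- paste(registry_now$key, registry_now$asym_required)
  sort(registry_now$label[!now_id %in% prior_id])
}
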