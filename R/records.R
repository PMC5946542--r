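#' Assemble a mitogenome record table
#'
#' The dataset container used across the package: one row per genome,
#' with the circular gene order held in a list-column so the table
#' remains a plain tibble that pipes through dplyr verbs.
#'
#' @param taxon_id character vector of unique record identifiers
#'   (must match tree tip labels when a phylogeny is used).
#' @param species,family character vectors of the same length.
#' @param order a list of `mt_order` objects.
#' @param genome_length_bp optional integer vector (`NA` where unknown).
#' @param source provenance of each record: `"parsed"`, `"fixture"` or
#'   `"generated"`.
#' @return a tibble with columns `taxon_id`, `species`, `family`,
#'   `genome_length_bp`, `source`, `order`.
#' @export
mito_records <- function(taxon_id, species = taxon_id, family = NA_character_,
                         order, genome_length_bp = NA_integer_,
                         source = "parsed") {
  if (anyDuplicated(taxon_id)) {
    stop("duplicate taxon_id: ",
         paste(unique(taxon_id[duplicated(taxon_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(order) || inherits(order, "mt_order")) order <- list(order)
  stopifnot(length(order) == length(taxon_id))
  ok <- vapply(order, inherits, TRUE, what = "mt_order")
  if (!all(ok)) stop("order must be a list of mt_order objects", call. = FALSE)
  tibble::tibble(
    taxon_id = as.character(taxon_id),
    species = as.character(species),
    family = as.character(family),
    genome_length_bp = as.integer(genome_length_bp),
    source = as.character(source),
    order = order
  )
}

#' Read / write a gene-order TSV
#'
#' Plain-text interchange format for gene orders: tab-separated columns
#' `taxon_id`, `species`, `family`, `order`, where `order` holds the
#' comma-separated token string of [parse_order_string()] (`-` prefix for
#' L-strand, `:len` suffix for lengths). An optional
#' `genome_length_bp` column is carried through. Lines starting with `#`
#' are comments. The round trip write-then-read is lossless for token
#' names, strands and lengths.
#'
#' @param path file path.
#' @return for `read_gene_orders`, a record tibble as produced by
#'   [mito_records()]; `write_gene_orders` returns `path` invisibly.
#' @export
read_gene_orders <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("taxon_id", "species", "family", "order")
  if (!all(need %in% names(raw))) {
    stop("gene-order TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$taxon_id)) {
    stop("duplicate taxon_id in ", path, ": ",
         paste(unique(raw$taxon_id[duplicated(raw$taxon_id)]), collapse = ", "),
         call. = FALSE)
  }
  orders <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    orders[[i]] <- tryCatch(
      parse_order_string(raw$order[i]),
      error = function(e) stop("line ", i, " (", raw$taxon_id[i], "): ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  glen <- if ("genome_length_bp" %in% names(raw)) {
    as.integer(raw$genome_length_bp)
  } else {
    NA_integer_
  }
  mito_records(raw$taxon_id, raw$species, raw$family, orders,
               genome_length_bp = glen, source = "parsed")
}

#' @rdname read_gene_orders
#' @param records a record tibble.
#' @export
write_gene_orders <- function(records, path) {
  out <- tibble::tibble(
    taxon_id = records$taxon_id,
    species = records$species,
    family = records$family,
    genome_length_bp = records$genome_length_bp,
    order = vapply(records$order, format_order_string, "", lengths = "all")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
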