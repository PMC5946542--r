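#' Construct a circular gene order
#'
#' A gene order is a tibble of tokens (one row per annotated feature, in
#' circular order) with class `mt_order`. Token identity is the triple
#' (name, strand, pseudo-ness); `length_bp` is carried for control
#' regions, non-coding blocks and generated records but is ignored by the
#' arrangement-identity rule.
#'
#' @param name character vector of standardized symbols (see
#'   [mt_vocabulary()]); pseudogenes carry a trailing `*`.
#' @param strand integer vector of +1 (H-strand) / -1 (L-strand);
#'   defaults to the typical vertebrate strand of each gene.
#' @param length_bp optional integer vector of feature lengths; `NA`
#'   where unknown. `NC` tokens must carry a length.
#' @return an `mt_order` tibble with columns `name`, `category`,
#'   `strand`, `length_bp`.
#' @examples
#' gene_order(c("F", "12S", "V", "16S"))
#' @export
gene_order <- function(name, strand = NULL, length_bp = NULL) {
  if (length(name) == 0L) stop("a gene order must contain at least one token", call. = FALSE)
  category <- token_category(name)
  if (is.null(strand)) strand <- default_strand(name)
  strand <- as.integer(strand)
  if (!all(strand %in% c(-1L, 1L))) stop("strand must be +1 or -1", call. = FALSE)
  if (is.null(length_bp)) length_bp <- rep(NA_integer_, length(name))
  length_bp <- as.integer(length_bp)
  if (any(!is.na(length_bp) & length_bp <= 0L)) {
    stop("length_bp must be positive where given", call. = FALSE)
  }
  if (any(category == "NC" & is.na(length_bp))) {
    stop("NC tokens must carry length_bp", call. = FALSE)
  }
  out <- tibble::tibble(name = as.character(name), category = category,
                        strand = strand, length_bp = length_bp)
  class(out) <- c("mt_order", class(out))
  out
}

#' Parse a comma-separated token string into a gene order
#'
#' The dialect used in gene-order TSV files: tokens separated by commas,
#' a `-` prefix for L-strand genes and a `:len` suffix for lengths, e.g.
#' `"F,12S,V,16S,ND1,I,CR:1100,L2,-Q,M"`.
#'
#' @param x a single token string.
#' @return an `mt_order`.
#' @export
parse_order_string <- function(x) {
  stopifnot(length(x) == 1L)
  x <- trimws(x)
  if (!nzchar(x)) stop("empty order string", call. = FALSE)
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  if (any(!nzchar(parts))) stop("malformed token: empty field in order string", call. = FALSE)
  m <- regmatches(parts, regexec("^(-?)([A-Za-z0-9]+\\*?)(:([0-9]+))?$", parts))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed token(s): ", paste(parts[bad], collapse = ", "), call. = FALSE)
  }
  strand <- ifelse(vapply(m, `[`, "", 2L) == "-", -1L, 1L)
  name <- vapply(m, `[`, "", 3L)
  len <- suppressWarnings(as.integer(vapply(m, `[`, "", 5L)))
  gene_order(name, strand, len)
}

#' Render a gene order as a token string
#'
#' Inverse of [parse_order_string()]. Lengths are written only where
#' known (or restricted to NC/CR tokens with `lengths = "diagnostic"`).
#'
#' @param order an `mt_order`.
#' @param lengths one of `"all"` (write every known length),
#'   `"diagnostic"` (only CR/NC lengths) or `"none"`.
#' @return a single string.
#' @export
format_order_string <- function(order, lengths = c("all", "diagnostic", "none")) {
  lengths <- match.arg(lengths)
  keep <- !is.na(order$length_bp)
  if (lengths == "diagnostic") keep <- keep & order$category %in% c("CR", "NC")
  if (lengths == "none") keep <- keep & order$category == "NC"  # NC must keep length
  paste0(ifelse(order$strand < 0L, "-", ""), order$name,
         ifelse(keep, paste0(":", order$length_bp), ""),
         collapse = ",")
}

#' @export
print.mt_order <- function(x, ...) {
  cat("<mt_order> circular,", nrow(x), "tokens\n")
  cat(" ", format_order_string(x, lengths = "diagnostic"), "\n")
  invisible(x)
}

token_id <- function(order, with_lengths = FALSE) {
  id <- paste0(ifelse(order$strand < 0L, "-", ""), order$name)
  if (with_lengths) {
    keep <- order$category %in% c("CR", "NC") & !is.na(order$length_bp)
    id <- ifelse(keep, paste0(id, ":", order$length_bp), id)
  }
  id
}

rotate_order <- function(order, k) {
  n <- nrow(order)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(order)
  idx <- c((k + 1L):n, 1L:k)
  out <- order[idx, ]
  class(out) <- class(order)
  out
}

# index of the lexicographically smallest rotation of a string vector,
# comparing whole token sequences elementwise
min_rotation_index <- function(ids) {
  n <- length(ids)
  if (n == 1L) return(1L)
  best <- 1L
  for (k in 2L:n) {
    a <- c(ids[k:n], ids[seq_len(k - 1L)])
    b <- c(ids[best:n], if (best > 1L) ids[seq_len(best - 1L)])
    cmp <- which(a != b)
    if (length(cmp) && a[cmp[1]] < b[cmp[1]]) best <- k
  }
  best
}

#' Linearize a circular gene order at an anchor gene
#'
#' Rotates the circular order so that it starts at the anchor. Under
#' anchor duplication the rotation yielding the lexicographically
#' smallest token sequence is chosen, making the result deterministic
#' and invariant under rotation of the input.
#'
#' @param order an `mt_order`.
#' @param anchor gene symbol to start from (default tRNA-Phe `F`,
#'   falling back to `12S` if absent).
#' @return an `mt_order` starting at the anchor.
#' @export
linearize <- function(order, anchor = "F") {
  hits <- which(order$name == anchor)
  if (length(hits) == 0L) {
    fallback <- setdiff(c("F", "12S"), anchor)
    present <- fallback[fallback %in% order$name]
    stop("anchor '", anchor, "' absent from order",
         if (length(present)) paste0("; try anchor '", present[1], "'") else "",
         call. = FALSE)
  }
  ids <- token_id(order)
  if (length(hits) == 1L) return(rotate_order(order, hits - 1L))
  rots <- lapply(hits - 1L, function(k) c(ids[(k + 1L):length(ids)], if (k > 0L) ids[seq_len(k)]))
  best <- hits[order(vapply(rots, paste, "", collapse = "\r"))[1]]
  rotate_order(order, best - 1L)
}

#' Canonical key of a circular gene order
#'
#' The lexicographically minimal rotation of the token-identity string
#' (name, strand, pseudo-ness; `NC` reduced to the bare symbol unless
#' `compare_lengths = TRUE`, in which case CR/NC lengths are part of the
#' key). Two circular orders have equal keys exactly when they are the
#' same arrangement.
#'
#' @param order an `mt_order`.
#' @param compare_lengths include CR/NC lengths in the key?
#' @return a single string.
#' @export
canonical_key <- function(order, compare_lengths = FALSE) {
  ids <- token_id(order, with_lengths = compare_lengths)
  k <- min_rotation_index(ids)
  rot <- c(ids[k:length(ids)], if (k > 1L) ids[seq_len(k - 1L)])
  paste(rot, collapse = ",")
}

#' Are two circular gene orders the same arrangement?
#'
#' Implements the typing rule: two genome arrangements are identical when
#' they have the same components and the same circular order. Feature
#' lengths are not part of the rule, so control regions of different
#' sizes still compare equal.
#'
#' @param a,b `mt_order` objects.
#' @return `TRUE`/`FALSE`.
#' @export
same_arrangement <- function(a, b) {
  identical(canonical_key(a), canonical_key(b))
}
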