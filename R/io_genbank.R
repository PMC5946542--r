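# Synonym table mapping GenBank gene/product qualifiers onto the
# standardized symbol vocabulary. Matching is case-insensitive.
genbank_synonyms <- function() {
  tab <- vocab_table()
  syn <- c(
    stats::setNames(tab$name, tolower(tab$full_name)),
    stats::setNames(tab$name, tolower(tab$name)),
    "trna-leu(uur)" = "L2", "trna-leu(cun)" = "L1",
    "trna-ser(ucn)" = "S2", "trna-ser(agy)" = "S1",
    "trna-ser(gcu)" = "S1", "trna-leu(uaa)" = "L2", "trna-leu(uag)" = "L1",
    "s-rrna" = "12S", "l-rrna" = "16S",
    "12s rrna" = "12S", "16s rrna" = "16S",
    "small subunit ribosomal rna" = "12S",
    "large subunit ribosomal rna" = "16S",
    "coi" = "COX1", "coii" = "COX2", "coiii" = "COX3",
    "co1" = "COX1", "co2" = "COX2", "co3" = "COX3",
    "cox i" = "COX1", "cox ii" = "COX2", "cox iii" = "COX3",
    "cytb" = "CYTB", "cyt b" = "CYTB", "cob" = "CYTB",
    "atpase 6" = "ATP6", "atpase 8" = "ATP8",
    "atpase6" = "ATP6", "atpase8" = "ATP8",
    "nad1" = "ND1", "nad2" = "ND2", "nad3" = "ND3", "nad4" = "ND4",
    "nad4l" = "ND4L", "nad5" = "ND5", "nad6" = "ND6",
    "d-loop" = "CR", "control region" = "CR",
    "rep_origin" = "OL", "origin of l-strand replication" = "OL",
    "ol" = "OL", "non-coding region" = "NC"
  )
  syn
}

lookup_symbol <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  unname(genbank_synonyms()[tolower(trimws(x))])
}

# ambiguous tRNA-Leu / tRNA-Ser (no anticodon given): NA placeholder
# resolved later from flanking genes
AMBIG_LEU <- ".LEU"
AMBIG_SER <- ".SER"

feature_symbol <- function(key, gene, product, note, pseudo_flag) {
  cand <- c(product, gene, note)
  cand <- cand[!is.na(cand) & nzchar(cand)]
  if (key == "D-loop") return("CR")
  if (key == "rep_origin") return("OL")
  sym <- NA_character_
  for (x in cand) {
    low <- tolower(trimws(x))
    if (key == "tRNA" && low %in% c("trna-leu", "trna-ser")) {
      return(if (low == "trna-leu") AMBIG_LEU else AMBIG_SER)
    }
    sym <- lookup_symbol(x)
    if (!is.na(sym)) break
  }
  if (key == "misc_feature" && is.na(sym)) {
    # pseudogene notes like "tRNA-Pro pseudogene"
    note_low <- tolower(paste(cand, collapse = " "))
    m <- regmatches(note_low, regexpr("trna-[a-z]{3}(\\([a-z]{3}\\))?", note_low))
    if (length(m)) sym <- lookup_symbol(m[1])
  }
  sym
}

parse_location <- function(loc) {
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  m <- regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc)
  g <- regmatches(loc, m)[[1]]
  if (length(g) == 0L) {
    m1 <- regexec("^([0-9]+)$", loc)
    g1 <- regmatches(loc, m1)[[1]]
    if (length(g1) == 0L) stop("cannot parse feature location: ", loc, call. = FALSE)
    return(list(start = as.integer(g1[2]), end = as.integer(g1[2]), strand = strand))
  }
  list(start = as.integer(g[2]), end = as.integer(g[3]), strand = strand)
}

#' Parse a GenBank flat file into a mitogenome record
#'
#' Reads the FEATURES table of a GenBank-format record and transcribes
#' it into a circular gene order. Feature keys `tRNA`, `rRNA`, `CDS`,
#' `D-loop`, `rep_origin` and `misc_feature` are consumed; gene/product
#' qualifiers are mapped to the standard vocabulary through a synonym
#' table; `misc_feature` entries annotated as pseudogenes become pseudo
#' tokens; unannotated gaps of at least `nc_threshold` bp (including the
#' wrap-around gap) become `NC` tokens. Coordinates are taken 1-based
#' inclusive, as in GenBank, and converted internally. A `tRNA-Leu` or
#' `tRNA-Ser` without an anticodon qualifier is disambiguated from its
#' flanking genes (Leu(CUN) sits next to Ser(AGY)/ND5, Ser(UCN) next to
#' COX1/Asp) and the inference is reported as a message.
#'
#' @param text a GenBank record as a single string, character vector of
#'   lines, or path to a file.
#' @param taxon_id,species,family metadata for the resulting record;
#'   `taxon_id` defaults to the LOCUS name.
#' @param nc_threshold minimum size (bp) for an unannotated gap to be
#'   kept as an `NC` token (default 50, well above typical intergenic
#'   spacers and below the smallest diagnostic insertion).
#' @return a one-row record tibble ([mito_records()]).
#' @export
read_genbank <- function(text, taxon_id = NULL, species = NA_character_,
                         family = NA_character_, nc_threshold = 50L) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  glen <- NA_integer_
  locus_name <- NA_character_
  if (length(locus_line)) {
    toks <- strsplit(trimws(locus_line[1]), "\\s+")[[1]]
    locus_name <- toks[2]
    bp <- which(toks == "bp")
    if (length(bp)) glen <- as.integer(toks[bp[1] - 1L])
  }
  if (is.null(taxon_id)) taxon_id <- locus_name
  def <- grep("^DEFINITION", lines, value = TRUE)
  if (is.na(species) && length(def)) {
    species <- sub("\\s+mitochondrion.*$", "", sub("^DEFINITION\\s+", "", def[1]))
  }

  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("no FEATURES table found", call. = FALSE)
  body <- lines[(fstart[1] + 1L):length(lines)]
  stop_at <- grep("^(ORIGIN|CONTIG|//)", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]

  # split into features: a feature header has a non-blank key in cols 6-20
  is_header <- grepl("^\\s{1,10}[A-Za-z'_-]+\\s+\\S", body) & !grepl("^\\s{21}", body)
  idx <- which(is_header)
  if (length(idx) == 0L) stop("FEATURES table contains no features", call. = FALSE)

  feats <- list()
  for (j in seq_along(idx)) {
    block <- body[idx[j]:(if (j < length(idx)) idx[j + 1L] - 1L else length(body))]
    head_toks <- strsplit(trimws(block[1]), "\\s+")[[1]]
    key <- head_toks[1]
    loc <- paste(head_toks[-1], collapse = "")
    rest <- paste(trimws(block[-1]), collapse = " ")
    # continuation of location before first qualifier
    if (!startsWith(rest, "/") && nzchar(rest)) {
      first_q <- regexpr("/", rest, fixed = TRUE)
      if (first_q > 0) {
        loc <- paste0(loc, gsub("\\s", "", substr(rest, 1, first_q - 1L)))
        rest <- substr(rest, first_q, nchar(rest))
      } else {
        loc <- paste0(loc, gsub("\\s", "", rest)); rest <- ""
      }
    }
    get_q <- function(q) {
      m <- regmatches(rest, regexec(paste0("/", q, '="([^"]*)"'), rest))[[1]]
      if (length(m) >= 2) m[2] else NA_character_
    }
    feats[[j]] <- list(
      key = key, loc = loc,
      gene = get_q("gene"), product = get_q("product"), note = get_q("note"),
      pseudo = grepl("/pseudo(\\s|$|/)", paste0(rest, " "))
    )
  }
  keep_keys <- c("tRNA", "rRNA", "CDS", "D-loop", "rep_origin", "misc_feature")
  feats <- Filter(function(f) f$key %in% keep_keys, feats)
  if (length(feats) == 0L) stop("no usable features (tRNA/rRNA/CDS/D-loop/rep_origin/misc_feature)",
                                call. = FALSE)

  rows <- purrr::map_dfr(feats, function(f) {
    lc <- parse_location(f$loc)
    sym <- feature_symbol(f$key, f$gene, f$product, f$note, f$pseudo)
    is_pseudo <- isTRUE(f$pseudo) ||
      grepl("pseudo", tolower(paste(f$note, "")), fixed = TRUE)
    len <- lc$end - lc$start + 1L
    if (f$key == "misc_feature" && is.na(sym)) {
      if (len < nc_threshold) return(NULL)
      sym <- "NC"; is_pseudo <- FALSE
    }
    if (is.na(sym)) {
      qual <- paste(stats::na.omit(c(f$gene, f$product, f$note)), collapse = " / ")
      stop("unknown gene name in ", f$key, " feature: '", qual, "'", call. = FALSE)
    }
    if (is_pseudo && !sym %in% c("CR", "OL", "NC")) sym <- paste0(sym, "*")
    tibble::tibble(name = sym, start = lc$start, end = lc$end,
                   strand = lc$strand, length_bp = len)
  })
  rows <- dplyr::arrange(rows, .data$start, .data$end)

  # overlapping features are permitted but reported
  if (nrow(rows) > 1L && any(rows$start[-1] <= rows$end[-nrow(rows)])) {
    rlang::inform("overlapping features detected; keeping all",
                  class = "mitorder_overlap")
  }

  # unannotated gaps >= threshold become NC tokens (incl. wrap-around)
  gaps <- tibble::tibble(name = character(), start = integer(),
                         end = integer(), strand = integer(), length_bp = integer())
  if (nrow(rows) > 1L) {
    gs <- rows$end[-nrow(rows)] + 1L
    ge <- rows$start[-1] - 1L
    big <- which(ge - gs + 1L >= nc_threshold)
    if (length(big)) {
      gaps <- tibble::tibble(name = "NC", start = gs[big], end = ge[big],
                             strand = 1L, length_bp = ge[big] - gs[big] + 1L)
    }
  }
  if (!is.na(glen)) {
    tail_gap <- glen - max(rows$end) + (min(rows$start) - 1L)
    if (tail_gap >= nc_threshold) {
      gaps <- dplyr::bind_rows(gaps, tibble::tibble(
        name = "NC", start = max(rows$end) + 1L, end = max(rows$end) + tail_gap,
        strand = 1L, length_bp = tail_gap))
    }
  }
  rows <- dplyr::arrange(dplyr::bind_rows(rows, gaps), .data$start, .data$end)

  # resolve anticodon-less Leu/Ser from flanking genes
  amb <- which(rows$name %in% c(AMBIG_LEU, AMBIG_SER))
  for (i in amb) {
    nb <- rows$name[c(if (i > 1L) i - 1L else nrow(rows),
                      if (i < nrow(rows)) i + 1L else 1L)]
    if (rows$name[i] == AMBIG_LEU) {
      rows$name[i] <- if (any(nb %in% c("S1", "ND5", AMBIG_SER))) "L1" else "L2"
    } else {
      rows$name[i] <- if (any(nb %in% c("COX1", "D"))) "S2" else "S1"
    }
    rlang::inform(paste0("anticodon not annotated; assigned ", rows$name[i],
                         " from flanking genes"), class = "mitorder_trna_inference")
  }

  ord <- gene_order(rows$name, rows$strand, rows$length_bp)
  mito_records(taxon_id, species, family, list(ord),
               genome_length_bp = glen, source = "parsed")
}

wrap_qualifier <- function(x) paste0("                     ", x)

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits a minimal but syntactically standard GenBank record (LOCUS,
#' DEFINITION, FEATURES, optional ORIGIN) for one record row. Feature
#' coordinates are laid out contiguously from position 1 in token order;
#' tokens with unknown length receive the package's default lengths.
#'
#' @param record a one-row record tibble.
#' @param path output file path; if `NULL` the text is returned as a
#'   character vector of lines.
#' @param emit_sequence write an ORIGIN section of seeded random
#'   nucleotides matching the feature lengths?
#' @param seed integer seed for the random sequence.
#' @return the lines invisibly (or written to `path`).
#' @export
write_genbank <- function(record, path = NULL, emit_sequence = FALSE, seed = 1L) {
  stopifnot(nrow(record) == 1L)
  ord <- record$order[[1]]
  len <- ord$length_bp
  len[is.na(len)] <- default_token_length(ord$name[is.na(len)])
  end <- cumsum(as.numeric(len))
  start <- c(1, end[-length(end)] + 1)
  glen <- end[length(end)]

  tab <- vocab_table()
  full <- function(nm) tab$full_name[match(sub("\\*$", "", nm), tab$name)]

  feat_lines <- character()
  for (i in seq_len(nrow(ord))) {
    loc <- sprintf("%d..%d", start[i], end[i])
    if (ord$strand[i] < 0L) loc <- sprintf("complement(%s)", loc)
    nm <- ord$name[i]; cat_i <- ord$category[i]
    hdr <- function(key) sprintf("     %-16s%s", key, loc)
    feat_lines <- c(feat_lines, switch(
      cat_i,
      tRNA = c(hdr("tRNA"), wrap_qualifier(sprintf('/product="%s"', full(nm)))),
      rRNA = c(hdr("rRNA"), wrap_qualifier(sprintf('/product="%s"', full(nm)))),
      PCG = c(hdr("CDS"), wrap_qualifier(sprintf('/gene="%s"', nm)),
              wrap_qualifier(sprintf('/product="%s"', full(nm)))),
      CR = c(hdr("D-loop"), wrap_qualifier('/note="control region"')),
      OL = c(hdr("rep_origin"), wrap_qualifier('/note="origin of L-strand replication"')),
      NC = c(hdr("misc_feature"), wrap_qualifier('/note="non-coding region"')),
      pseudo = c(hdr("misc_feature"),
                 wrap_qualifier(sprintf('/gene="%s"', full(nm))),
                 wrap_qualifier(sprintf('/note="%s pseudogene"', full(nm))))
    ))
  }

  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular     UNA",
            record$taxon_id, as.integer(glen)),
    sprintf("DEFINITION  %s mitochondrion, complete genome (synthetic).",
            record$species),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", sprintf("1..%d", as.integer(glen))),
    wrap_qualifier(sprintf('/organism="%s"', record$species)),
    feat_lines
  )
  if (emit_sequence) {
    seq <- paste(sample_nucleotides(make_rng(seed), as.integer(glen)),
                 collapse = "")
    blocks <- substring(seq, seq(1, nchar(seq), 60), pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
    origin <- sprintf("%9d %s", seq(1, nchar(seq), 60),
                      vapply(blocks, function(b) {
                        paste(substring(b, seq(1, nchar(b), 10),
                                        pmin(seq(10, nchar(b) + 9, 10), nchar(b))),
                              collapse = " ")
                      }, ""))
    lines <- c(lines, "ORIGIN", origin)
  }
  lines <- c(lines, "//")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# local RNG helpers: keep generator output independent of the caller's
# .Random.seed
make_rng <- function(seed) {
  env <- new.env()
  env$state <- seed
  env
}

sample_nucleotides <- function(rng, n) {
  # linear congruential stream, deterministic per seed, no global state
  out <- character(n)
  s <- as.double(rng$state %% 2147483647L)
  if (s <= 0) s <- s + 2147483646
  bases <- c("a", "c", "g", "t")
  for (i in seq_len(n)) {
    s <- (s * 16807) %% 2147483647
    out[i] <- bases[(floor(s) %% 4) + 1]
  }
  rng$state <- s
  out
}
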