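#' Standard vertebrate mitochondrial gene vocabulary
#'
#' The closed symbol vocabulary used throughout the package: the 22 tRNA
#' genes (single-letter amino-acid codes, with the two leucine and two
#' serine isoacceptors disambiguated as `L1` = Leu(CUN), `L2` = Leu(UUR),
#' `S1` = Ser(AGY), `S2` = Ser(UCN)), the two rRNA genes (`12S`, `16S`),
#' the 13 protein-coding genes, the control region `CR`, the light-strand
#' replication origin `OL`, and `NC` for an unassigned non-coding block.
#' Pseudogene tokens are written with a trailing `*` (e.g. `P*` for the
#' degenerate tRNA-Pro copy found next to duplicated control regions) and
#' never compare equal to their functional counterpart.
#'
#' @format A tibble with columns `name`, `category`
#'   (tRNA/rRNA/PCG/CR/OL/NC) and `full_name`.
#' @export
mt_vocabulary <- function() {
  trna <- tibble::tibble(
    name = c("F", "V", "L2", "I", "Q", "M", "W", "A", "N", "C", "Y",
             "S2", "D", "K", "G", "R", "H", "S1", "L1", "E", "T", "P"),
    category = "tRNA",
    full_name = c("tRNA-Phe", "tRNA-Val", "tRNA-Leu(UUR)", "tRNA-Ile",
                  "tRNA-Gln", "tRNA-Met", "tRNA-Trp", "tRNA-Ala",
                  "tRNA-Asn", "tRNA-Cys", "tRNA-Tyr", "tRNA-Ser(UCN)",
                  "tRNA-Asp", "tRNA-Lys", "tRNA-Gly", "tRNA-Arg",
                  "tRNA-His", "tRNA-Ser(AGY)", "tRNA-Leu(CUN)",
                  "tRNA-Glu", "tRNA-Thr", "tRNA-Pro")
  )
  rrna <- tibble::tibble(
    name = c("12S", "16S"), category = "rRNA",
    full_name = c("12S ribosomal RNA", "16S ribosomal RNA")
  )
  pcg <- tibble::tibble(
    name = c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
             "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB"),
    category = "PCG",
    full_name = c("NADH dehydrogenase subunit 1", "NADH dehydrogenase subunit 2",
                  "cytochrome c oxidase subunit I", "cytochrome c oxidase subunit II",
                  "ATP synthase F0 subunit 8", "ATP synthase F0 subunit 6",
                  "cytochrome c oxidase subunit III", "NADH dehydrogenase subunit 3",
                  "NADH dehydrogenase subunit 4L", "NADH dehydrogenase subunit 4",
                  "NADH dehydrogenase subunit 5", "NADH dehydrogenase subunit 6",
                  "cytochrome b")
  )
  other <- tibble::tibble(
    name = c("CR", "OL", "NC"), category = c("CR", "OL", "NC"),
    full_name = c("control region", "origin of L-strand replication",
                  "non-coding region")
  )
  dplyr::bind_rows(trna, rrna, pcg, other)
}

# cached lookup, built once at load
.vocab_env <- new.env(parent = emptyenv())

vocab_table <- function() {
  if (is.null(.vocab_env$tab)) .vocab_env$tab <- mt_vocabulary()
  .vocab_env$tab
}

#' Category of a standardized gene symbol
#'
#' Pseudogene symbols (trailing `*`) have category `"pseudo"`; unknown
#' symbols raise an error.
#'
#' @param name character vector of symbols, e.g. `c("F", "P*", "ND4")`.
#' @return character vector of categories.
#' @export
token_category <- function(name) {
  tab <- vocab_table()
  base <- sub("\\*$", "", name)
  is_pseudo <- endsWith(name, "*")
  idx <- match(base, tab$name)
  if (anyNA(idx)) {
    stop("unknown gene symbol(s): ", paste(unique(name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  ifelse(is_pseudo, "pseudo", tab$category[idx])
}

#' Default H/L strand of a symbol in the typical vertebrate arrangement
#'
#' Genes encoded on the light strand in the typical vertebrate mitogenome
#' (Q, A, N, C, Y, S2, E, P and ND6) default to strand `-1`; everything
#' else to `+1`. Pseudo tokens inherit the strand of their base gene.
#'
#' @param name character vector of symbols.
#' @return integer vector of +1/-1.
#' @export
default_strand <- function(name) {
  l_strand <- c("Q", "A", "N", "C", "Y", "S2", "E", "P", "ND6")
  base <- sub("\\*$", "", name)
  ifelse(base %in% l_strand, -1L, 1L)
}

# Typical feature lengths (bp) used by the record generator when no
# override is supplied. tRNAs are short in snakes; values are round
# figures of typical vertebrate gene sizes, not measurements.
default_length_table <- function() {
  c(F = 67L, V = 67L, L2 = 74L, I = 69L, Q = 70L, M = 69L, W = 70L,
    A = 67L, N = 72L, C = 65L, Y = 67L, S2 = 71L, D = 68L, K = 72L,
    G = 68L, R = 66L, H = 68L, S1 = 62L, L1 = 71L, E = 67L, T = 69L,
    P = 68L,
    `12S` = 935L, `16S` = 1505L,
    ND1 = 963L, ND2 = 1035L, COX1 = 1545L, COX2 = 684L, ATP8 = 165L,
    ATP6 = 681L, COX3 = 784L, ND3 = 345L, ND4L = 294L, ND4 = 1377L,
    ND5 = 1785L, ND6 = 510L, CYTB = 1110L,
    CR = 1100L, OL = 32L, NC = 100L)
}

default_token_length <- function(name) {
  tab <- default_length_table()
  base <- sub("\\*$", "", name)
  out <- unname(tab[base])
  # pseudogenes are truncated remnants of their source gene
  out[endsWith(name, "*")] <- 45L
  out[is.na(out)] <- 100L
  as.integer(out)
}
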