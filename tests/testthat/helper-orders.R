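# shared fixtures, built once per test run
.cache <- new.env(parent = emptyenv())

test_registry <- function() {
  if (is.null(.cache$registry)) .cache$registry <- arrangement_registry()
  .cache$registry
}

test_fixture <- function() {
  if (is.null(.cache$fixture)) {
    .cache$fixture <- build_fixture_set(seed = 1, registry = test_registry())
  }
  .cache$fixture
}

type_order <- function(label) {
  reg <- test_registry()
  reg$order[[match(label, reg$label)]]
}

# a random valid circular order: a shuffled subset of the canonical
# tokens (anchors retained)
random_order <- function() {
  can <- canonical_reference_order()
  keep <- sort(unique(c(1:4, sample(nrow(can), sample(10:nrow(can), 1)))))
  idx <- sample(keep)
  out <- can[idx, ]
  class(out) <- class(can)
  out
}

rotate_any <- function(order) {
  n <- nrow(order)
  k <- sample(n, 1)
  out <- order[((seq_len(n) + k - 1) %% n) + 1, ]
  class(out) <- class(order)
  out
}

# a random unrooted-shape rooted binary tree with random tip states
random_tree_states <- function(n_tips = 8, n_states = 3) {
  tr <- ape::rtree(n_tips)
  tr$edge.length <- NULL
  states <- stats::setNames(
    sample(LETTERS[seq_len(n_states)], n_tips, replace = TRUE), tr$tip.label)
  list(tree = tr, states = states)
}

# name pairs adjacent exactly once in the circular order
unique_junctions <- function(order) {
  n <- nrow(order)
  prev <- order$name
  nxt <- order$name[c(2:n, 1)]
  pair <- paste(prev, nxt)
  keep <- pair %in% names(which(table(pair) == 1))
  tibble::tibble(i = seq_len(n)[keep], prev = prev[keep], next_ = nxt[keep])
}

# draw a random applicable single event on an order, constrained so the
# event is unambiguously recoverable (destination flanks disjoint from
# the source neighborhood, unique junctions)
random_event <- function(order) {
  n <- nrow(order)
  singles <- names(which(table(order$name) == 1))
  trna_singles <- intersect(singles, order$name[order$category == "tRNA"])
  kinds <- c("LOSS", "DUPLICATION", "PSEUDOGENIZATION", "INSERTION", "TRANSLOCATION")
  for (kind in sample(kinds, length(kinds))) {
    if (kind == "LOSS" && length(trna_singles)) {
      subj <- sample(trna_singles, 1)
      i <- which(order$name == subj)
      nb <- c(order$name[if (i == 1) n else i - 1], order$name[if (i == n) 1 else i + 1])
      return(event_annotation("LOSS", subj, from = nb))
    }
    jx <- unique_junctions(order)
    if (kind %in% c("DUPLICATION", "PSEUDOGENIZATION", "INSERTION", "TRANSLOCATION") &&
        nrow(jx) > 0) {
      if (kind == "DUPLICATION" && length(trna_singles)) {
        subj <- sample(trna_singles, 1)
        i <- which(order$name == subj)
        far <- jx[abs(jx$i - i) > 2 & abs(jx$i - i) < n - 2 &
                    jx$prev != subj & jx$next_ != subj, ]
        if (nrow(far)) {
          j <- far[sample(nrow(far), 1), ]
          return(event_annotation("DUPLICATION", subj, to = c(j$prev, j$next_)))
        }
      }
      if (kind == "PSEUDOGENIZATION") {
        cand <- setdiff(c("P", "I", "T", "N"), sub("\\*$", "", order$name[order$category == "pseudo"]))
        if (length(cand)) {
          subj <- paste0(sample(cand, 1), "*")
          jx2 <- jx[jx$prev != subj & jx$next_ != subj, ]
          if (nrow(jx2)) {
            j <- jx2[sample(nrow(jx2), 1), ]
            return(event_annotation("PSEUDOGENIZATION", subj, to = c(j$prev, j$next_)))
          }
        }
      }
      if (kind == "INSERTION") {
        jx2 <- jx[jx$prev != "NC" & jx$next_ != "NC", ]
        if (nrow(jx2)) {
          j <- jx2[sample(nrow(jx2), 1), ]
          return(event_annotation("INSERTION", "NC", to = c(j$prev, j$next_),
                                  length_bp = sample(300:900, 1)))
        }
      }
      if (kind == "TRANSLOCATION" && length(trna_singles)) {
        subj <- sample(trna_singles, 1)
        i <- which(order$name == subj)
        nbn <- order$name[c(if (i == 1) n else i - 1, if (i == n) 1 else i + 1)]
        far <- jx[abs(jx$i - i) > 2 & abs(jx$i - i) < n - 2 &
                    !jx$prev %in% c(subj, nbn) & !jx$next_ %in% c(subj, nbn), ]
        if (nrow(far)) {
          j <- far[sample(nrow(far), 1), ]
          return(event_annotation("TRANSLOCATION", subj, from = nbn,
                                  to = c(j$prev, j$next_)))
        }
      }
    }
  }
  NULL
}
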