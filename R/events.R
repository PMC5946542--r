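EVENT_KINDS <- c("LOSS", "INSERTION", "PSEUDOGENIZATION", "DUPLICATION",
                 "TRANSLOCATION", "CR_ASYMMETRY")

#' Construct a rearrangement event annotation
#'
#' @param kind one of LOSS, INSERTION, PSEUDOGENIZATION, DUPLICATION,
#'   TRANSLOCATION, CR_ASYMMETRY.
#' @param subject gene/token name the event concerns.
#' @param from,to neighbor pairs (character length 2) giving the source
#'   and destination context; TRANSLOCATION requires both, LOSS requires
#'   `from` only, INSERTION/DUPLICATION/PSEUDOGENIZATION require `to`.
#' @param length_bp optional length for inserted NC tokens.
#' @return a one-row tibble.
#' @export
event_annotation <- function(kind, subject, from = NULL, to = NULL,
                             length_bp = NA_integer_) {
  kind <- match.arg(kind, EVENT_KINDS)
  if (kind == "TRANSLOCATION" && (is.null(from) || is.null(to))) {
    stop("TRANSLOCATION requires both from and to contexts", call. = FALSE)
  }
  if (kind == "LOSS" && is.null(from)) {
    stop("LOSS requires a from context", call. = FALSE)
  }
  if (kind %in% c("INSERTION", "PSEUDOGENIZATION", "DUPLICATION") && is.null(to)) {
    stop(kind, " requires a to context", call. = FALSE)
  }
  tibble::tibble(
    kind = kind, subject = subject,
    from_prev = if (is.null(from)) NA_character_ else from[1],
    from_next = if (is.null(from)) NA_character_ else from[2],
    to_prev = if (is.null(to)) NA_character_ else to[1],
    to_next = if (is.null(to)) NA_character_ else to[2],
    length_bp = as.integer(length_bp)
  )
}

empty_events <- function() {
  tibble::tibble(kind = character(), subject = character(),
                 from_prev = character(), from_next = character(),
                 to_prev = character(), to_next = character(),
                 length_bp = integer())
}

# occurrences of an identity in an order, with neighbor names
occ_contexts <- function(order, id) {
  ids <- token_id(order)
  pos <- which(ids == id)
  lapply(pos, function(i) {
    nb <- circular_neighbors(nrow(order), i)
    list(pos = i, prev = order$name[nb[1]], next_ = order$name[nb[2]])
  })
}

cr_ratio <- function(order) {
  lens <- order$length_bp[order$category == "CR"]
  if (length(lens) < 2L || anyNA(lens)) return(NA_real_)
  max(lens) / min(lens)
}

#' Infer the rearrangement event path between two arrangements
#'
#' Deterministic decomposition of the difference between a parent and a
#' child gene order into atomic events: (1) token multiset difference —
#' tokens present only in the parent become LOSS events; tokens present
#' only in the child become INSERTION (non-coding), PSEUDOGENIZATION
#' (pseudo token) or DUPLICATION (second copy of a functional gene or
#' control region) events; (2) on the shared single-copy tokens, a
#' neighbor comparison (as in [detect_translocations()]) yields
#' TRANSLOCATION events; (3) a control-region length ratio crossing the
#' asymmetry threshold yields a CR_ASYMMETRY event. Events are emitted
#' in that category order, alphabetically by subject within a category.
#'
#' @param parent,child `mt_order` objects.
#' @param asymmetry_ratio CR length-ratio threshold (default 1.2).
#' @return a tibble of events ([event_annotation()] rows).
#' @export
infer_event_path <- function(parent, child, asymmetry_ratio = 1.2) {
  if (is.null(parent) || is.null(child) || nrow(parent) == 0L || nrow(child) == 0L) {
    stop("both orders must be non-empty", call. = FALSE)
  }
  idp <- token_id(parent); idc <- token_id(child)
  cp <- table(idp); cc <- table(idc)
  all_ids <- union(names(cp), names(cc))
  np <- ifelse(is.na(cp[all_ids]), 0L, cp[all_ids])
  nc <- ifelse(is.na(cc[all_ids]), 0L, cc[all_ids])
  names(np) <- names(nc) <- all_ids

  events <- empty_events()

  # losses: occurrences in parent beyond the child's count
  for (id in sort(all_ids[np > nc])) {
    ctxs <- occ_contexts(parent, id)
    # report the parent occurrences that have no positional match in the
    # child (for full loss, all of them)
    n_lost <- np[id] - nc[id]
    for (k in seq_len(n_lost)) {
      ctx <- ctxs[[k]]
      events <- dplyr::bind_rows(events, event_annotation(
        "LOSS", strip_strand(id), from = c(ctx$prev, ctx$next_)))
    }
  }

  # gains, classified by token category
  gained <- all_ids[nc > np]
  if (length(gained)) {
    subj <- strip_strand(gained)
    cat_g <- token_category(subj)
    kind_of <- ifelse(cat_g == "NC", "INSERTION",
                      ifelse(cat_g == "pseudo", "PSEUDOGENIZATION", "DUPLICATION"))
    for (kind in c("INSERTION", "PSEUDOGENIZATION", "DUPLICATION")) {
      for (j in order(subj)[kind_of[order(subj)] == kind]) {
        id <- gained[j]
        ctxs <- occ_contexts(child, id)
        if (np[id] > 0L) {
          # pick the new occurrence(s): those whose neighborhood does not
          # match any parent occurrence of the same identity
          pctx <- occ_contexts(parent, id)
          pkeys <- vapply(pctx, function(x) paste(x$prev, x$next_), "")
          is_new <- vapply(ctxs, function(x) !paste(x$prev, x$next_) %in% pkeys, TRUE)
          if (any(is_new)) ctxs <- ctxs[is_new]
        }
        n_new <- nc[id] - np[id]
        for (k in seq_len(min(n_new, length(ctxs)))) {
          ctx <- ctxs[[k]]
          len <- child$length_bp[ctx$pos]
          events <- dplyr::bind_rows(events, event_annotation(
            kind, subj[j], to = c(ctx$prev, ctx$next_), length_bp = len))
        }
      }
    }
  }

  # translocations on shared single-copy tokens
  tr <- detect_translocations(child, parent)
  if (nrow(tr)) {
    for (i in order(tr$gene)) {
      events <- dplyr::bind_rows(events, event_annotation(
        "TRANSLOCATION", tr$gene[i],
        from = c(tr$ref_prev[i], tr$ref_next[i]),
        to = c(tr$obs_prev[i], tr$obs_next[i])))
    }
  }

  # control-region asymmetry appearing across the threshold
  rp <- cr_ratio(parent); rc <- cr_ratio(child)
  if (!is.na(rc) && rc > asymmetry_ratio && (is.na(rp) || rp <= asymmetry_ratio)) {
    events <- dplyr::bind_rows(events, tibble::tibble(
      kind = "CR_ASYMMETRY", subject = "CR",
      from_prev = NA_character_, from_next = NA_character_,
      to_prev = NA_character_, to_next = NA_character_,
      length_bp = NA_integer_))
  }

  events$kind <- factor(events$kind, levels = EVENT_KINDS)
  events <- dplyr::arrange(events, .data$kind, .data$subject)
  events$kind <- as.character(events$kind)
  events
}

#' Build the arrangement derivation graph from a reconstructed tree
#'
#' Runs Fitch parsimony with the indeterminate ancestral state at the
#' root, resolves ancestral arrangement types, and collects every
#' distinct (parent type, child type) transition on the resolved tree
#' as a directed edge. Edges out of the indeterminate root state are
#' annotated with the child type's stored diagnostic events; edges
#' between concrete types are annotated by [infer_event_path()] on the
#' registry reference orders. The result must be acyclic.
#'
#' @param registry an arrangement registry.
#' @param tree a rooted `phylo` tree.
#' @param tip_types tibble with `taxon_id`, `type` (or a named character
#'   vector).
#' @param resolution `"deltran"` (default) or `"acctran"`.
#' @param asymmetry_ratio CR asymmetry threshold used in event paths.
#' @return an object of class `derivation_graph`: a list with `nodes`
#'   (character), `edges` (tibble `from`, `to`, `n_transitions`,
#'   `events` list-column) and the resolved reconstruction.
#' @export
derivation_graph <- function(registry, tree, tip_types,
                             resolution = c("deltran", "acctran"),
                             asymmetry_ratio = 1.2) {
  resolution <- match.arg(resolution)
  states <- as_charmap(tip_types)
  if (length(unique(unname(states))) == 1L) {
    # a single observed arrangement carries no transition evidence;
    # return the one-node graph rather than an uninformative edge out
    # of the indeterminate root
    return(structure(list(nodes = unique(unname(states)),
                          edges = dplyr::mutate(
                            tibble::tibble(from = character(), to = character(),
                                           n_transitions = integer()),
                            events = list()),
                          reconstruction = NULL),
                     class = "derivation_graph"))
  }
  fit <- fitch_reconstruct(tree, states, root_state = "UNKNOWN")
  res <- resolve_states(fit, mode = resolution)

  tr <- transitions(res)
  edges <- dplyr::summarise(dplyr::group_by(tr, .data$from, .data$to),
                            n_transitions = dplyr::n(), .groups = "drop")

  ev <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    to_row <- registry[registry$label == edges$to[i], ]
    if (edges$from[i] == "UNKNOWN") {
      ev[[i]] <- if (nrow(to_row)) to_row$events[[1]] else empty_events()
    } else {
      from_row <- registry[registry$label == edges$from[i], ]
      ev[[i]] <- if (nrow(to_row) && nrow(from_row)) {
        infer_event_path(from_row$order[[1]], to_row$order[[1]], asymmetry_ratio)
      } else {
        empty_events()
      }
    }
  }
  edges$events <- ev
  nodes <- union("UNKNOWN", sort(unique(c(states, edges$from, edges$to))))

  assert_dag(nodes, edges)
  structure(list(nodes = nodes, edges = edges, reconstruction = res),
            class = "derivation_graph")
}

assert_dag <- function(nodes, edges) {
  remaining <- nodes
  adj <- split(edges$to, edges$from)
  repeat {
    indeg <- table(factor(unlist(adj[remaining], use.names = FALSE), levels = remaining))
    leaves <- remaining[indeg[remaining] == 0L]
    if (length(leaves) == 0L) break
    remaining <- setdiff(remaining, leaves)
    adj <- lapply(adj, setdiff, y = leaves)
  }
  if (length(remaining)) {
    stop("derivation graph contains a cycle among: ",
         paste(remaining, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Types descending from a given type in a derivation graph
#'
#' @param graph a `derivation_graph`.
#' @param label starting type label.
#' @return character vector of labels reachable from `label` (directly
#'   or indirectly), excluding `label` itself.
#' @export
descendant_types <- function(graph, label) {
  adj <- split(graph$edges$to, graph$edges$from)
  seen <- character()
  frontier <- label
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), c(seen, label))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' @export
print.derivation_graph <- function(x, ...) {
  cat("<derivation_graph>", length(x$nodes), "types,", nrow(x$edges), "transitions\n")
  for (i in seq_len(nrow(x$edges))) {
    ev <- x$edges$events[[i]]
    cat(sprintf("  %s -> %s  [%s]\n", x$edges$from[i], x$edges$to[i],
                paste(paste(ev$kind, ev$subject), collapse = "; ")))
  }
  invisible(x)
}

#' Export a derivation graph as DOT or JSON
#'
#' @param graph a `derivation_graph`.
#' @param path output path; format chosen by extension (`.dot`/`.gv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_derivation_graph <- function(graph, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(nodes = graph$nodes,
           edges = dplyr::select(graph$edges, "from", "to", "n_transitions")),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    lab <- function(ev) paste(paste(ev$kind, ev$subject), collapse = "\\n")
    lines <- c(
      "digraph arrangements {",
      "  rankdir=TB;",
      sprintf('  "%s";', graph$nodes),
      sprintf('  "%s" -> "%s" [label="%s"];',
              graph$edges$from, graph$edges$to,
              vapply(graph$edges$events, lab, "")),
      "}")
    writeLines(lines, path)
  }
  invisible(path)
}
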