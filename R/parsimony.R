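as_charmap <- function(x) {
  if (is.character(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    cols <- intersect(c("taxon_id", "tip", "label"), names(x))
    state_col <- intersect(c("state", "type"), names(x))
    if (length(cols) && length(state_col)) {
      return(stats::setNames(as.character(x[[state_col[1]]]),
                             as.character(x[[cols[1]]])))
    }
  }
  stop("tip states must be a named character vector or a tibble with ",
       "taxon_id and state/type columns", call. = FALSE)
}

tree_children <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

postorder_nodes <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1])
}

#' Fitch parsimony reconstruction of an unordered character
#'
#' Bottom-up Fitch state sets for a rooted tree (multifurcations are
#' handled by iterated pairwise intersection over the children in their
#' newick order, a documented deterministic generalization). The change
#' count equals the number of empty-intersection events, which is the
#' exact parsimony score on binary trees. When `root_state` is supplied
#' the root is constrained to that state and one extra change is charged
#' if the bottom-up root set does not contain it — this is how
#' outgroup knowledge (e.g. OL presence in lizards) or a deliberately
#' indeterminate ancestral arrangement enters the reconstruction.
#'
#' @param tree a rooted `phylo` object.
#' @param states tip states: named character vector (names = tip
#'   labels) or a tibble with `taxon_id` and `state`/`type` columns.
#' @param root_state optional state to force at the root.
#' @return an object of class `fitch_fit`: list with `tree`, `states`,
#'   `sets` (per-node state sets), `score`, `root_state`.
#' @export
fitch_reconstruct <- function(tree, states, root_state = NULL) {
  states <- as_charmap(states)
  ntip <- ape::Ntip(tree)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing)) {
    stop("unlabeled tip(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(states), tree$tip.label)
  if (length(extra)) {
    stop("state(s) for unknown tip(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  n_all <- ntip + tree$Nnode
  sets <- vector("list", n_all)
  for (i in seq_len(ntip)) sets[[i]] <- unname(states[tree$tip.label[i]])

  kids <- tree_children(tree)
  score <- 0L
  for (nd in postorder_nodes(tree)) {
    s <- sets[[kids[[nd]][1]]]
    for (ch in kids[[nd]][-1]) {
      inter <- intersect(s, sets[[ch]])
      if (length(inter) == 0L) {
        s <- sort(union(s, sets[[ch]]))
        score <- score + 1L
      } else {
        s <- inter
      }
    }
    sets[[nd]] <- s
  }
  root <- ntip + 1L
  if (!is.null(root_state) && !root_state %in% sets[[root]]) score <- score + 1L
  structure(list(tree = tree, states = states, sets = sets,
                 score = score, root_state = root_state),
            class = "fitch_fit")
}

#' @export
print.fitch_fit <- function(x, ...) {
  cat("<fitch_fit>", ape::Ntip(x$tree), "tips, score", x$score, "\n")
  invisible(x)
}

#' Resolve ambiguous ancestral states
#'
#' Top-down resolution of the Fitch state sets to one state per node.
#' Under `"deltran"` (the default) each node keeps its parent's state
#' whenever the parent's state is in its own set, delaying
#' transformations toward the tips — the reading under which repeated
#' derived arrangements are scored as parallel gains. Under
#' `"acctran"` a node with an ambiguous set prefers a state different
#' from its parent, accelerating transformations toward the root. Where
#' the parent carries the indeterminate placeholder state (outside the
#' tip alphabet) and the node's set is still ambiguous, the placeholder
#' is propagated: the ancestral condition remains indeterminate rather
#' than being forced to an arbitrary alphabet member.
#'
#' @param fit a `fitch_fit`.
#' @param mode `"deltran"` or `"acctran"`.
#' @return an object of class `fitch_resolved`: list with `tree`,
#'   `node_state` (character, one per node), `score`, `mode`.
#' @export
resolve_states <- function(fit, mode = c("deltran", "acctran")) {
  mode <- match.arg(mode)
  tree <- fit$tree
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  n_all <- ntip + tree$Nnode
  alphabet <- sort(unique(unname(fit$states)))
  st <- character(n_all)

  st[root] <- if (!is.null(fit$root_state)) {
    fit$root_state
  } else {
    sort(fit$sets[[root]])[1]
  }

  pre <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(pre$edge))) {
    p <- pre$edge[i, 1]; ch <- pre$edge[i, 2]
    set <- fit$sets[[ch]]
    parent_state <- st[p]
    st[ch] <- if (parent_state %in% set) {
      if (mode == "acctran" && length(set) > 1L) {
        # accelerate: take a non-parental member where the set allows
        sort(setdiff(set, parent_state))[1]
      } else {
        parent_state
      }
    } else if (!parent_state %in% alphabet && length(set) > 1L) {
      parent_state  # indeterminate ancestor persists through ambiguity
    } else {
      sort(set)[1]
    }
  }
  structure(list(tree = tree, node_state = st, score = fit$score, mode = mode),
            class = "fitch_resolved")
}

#' @export
print.fitch_resolved <- function(x, ...) {
  cat("<fitch_resolved>", x$mode, "resolution;",
      nrow(transitions(x)), "state-changing edges\n")
  invisible(x)
}

#' State transitions on a resolved tree
#'
#' @param resolved a `fitch_resolved`.
#' @return a tibble with one row per state-changing edge: `parent`,
#'   `child` (node indices), `from`, `to`.
#' @export
transitions <- function(resolved) {
  e <- resolved$tree$edge
  from <- resolved$node_state[e[, 1]]
  to <- resolved$node_state[e[, 2]]
  keep <- from != to
  tibble::tibble(parent = e[keep, 1], child = e[keep, 2],
                 from = from[keep], to = to[keep])
}

#' Count independent origins / losses of a state
#'
#' On the resolved tree, an origin of `state` is an edge whose parent is
#' in another state and whose child is in `state`; a loss is the
#' reverse. With DELTRAN resolution of a binary presence character the
#' origin count equals the number of maximal presence subtrees.
#'
#' @param resolved a `fitch_resolved` (or a `fitch_fit`, which is then
#'   resolved with DELTRAN defaults).
#' @param state the state whose origins/losses are counted.
#' @return an integer count.
#' @export
count_origins <- function(resolved, state) {
  if (inherits(resolved, "fitch_fit")) resolved <- resolve_states(resolved)
  tr <- transitions(resolved)
  sum(tr$to == state)
}

#' @rdname count_origins
#' @export
count_losses <- function(resolved, state) {
  if (inherits(resolved, "fitch_fit")) resolved <- resolve_states(resolved)
  tr <- transitions(resolved)
  sum(tr$from == state)
}

#' Exact parsimony by exhaustive enumeration (testing oracle)
#'
#' Enumerates every assignment of states to internal nodes of a small
#' rooted tree and returns the exact minimum change count together with
#' all optimal labelings. Intended as an independent oracle for
#' [fitch_reconstruct()] and for bounding origin counts over the set of
#' optimal reconstructions; refuses trees beyond `max_tips`.
#'
#' @param tree a rooted `phylo` with at most `max_tips` tips.
#' @param states tip states (named vector or tibble).
#' @param root_state optional forced root state.
#' @param max_tips refusal threshold (default 12).
#' @return list with `score`, `labelings` (matrix, one row per optimal
#'   labeling, columns = internal nodes), `origin_range` (function of a
#'   state returning min/max origins over optimal labelings).
#' @export
brute_force_parsimony <- function(tree, states, root_state = NULL, max_tips = 12L) {
  states <- as_charmap(states)
  ntip <- ape::Ntip(tree)
  if (ntip > max_tips) {
    stop("tree too large for exhaustive enumeration (", ntip, " tips)", call. = FALSE)
  }
  alphabet <- sort(unique(c(unname(states), root_state)))
  nnode <- tree$Nnode
  root <- ntip + 1L
  e <- tree$edge
  tip_state <- stats::setNames(unname(states[tree$tip.label]), seq_len(ntip))

  n_assign <- length(alphabet)^nnode
  if (n_assign > 2e6) stop("state space too large for enumeration", call. = FALSE)

  grid <- rep(list(alphabet), nnode)
  assigns <- as.matrix(expand.grid(grid, stringsAsFactors = FALSE))
  colnames(assigns) <- as.character(root:(ntip + nnode))
  if (!is.null(root_state)) {
    assigns <- assigns[assigns[, 1] == root_state, , drop = FALSE]
  }

  node_state <- function(lab, idx) {
    out <- character(length(idx))
    tip <- idx <= ntip
    out[tip] <- tip_state[as.character(idx[tip])]
    out[!tip] <- lab[idx[!tip] - ntip]
    out
  }
  costs <- apply(assigns, 1L, function(lab) {
    sum(node_state(lab, e[, 1]) != node_state(lab, e[, 2]))
  })
  best <- min(costs)
  opt <- assigns[costs == best, , drop = FALSE]

  origin_range <- function(state) {
    counts <- apply(opt, 1L, function(lab) {
      sum(node_state(lab, e[, 1]) != state & node_state(lab, e[, 2]) == state)
    })
    c(min = min(counts), max = max(counts))
  }
  list(score = best, labelings = opt, origin_range = origin_range)
}

#' Read a rooted tree in newick format
#'
#' Thin wrapper over [ape::read.tree()] that validates rootedness and
#' unique tip labels.
#'
#' @param path newick file path.
#' @return a `phylo` object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels in tree", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  tree
}
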