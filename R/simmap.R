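#' Regime-painted phylogenies (stochastic-map trees)
#'
#' A `simmap` object is an [ape::read.tree()]-style `phylo` tree whose every
#' branch carries an ordered sequence of regime segments, as produced by
#' stochastic character mapping or by forward simulation of a discrete
#' character. The representation follows the convention popularised by the
#' `phytools` package: `$maps` is a list (one element per row of `$edge`) of
#' named numeric vectors, names being regime labels and values segment
#' durations ordered from the parent (rootward) end of the branch; segment
#' durations on each branch sum to the branch length.
#'
#' @param tree a `phylo` object.
#' @param maps list of named numeric vectors, one per edge (rows of
#'   `tree$edge`), rootward segment first.
#' @param node_states character vector of length `Ntip + Nnode` giving the
#'   state at every node (tips first, in `tip.label` order).
#' @return an object of class `c("simmap", "phylo")`.
#' @seealso [sample_stochastic_map()], [simulate_mk()], [paint_constant()]
#' @export
as_simmap <- function(tree, maps, node_states) {
  if (!inherits(tree, "phylo")) stopf("'tree' must be a 'phylo' object")
  ne <- nrow(tree$edge)
  if (length(maps) != ne) stopf("'maps' must have one element per edge")
  for (i in seq_len(ne)) {
    m <- maps[[i]]
    if (is.null(names(m)) || any(m < 0))
      stopf("edge %d: segments must be named, non-negative durations", i)
    if (abs(sum(m) - tree$edge.length[i]) > 1e-9 * max(1, tree$edge.length[i]))
      stopf("edge %d: segment durations do not sum to the branch length", i)
  }
  nn <- length(tree$tip.label) + tree$Nnode
  if (length(node_states) != nn)
    stopf("'node_states' must have length Ntip + Nnode (%d)", nn)
  tree$maps <- maps
  tree$node.states <- as.character(node_states)
  tree$states <- stats::setNames(node_states[seq_along(tree$tip.label)],
                                 tree$tip.label)
  class(tree) <- c("simmap", class(tree)[class(tree) != "simmap"])
  tree
}

#' Paint an entire tree with a single regime
#'
#' Convenience constructor for the single-regime case (e.g. BM1/OU1 fits):
#' every branch becomes one segment in state `state`.
#'
#' @param tree a `phylo` object.
#' @param state regime label (default `"global"`).
#' @return a [as_simmap()] object with one regime.
#' @export
paint_constant <- function(tree, state = "global") {
  maps <- lapply(tree$edge.length, function(l) stats::setNames(l, state))
  nn <- length(tree$tip.label) + tree$Nnode
  as_simmap(tree, maps, rep(state, nn))
}

#' @export
print.simmap <- function(x, ...) {
  st <- simmap_states(x)
  cat(sprintf("Regime-painted phylogeny: %d tips, %d regime state(s): %s\n",
              length(x$tip.label), length(st), paste(st, collapse = ", ")))
  cat(sprintf("Total mapped time: %.4f; transitions: %d\n",
              sum(unlist(x$maps)), simmap_n_transitions(x)))
  invisible(x)
}

#' Regime states present on a painted tree
#' @param x a `simmap` object.
#' @return sorted character vector of regime labels.
#' @export
simmap_states <- function(x) sort(unique(names(unlist(x$maps))))

# Number of regime transitions painted on the tree.
simmap_n_transitions <- function(x) {
  sum(vapply(x$maps, function(m) length(m) - 1L, integer(1)))
}

#' Per-edge time spent in each regime
#' @param x a `simmap` object.
#' @return matrix (edges x states) of durations.
#' @export
mapped_edge <- function(x) {
  st <- simmap_states(x)
  out <- matrix(0, nrow(x$edge), length(st), dimnames = list(NULL, st))
  for (i in seq_along(x$maps)) {
    m <- x$maps[[i]]
    for (j in seq_along(m)) out[i, names(m)[j]] <- out[i, names(m)[j]] + m[j]
  }
  out
}

# State at the root node.
simmap_root_state <- function(x) x$node.states[length(x$tip.label) + 1L]

# For each tip, the ordered root-to-tip regime segments as a data.frame with
# columns regime, t0, t1 (absolute time from the root). Used by the Hansen
# OU mean construction.
simmap_tip_paths <- function(x) {
  ntip <- length(x$tip.label)
  nn <- ntip + x$Nnode
  ord <- reorder_edges_preorder(x)
  depth <- ape::node.depth.edgelength(x)
  segs <- vector("list", nn) # per-node list of (regime, t0, t1) rows
  segs[[ntip + 1L]] <- list(regime = character(0), t0 = numeric(0),
                            t1 = numeric(0))
  for (i in ord) {
    par <- x$edge[i, 1L]; ch <- x$edge[i, 2L]
    m <- x$maps[[i]]
    t0 <- depth[par] + c(0, cumsum(m))[seq_along(m)]
    t1 <- depth[par] + cumsum(m)
    p <- segs[[par]]
    segs[[ch]] <- list(regime = c(p$regime, names(m)),
                       t0 = c(p$t0, t0), t1 = c(p$t1, t1))
  }
  out <- lapply(seq_len(ntip), function(k) {
    s <- segs[[k]]
    data.frame(regime = s$regime, t0 = s$t0, t1 = s$t1,
               stringsAsFactors = FALSE)
  })
  names(out) <- x$tip.label
  out
}

# Edge indices in preorder (root -> tips).
reorder_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  rev(tr)
}

# Per-regime shared-path matrices S_r (tips x tips): S_r[i, j] is the time the
# shared root-to-MRCA(i, j) path spends in regime r; diagonal is the tip's own
# total time in r. Sum over regimes is the usual BM vcv matrix.
simmap_regime_vcv <- function(x) {
  ntip <- length(x$tip.label)
  st <- simmap_states(x)
  S <- lapply(st, function(s) matrix(0, ntip, ntip,
                                     dimnames = list(x$tip.label, x$tip.label)))
  names(S) <- st
  desc <- clade_tips(x)
  for (i in seq_along(x$maps)) {
    tips <- desc[[x$edge[i, 2L]]]
    m <- x$maps[[i]]
    for (j in seq_along(m)) {
      S[[names(m)[j]]][tips, tips] <- S[[names(m)[j]]][tips, tips] + m[j]
    }
  }
  S
}

# List (length Ntip+Nnode) of tip indices descending from each node.
clade_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  out <- vector("list", nn)
  for (k in seq_len(ntip)) out[[k]] <- k
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    out[[par]] <- c(out[[par]], out[[ch]])
  }
  out
}

#' Flatten a painted tree to a segment table
#'
#' @param x a `simmap` object.
#' @return data.frame with one row per branch segment: edge index, parent and
#'   child node ids, segment order along the branch (rootward first), regime
#'   and duration.
#' @export
simmap_segments <- function(x) {
  rows <- lapply(seq_along(x$maps), function(i) {
    m <- x$maps[[i]]
    data.frame(edge = i, parent = x$edge[i, 1L], child = x$edge[i, 2L],
               segment = seq_along(m), regime = names(m), duration = unname(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize painted trees in the extended-Newick regime annotation style
#'
#' Branch lengths are replaced by `{state,duration:state,duration}` blocks,
#' tipward segment first, matching the widely used stochastic-map text format.
#'
#' @param x a `simmap` object or list of them.
#' @param file optional path; when empty the string(s) are returned.
#' @return character vector of serialized trees, invisibly when writing.
#' @export
write_simmap <- function(x, file = "") {
  trees <- if (inherits(x, "simmap")) list(x) else x
  lines <- vapply(trees, simmap_newick_string, character(1))
  if (nzchar(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

simmap_newick_string <- function(x) {
  ntip <- length(x$tip.label)
  edge_of <- integer(ntip + x$Nnode)
  edge_of[x$edge[, 2L]] <- seq_len(nrow(x$edge))
  children <- split(x$edge[, 2L], x$edge[, 1L])
  map_str <- function(i) {
    m <- rev(x$maps[[i]]) # tipward segment first
    paste0("{", paste(sprintf("%s,%s", names(m), format(unname(m), digits = 12)),
                      collapse = ":"), "}")
  }
  rec <- function(node) {
    lab <- if (node <= ntip) x$tip.label[node] else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    }
    if (node == ntip + 1L) return(lab)
    paste0(lab, ":", map_str(edge_of[node]))
  }
  paste0(rec(ntip + 1L), ";")
}
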