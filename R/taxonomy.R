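#' Build a rooted taxonomy from child-parent edges
#'
#' @param edges Data.frame (or 2-column matrix) with columns `child`,
#'   `parent`. The edges must form a single rooted tree: exactly one node
#'   appears as a parent without being anyone's child, and no cycles.
#' @return A list of class `taxonomy` with `parent` (named character
#'   vector, `NA` for the root), `root`, `depth` (root = 0), and `nodes`.
#' @export
build_taxonomy <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent") %in% names(edges)))
  child <- as.character(edges$child)
  parent <- as.character(edges$parent)
  if (anyDuplicated(child)) {
    stop("a node has more than one parent: ",
         paste(unique(child[duplicated(child)]), collapse = ", "),
         call. = FALSE)
  }
  nodes <- union(child, parent)
  roots <- setdiff(parent, child)
  if (length(unique(roots)) != 1) {
    stop("taxonomy must have exactly one root; found: ",
         paste(unique(roots), collapse = ", "), call. = FALSE)
  }
  root <- unique(roots)
  pmap <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  pmap[child] <- parent

  depth <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  depth[root] <- 0
  for (nd in nodes) {
    if (!is.na(depth[nd])) next
    chain <- nd
    cur <- nd
    while (is.na(depth[cur])) {
      cur <- pmap[[cur]]
      if (is.na(cur)) stop("disconnected node: ", nd, call. = FALSE)
      if (cur %in% chain) {
        stop("cycle detected involving node: ", cur, call. = FALSE)
      }
      chain <- c(chain, cur)
    }
    d <- depth[cur]
    for (x in rev(chain[chain != cur])) {
      d <- d + 1
      depth[x] <- d
    }
  }
  structure(list(parent = pmap, root = root, depth = depth, nodes = nodes),
            class = "taxonomy")
}

#' Path from a node to the root
#'
#' @param taxonomy A `taxonomy`.
#' @param node Node identifier.
#' @return Character vector from `node` up to and including the root.
#' @export
path_to_root <- function(taxonomy, node) {
  stopifnot(node %in% taxonomy$nodes)
  path <- node
  while (!is.na(taxonomy$parent[[node]])) {
    node <- taxonomy$parent[[node]]
    path <- c(path, node)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param taxonomy A `taxonomy`.
#' @param nodes Character vector of node identifiers.
#' @return The deepest node ancestral to (or equal to) every input node.
#' @export
taxonomy_lca <- function(taxonomy, nodes) {
  nodes <- unique(as.character(nodes))
  stopifnot(length(nodes) >= 1, all(nodes %in% taxonomy$nodes))
  anc <- path_to_root(taxonomy, nodes[1])
  for (nd in nodes[-1]) {
    anc <- anc[anc %in% path_to_root(taxonomy, nd)]
  }
  anc[1]  # paths are ordered deepest-first
}

#' Leaves of a taxonomy
#'
#' @param taxonomy A `taxonomy`.
#' @return Character vector of nodes that are nobody's parent.
#' @export
taxonomy_leaves <- function(taxonomy) {
  setdiff(taxonomy$nodes, stats::na.omit(taxonomy$parent))
}
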