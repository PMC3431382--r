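#' Read a rooted, dated tree from Newick text
#'
#' Thin, validating wrapper around [ape::read.tree()]. Trees are returned as
#' standard `phylo` objects with edge lengths in million years (My). The
#' `node-ages` dialect interprets the number after each colon as the *age* of
#' the node it annotates (tips 0) rather than the length of the subtending
#' branch; ages are converted to branch lengths on read, so downstream code
#' always sees ordinary branch lengths.
#'
#' Underscores in tip labels are preserved literally (binomials such as
#' `Leiopelma_archeyi` round-trip unchanged). Multifurcations are preserved.
#'
#' @param text Newick string (ignored when `file` is given).
#' @param file Path to a Newick file.
#' @param dialect `"branch-lengths"` (default, standard Newick) or
#'   `"node-ages"`.
#' @return A rooted `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
read_newick <- function(text = NULL, file = NULL,
                        dialect = c("branch-lengths", "node-ages")) {
  dialect <- match.arg(dialect)
  if (is.null(text) && is.null(file)) abort("supply `text` or `file`")
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(paste0("unbalanced parentheses in Newick input (", n_open,
                 " '(' vs ", n_close, "')')"))
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) abort("ape could not parse the Newick input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0) {
    abort(paste0("duplicate tip label(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE)) {
    i <- which(tr$edge.length < 0)[1]
    child <- tr$edge[i, 2]
    lab <- if (child <= ape::Ntip(tr)) tr$tip.label[child] else paste0("node ", child)
    abort(paste0("negative branch length (", tr$edge.length[i], ") above ", lab))
  }
  if (dialect == "node-ages") {
    if (is.null(tr$edge.length)) abort("node-ages dialect requires ':age' annotations")
    age <- numeric(ape::Ntip(tr) + tr$Nnode)
    age[tr$edge[, 2]] <- tr$edge.length
    root <- ape::Ntip(tr) + 1L
    age[root] <- if (!is.null(tr$root.edge)) tr$root.edge else max(age)
    tr$edge.length <- age[tr$edge[, 1]] - age[tr$edge[, 2]]
    tr$root.edge <- NULL
    if (any(tr$edge.length < -1e-9)) {
      abort("node-ages dialect: a child is older than its parent")
    }
  }
  tr
}

#' Write a dated tree as Newick
#'
#' @param tree A `phylo` object with all branch lengths defined.
#' @param file Optional path; when omitted the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to a file. A single-tip
#'   tree is written as `A;` (the label, no parentheses).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree has undated branches; run date_pure_birth() first")
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Node ages of a dated tree
#'
#' Ages are distances below the root's height, i.e. the root has the largest
#' age and tips of an ultrametric tree have age 0 (within rounding).
#'
#' @param tree A dated `phylo`.
#' @return Numeric vector of length `Ntip + Nnode`, indexed like ape node ids.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree has undated branches; ages are undefined")
  }
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

is_ultrametric <- function(tree, tol = 1e-8) {
  ape::is.ultrametric(tree, option = 2, tol = tol)
}

# Resolve a node identifier (tip label, node label, or integer id) to an id.
resolve_node <- function(tree, node) {
  n <- ape::Ntip(tree) + tree$Nnode
  if (is.character(node)) {
    id <- match(node, tree$tip.label)
    if (is.na(id) && !is.null(tree$node.label)) {
      hit <- match(node, tree$node.label)
      if (!is.na(hit)) id <- ape::Ntip(tree) + hit
    }
    if (is.na(id)) abort(paste0("node '", node, "' not found in tree"))
    return(id)
  }
  node <- as.integer(node)
  if (is.na(node) || node < 1 || node > n) {
    abort(paste0("node id ", node, " is not in the tree (1..", n, ")"))
  }
  node
}

#' Edge-count distance between two nodes
#'
#' The number of edges on the unique path joining two nodes of the tree; the
#' formalisation of "clades away" used by the topology-perturbation
#' experiments. Symmetric, and zero only for a node paired with itself.
#'
#' @param tree A `phylo`.
#' @param u,v Node ids (ape numbering) or tip/node labels.
#' @return A non-negative integer.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' clade_distance(tr, "A", "B") # 2: up to the cherry node, down again
clade_distance <- function(tree, u, v) {
  u <- resolve_node(tree, u)
  v <- resolve_node(tree, v)
  d <- node_distances_from(tree, u)
  d[v]
}

# BFS edge-count distances from node `from` to every node (undirected).
node_distances_from <- function(tree, from) {
  n <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- rep.int(NA_integer_, n)
  d[from] <- 0L
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (x in frontier) {
      for (y in adj[[x]]) {
        if (is.na(d[y])) {
          d[y] <- d[x] + 1L
          nxt <- c(nxt, y)
        }
      }
    }
    frontier <- nxt
  }
  d
}

#' Total phylogenetic diversity (sum of branch lengths)
#'
#' @param tree A dated `phylo`.
#' @return Sum of all branch lengths, in My.
#' @export
phylogenetic_diversity <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  sum(tree$edge.length)
}
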