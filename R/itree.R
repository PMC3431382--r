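# Internal mutable-ish tree representation.
#
# Public functions speak `phylo` + tibbles; internally, grafting, dating,
# ED and the replicate loops of the perturbation experiments use a plain
# parent/children/age list ("itree") that supports multifurcations, undated
# nodes (age NA) and cheap tip moves. Node ids follow ape convention where
# possible: tips first, then internal nodes; `alive` marks nodes spliced out
# by tip moves.
#
# Fields: ntip, root, parent (0 at root), children (list of int vectors),
# age (NA = undated), label ("" for unnamed internals), alive (logical).

itree_new <- function(ntip, nnode) {
  n <- ntip + nnode
  list(
    ntip = ntip,
    root = ntip + 1L,
    parent = integer(n),
    children = vector("list", n),
    age = rep.int(NA_real_, n),
    label = character(n),
    alive = rep.int(TRUE, n)
  )
}

phylo_to_itree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  it <- itree_new(ntip, tree$Nnode)
  it$parent[tree$edge[, 2]] <- tree$edge[, 1]
  it$children <- split_children(tree$edge, ntip + tree$Nnode)
  it$label[seq_len(ntip)] <- tree$tip.label
  if (!is.null(tree$node.label)) {
    it$label[ntip + seq_len(tree$Nnode)] <- tree$node.label
  }
  if (!is.null(tree$node.age)) {
    it$age <- tree$node.age
  } else if (!is.null(tree$edge.length) && !anyNA(tree$edge.length)) {
    it$age <- node_ages(tree)
    it$age[seq_len(ntip)][abs(it$age[seq_len(ntip)]) < 1e-9] <- 0
  }
  it
}

# children lists from an edge matrix, preserving edge order
split_children <- function(edge, n) {
  kids <- vector("list", n)
  sp <- split(edge[, 2], edge[, 1])
  kids[as.integer(names(sp))] <- sp
  kids
}

# preorder over alive nodes (parents before children), iterative DFS
itree_preorder <- function(it) {
  n <- length(it$parent)
  ord <- integer(n)
  stack <- integer(n)
  stack[1] <- it$root
  sp <- 1L; k <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    k <- k + 1L
    ord[k] <- v
    kids <- it$children[[v]]
    nk <- length(kids)
    if (nk > 0L) {
      stack[sp + seq_len(nk)] <- kids[nk:1]
      sp <- sp + nk
    }
  }
  ord[seq_len(k)]
}

# number of tips descended from every node (tips count themselves)
itree_ntips_below <- function(it, ord = itree_preorder(it)) {
  n <- length(it$parent)
  cnt <- numeric(n)
  cnt[seq_len(it$ntip)][it$alive[seq_len(it$ntip)]] <- 1
  for (v in rev(ord)) {
    p <- it$parent[v]
    if (p > 0L) cnt[p] <- cnt[p] + cnt[v]
  }
  as.integer(cnt)
}

# Fair-proportion ED per tip on a fully dated itree.
# Each branch contributes (its length / tips below it) to each descendant tip;
# per-tip totals are the preorder cumulative sum of those per-branch shares.
itree_ed <- function(it) {
  ord <- itree_preorder(it)
  ntips <- itree_ntips_below(it, ord)
  n <- length(it$parent)
  share <- numeric(n)
  has_par <- it$parent > 0L
  share[has_par] <- (it$age[it$parent[has_par]] - it$age[has_par]) / ntips[has_par]
  cum <- numeric(n)
  for (v in ord) {
    p <- it$parent[v]
    cum[v] <- share[v] + if (p > 0L) cum[p] else 0
  }
  tips <- seq_len(it$ntip)
  tips <- tips[it$alive[tips]]
  setNames(cum[tips], it$label[tips])
}

# Detach tip and re-attach as an extra child of `target` (internal, alive).
# If the old parent is left with a single child it is spliced out.
itree_move_tip <- function(it, tip, target) {
  old <- it$parent[tip]
  if (old == target) return(it)
  kids <- it$children[[old]]
  it$children[[old]] <- kids[kids != tip]
  it$parent[tip] <- target
  it$children[[target]] <- c(it$children[[target]], tip)
  if (length(it$children[[old]]) == 1L && old != it$root) {
    only <- it$children[[old]]
    gp <- it$parent[old]
    gkids <- it$children[[gp]]
    gkids[gkids == old] <- only
    it$children[[gp]] <- gkids
    it$parent[only] <- gp
    it$children[old] <- list(NULL)
    it$parent[old] <- 0L
    it$alive[old] <- FALSE
  } else if (length(it$children[[old]]) == 1L && old == it$root) {
    # root left unary: promote its only child to root
    only <- it$children[[old]]
    it$parent[only] <- 0L
    it$root <- only
    it$children[old] <- list(NULL)
    it$alive[old] <- FALSE
  }
  it
}

itree_to_phylo <- function(it) {
  ord <- itree_preorder(it)
  is_tip <- ord <= it$ntip
  tips <- ord[is_tip]
  ints <- ord[!is_tip]
  ntip <- length(tips)
  new_id <- integer(length(it$parent))
  new_id[tips] <- seq_len(ntip)
  new_id[ints] <- ntip + seq_along(ints)
  edge <- cbind(new_id[it$parent[ord[-1]]], new_id[ord[-1]])
  # ord[-1] drops the root; every other alive node has one parent edge
  phy <- list(
    edge = edge,
    tip.label = it$label[tips],
    Nnode = length(ints),
    edge.length = it$age[it$parent[ord[-1]]] - it$age[ord[-1]]
  )
  labs <- it$label[ints]
  if (any(nzchar(labs))) phy$node.label <- labs
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy$node.age <- rep(NA_real_, ntip + phy$Nnode)
  phy$node.age[new_id[ord]] <- it$age[ord]
  phy
}
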