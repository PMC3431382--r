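#' Date undated nodes with the pure-birth interpolation
#'
#' Assigns an age to every undated node of a partly dated tree using the
#' pure-birth (Yule) estimator: a node's age is `T * ln(a) / ln(b)`, where `T`
#' is the age of its (already dated) parent, `a` the number of tips descended
#' from the node, and `b` the number descended from the parent. Nodes are
#' processed root-to-tip, so each undated node inherits its immediate parent's
#' possibly just-computed age, matching the sequential interpolation used when
#' grafting species-level taxa under a calibrated backbone. Tips are dated at
#' age 0; already dated nodes are left untouched.
#'
#' Undated nodes are marked in the `node.age` component produced by
#' [graft_species()] (`NA` = undated). A fully dated `phylo` (complete branch
#' lengths, no `node.age`) passes through unchanged apart from gaining a
#' `node.age` component.
#'
#' The degenerate case `a == b` (a chain node adding no branching, which the
#' interpolation cannot separate from its parent) is resolved by assigning
#' `0.99 * T`, preserving strict parent-over-child ordering; occurrences are
#' reported via a message.
#'
#' @param tree A `phylo`, optionally carrying a `node.age` numeric vector
#'   (length `Ntip + Nnode`, `NA` for undated nodes).
#' @return A fully dated `phylo` with branch lengths derived from node ages
#'   and a complete `node.age` component.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$node.age <- c(0, 0, 0, 100, NA) # root 100 My, cherry undated
#' dated <- date_pure_birth(tr)
#' dated$node.age[5] # 100 * ln(2)/ln(3)
date_pure_birth <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  it <- phylo_to_itree(tree)
  tips <- seq_len(it$ntip)
  it$age[tips][is.na(it$age[tips])] <- 0
  if (is.na(it$age[it$root])) {
    abort("root is undated; a calibrated root age is required")
  }
  ord <- itree_preorder(it)
  ntips <- itree_ntips_below(it, ord)
  n_degenerate <- 0L
  for (v in ord) {
    if (!is.na(it$age[v])) next
    p <- it$parent[v]
    T_par <- it$age[p]
    a <- ntips[v]
    b <- ntips[p]
    if (a < 2L) abort("internal node with a single descendant tip cannot be dated")
    if (a == b) {
      it$age[v] <- 0.99 * T_par
      n_degenerate <- n_degenerate + 1L
    } else {
      it$age[v] <- T_par * log(a) / log(b)
    }
    if (it$age[v] > T_par + 1e-9) {
      abort("computed child age exceeds parent age") # unreachable for a <= b
    }
  }
  if (n_degenerate > 0L) {
    message(n_degenerate, " degenerate chain node(s) dated at 0.99 * parent age")
  }
  idx <- which(it$parent > 0L)
  bad <- idx[it$age[it$parent[idx]] - it$age[idx] < -1e-9]
  if (length(bad) > 0) {
    abort("pre-dated node older than its parent; check input calibration")
  }
  out <- itree_to_phylo(it)
  out
}
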