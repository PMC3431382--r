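#' Fair-proportion Evolutionary Distinctiveness
#'
#' Each branch's length is divided equally among the tips descending from it;
#' a tip's ED is the sum of its shares over all ancestral branches (pendant
#' branch included). Summed over tips, ED equals the tree's total
#' phylogenetic diversity.
#'
#' @param tree A fully dated `phylo` (multifurcations allowed).
#' @return A tibble with columns `species`, `ed` (My) and `rank_ed`
#'   (1 = most distinct; ties share the minimum rank ordering by name).
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ed_fair_proportion(tr)
ed_fair_proportion <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree has undated branches; run date_pure_birth() first")
  }
  it <- phylo_to_itree(tree)
  ed <- itree_ed(it)
  ed_table(ed)
}

ed_table <- function(ed) {
  out <- tibble::tibble(species = names(ed), ed = unname(ed))
  out$rank_ed <- rank(-out$ed, ties.method = "first")
  # deterministic tie order: higher ed first, then name
  ord <- order(-out$ed, out$species)
  out$rank_ed[ord] <- seq_len(nrow(out))
  out
}

#' Polytomy-corrected Evolutionary Distinctiveness
#'
#' Fair-proportion ED treats a polytomy as a literal simultaneous radiation,
#' which understates the branch sharing any true (unknown) resolution would
#' impose. This correction replaces, for every polytomy, each child's share
#' of the polytomy's branching with its *expected* share over random dated
#' resolutions of that polytomy: each resolution is a labeled binary topology
#' on the polytomy's children, its internal nodes dated by the pure-birth
#' interpolation (`T ln(a)/ln(b)`, see [date_pure_birth()]). Polytomies with
#' at most `max_exact` children are averaged over *all* labeled topologies
#' (3, 15, 105, 945, 10395 for 3..7 children); larger ones use a seeded
#' Monte-Carlo average over `n_samples` random resolutions. Binary trees are
#' returned unchanged.
#'
#' Resolutions are weighted uniformly over labeled topologies by default;
#' `weights = "yule"` instead weights each topology by its probability under
#' a pure-birth branching process on the polytomy's children. Nested
#' polytomies are corrected independently (the correction at a node depends
#' only on its children's ages and tip counts, so order is immaterial).
#'
#' @param tree A fully dated `phylo`.
#' @param weights `"uniform"` (default) or `"yule"` resolution weighting.
#' @param n_samples Monte-Carlo draws per polytomy above the exact cutoff.
#' @param max_exact Largest polytomy resolved by exhaustive enumeration.
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param renormalize If `TRUE`, rescale corrected scores so their sum equals
#'   the tree's phylogenetic diversity (off by default; the raw expectation
#'   is reported as-is).
#' @return A tibble like [ed_fair_proportion()]'s.
#' @export
ed_polytomy_corrected <- function(tree, weights = c("uniform", "yule"),
                                  n_samples = 1000, max_exact = 7,
                                  seed = NULL, renormalize = FALSE) {
  weights <- match.arg(weights)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree has undated branches; run date_pure_birth() first")
  }
  it <- phylo_to_itree(tree)
  run <- function() itree_ed_corrected(it, weights = weights,
                                       n_samples = n_samples,
                                       max_exact = max_exact)
  ed <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (renormalize) {
    pd <- sum(itree_ed(it))
    ed <- ed * pd / sum(ed)
  }
  ed_table(ed)
}

# corrected ED on an itree; returns named per-tip vector
itree_ed_corrected <- function(it, weights = "uniform", n_samples = 1000,
                               max_exact = 7) {
  ord <- itree_preorder(it)
  ntips <- itree_ntips_below(it, ord)
  ed <- itree_ed(it)
  tip_ids <- seq_len(it$ntip)[it$alive[seq_len(it$ntip)]]
  pos <- integer(length(it$parent))
  pos[tip_ids] <- seq_along(tip_ids)   # tip id -> position in ed vector

  # tips under each node, collected lazily where needed
  tips_under <- function(v) {
    if (v <= it$ntip) return(v)
    unlist(lapply(it$children[[v]], tips_under), use.names = FALSE)
  }

  for (v in ord) {
    kids <- it$children[[v]]
    k <- length(kids)
    if (k <= 2L) next
    T_par <- it$age[v]
    m <- ntips[kids]
    ages <- it$age[kids]
    pure_star <- all(kids <= it$ntip)
    if (pure_star) {
      share <- star_share(k, weights = weights, n_samples = n_samples,
                          max_exact = max_exact)
      # expected per-tip share (T = 1 scales linearly) minus the star's
      # literal pendant share T
      ed[pos[kids]] <- ed[pos[kids]] + T_par * (share - 1)
    } else {
      e <- expected_unit_shares(m, ages, T_par, weights = weights,
                                n_samples = n_samples, max_exact = max_exact)
      for (j in seq_len(k)) {
        star_per_tip <- (T_par - ages[j]) / m[j]
        tj <- tips_under(kids[j])
        tj <- tj[it$alive[tj]]
        ed[pos[tj]] <- ed[pos[tj]] + (e[j] - star_per_tip)
      }
    }
  }
  ed
}
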