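# --- internal helpers shared by perturb_ed and run_experiment -------------

# Edge-count distances between internal nodes only. Paths between internal
# nodes never pass through tips, so BFS over the internal-node adjacency is
# equivalent to clade_distance() restricted to internal nodes, and the dense
# matrix makes per-move candidate lookup a vector operation.
internal_distance_matrix <- function(it) {
  ids <- which(seq_along(it$parent) > it$ntip & it$alive)
  idx <- integer(length(it$parent))
  idx[ids] <- seq_along(ids)
  adj <- vector("list", length(ids))
  for (v in ids) {
    p <- it$parent[v]
    if (p > 0L) {
      adj[[idx[v]]] <- c(adj[[idx[v]]], idx[p])
      adj[[idx[p]]] <- c(adj[[idx[p]]], idx[v])
    }
  }
  n <- length(ids)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d <- rep.int(NA_integer_, n)
    d[s] <- 0L
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (x in frontier) {
        ys <- adj[[x]]
        new <- ys[is.na(d[ys])]
        d[new] <- d[x] + 1L
        nxt <- c(nxt, new)
      }
      frontier <- nxt
    }
    D[s, ] <- d
  }
  list(ids = ids, idx = idx, D = D)
}

# Move `tips` (ids) each to a clade `clades_away` edges from its original
# parent, on a working copy of `it`. Falls back to the farthest available
# clade when none exists at the requested distance. Uses distances computed
# on the original tree (`dist`), restricted to clades still alive.
move_tips <- function(it, tips, clades_away, dist) {
  n_fallback <- 0L
  for (tip in tips) {
    par <- it$parent[tip]
    # original parent may already have been spliced out by an earlier move;
    # distances are anchored at the tip's *current* parent in that case
    row <- dist$idx[par]
    if (row == 0L || is.na(row)) next
    d <- dist$D[row, ]
    ok <- it$alive[dist$ids] & !is.na(d) & d > 0L
    if (!any(ok)) next
    cand <- which(ok & d == clades_away)
    if (length(cand) == 0L) {
      # no clade at exactly the requested distance: use the maximum
      # available when the request exceeds it, otherwise the nearest
      # available distance (exact-distance clades can vanish when earlier
      # moves splice out emptied nodes)
      avail <- sort(unique(d[ok]))
      use <- if (clades_away >= max(avail)) max(avail) else
        avail[which.min(abs(avail - clades_away))]
      cand <- which(ok & d == use)
      n_fallback <- n_fallback + 1L
    }
    target <- dist$ids[cand[[sample.int(length(cand), 1L)]]]
    it <- itree_move_tip(it, tip, target)
  }
  attr(it, "n_fallback") <- n_fallback
  it
}

#' Perturb a phylogeny by moving species to nearby clades
#'
#' Moves a random subset of tips each into a clade a fixed number of edges
#' away from the tip's parent clade (edge-count distance on the unperturbed
#' tree, see [clade_distance()]). The target clade is drawn uniformly among
#' clades at exactly that distance; if none exists, the farthest available
#' distance is used. A moved tip joins the target clade's root polytomy with
#' a pendant branch equal to the target node's age, so the tree stays
#' ultrametric; emptied binary parents are spliced out. The tip set is
#' unchanged.
#'
#' @param tree A fully dated `phylo`.
#' @param fraction Fraction of tips to move; `ceiling(fraction * Ntip)` tips
#'   are drawn. Must select at least one tip.
#' @param clades_away Target edge-count distance (the severity knob; the
#'   experiments use 1, 2, 4, 8, 16).
#' @param seed Integer seed.
#' @return The perturbed `phylo`.
#' @export
perturb_ed <- function(tree, fraction, clades_away, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  it <- phylo_to_itree(tree)
  if (anyNA(it$age)) abort("tree has undated nodes; run date_pure_birth() first")
  if (fraction * it$ntip < 1) abort("fraction selects no tips")
  k <- ceiling(fraction * it$ntip)
  dist <- internal_distance_matrix(it)
  run <- function() {
    tips <- sample.int(it$ntip, k)
    move_tips(it, tips, clades_away, dist)
  }
  it2 <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  nf <- attr(it2, "n_fallback")
  if (!is.null(nf) && nf > 0L) {
    message(nf, " tip(s) had no clade at distance ", clades_away,
            "; moved to the farthest available clade")
  }
  itree_to_phylo(it2)
}

shift_category <- function(category, steps) {
  ge <- ge_of(category)
  movable <- !is.na(ge)
  ge[movable] <- pmin(pmax(ge[movable] + steps[movable], 0L), 4L)
  category[movable] <- c("LC", "NT", "VU", "EN", "CR")[ge[movable] + 1L]
  category
}

#' Perturb Red List categories up or down
#'
#' A random subset of assessable species (not DD/EX) is shifted
#' `n_categories` steps up or down the threat scale, direction by fair coin
#' per species, clamped at Least Concern and Critically Endangered (an LC
#' species drawn to move down stays LC; a CR drawn to move up stays CR).
#'
#' @param data Data frame with `species` and `category`.
#' @param fraction Fraction of assessable species to perturb.
#' @param n_categories Steps to move (the severity knob; 1..4).
#' @param seed Integer seed.
#' @return `data` with perturbed `category`.
#' @export
perturb_ge <- function(data, fraction, n_categories, seed = NULL) {
  data <- tibble::as_tibble(data)
  check_category(data$category)
  movable <- which(!data$category %in% c("DD", "EX"))
  k <- ceiling(fraction * length(movable))
  run <- function() {
    pick <- sample(movable, min(k, length(movable)))
    dir <- sample(c(-1L, 1L), length(pick), replace = TRUE)
    steps <- integer(nrow(data))
    steps[pick] <- dir * as.integer(n_categories)
    data$category <- shift_category(data$category, steps)
    data
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Impute threat categories for Data Deficient species
#'
#' Every DD species receives a category drawn from the empirical category
#' mixture (CR:EN:VU:NT:LC) of the assessed species, then shifted by
#' `dd_shift` levels (positive = more threatened), clamped at LC and CR.
#' Non-DD species are untouched.
#'
#' @param data Data frame with `species` and `category`.
#' @param dd_shift Integer in -2..2 applied after imputation.
#' @param seed Integer seed.
#' @return `data` with DD categories replaced.
#' @export
impute_dd <- function(data, dd_shift = 0, seed = NULL) {
  data <- tibble::as_tibble(data)
  check_category(data$category)
  known <- data$category[!data$category %in% c("DD", "EX")]
  if (length(known) == 0) abort("no assessed species to estimate the category mixture")
  dd <- which(data$category == "DD")
  if (length(dd) == 0) return(data)
  lev <- c("LC", "NT", "VU", "EN", "CR")
  mix <- table(factor(known, levels = lev)) / length(known)
  run <- function() {
    draw <- sample(lev, length(dd), replace = TRUE, prob = as.numeric(mix))
    steps <- integer(nrow(data))
    data$category[dd] <- draw
    steps[dd] <- as.integer(dd_shift)
    data$category <- shift_category(data$category, steps)
    data
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Top-list similarity between two priority lists
#'
#' @param a,b Character vectors of species (ordered or not).
#' @param n List size compared (default 100).
#' @return Proportion of the top `n` shared, in `[0, 1]`.
#' @export
top_list_similarity <- function(a, b, n = 100) {
  a <- head(a, n); b <- head(b, n)
  length(intersect(a, b)) / max(length(a), length(b))
}
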