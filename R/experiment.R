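#' Monte-Carlo robustness experiment on the top-100 priority list
#'
#' Replicates one of the four uncertainty experiments: `"ed"` perturbs the
#' phylogeny by moving a fraction of species to clades a fixed distance away
#' ([perturb_ed()]); `"ge"` shifts a fraction of species' Red List categories
#' up or down ([perturb_ge()]); `"dd"` imputes categories for Data Deficient
#' species ([impute_dd()]), letting them compete for list membership; and
#' `"combined"` draws one subset of species and, for each drawn species
#' independently, applies an ED move (probability 1/2, severity uniform on
#' 1–2 clades) and/or a GE shift (probability 1/2, severity uniform on 1–2
#' categories), with DD species imputed at `dd_shift`. Every replicate
#' rescores the perturbed data under `scheme` and records the proportion of
#' the reference top-`top_n` list it retains.
#'
#' The reference list is computed from the unperturbed inputs with the same
#' scoring settings and is never mutated. Replicate seeds are drawn once from
#' `seed`, so any single replicate can be reproduced in isolation.
#'
#' @param tree Fully dated `phylo` whose tips match `species$species`.
#' @param species Data frame with `species` and `category`.
#' @param kind `"ed"`, `"ge"`, `"dd"` or `"combined"`.
#' @param fraction Fraction of species perturbed (ignored for `"dd"`). A
#'   value of 0 makes every replicate a no-op (similarity 1).
#' @param clades_away Severity of ED moves (kinds `"ed"`).
#' @param n_categories Severity of GE shifts (kind `"ge"`).
#' @param dd_shift Shift applied after DD imputation (kinds `"dd"`,
#'   `"combined"`).
#' @param replicates Number of Monte-Carlo replicates (default 1000).
#' @param seed Master integer seed.
#' @param scheme Weighting scheme used for ranking (see
#'   [edge_scheme_names()]).
#' @param top_n Priority-list size compared (default 100).
#' @param correction `"none"` (fair-proportion ED inside replicates, the
#'   default) or `"polytomy"` (expected-ED polytomy correction, slower).
#' @param n_samples Monte-Carlo draws per large polytomy when
#'   `correction = "polytomy"`.
#' @return An `edge_experiment` object; see [tidy.edge_experiment()] and
#'   [glance.edge_experiment()].
#' @export
run_experiment <- function(tree, species,
                           kind = c("ed", "ge", "dd", "combined"),
                           fraction = 0.1, clades_away = 1, n_categories = 1,
                           dd_shift = 0, replicates = 1000, seed = 1,
                           scheme = "edge_log2", top_n = 100,
                           correction = c("none", "polytomy"),
                           n_samples = 200) {
  kind <- match.arg(kind)
  correction <- match.arg(correction)
  scheme <- match.arg(scheme, edge_scheme_names())
  stopifnot(inherits(tree, "phylo"), replicates >= 1)
  species <- tibble::as_tibble(species)
  check_category(species$category)
  if (!setequal(tree$tip.label, species$species)) {
    abort("tree tips and species table do not match")
  }
  species <- species[match(tree$tip.label, species$species), ]

  it0 <- phylo_to_itree(tree)
  if (anyNA(it0$age)) abort("tree has undated nodes; run date_pure_birth() first")
  compute_ed <- function(it) {
    if (correction == "polytomy") {
      itree_ed_corrected(it, n_samples = n_samples)
    } else {
      itree_ed(it)
    }
  }
  ed0 <- withr::with_seed(seed, compute_ed(it0))
  ed0 <- ed0[species$species]

  top_of <- function(ed, category) {
    ok <- !category %in% c("DD", "EX")
    sc <- scheme_score(scheme, ed[ok], category[ok])
    sp <- species$species[ok]
    sp[priority_order(sc, ed[ok], sp)][seq_len(min(top_n, sum(ok)))]
  }
  ref_top <- top_of(ed0, species$category)
  dd0 <- species$category == "DD"

  need_dist <- kind %in% c("ed", "combined")
  dist <- if (need_dist) internal_distance_matrix(it0) else NULL
  n <- it0$ntip
  k_sel <- ceiling(fraction * n)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, replicates))

  one_rep <- function(rs) {
    withr::with_seed(rs, {
      cats <- species$category
      ed <- ed0
      if (kind == "ed" && fraction > 0) {
        tips <- sample.int(n, k_sel)
        it <- move_tips(it0, tips, clades_away, dist)
        ed <- compute_ed(it)[species$species]
      } else if (kind == "ge" && fraction > 0) {
        cats <- perturb_ge(species, fraction, n_categories)$category
      } else if (kind == "dd") {
        cats <- impute_dd(species, dd_shift)$category
      } else if (kind == "combined") {
        if (fraction > 0) {
          pick <- sample.int(n, k_sel)
          do_ed <- pick[runif(length(pick)) < 0.5]
          do_ge <- pick[runif(length(pick)) < 0.5]
          if (length(do_ed) > 0) {
            sev <- sample(1:2, length(do_ed), replace = TRUE)
            it <- it0
            for (s in 1:2) {
              sub <- do_ed[sev == s]
              if (length(sub) > 0) it <- move_tips(it, sub, s, dist)
            }
            ed <- compute_ed(it)[species$species]
          }
          do_ge <- do_ge[!cats[do_ge] %in% c("DD", "EX")]
          if (length(do_ge) > 0) {
            steps <- integer(length(cats))
            steps[do_ge] <- sample(c(-1L, 1L), length(do_ge), replace = TRUE) *
              sample(1:2, length(do_ge), replace = TRUE)
            cats <- shift_category(cats, steps)
          }
        }
        cats <- impute_dd(tibble::tibble(species = species$species, category = cats),
                          dd_shift)$category
      }
      top <- top_of(ed, cats)
      tibble::tibble(
        similarity = top_list_similarity(top, ref_top, top_n),
        n_dd_entrants = sum(top %in% species$species[dd0])
      )
    })
  }
  reps <- purrr::map(rep_seeds, one_rep)
  reps <- dplyr::bind_rows(reps, .id = "replicate")
  reps$replicate <- as.integer(reps$replicate)
  reps$seed <- rep_seeds

  structure(
    list(
      replicates = reps,
      kind = kind, fraction = fraction, clades_away = clades_away,
      n_categories = n_categories, dd_shift = dd_shift, scheme = scheme,
      top_n = top_n, seed = seed, correction = correction,
      reference_top = ref_top, n_species = n
    ),
    class = "edge_experiment"
  )
}

#' @export
print.edge_experiment <- function(x, ...) {
  g <- glance(x)
  cat("<edge_experiment> kind =", x$kind,
      " fraction =", x$fraction,
      " replicates =", nrow(x$replicates), "\n")
  cat(sprintf("  top-%d similarity: mean %.3f [%.3f, %.3f]\n",
              x$top_n, g$mean_similarity, g$conf_low, g$conf_high))
  invisible(x)
}

#' Per-replicate results of a robustness experiment
#'
#' @param x An `edge_experiment`.
#' @param ... Unused.
#' @return Tibble with one row per replicate: `replicate`, `similarity`
#'   (proportion of the reference top list retained), `n_dd_entrants`
#'   (originally-DD species present in the perturbed top list) and the
#'   replicate `seed`.
#' @export
tidy.edge_experiment <- function(x, ...) x$replicates

#' One-row summary of a robustness experiment
#'
#' @param x An `edge_experiment`.
#' @param ... Unused.
#' @return One-row tibble: experiment settings, `mean_similarity`, the 2.5%
#'   and 97.5% similarity quantiles (`conf_low`, `conf_high`), the standard
#'   error of the mean, and `mean_dd_entrants`.
#' @export
glance.edge_experiment <- function(x, ...) {
  s <- x$replicates$similarity
  tibble::tibble(
    kind = x$kind, fraction = x$fraction, clades_away = x$clades_away,
    n_categories = x$n_categories, dd_shift = x$dd_shift, scheme = x$scheme,
    replicates = length(s),
    mean_similarity = mean(s),
    conf_low = unname(quantile(s, 0.025)),
    conf_high = unname(quantile(s, 0.975)),
    se = stats::sd(s) / sqrt(length(s)),
    mean_dd_entrants = mean(x$replicates$n_dd_entrants)
  )
}
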