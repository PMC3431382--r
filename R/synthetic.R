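#' Simulate a dated Yule (pure-birth) tree
#'
#' A binary ultrametric tree grown under a constant-rate pure-birth process
#' conditioned on the number of extant tips, rescaled so the root sits at
#' `root_age`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age Root age in My.
#' @param seed Integer seed.
#' @return An ultrametric `phylo`, tips labeled `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, root_age = 1, seed = NULL) {
  if (n_tips < 2) abort("n_tips must be at least 2")
  run <- function() ape::rphylo(n_tips, birth = 1, death = 0)
  tr <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * root_age / depth
  tr
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a class-wide amphibian assessment: ~5700 species over
#' ~380 higher taxa, a deep (300 My) Yule backbone, genus sizes drawn from a
#' log-series (many monotypic genera, a few huge ones, which produces the
#' right-skewed ED distribution such data show), most genera left as pure
#' star polytomies, and a Red List mixture with roughly a third threatened
#' and a quarter Data Deficient.
#'
#' @param n_species Total species.
#' @param backbone_tips Number of higher taxa (backbone tips).
#' @param root_age Backbone root age, My.
#' @param category_mix Named proportions over LC/NT/VU/EN/CR/DD/EX (sums
#'   to 1).
#' @param star_fraction Fraction of polytypic genera left fully unresolved.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 5700, backbone_tips = 380,
                             root_age = 300,
                             category_mix = c(LC = 0.34, NT = 0.07, VU = 0.13,
                                              EN = 0.13, CR = 0.08, DD = 0.24,
                                              EX = 0.01),
                             star_fraction = 0.7, seed = 1) {
  if (abs(sum(category_mix) - 1) > 1e-8 || any(category_mix < 0)) {
    abort("category_mix must be non-negative proportions summing to 1")
  }
  if (!setequal(names(category_mix), iucn_categories())) {
    abort("category_mix must be named over the seven Red List categories")
  }
  if (n_species < backbone_tips) abort("n_species must be >= backbone_tips")
  structure(
    list(n_species = n_species, backbone_tips = backbone_tips,
         root_age = root_age, category_mix = category_mix,
         star_fraction = star_fraction, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# log-series ("logarithmic") genus sizes with a given mean, adjusted to sum
# exactly to `total`: many monotypic genera, a long right tail
sample_genus_sizes <- function(n_genera, total) {
  mean_size <- total / n_genera
  if (mean_size <= 1.0001) {
    sizes <- rep(1L, n_genera)
  } else {
    p <- uniroot(function(p) -p / ((1 - p) * log(1 - p)) - mean_size,
                 c(1e-8, 1 - 1e-12), tol = 1e-12)$root
    kmax <- 1
    while (p^kmax / kmax > 1e-12 * (1 - p)) kmax <- kmax + 50
    k <- seq_len(kmax)
    prob <- p^k / k
    sizes <- sample(k, n_genera, replace = TRUE, prob = prob)
  }
  # repair the total while keeping the shape: random unit increments or
  # decrements (never below 1)
  diff <- total - sum(sizes)
  while (diff != 0) {
    i <- sample.int(n_genera, 1L)
    if (diff > 0) {
      sizes[i] <- sizes[i] + 1L
      diff <- diff - 1L
    } else if (sizes[i] > 1L) {
      sizes[i] <- sizes[i] - 1L
      diff <- diff + 1L
    }
  }
  as.integer(sizes)
}

#' Generate a synthetic backbone and species table
#'
#' Produces inputs with the statistical structure the prioritization
#' pipeline assumes: a Yule higher-taxon backbone; species allocated to
#' genera with log-series sizes; a `star_fraction` of polytypic genera left
#' as pure stars while the rest get 2–6 random species groups; and Red List
#' categories sampled from `category_mix`. The output feeds straight into
#' [graft_species()].
#'
#' @param config A [synthetic_config()].
#' @return List with `backbone` (dated `phylo`, tips `g1..gN`) and `species`
#'   (tibble: `species`, `higher_taxon`, `subclade`, `category`).
#' @export
#' @examples
#' st <- simulate_study(synthetic_config(n_species = 60, backbone_tips = 12,
#'                                       root_age = 100, seed = 42))
#' dplyr::count(st$species, higher_taxon)
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    nb <- config$backbone_tips
    backbone <- ape::rphylo(nb, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(backbone))
    backbone$edge.length <- backbone$edge.length * config$root_age / depth
    backbone$tip.label <- paste0("g", seq_len(nb))

    sizes <- sample_genus_sizes(nb, config$n_species)
    genus <- rep(backbone$tip.label, sizes)
    species <- paste0(genus, "_sp", unlist(lapply(sizes, seq_len)))

    subclade <- rep(NA_character_, length(species))
    polytypic <- which(sizes >= 4L)
    resolved <- polytypic[runif(length(polytypic)) > config$star_fraction]
    for (g in resolved) {
      rows <- which(genus == backbone$tip.label[g])
      ngrp <- sample(2:min(6L, sizes[g] - 1L), 1L)
      subclade[rows] <- paste0(backbone$tip.label[g], "_grp",
                               sample.int(ngrp, length(rows), replace = TRUE))
    }
    category <- sample(names(config$category_mix), length(species),
                       replace = TRUE, prob = config$category_mix)
    list(
      backbone = backbone,
      species = tibble::tibble(species = species, higher_taxon = genus,
                               subclade = subclade, category = category)
    )
  })
}
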