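test_that("fair-proportion ED matches hand computations", {
  cherry <- read_newick("(A:1,B:1);")
  expect_close(ed_fair_proportion(cherry)$ed, c(1, 1))

  bal <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  tab <- ed_fair_proportion(bal)
  expect_close(tab$ed, rep(1.5, 4))
  expect_close(sum(tab$ed), phylogenetic_diversity(bal))  # = 6
})

test_that("ED sums to PD and agrees with an independent implementation", {
  skip_if_not_installed("picante")
  for (seed in 1:5) {
    tr <- simulate_yule_tree(50, root_age = 120, seed = seed)
    tab <- ed_fair_proportion(tr)
    expect_close(sum(tab$ed), phylogenetic_diversity(tr), tol = 1e-9 * 120 * 50)
    oracle <- picante::evol.distinct(tr, type = "fair.proportion")
    expect_close(tab$ed[match(oracle$Species, tab$species)], oracle$w,
                 tol = 1e-8)
  }
})

test_that("polytomy correction is the identity on binary trees", {
  tr <- simulate_yule_tree(40, root_age = 90, seed = 8)
  expect_equal(ed_polytomy_corrected(tr), ed_fair_proportion(tr))
})

test_that("3-tip star correction matches the enumerated expectation", {
  # all 3 resolutions: cherry at t = T*ln2/ln3; mean per-tip ED = (2T + t)/3
  for (T in c(1, 10, 37.5)) {
    st <- star_tree(3, T)
    got <- ed_polytomy_corrected(st)$ed
    t <- T * log(2) / log(3)
    expect_close(got, rep((2 * T + t) / 3, 3), tol = 1e-9)
    expect_close(got[1] / T, 0.8770, tol = 1e-4)
  }
})

test_that("star tips are exchangeable and share less than the star depth", {
  for (n in c(4, 6, 9, 15)) {
    got <- ed_polytomy_corrected(star_tree(n, 10), seed = 1)$ed
    expect_close(got, rep(got[1], n))   # exchangeability
    expect_lt(got[1], 10)               # branch sharing always expected
    expect_gt(got[1], 10 / n)           # but more than an even split
  }
})

test_that("Monte-Carlo resolutions converge to exhaustive enumeration", {
  # force the sampler on a mixed polytomy the enumerator can still do
  # exactly (pure stars take a deterministic internally-seeded path instead)
  tr <- read_newick("((A:2,B:2):8,C:10,D:10,(E:3,F:3):7,G:10);")
  exact <- ed_polytomy_corrected(tr)$ed
  draws <- vapply(1:8, function(s) {
    ed_polytomy_corrected(tr, max_exact = 3, n_samples = 400, seed = s)$ed
  }, numeric(7))
  se <- apply(draws, 1, stats::sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - exact) < 4 * se + 1e-3))
})

test_that("correction handles mixed and nested polytomies locally", {
  # polytomy whose children include a dated cherry: only local shares change
  tr <- read_newick("((A:2,B:2):8,C:10,D:10,(E:10,F:10,G:10):20);")
  fp <- ed_fair_proportion(tr)
  corr <- ed_polytomy_corrected(tr, seed = 2)
  m <- match(fp$species, corr$species)
  # every tip descends from some polytomy here, so all scores shrink or stay
  expect_true(all(corr$ed[m] <= fp$ed + 1e-9))
  # tips of the inner star remain exchangeable
  inner <- corr$ed[corr$species %in% c("E", "F", "G")]
  expect_close(inner, rep(inner[1], 3))
})

test_that("yule weighting matches uniform for 3 units and runs for larger", {
  st <- star_tree(3, 10)
  expect_equal(ed_polytomy_corrected(st, weights = "yule"),
               ed_polytomy_corrected(st, weights = "uniform"))
  st5 <- star_tree(5, 10)
  yw <- ed_polytomy_corrected(st5, weights = "yule")$ed
  uw <- ed_polytomy_corrected(st5, weights = "uniform")$ed
  expect_false(isTRUE(all.equal(yw[1], uw[1], tolerance = 1e-12)))
})

test_that("renormalization restores the PD sum", {
  sc <- scaled_study(n_species = 150, backbone_tips = 20, seed = 6)
  raw <- ed_polytomy_corrected(sc$tree, seed = 1)
  ren <- ed_polytomy_corrected(sc$tree, seed = 1, renormalize = TRUE)
  expect_close(sum(ren$ed), phylogenetic_diversity(sc$tree), tol = 1e-6)
  expect_lt(sum(raw$ed), phylogenetic_diversity(sc$tree))
})
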