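test_that("a cherry tip moved two clades away joins its uncle clade", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # only internal node at distance 2 from A's parent is the (C,D) cherry
  moved <- perturb_ed(tr, fraction = 0.25, clades_away = 2, seed = 1)
  expect_setequal(moved$tip.label, tr$tip.label)
  it <- edgeprior:::phylo_to_itree(moved)
  sizes <- lengths(it$children)[it$alive & seq_along(it$parent) > it$ntip]
  # old cherry spliced away: a root cherry plus one trifurcating clade
  expect_setequal(sizes, c(2, 3))
  tri <- which(lengths(it$children) == 3)
  labs <- it$label[it$children[[tri]]]
  expect_true(all(c("A", "B") %in% labs) || all(c("C", "D") %in% labs))
})

test_that("an unreachable distance falls back to the farthest clade", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_message(moved <- perturb_ed(tr, 0.25, clades_away = 50, seed = 2),
                 "farthest available")
  expect_setequal(moved$tip.label, tr$tip.label)
  expect_true(ape::is.ultrametric(moved, option = 2))
})

test_that("perturb_ed keeps the tip set, ultrametry, and is seed-stable", {
  sc <- scaled_study(n_species = 200, backbone_tips = 20, seed = 3)
  m1 <- perturb_ed(sc$tree, 0.1, 4, seed = 99)
  m2 <- perturb_ed(sc$tree, 0.1, 4, seed = 99)
  expect_identical(write_newick(m1), write_newick(m2))
  expect_setequal(m1$tip.label, sc$tree$tip.label)
  expect_true(ape::is.ultrametric(m1, option = 2))
  expect_error(perturb_ed(sc$tree, 0.0001, 1), "no tips")
})

test_that("category shifts clamp at LC and CR", {
  lc <- tibble::tibble(species = paste0("s", 1:50), category = "LC")
  out <- perturb_ge(lc, fraction = 1, n_categories = 1, seed = 1)
  expect_true(all(out$category %in% c("LC", "NT")))  # down-moves stay LC
  cr <- tibble::tibble(species = paste0("s", 1:50), category = "CR")
  out <- perturb_ge(cr, fraction = 1, n_categories = 1, seed = 1)
  expect_true(all(out$category %in% c("EN", "CR")))  # up-moves stay CR
  vu <- tibble::tibble(species = paste0("s", 1:50), category = "VU")
  out <- perturb_ge(vu, fraction = 1, n_categories = 2, seed = 1)
  expect_true(all(out$category %in% c("LC", "CR")))  # VU +/- 2
  dd <- tibble::tibble(species = paste0("s", 1:10),
                       category = c(rep("DD", 5), rep("EX", 5)))
  dd2 <- tibble::tibble(species = "s11", category = "VU")
  out <- perturb_ge(dplyr::bind_rows(dd, dd2), fraction = 1, n_categories = 4,
                    seed = 1)
  expect_equal(out$category[1:10], dd$category)      # DD/EX never move
})

test_that("DD imputation reproduces the assessed mixture and applies shifts", {
  base <- tibble::tibble(
    species = paste0("s", 1:2000),
    category = c(rep("LC", 500), rep("VU", 300), rep("EN", 150),
                 rep("CR", 50), rep("DD", 1000))
  )
  imp <- impute_dd(base, dd_shift = 0, seed = 7)
  expect_false(any(imp$category == "DD"))
  expect_equal(imp$category[1:1000], base$category[1:1000])
  got <- table(factor(imp$category[1001:2000],
                      levels = c("LC", "NT", "VU", "EN", "CR")))
  p <- c(500, 0, 300, 150, 50) / 1000
  test <- stats::chisq.test(got[p > 0], p = p[p > 0])
  expect_gt(test$p.value, 0.001)

  up2 <- impute_dd(base, dd_shift = 2, seed = 7)
  lev <- c("LC", "NT", "VU", "EN", "CR")
  expect_true(all(match(up2$category[1001:2000], lev) >=
                    pmin(match(imp$category[1001:2000], lev) + 2, 5)))
  dn2 <- impute_dd(base, dd_shift = -2, seed = 7)
  expect_true(all(dn2$category[1001:2000] %in% c("LC", "NT", "VU")))
  expect_error(impute_dd(tibble::tibble(species = "a", category = "DD")),
               "no assessed species")
})

test_that("top-list similarity is a proportion with the right extremes", {
  expect_equal(top_list_similarity(letters[1:10], letters[1:10], 10), 1)
  expect_equal(top_list_similarity(letters[1:10], LETTERS[1:10], 10), 0)
  expect_equal(top_list_similarity(letters[1:10], c(letters[1:5], LETTERS[1:5]), 10), 0.5)
})
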