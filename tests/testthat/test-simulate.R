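test_that("Yule simulation is ultrametric, correctly sized and scaled", {
  expect_error(simulate_yule_tree(1), "at least 2")
  cherry <- simulate_yule_tree(2, root_age = 42, seed = 1)
  expect_equal(ape::Ntip(cherry), 2)
  expect_close(node_ages(cherry)[3], 42)
  for (seed in 1:5) {
    tr <- simulate_yule_tree(64, root_age = 10, seed = seed)
    expect_true(ape::is.ultrametric(tr, option = 2, tol = 1e-9))
    expect_close(max(node_ages(tr)), 10)
  }
})

test_that("lineages through time grow exponentially as Yule predicts", {
  # E[N(t)] ~ e^(lambda t) and e^(lambda T) = n, so about sqrt(n) lineages
  # should be present at half depth
  n <- 100
  counts <- vapply(1:40, function(seed) {
    tr <- simulate_yule_tree(n, root_age = 1, seed = seed)
    ages <- node_ages(tr)[-seq_len(n)]
    sum(ages > 0.5) + 1  # branches crossing half depth
  }, 0)
  expect_gt(mean(counts), 0.5 * sqrt(n))
  expect_lt(mean(counts), 2.0 * sqrt(n))
})

test_that("synthetic study is reproducible and respects its config", {
  cfg <- synthetic_config(n_species = 400, backbone_tips = 50, root_age = 150,
                          seed = 9)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$species, s2$species)
  expect_identical(write_newick(s1$backbone), write_newick(s2$backbone))
  expect_equal(nrow(s1$species), 400)
  expect_equal(ape::Ntip(s1$backbone), 50)
  expect_equal(sum(table(s1$species$higher_taxon)), 400)
  expect_error(synthetic_config(category_mix = c(LC = 1)), "seven")
  expect_error(synthetic_config(n_species = 10, backbone_tips = 20), ">=")
})

test_that("all-monotypic config reduces grafting to renaming", {
  cfg <- synthetic_config(n_species = 30, backbone_tips = 30, root_age = 100,
                          seed = 2)
  st <- simulate_study(cfg)
  asm <- graft_species(st$backbone, st$species)
  expect_equal(ape::Ntip(asm$tree), 30)
  expect_equal(asm$tree$Nnode, st$backbone$Nnode)  # no new nodes
  expect_false(anyNA(asm$tree$node.age))
})

test_that("category frequencies match the configured mixture", {
  cfg <- synthetic_config(n_species = 4000, backbone_tips = 100, seed = 3)
  st <- simulate_study(cfg)
  got <- table(factor(st$species$category, levels = iucn_categories()))
  test <- stats::chisq.test(got, p = cfg$category_mix[iucn_categories()])
  expect_gt(test$p.value, 0.001)
})

test_that("amphibian-like defaults give a right-skewed (J-shaped) ED tail", {
  for (seed in c(1, 2)) {
    sc <- scaled_study(n_species = 1500, backbone_tips = 120, seed = seed,
                       root_age = 300)
    ed <- ed_polytomy_corrected(sc$tree, seed = 1)$ed
    q95 <- quantile(ed, 0.95)
    expect_lt(q95, 0.5 * max(ed))          # long tail: 95th pct far below max
    expect_lt(stats::median(ed), mean(ed)) # right skew
  }
})

test_that("the full pipeline runs end-to-end with a stable manifest", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(
    seed = 5,
    synthetic = list(n_species = 200, backbone_tips = 25, root_age = 150),
    experiments = list(list(kind = "ge", fraction = 0.1, replicates = 5))
  )
  m1 <- run_pipeline(config, out1)
  m2 <- run_pipeline(config, out2)
  for (f in c("scores.csv", "candidate_list.csv", "running_mean_ed.csv",
              "assembly_report.csv", "tree.nwk", "experiments.csv")) {
    expect_true(file.exists(file.path(out1, f)), label = f)
    expect_identical(m1$outputs[[f]], m2$outputs[[f]], label = f)
  }
  expect_true(file.exists(file.path(out1, "manifest.json")))
  scores <- utils::read.csv(file.path(out1, "scores.csv"))
  expect_true(all(c("score_edge_log2", "rank_iucn500") %in% names(scores)))
})
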