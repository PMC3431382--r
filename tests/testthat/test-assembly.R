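test_that("grafting builds stars, subclade cherries, and renames monotypes", {
  ts <- toy_study()
  asm <- graft_species(ts$backbone, ts$species, seed = 1)
  tree <- asm$tree

  expect_setequal(tree$tip.label, ts$species$species)
  expect_equal(asm$report$n_assigned, 8L)
  expect_equal(asm$report$n_unplaced, 0L)

  it <- edgeprior:::phylo_to_itree(tree)
  # g1: 3 species, no subclades -> trifurcating star
  g1 <- which(it$label == "g1")
  expect_length(it$children[[g1]], 3)
  expect_true(all(it$children[[g1]] <= it$ntip))
  # g2: single species renamed, no new node
  expect_false("g2" %in% it$label)
  expect_true("g2_a" %in% tree$tip.label)
  # g3: two subclades of two -> two cherries under the genus node
  g3 <- which(it$label == "g3")
  kids <- it$children[[g3]]
  expect_length(kids, 2)
  expect_true(all(lengths(it$children[kids]) == 2))
  # new nodes are undated, backbone nodes keep their ages
  expect_true(is.na(tree$node.age[g1]))
  expect_close(sort(tree$node.age[!is.na(tree$node.age) &
                                    seq_along(tree$node.age) > it$ntip]),
               c(50, 100))
})

test_that("unknown higher taxa are dropped with a warning, not an error", {
  ts <- toy_study()
  ts$species$higher_taxon[2] <- "missing_genus"
  expect_warning(asm <- graft_species(ts$backbone, ts$species), "dropped")
  expect_equal(asm$report$n_unplaced, 1L)
  expect_equal(asm$report$n_assigned, 7L)
  expect_equal(asm$report$n_assigned + asm$report$n_unplaced, nrow(ts$species))
})

test_that("grafting preserves the backbone above the grafts and is reproducible", {
  sc <- scaled_study(n_species = 200, backbone_tips = 25, seed = 4)
  st <- simulate_study(synthetic_config(n_species = 200, backbone_tips = 25,
                                        root_age = 200, seed = 4))
  asm1 <- graft_species(st$backbone, st$species, seed = 9)
  asm2 <- graft_species(st$backbone, st$species, seed = 9)
  expect_identical(write_newick(date_pure_birth(asm1$tree)),
                   write_newick(date_pure_birth(asm2$tree)))
  expect_equal(ape::Ntip(asm1$tree), asm1$report$n_assigned)

  # backbone recovered by keeping one representative per genus
  dated <- date_pure_birth(asm1$tree)
  rep_sp <- st$species[!duplicated(st$species$higher_taxon), ]
  pruned <- ape::keep.tip(dated, rep_sp$species)
  pruned$tip.label <- rep_sp$higher_taxon[match(pruned$tip.label, rep_sp$species)]
  d1 <- ape::cophenetic.phylo(pruned)
  d2 <- ape::cophenetic.phylo(st$backbone)[rownames(d1), colnames(d1)]
  expect_close(d2, d1, tol = 1e-6)
})

test_that("nested subclade paths give stars within stars", {
  backbone <- read_newick("(sup:50,out:50);")
  species <- tibble::tibble(
    species = paste0("s", 1:5),
    higher_taxon = c(rep("sup", 4), "out"),
    subclade = c("genA/grp1", "genA/grp1", "genA", "genB", NA)
  )
  asm <- graft_species(backbone, species)
  it <- edgeprior:::phylo_to_itree(asm$tree)
  sup <- which(it$label == "sup")
  genA <- which(it$label == "genA")
  expect_equal(it$parent[genA], sup)
  # genA holds the grp1 cherry plus its direct species; genB collapsed to tip
  expect_length(it$children[[genA]], 2)
  expect_false("genB" %in% it$label)
})

test_that("orphan assignment policies behave and randomize uniformly", {
  sp <- tibble::tibble(
    species = paste0("x", 1:6),
    higher_taxon = "G",
    subclade = c("a", "b", "c", NA, NA, NA)
  )
  oc <- assign_orphans(sp, "G", mode = "orphan-clade")
  expect_true(all(oc$subclade[4:6] == "G_orphans"))

  one <- tibble::tibble(species = c("y1", "y2"), higher_taxon = "G",
                        subclade = c("only", NA))
  r1 <- assign_orphans(one, "G", mode = "random", seed = 5)
  expect_equal(r1$subclade[2], "only")   # single possible outcome

  expect_error(assign_orphans(tibble::tibble(species = "z", higher_taxon = "G",
                                             subclade = NA_character_),
                              "G", mode = "random"), "no named subclades")

  # frequencies uniform across groups over many seeds
  counts <- table(vapply(1:300, function(s) {
    assign_orphans(sp, "G", mode = "random", seed = s)$subclade[4]
  }, ""))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})
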