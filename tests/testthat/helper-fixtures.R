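# Small fixtures built in code, shared across test files.

# ((A,B),C) ultrametric: cherry at 1, root at 2
three_tip <- function() read_newick("((A:1,B:1):1,C:2);")

# caterpillar (((A,B),C),D), unit branch lengths
caterpillar4 <- function() read_newick("(((A:1,B:1):1,C:2):1,D:3);")

# star of n tips at depth T
star_tree <- function(n, T = 10) {
  read_newick(paste0("(", paste0("t", seq_len(n), ":", T, collapse = ","), ");"))
}

# tiny backbone + species table exercising stars, subclades, monotypes
toy_study <- function() {
  backbone <- read_newick("((g1:50,g2:50):50,g3:100);")
  species <- tibble::tibble(
    species = c("g1_a", "g1_b", "g1_c", "g2_a", "g3_a", "g3_b", "g3_c", "g3_d"),
    higher_taxon = c("g1", "g1", "g1", "g2", "g3", "g3", "g3", "g3"),
    subclade = c(NA, NA, NA, NA, "s1", "s1", "s2", "s2"),
    category = c("LC", "CR", "DD", "EN", "VU", "LC", "DD", "EX")
  )
  list(backbone = backbone, species = species)
}

# dated species-level tree + category table at a given synthetic scale
scaled_study <- function(n_species = 500, backbone_tips = 40, seed = 11,
                         root_age = 200) {
  st <- simulate_study(synthetic_config(n_species = n_species,
                                        backbone_tips = backbone_tips,
                                        root_age = root_age, seed = seed))
  asm <- graft_species(st$backbone, st$species, seed = seed)
  tree <- date_pure_birth(asm$tree)
  list(tree = tree, species = st$species, report = asm$report)
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) <= tol),
              label = paste0(deparse(substitute(object)), " within ", tol))
}
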