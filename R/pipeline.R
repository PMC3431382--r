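#' Run the full prioritization pipeline
#'
#' Orchestrates assemble → date → ED → score → candidate list → curves →
#' (optional) robustness experiments, writing CSV/JSON outputs and a run
#' manifest with input descriptions, seeds, stage timings and md5 checksums
#' of every file written, so deterministic stages can be verified to
#' reproduce bit-identical outputs.
#'
#' The configuration is a YAML file or an equivalent nested list with either
#' * `synthetic:` — arguments for [synthetic_config()], or
#' * `inputs:` — `tree:` a dated species-level Newick file (then scoring
#'   starts from it directly) or `backbone:` + `species:` (Newick +
#'   CSV with columns species, higher_taxon, subclade, category);
#' plus optional `seed:`, `scheme:`, `correction:` (`none`/`polytomy`),
#' `top_fraction:` (candidate list), and `experiments:` — a list of
#' [run_experiment()] argument sets (`kind`, `fraction`, `clades_away`,
#' `n_categories`, `dd_shift`, `replicates`).
#'
#' @param config Path to a YAML file, or a list.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  scheme <- config$scheme %||% "edge_log2"
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inputs <- list()
  if (!is.null(config$synthetic)) {
    cfg <- do.call(synthetic_config, c(config$synthetic, list(seed = seed)))
    st <- stage("generate", simulate_study(cfg))
    backbone <- st$backbone
    species <- st$species
    inputs$synthetic <- config$synthetic
  } else if (!is.null(config$inputs)) {
    inputs <- config$inputs
    if (!is.null(config$inputs$tree)) {
      tree <- stage("read", read_newick(file = config$inputs$tree))
      species <- tibble::as_tibble(utils::read.csv(config$inputs$species,
                                                   stringsAsFactors = FALSE))
      backbone <- NULL
    } else {
      backbone <- read_newick(file = config$inputs$backbone)
      species <- tibble::as_tibble(utils::read.csv(config$inputs$species,
                                                   stringsAsFactors = FALSE))
    }
  } else {
    abort("config must contain a `synthetic` or `inputs` section")
  }

  if (!is.null(backbone)) {
    asm <- stage("assemble", graft_species(backbone, species, seed = seed))
    tree <- stage("date", date_pure_birth(asm$tree))
    report <- asm$report
  } else {
    report <- tibble::tibble(n_assigned = ape::Ntip(tree),
                             n_orphans_randomized = 0L, n_unplaced = 0L,
                             seed = as.integer(seed))
  }

  correction <- config$correction %||% "polytomy"
  ed <- stage("ed", {
    if (identical(correction, "none")) ed_fair_proportion(tree)
    else ed_polytomy_corrected(tree, seed = seed)
  })
  tab <- dplyr::left_join(ed,
                          species[, intersect(c("species", "category"), names(species))],
                          by = "species")
  scored <- stage("score", edge_scores(tab, quiet = TRUE))
  cand <- stage("candidates", candidate_list(tab, config$top_fraction %||% 0.05))
  curves <- stage("curves", running_mean_ed(scored,
                                            n_max = min(100, nrow(scored))))

  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit(scored, "scores.csv")
  emit(cand, "candidate_list.csv")
  emit(as.data.frame(curves), "running_mean_ed.csv")
  emit(report, "assembly_report.csv")
  tree_path <- file.path(out_dir, "tree.nwk")
  write_newick(tree, tree_path)
  files <- c(files, tree_path)

  if (!is.null(config$experiments)) {
    glances <- purrr::imap(config$experiments, function(ex, i) {
      args <- c(list(tree = tree, species = tab[, c("species", "category")],
                     scheme = scheme,
                     seed = seed + as.integer(i)), ex)
      glance(stage(paste0("experiment_", i), do.call(run_experiment, args)))
    })
    emit(dplyr::bind_rows(glances), "experiments.csv")
  }

  manifest <- list(
    package = "edgeprior",
    version = as.character(utils::packageVersion("edgeprior")),
    seed = seed, scheme = scheme, correction = correction,
    inputs = inputs,
    stage_timings_s = timings,
    outputs = lapply(setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
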