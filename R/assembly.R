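#' Assign orphan species of a genus to subclades
#'
#' Species tables often resolve only part of a genus into subgenera or species
#' groups, leaving "orphan" species assigned to the genus but to no subclade.
#' Two placement policies are supported: collect all orphans into a fresh
#' shared `"<genus>_orphans"` clade (used for large genera where orphans are a
#' substantial fraction), or scatter each orphan uniformly at random across
#' the genus's existing subclades (used where the orphan fraction is small).
#'
#' @param species Data frame with columns `species`, `higher_taxon` and
#'   (optionally) `subclade`; missing or empty `subclade` marks an orphan.
#' @param genus Value of `higher_taxon` selecting the genus to process.
#' @param mode `"orphan-clade"` or `"random"`.
#' @param seed Integer seed making `"random"` assignments reproducible.
#' @return The species tibble with orphan rows of `genus` given a `subclade`,
#'   and a logical `orphan_assigned` column marking them.
#' @export
#' @examples
#' sp <- tibble::tibble(
#'   species = c("G_a", "G_b", "G_c"),
#'   higher_taxon = "GenusX",
#'   subclade = c("grp1", NA, NA)
#' )
#' assign_orphans(sp, "GenusX", mode = "random", seed = 1)
assign_orphans <- function(species, genus, mode = c("orphan-clade", "random"),
                           seed = NULL) {
  mode <- match.arg(mode)
  species <- tibble::as_tibble(species)
  if (!"subclade" %in% names(species)) species$subclade <- NA_character_
  if (!"orphan_assigned" %in% names(species)) species$orphan_assigned <- FALSE
  in_genus <- species$higher_taxon == genus
  if (!any(in_genus)) abort(paste0("no species assigned to '", genus, "'"))
  orphan <- in_genus & (is.na(species$subclade) | !nzchar(species$subclade))
  if (!any(orphan)) return(species)
  if (mode == "orphan-clade") {
    species$subclade[orphan] <- paste0(genus, "_orphans")
  } else {
    pool <- unique(species$subclade[in_genus & !is.na(species$subclade) &
                                      nzchar(species$subclade)])
    if (length(pool) == 0) {
      abort(paste0("'", genus, "' has no named subclades to sample from"))
    }
    draw <- function() sample(pool, sum(orphan), replace = TRUE)
    species$subclade[orphan] <- if (is.null(seed)) draw() else
      withr::with_seed(seed, draw())
  }
  species$orphan_assigned[orphan] <- TRUE
  species
}

# Nested grouping of one higher taxon's species by their subclade path.
# Returns a list of units; each unit is either
#   list(kind = "tip", species = <name>) or
#   list(kind = "node", label = <group>, units = <list of units>).
# A group resolving to a single species collapses to a plain tip unit.
group_units <- function(sp, paths) {
  direct <- lengths(paths) == 0L
  units <- lapply(sp[direct], function(s) list(kind = "tip", species = s))
  if (any(!direct)) {
    first <- vapply(paths[!direct], `[[`, "", 1L)
    for (g in unique(first)) {
      sel <- which(!direct)[first == g]
      sub <- group_units(sp[sel], lapply(paths[sel], function(p) p[-1L]))
      units <- c(units, list(
        if (length(sub) == 1L && sub[[1L]]$kind == "tip") sub[[1L]]
        else list(kind = "node", label = g, units = sub)
      ))
    }
  }
  units
}

count_group_nodes <- function(units) {
  sum(vapply(units, function(u) {
    if (u$kind == "tip") 0L else 1L + count_group_nodes(u$units)
  }, integer(1)))
}

count_group_tips <- function(units) {
  sum(vapply(units, function(u) {
    if (u$kind == "tip") 1L else count_group_tips(u$units)
  }, integer(1)))
}

#' Graft a species table onto a dated higher-taxon backbone
#'
#' Every backbone tip carrying `k >= 2` assigned species becomes an internal
#' node whose children are those species — a star polytomy, or nested stars
#' when `subclade` labels are present (subclades are treated as monophyletic;
#' nested paths such as `"Genus/Group"` give stars within stars, which is how
#' suprageneric backbone tips are handled). Backbone tips with exactly one
#' assigned species are renamed to that species. New internal nodes are left
#' undated (`NA` in `node.age`) for [date_pure_birth()]; backbone node ages
#' are preserved, so grafting never alters the backbone topology or dates.
#'
#' Species whose `higher_taxon` matches no backbone tip are dropped with a
#' warning and counted in the report rather than aborting the assembly,
#' mirroring how class-wide syntheses handle unplaceable taxa.
#'
#' @param backbone Dated ultrametric `phylo`; tip labels are higher taxa.
#' @param species Data frame with columns `species`, `higher_taxon`, optional
#'   `subclade` (use `/` for nested paths) and optional `category`.
#' @param seed Integer recorded in the report (grafting itself is
#'   deterministic; randomness enters only via [assign_orphans()]).
#' @return List with `tree` (a `phylo` with a `node.age` component, `NA` at
#'   new nodes) and `report` (one-row tibble: `n_assigned`,
#'   `n_orphans_randomized`, `n_unplaced`, `seed`).
#' @export
graft_species <- function(backbone, species, seed = NULL) {
  stopifnot(inherits(backbone, "phylo"))
  species <- tibble::as_tibble(species)
  for (col in c("species", "higher_taxon")) {
    if (!col %in% names(species)) abort(paste0("species table lacks column '", col, "'"))
  }
  if (anyDuplicated(species$species)) {
    abort("duplicate species names in the species table")
  }
  if (!"subclade" %in% names(species)) species$subclade <- NA_character_
  if ("category" %in% names(species)) check_category(species$category)

  placed <- species$higher_taxon %in% backbone$tip.label
  if (any(!placed)) {
    warn(paste0(sum(!placed), " species had an unknown higher_taxon and were dropped"))
  }
  sp <- species[placed, ]
  bt <- phylo_to_itree(backbone)
  b_ntip <- bt$ntip
  b_nnode <- length(bt$parent) - b_ntip

  # per backbone tip: nested grouping of its species
  idx_by_tip <- split(seq_len(nrow(sp)), factor(sp$higher_taxon, levels = bt$label[seq_len(b_ntip)]))
  groupings <- vector("list", b_ntip)
  n_new_nodes <- 0L
  for (i in seq_len(b_ntip)) {
    rows <- idx_by_tip[[i]]
    if (length(rows) < 2L) next
    paths <- strsplit(ifelse(is.na(sp$subclade[rows]) | !nzchar(sp$subclade[rows]),
                             "", sp$subclade[rows]), "/", fixed = TRUE)
    paths <- lapply(paths, function(p) p[nzchar(p)])
    groupings[[i]] <- group_units(sp$species[rows], paths)
    n_new_nodes <- n_new_nodes + 1L + count_group_nodes(groupings[[i]])
  }

  n_multi_tips <- sum(vapply(groupings, function(g) if (is.null(g)) 0L else count_group_tips(g), integer(1)))
  n_single <- sum(lengths(idx_by_tip) == 1L)
  n_empty <- sum(lengths(idx_by_tip) == 0L)
  new_ntip <- n_multi_tips + n_single + n_empty
  N <- new_ntip + b_nnode + n_new_nodes
  it <- itree_new(new_ntip, b_nnode + n_new_nodes)

  # backbone internal nodes keep their relative ids (and ages)
  map_int <- function(b_id) new_ntip + (b_id - b_ntip)
  internal_ids <- (b_ntip + 1L):(b_ntip + b_nnode)
  it$age[map_int(internal_ids)] <- bt$age[internal_ids]
  it$label[map_int(internal_ids)] <- bt$label[internal_ids]
  it$root <- map_int(bt$root)

  tip_cursor <- 0L
  node_cursor <- new_ntip + b_nnode
  add_tip <- function(label, parent) {
    tip_cursor <<- tip_cursor + 1L
    it$label[tip_cursor] <<- label
    it$age[tip_cursor] <<- 0
    it$parent[tip_cursor] <<- parent
    it$children[[parent]] <<- c(it$children[[parent]], tip_cursor)
    tip_cursor
  }
  add_node <- function(label, parent) {
    node_cursor <<- node_cursor + 1L
    it$label[node_cursor] <<- label
    it$parent[node_cursor] <<- parent
    it$children[[parent]] <<- c(it$children[[parent]], node_cursor)
    node_cursor
  }
  build_units <- function(units, parent) {
    for (u in units) {
      if (u$kind == "tip") {
        add_tip(u$species, parent)
      } else {
        nd <- add_node(u$label, parent)
        build_units(u$units, nd)
      }
    }
  }

  for (i in seq_len(b_ntip)) {
    parent <- map_int(bt$parent[i])
    rows <- idx_by_tip[[i]]
    if (length(rows) == 0L) {
      add_tip(bt$label[i], parent)          # empty higher taxon stays a tip
    } else if (length(rows) == 1L) {
      add_tip(sp$species[rows], parent)     # monotypic: rename only
    } else {
      genus_node <- add_node(bt$label[i], parent)
      build_units(groupings[[i]], genus_node)
    }
  }
  # children of backbone internal nodes that are themselves internal
  for (b_id in internal_ids) {
    kids <- bt$children[[b_id]]
    kid_internal <- kids[kids > b_ntip]
    # order: internal children appended after grafted tips is irrelevant to
    # the model; preserve backbone order for internal-internal edges
    it$children[[map_int(b_id)]] <- c(it$children[[map_int(b_id)]], map_int(kid_internal))
    it$parent[map_int(kid_internal)] <- map_int(b_id)
  }

  tree <- itree_to_phylo(it)
  n_orph <- if ("orphan_assigned" %in% names(species)) sum(species$orphan_assigned[placed]) else 0L
  report <- tibble::tibble(
    n_assigned = nrow(sp),
    n_orphans_randomized = as.integer(n_orph),
    n_unplaced = sum(!placed),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  list(tree = tree, report = report)
}
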