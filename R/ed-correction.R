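# Expected ED shares over random dated resolutions of a polytomy.
#
# A polytomy node of age T with children c_1..c_k is treated as k "units";
# unit j subtends m_j tips and has age age_j. A resolution is a labeled
# rooted binary topology on the k units; its internal nodes are dated
# top-down by the pure-birth interpolation (age = T_parent * ln(a)/ln(b)
# with a, b the tip totals below node and parent), floored at the oldest
# unit it contains so pre-dated child clades never get a negative branch.
# For each resolution, every tip below unit j receives
#   sum over edges on the root-to-unit-j path of (edge length / tips below)
# and the correction is the (weighted) mean of that per-tip share.
#
# Topologies are weighted uniformly, or by their pure-birth probability
# (proportional to prod over internal nodes of 1/(units below - 1)).

# --- topology enumeration (nested pair lists; leaf = unit index) ----------

# every way of inserting `leaf` on an edge of `tree` (root edge included)
all_attach <- function(tree, leaf) {
  out <- list(list(tree, leaf))
  if (is.list(tree)) {
    for (t2 in all_attach(tree[[1]], leaf)) out <- c(out, list(list(t2, tree[[2]])))
    for (t2 in all_attach(tree[[2]], leaf)) out <- c(out, list(list(tree[[1]], t2)))
  }
  out
}

enumerate_topologies <- function(k) {
  key <- as.character(k)
  if (!is.null(the$topo[[key]])) return(the$topo[[key]])
  trees <- list(1L)
  if (k >= 2) {
    for (j in 2:k) {
      trees <- unlist(lapply(trees, all_attach, leaf = j), recursive = FALSE)
    }
  }
  if (is.null(the$topo)) the$topo <- list()
  if (k <= 7) the$topo[[key]] <- trees
  trees
}

n_leaves_nested <- function(tree) {
  if (!is.list(tree)) return(1L)
  n_leaves_nested(tree[[1]]) + n_leaves_nested(tree[[2]])
}

# Random labeled topologies as parent vectors (nodes 1..k are the units,
# internal nodes k+1..2k-1 are created as needed; root has parent 0).
# Uniform law: sequential insertion of unit j above a uniformly chosen
# existing node (each node stands for its parent edge; the root stands for
# the root edge), which yields the uniform distribution over the
# (2k-3)!! labeled topologies. Pure-birth law: repeated uniform pairwise
# joins (pure-birth and coalescent induce the same labeled-topology law).
sample_parents_uniform <- function(k) {
  n <- 2L * k - 1L
  parent <- integer(n)
  nodes <- integer(n)      # nodes currently in the tree
  nodes[1] <- 1L
  n_nodes <- 1L
  nxt <- k
  for (j in 2:k) {
    x <- nodes[sample.int(n_nodes, 1L)]
    nxt <- nxt + 1L        # new internal node above x
    parent[nxt] <- parent[x]
    parent[x] <- nxt
    parent[j] <- nxt
    nodes[n_nodes + 1L] <- j
    nodes[n_nodes + 2L] <- nxt
    n_nodes <- n_nodes + 2L
  }
  parent
}

sample_parents_yule <- function(k) {
  n <- 2L * k - 1L
  parent <- integer(n)
  roots <- seq_len(k)      # current forest roots
  nxt <- k
  while (length(roots) > 1L) {
    pair <- sample.int(length(roots), 2L)
    nxt <- nxt + 1L
    parent[roots[pair]] <- nxt
    roots <- c(roots[-pair], nxt)
  }
  parent
}

# per-unit per-tip shares for one parent-vector topology, O(k)
parent_vector_shares <- function(parent, m, ages, T_par) {
  k <- length(m)
  n <- length(parent)
  root <- which(parent == 0L)
  kids <- split_children(cbind(parent[-root], seq_len(n)[-root]), n)
  # postorder via preorder reversal
  ord <- integer(n)
  stack <- integer(n)
  stack[1] <- root
  sp <- 1L; cnt <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    cnt <- cnt + 1L
    ord[cnt] <- v
    for (ch in kids[[v]]) {
      sp <- sp + 1L
      stack[sp] <- ch
    }
  }
  msum <- c(m, numeric(n - k))
  maxage <- c(ages, numeric(n - k))
  for (v in rev(ord)) {
    p <- parent[v]
    if (p > 0L) {
      msum[p] <- msum[p] + msum[v]
      maxage[p] <- max(maxage[p], maxage[v])
    }
  }
  age <- numeric(n)
  contrib <- numeric(n)
  cum <- numeric(n)
  age[root] <- T_par
  for (v in ord) {
    p <- parent[v]
    if (p == 0L) next
    if (v <= k) {
      age[v] <- ages[v]
      contrib[v] <- (age[p] - age[v]) / m[v]
    } else {
      a <- age[p] * log(msum[v]) / log(msum[p])
      age[v] <- min(max(a, maxage[v]), age[p])
      contrib[v] <- (age[p] - age[v]) / msum[v]
    }
    cum[v] <- cum[p] + contrib[v]
  }
  cum[seq_len(k)]
}

# --- dating a resolution and collecting per-unit shares -------------------

# returns list(shares = numeric k (per-tip share for each unit),
#              logw = log pure-birth weight of the topology)
resolution_shares <- function(topo, m, ages, T_par) {
  k <- length(m)
  shares <- numeric(k)
  logw <- 0
  walk <- function(node, parent_age, parent_m) {
    if (!is.list(node)) {
      j <- node
      shares[j] <<- shares[j] + (parent_age - ages[j]) / m[j]
      return(list(msum = m[j], maxage = ages[j], units = j, nunits = 1L))
    }
    # subtree summaries first (cheap, k is small)
    info_l <- subtree_info(node[[1]])
    info_r <- subtree_info(node[[2]])
    msum <- info_l$msum + info_r$msum
    nunits <- info_l$nunits + info_r$nunits
    maxage <- max(info_l$maxage, info_r$maxage)
    age <- parent_age * log(msum) / log(parent_m)
    age <- min(max(age, maxage), parent_age)
    units <- c(info_l$units, info_r$units)
    shares[units] <<- shares[units] + (parent_age - age) / msum
    logw <<- logw - log(nunits - 1L)
    walk(node[[1]], age, msum)
    walk(node[[2]], age, msum)
    list(msum = msum, maxage = maxage, units = units, nunits = nunits)
  }
  subtree_info <- function(node) {
    if (!is.list(node)) {
      return(list(msum = m[node], maxage = ages[node], units = node, nunits = 1L))
    }
    l <- subtree_info(node[[1]])
    r <- subtree_info(node[[2]])
    list(msum = l$msum + r$msum, maxage = max(l$maxage, r$maxage),
         units = c(l$units, r$units), nunits = l$nunits + r$nunits)
  }
  if (!is.list(topo)) {
    # single unit: no resolution needed; its pendant share is the star share
    shares[topo] <- (T_par - ages[topo]) / m[topo]
    return(list(shares = shares, logw = 0))
  }
  # root of the resolution is the polytomy node itself (age T_par)
  info_l <- subtree_info(topo[[1]])
  info_r <- subtree_info(topo[[2]])
  total_m <- info_l$msum + info_r$msum
  logw <- -log(k - 1L)
  walk(topo[[1]], T_par, total_m)
  walk(topo[[2]], T_par, total_m)
  list(shares = shares, logw = logw)
}

# expected per-tip share for each unit of a polytomy
expected_unit_shares <- function(m, ages, T_par, weights = "uniform",
                                 n_samples = 1000, max_exact = 7) {
  k <- length(m)
  stopifnot(k >= 2, length(ages) == k)
  if (k <= max_exact) {
    topos <- enumerate_topologies(k)
    acc <- numeric(k)
    wsum <- 0
    for (tp in topos) {
      r <- resolution_shares(tp, m, ages, T_par)
      w <- if (weights == "yule") exp(r$logw) else 1
      acc <- acc + w * r$shares
      wsum <- wsum + w
    }
    acc / wsum
  } else {
    sampler <- if (weights == "yule") sample_parents_yule else sample_parents_uniform
    acc <- numeric(k)
    for (i in seq_len(n_samples)) {
      acc <- acc + parent_vector_shares(sampler(k), m, ages, T_par)
    }
    acc / n_samples
  }
}

# Expected per-tip share for a pure star of k tips at unit depth (T = 1).
# Deterministic: exact below the cutoff, and Monte-Carlo with a fixed
# internal seed (isolated from the caller's RNG) above it; cached.
star_share <- function(k, weights = "uniform", n_samples = 1000, max_exact = 7) {
  key <- paste(weights, k, n_samples, max_exact, sep = "|")
  if (is.null(the$star)) the$star <- list()
  if (!is.null(the$star[[key]])) return(the$star[[key]])
  m <- rep(1L, k)
  ages <- rep(0, k)
  val <- if (k <= max_exact) {
    mean(expected_unit_shares(m, ages, 1, weights = weights,
                              n_samples = n_samples, max_exact = max_exact))
  } else {
    withr::with_seed(7000L + k, {
      mean(expected_unit_shares(m, ages, 1, weights = weights,
                                n_samples = n_samples, max_exact = max_exact))
    })
  }
  the$star[[key]] <- val
  val
}
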