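#' Available ED-by-threat weighting schemes
#'
#' Five ways of combining ED with Red List category:
#' * `edge_log2`, `edge_log125`, `edge_log5` — the EDGE family,
#'   `ln(1 + ED) + GE * ln(f)` with fold-increase `f` of 2, 1.25 or 5 per
#'   category step (GE = 0..4 for LC..CR);
#' * `exp_loss` — expected loss, `ED * p100` with 100-year extinction
#'   probabilities 0.001, 0.01, 0.1, 0.67, 0.999 for LC, NT, VU, EN, CR;
#' * `iucn500` — the 500-year variant with probabilities
#'   0.005, 0.05, 0.39, 0.996, 1.
#'
#' @return Character vector of scheme identifiers.
#' @export
edge_scheme_names <- function() {
  c("edge_log2", "edge_log125", "edge_log5", "exp_loss", "iucn500")
}

el_probs <- c(LC = 0.001, NT = 0.01, VU = 0.1, EN = 0.67, CR = 0.999)
iucn500_probs <- c(LC = 0.005, NT = 0.05, VU = 0.39, EN = 0.996, CR = 1)

# score vector for one scheme; category must be LC/NT/VU/EN/CR
scheme_score <- function(scheme, ed, category) {
  ge <- ge_of(category)
  switch(scheme,
    edge_log2   = log1p(ed) + ge * log(2),
    edge_log125 = log1p(ed) + ge * log(1.25),
    edge_log5   = log1p(ed) + ge * log(5),
    exp_loss    = ed * unname(el_probs[category]),
    iucn500     = ed * unname(iucn500_probs[category]),
    abort(paste0("unknown scheme '", scheme, "'; see edge_scheme_names()"))
  )
}

# deterministic priority order: score desc, then ED desc, then name
priority_order <- function(score, ed, species) order(-score, -ed, species)

#' Score and rank species under ED-by-threat weighting schemes
#'
#' Data Deficient and Extinct species carry no threat weight and are excluded
#' from scoring (their count is reported via a message); use
#' [candidate_list()] to surface high-ED Data Deficient species instead.
#' Ranks are a permutation of `1..n_scored` per scheme; ties are broken by
#' higher ED, then species name, so ranked lists are reproducible.
#'
#' @param data Data frame with columns `species`, `ed`, `category`.
#' @param schemes Scheme identifiers (see [edge_scheme_names()]); defaults to
#'   all five.
#' @param quiet Suppress the exclusion message.
#' @return Tibble with `species`, `ed`, `category`, `ge` and, per scheme,
#'   `score_<scheme>` and `rank_<scheme>` columns.
#' @export
#' @examples
#' tab <- tibble::tibble(species = c("a", "b"), ed = c(20, 5),
#'                       category = c("CR", "LC"))
#' edge_scores(tab, "edge_log2")
edge_scores <- function(data, schemes = edge_scheme_names(), quiet = FALSE) {
  data <- tibble::as_tibble(data)
  for (col in c("species", "ed", "category")) {
    if (!col %in% names(data)) abort(paste0("`data` lacks column '", col, "'"))
  }
  check_category(data$category)
  schemes <- match.arg(schemes, edge_scheme_names(), several.ok = TRUE)
  excl <- data$category %in% c("DD", "EX")
  if (any(excl) && !quiet) {
    message(sum(data$category == "DD"), " DD and ", sum(data$category == "EX"),
            " EX species excluded from scoring")
  }
  out <- data[!excl, c("species", "ed", "category")]
  out$ge <- ge_of(out$category)
  for (s in schemes) {
    sc <- scheme_score(s, out$ed, out$category)
    rk <- integer(nrow(out))
    rk[priority_order(sc, out$ed, out$species)] <- seq_len(nrow(out))
    out[[paste0("score_", s)]] <- sc
    out[[paste0("rank_", s)]] <- rk
  }
  out
}

#' Data Deficient candidate list
#'
#' Data Deficient species cannot be EDGE-ranked, but those in the top
#' fraction of the all-species ED distribution are flagged as candidates for
#' urgent assessment: if found threatened they would enter the priority list
#' near its head.
#'
#' @param data Data frame with `species`, `ed`, `category` for *all* species
#'   (DD included; the ED quantile is taken over every species).
#' @param top_fraction ED quantile defining "high ED" (default 0.05: the top
#'   5%, i.e. ED at or above the 95th percentile).
#' @return Tibble of DD species with `ed` at/above the threshold, ordered by
#'   descending ED, with a `rank` column; the threshold is attached as the
#'   `"ed_threshold"` attribute.
#' @export
candidate_list <- function(data, top_fraction = 0.05) {
  data <- tibble::as_tibble(data)
  check_category(data$category)
  thr <- unname(quantile(data$ed, 1 - top_fraction, names = FALSE))
  out <- data[data$category == "DD" & data$ed >= thr, c("species", "ed")]
  out <- out[order(-out$ed, out$species), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "ed_threshold") <- thr
  out
}

#' Running mean ED of the top-n priority species, with envelope bounds
#'
#' For each scheme, ranks species and reports the mean ED of the top `n`
#' species for `n = 1..n_max`, together with the two bounding curves: the
#' upper bound ranks purely by ED; the lower bound selects all CR species in
#' decreasing ED order, then EN, and so on down the threat scale. Curves
#' summarise how even-handedly a scheme trades distinctiveness against
#' threat.
#'
#' @param data Scored table from [edge_scores()], or a raw `species`/`ed`/
#'   `category` table (scored on the fly).
#' @param schemes Scheme identifiers to include (default: all five).
#' @param n_max Largest list size (default 100); truncated with a warning if
#'   it exceeds the number of scored species.
#' @return An `edge_curves` tibble (long): `scheme`, `n`, `mean_ed`, where
#'   `scheme` includes `upper_bound` and `lower_bound`.
#' @export
running_mean_ed <- function(data, schemes = edge_scheme_names(), n_max = 100) {
  data <- tibble::as_tibble(data)
  if (!all(paste0("rank_", schemes) %in% names(data))) {
    data <- edge_scores(data, schemes, quiet = TRUE)
  }
  n <- nrow(data)
  if (n_max > n) {
    warn(paste0("n_max = ", n_max, " exceeds the ", n,
                " scored species; truncating"))
    n_max <- n
  }
  run_mean <- function(ord) cumsum(data$ed[ord])[seq_len(n_max)] / seq_len(n_max)
  curves <- purrr::map(schemes, function(s) {
    tibble::tibble(scheme = s, n = seq_len(n_max),
                   mean_ed = run_mean(order(data[[paste0("rank_", s)]])))
  })
  upper <- order(-data$ed, data$species)
  sev <- ge_of(data$category)
  lower <- order(-sev, -data$ed, data$species)
  curves <- c(curves, list(
    tibble::tibble(scheme = "upper_bound", n = seq_len(n_max), mean_ed = run_mean(upper)),
    tibble::tibble(scheme = "lower_bound", n = seq_len(n_max), mean_ed = run_mean(lower))
  ))
  out <- dplyr::bind_rows(curves)
  class(out) <- c("edge_curves", class(out))
  out
}
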