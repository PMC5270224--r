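#' Consensus chromatin state of a region
#'
#' The modal state across biological replicates if that state is observed in
#' at least 80% of them, otherwise `"variable"` (dynamic local chromatin).
#' Modal ties are by definition below the threshold and yield `"variable"`.
#'
#' @param states Character vector of per-replicate state calls (>= 5
#'   replicates).
#' @param min_frac Consensus threshold on the modal replicate fraction.
#' @return A single state label or `"variable"`.
#' @export
consensus_state <- function(states, min_frac = 0.8) {
  if (length(states) < 5)
    stop("consensus calling requires at least 5 replicates")
  tab <- table(states)
  top <- max(tab)
  if (sum(tab == top) > 1) return("variable")
  if (top / length(states) >= min_frac) names(tab)[which.max(tab)]
  else "variable"
}

#' Consensus states for all regions in a calls table
#'
#' @param calls Data frame with `region_id`, `replicate_id`, `state`.
#' @param min_frac Passed to [consensus_state()].
#' @return Data frame `region_id`, `consensus`.
#' @export
consensus_state_table <- function(calls, min_frac = 0.8) {
  out <- vapply(split(calls$state, calls$region_id),
                consensus_state, character(1), min_frac = min_frac)
  data.frame(region_id = names(out), consensus = unname(out),
             row.names = NULL)
}

#' Hypergeometric enrichment / depletion test
#'
#' For a set of `n_set` features of which `k_set` carry a category, against
#' a background of `n_bg` features with `k_bg` carriers:
#' `p_enrich = P(X >= k_set)` and `p_deplete = P(X <= k_set)` for
#' `X ~ Hypergeometric(n_bg, k_bg, n_set)`, plus the fold ratio of carrier
#' rates.
#'
#' @param k_set,n_set,k_bg,n_bg Counts as above.
#' @return List with `p_enrich`, `p_deplete`, `fold`.
#' @export
hypergeom_enrichment <- function(k_set, n_set, k_bg, n_bg) {
  if (k_set > n_set || n_set > n_bg || k_set > k_bg || k_bg > n_bg ||
      any(c(k_set, n_set, k_bg, n_bg) < 0))
    stop("inconsistent counts")
  p_enrich <- stats::phyper(k_set - 1, k_bg, n_bg - k_bg, n_set,
                            lower.tail = FALSE)
  p_deplete <- stats::phyper(k_set, k_bg, n_bg - k_bg, n_set)
  fold <- if (k_bg == 0) NaN else (k_set / n_set) / (k_bg / n_bg)
  list(p_enrich = p_enrich, p_deplete = p_deplete, fold = fold)
}

#' Enrichment by repeated random sampling
#'
#' Draws `n_resamples` random subsets of the size of the feature set from
#' the background (all features that passed quality control) without
#' replacement, and compares the observed number of category carriers with
#' the resampled distribution. The empirical p uses add-one smoothing so it
#' is never exactly zero.
#'
#' @param set Character vector of feature ids (must be a subset of the
#'   background).
#' @param background Character vector of all QC-passing feature ids.
#' @param categories Character vector of category labels aligned to
#'   `background`.
#' @param category The category tested.
#' @param n_resamples Number of random draws.
#' @param seed Integer seed (resampling is deterministic given it).
#' @return List mirroring an enrichment-result row: `category`, `n_set`,
#'   `k_set`, `n_background`, `k_background`, `fold`, `p_enrich`,
#'   `p_deplete`, `p_empirical`, `n_resamples`, `seed`.
#' @export
resampling_enrichment <- function(set, background, categories, category,
                                  n_resamples = 1000, seed = 1) {
  if (!all(set %in% background))
    stop("the feature set must be a subset of the background")
  if (length(categories) != length(background))
    stop("'categories' must align with 'background'")
  carrier <- categories == category
  if (!any(carrier)) stop("category absent from background")
  k_obs <- sum(carrier[match(set, background)])
  n_set <- length(set)
  n_bg <- length(background)
  k_bg <- sum(carrier)
  set.seed(seed)
  k_res <- vapply(seq_len(n_resamples), function(i) {
    sum(carrier[sample.int(n_bg, n_set)])
  }, numeric(1))
  hg <- hypergeom_enrichment(k_obs, n_set, k_bg, n_bg)
  list(
    category = category,
    n_set = n_set,
    k_set = k_obs,
    n_background = n_bg,
    k_background = k_bg,
    fold = if (mean(k_res) > 0) k_obs / mean(k_res) else NaN,
    p_enrich = hg$p_enrich,
    p_deplete = hg$p_deplete,
    p_empirical = (1 + sum(k_res >= k_obs)) / (n_resamples + 1),
    p_empirical_deplete = (1 + sum(k_res <= k_obs)) / (n_resamples + 1),
    n_resamples = n_resamples,
    seed = seed
  )
}

#' Enrichment of a feature set over every category of an annotation system
#'
#' Runs [resampling_enrichment()] for each category present in the
#' background (genomic feature, gene element, or chromatin-state systems are
#' evaluated independently), with BH adjustment of the hypergeometric
#' enrichment p across the categories of the system.
#'
#' @inheritParams resampling_enrichment
#' @return Data frame, one row per category.
#' @export
enrich_categories <- function(set, background, categories,
                              n_resamples = 1000, seed = 1) {
  cats <- sort(unique(categories))
  rows <- lapply(seq_along(cats), function(i) {
    as.data.frame(resampling_enrichment(set, background, categories, cats[i],
                                        n_resamples = n_resamples,
                                        seed = seed + i))
  })
  out <- do.call(rbind, rows)
  out$q_enrich <- bh_adjust(out$p_enrich)
  out$q_deplete <- bh_adjust(out$p_deplete)
  out
}
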