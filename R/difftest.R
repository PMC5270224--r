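#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; NA p-values are excluded from the family size and
#' propagated as NA.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(q) <- names(p)
  q
}

#' Paired moderated test of differential variability
#'
#' The paired deviation test at the core of the combined approach. For each
#' feature, donor-wise differences of absolute deviations
#' `z_i = absdev_A[donor i] - absdev_B[donor i]` are tested with a one-sample
#' moderated t: `t = mean(z) / (s_tilde / sqrt(n))`, where the posterior
#' variance shrinks the per-feature variance of z toward an empirical-Bayes
#' prior estimated across features. Two-sided p-values use `d0 + n - 1`
#' degrees of freedom. Only donors present in both cell types are used.
#'
#' @param absdev_a,absdev_b Feature-by-sample matrices of absolute deviations
#'   (see [group_stats()]) with donor ids as column names.
#' @param d0 `NULL` to estimate the prior from the data (default); `0`
#'   disables moderation (classical paired t).
#' @return Data frame: `feature_id`, `mean_absdev_diff`, `t`, `p`, `q`, with
#'   attributes `n_pairs`, `n_dropped` (donors missing one sample) and
#'   `moderation` (the prior parameters used).
#' @export
paired_diffvar_test <- function(absdev_a, absdev_b, d0 = NULL) {
  if (!identical(rownames(absdev_a), rownames(absdev_b)))
    stop("feature universes differ between the two groups")
  donors <- intersect(colnames(absdev_a), colnames(absdev_b))
  n_dropped <- length(union(colnames(absdev_a), colnames(absdev_b))) -
    length(donors)
  n <- length(donors)
  if (n < 4)
    stop("fewer than 4 complete donor pairs")
  if (n_dropped > 0)
    message(sprintf("dropping %d donors without both samples", n_dropped))
  z <- absdev_a[, donors, drop = FALSE] - absdev_b[, donors, drop = FALSE]
  zbar <- rowMeans(z)
  s2 <- rowSums((z - zbar) ^ 2) / (n - 1)
  if (is.null(d0)) {
    params <- estimate_moderation(s2, df = n - 1)
  } else if (identical(d0, 0) || identical(d0, 0L)) {
    params <- list(d0 = 0, s0_sq = NA_real_, df = n - 1)
  } else {
    stop("'d0' must be NULL (estimate) or 0 (no moderation)")
  }
  s2_tilde <- moderate_var(s2, params)
  se <- sqrt(s2_tilde / n)
  t_stat <- ifelse(se > 0, zbar / se,
                   ifelse(zbar == 0, 0, sign(zbar) * Inf))
  df_total <- params$d0 + (n - 1)
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  res <- data.frame(
    feature_id = rownames(absdev_a),
    mean_absdev_diff = zbar,
    t = t_stat,
    p = p,
    q = bh_adjust(p),
    row.names = NULL
  )
  attr(res, "n_pairs") <- n
  attr(res, "n_dropped") <- n_dropped
  attr(res, "moderation") <- params
  res
}

#' Combined hypervariability decision for one contrast
#'
#' A feature is called hypervariable in cell type A versus B iff the BH-
#' adjusted p of the paired deviation test is below `alpha`, the EV/MV
#' difference `ev_a - ev_b` is at least `rel_delta` of the observed range of
#' the pooled EV/MV values of both cell types, and the deviation difference
#' agrees in sign. Symmetric for B.
#'
#' @param q BH-adjusted p-values from [paired_diffvar_test()].
#' @param ev_a,ev_b Variability scores of the two cell types (same features).
#' @param mean_absdev_diff Mean donor-wise absolute-deviation difference
#'   (A minus B).
#' @param alpha Significance level on q.
#' @param rel_delta Minimum EV difference relative to the pooled range.
#' @return Character vector with values `"up_in_a"`, `"up_in_b"`, `"none"`,
#'   with attribute `delta` (the absolute EV-difference threshold used).
#' @export
combined_decision <- function(q, ev_a, ev_b, mean_absdev_diff,
                              alpha = 0.05, rel_delta = 0.10) {
  pooled <- range(c(ev_a, ev_b), na.rm = TRUE)
  delta <- rel_delta * (pooled[2] - pooled[1])
  if (delta == 0)
    warning("degenerate pooled EV range; delta threshold is 0")
  ev_diff <- ev_a - ev_b
  sig <- !is.na(q) & q < alpha
  call <- rep("none", length(q))
  call[sig & ev_diff >= delta & mean_absdev_diff > 0] <- "up_in_a"
  call[sig & -ev_diff >= delta & mean_absdev_diff < 0] <- "up_in_b"
  attr(call, "delta") <- delta
  call
}

#' Run one full pairwise contrast
#'
#' Paired moderated deviation test plus the combined decision rule for a
#' pair of cell types, given their per-cell-type variability results.
#'
#' @param vt_a,vt_b Results of [variability_table()] for the two cell types.
#' @param cells Character vector of the two cell-type labels `c(A, B)`.
#' @param alpha,rel_delta,d0 Passed to [combined_decision()] and
#'   [paired_diffvar_test()].
#' @return Data frame with feature_id, cell_a, cell_b, mean_absdev_diff, t,
#'   p, q, ev_diff and call.
#' @export
contrast_cells <- function(vt_a, vt_b, cells,
                           alpha = 0.05, rel_delta = 0.10, d0 = NULL) {
  tst <- paired_diffvar_test(vt_a$absdev, vt_b$absdev, d0 = d0)
  call <- combined_decision(tst$q, vt_a$table$ev, vt_b$table$ev,
                            tst$mean_absdev_diff,
                            alpha = alpha, rel_delta = rel_delta)
  out <- data.frame(
    feature_id = tst$feature_id,
    cell_a = cells[1],
    cell_b = cells[2],
    mean_absdev_diff = tst$mean_absdev_diff,
    t = tst$t,
    p = tst$p,
    q = tst$q,
    ev_diff = vt_a$table$ev - vt_b$table$ev,
    call = call,
    row.names = NULL
  )
  attr(out, "delta") <- attr(call, "delta")
  attr(out, "n_pairs") <- attr(tst, "n_pairs")
  out
}

#' Mutually exclusive hypervariability classification
#'
#' Combines the three pairwise contrast calls into one label per feature.
#' A feature is specific to cell type A iff it is called hypervariable in A
#' in both contrasts involving A; specificity is evaluated first. A feature
#' is shared between A and B iff A is hypervariable versus C and B is
#' hypervariable versus C (and the feature is not cell-type-specific).
#' Labels are disjoint by construction: no feature appears in more than one
#' list.
#'
#' @param ab,ac,bc Call vectors (values `up_in_a`/`up_in_b`/`none`) for the
#'   contrasts (A vs B), (A vs C), (B vs C), aligned on the same features.
#' @param cells Labels of the three cell types `c(A, B, C)`.
#' @param feature_id Feature identifiers.
#' @return Data frame `feature_id`, `label` with labels
#'   `"specific:<cell>"`, `"shared:<cell>+<cell>"` or `"none"`.
#' @export
classify_features <- function(ab, ac, bc, cells, feature_id) {
  if (length(cells) != 3) stop("exactly 3 cell types required")
  nfeat <- length(feature_id)
  if (length(ab) != nfeat || length(ac) != nfeat || length(bc) != nfeat)
    stop("contrast call vectors must align with feature_id")
  a <- cells[1]; b <- cells[2]; cc <- cells[3]
  label <- rep("none", nfeat)
  # shared first as scaffold, specific overrides (specific takes precedence)
  label[ac == "up_in_a" & bc == "up_in_a"] <- paste0("shared:", a, "+", b)
  label[ab == "up_in_a" & bc == "up_in_b"] <- paste0("shared:", a, "+", cc)
  label[ab == "up_in_b" & ac == "up_in_b"] <- paste0("shared:", b, "+", cc)
  label[ab == "up_in_a" & ac == "up_in_a"] <- paste0("specific:", a)
  label[ab == "up_in_b" & bc == "up_in_a"] <- paste0("specific:", b)
  label[ac == "up_in_b" & bc == "up_in_b"] <- paste0("specific:", cc)
  data.frame(feature_id = feature_id, label = label, row.names = NULL)
}

#' Rank-based list of features variable in all cell types
#'
#' Ranks features from high to low variability separately by MAD and by
#' EV within each cell type (six rankings, average ranks on ties). A
#' feature's score is its worst (largest) rank over the six rankings; the
#' `n` features with the smallest score are returned, ties broken by mean
#' rank and then by feature id.
#'
#' @param vt_tables Named list of per-cell-type variability data frames
#'   (columns `feature_id`, `ev`, `mad`), same features in the same order.
#' @param n Number of features to return.
#' @return Character vector of `n` feature ids.
#' @export
rank_common <- function(vt_tables, n) {
  ids <- vt_tables[[1]]$feature_id
  for (tab in vt_tables)
    if (!identical(tab$feature_id, ids))
      stop("variability tables must share the same feature order")
  if (n < 1 || n > length(ids))
    stop("'n' must be between 1 and the number of features")
  ranks <- do.call(cbind, lapply(vt_tables, function(tab) {
    cbind(rank(-tab$mad, ties.method = "average"),
          rank(-tab$ev, ties.method = "average"))
  }))
  score <- apply(ranks, 1, max)
  mean_rank <- rowMeans(ranks)
  ord <- order(score, mean_rank, ids)
  ids[ord][seq_len(n)]
}

#' Sex-specific differential mean expression
#'
#' Two-sample moderated t-test (pooled variance, empirical-Bayes shrinkage)
#' of male versus female mean log2 expression per feature. Significance
#' requires BH-adjusted p < `alpha` and `|logFC| >= lfc_min` (set
#' `lfc_min = 0` for the no-effect-size screen). An age ceiling restricts
#' the analysis to younger donors.
#'
#' @param values Feature-by-sample log2 expression matrix.
#' @param sex Character/factor vector aligned to columns, values `"male"` /
#'   `"female"`.
#' @param lfc_min Minimum absolute log2 fold change for significance.
#' @param alpha FDR level.
#' @param d0 `NULL` to estimate moderation, `0` for the classical pooled t.
#' @param age Optional donor ages aligned to columns.
#' @param age_max If given, only samples with `age < age_max` are analysed.
#' @return Data frame: feature_id, logFC (male minus female), t, p, q,
#'   significant.
#' @export
sex_diff_expression <- function(values, sex, lfc_min = 1, alpha = 0.05,
                                d0 = NULL, age = NULL, age_max = NULL) {
  values <- unclass(values)
  sex <- as.character(sex)
  if (!is.null(age_max)) {
    if (is.null(age)) stop("'age' required when 'age_max' is set")
    keep <- age < age_max
    values <- values[, keep, drop = FALSE]
    sex <- sex[keep]
  }
  is_m <- sex == "male"
  is_f <- sex == "female"
  nm <- sum(is_m); nf <- sum(is_f)
  if (nm < 3 || nf < 3)
    stop("both sexes need at least 3 samples")
  xm <- values[, is_m, drop = FALSE]
  xf <- values[, is_f, drop = FALSE]
  mm <- rowMeans(xm); mf <- rowMeans(xf)
  s2m <- rowSums((xm - mm) ^ 2) / (nm - 1)
  s2f <- rowSums((xf - mf) ^ 2) / (nf - 1)
  df <- nm + nf - 2
  s2 <- ((nm - 1) * s2m + (nf - 1) * s2f) / df
  if (is.null(d0)) {
    params <- estimate_moderation(s2, df = df)
  } else if (identical(d0, 0) || identical(d0, 0L)) {
    params <- list(d0 = 0, s0_sq = NA_real_, df = df)
  } else {
    stop("'d0' must be NULL or 0")
  }
  s2_tilde <- moderate_var(s2, params)
  logfc <- mm - mf
  se <- sqrt(s2_tilde * (1 / nm + 1 / nf))
  t_stat <- ifelse(se > 0, logfc / se,
                   ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- 2 * stats::pt(-abs(t_stat), df = params$d0 + df)
  q <- bh_adjust(p)
  data.frame(
    feature_id = rownames(values),
    logFC = logfc,
    t = t_stat,
    p = p,
    q = q,
    significant = !is.na(q) & q < alpha & abs(logfc) >= lfc_min,
    row.names = NULL
  )
}
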