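# shared fixture builders

# drop the omics_matrix wrapper, keeping only dim/dimnames
strip_omics <- function(x) {
  x <- unclass(x)
  attr(x, "scale") <- NULL
  x
}

# matrix with dimnames from a numeric vector/matrix
mat_named <- function(x, nrow, ncol, prefix = c("f", "s")) {
  m <- matrix(x, nrow, ncol)
  dimnames(m) <- list(sprintf("%s%03d", prefix[1], seq_len(nrow)),
                      sprintf("%s%03d", prefix[2], seq_len(ncol)))
  m
}

# small null cohort (expression only) used by several suites
null_cohort <- function(n_genes = 400, n_donors = 40, seed = 1) {
  simulate_cohort(sim_config(n_genes = n_genes, n_cpgs = 0,
                             n_donors = n_donors, seed = seed))
}

# run the three pairwise contrasts + classification on a cohort's expression
classify_expression <- function(cohort, alpha = 0.05, rel_delta = 0.10) {
  vts <- lapply(cohort$expression, variability_table)
  cells <- cohort$config$cell_types
  pairs <- list(cells[1:2], cells[c(1, 3)], cells[2:3])
  ctr <- lapply(pairs, function(p)
    contrast_cells(vts[[p[1]]], vts[[p[2]]], p,
                   alpha = alpha, rel_delta = rel_delta))
  cls <- classify_features(ctr[[1]]$call, ctr[[2]]$call, ctr[[3]]$call,
                           cells, ctr[[1]]$feature_id)
  list(vts = vts, contrasts = ctr, classification = cls, cells = cells)
}

# independent BH oracle: with p sorted ascending,
# q_(i) = min(1, min_{j >= i} m * p_(j) / j), mapped back to input order
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
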