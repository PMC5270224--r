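#' Spearman correlation screen of features against a donor trait
#'
#' Average-rank Spearman rho of each feature row against a trait vector over
#' donors present in both, with p-values from the large-sample t
#' approximation and BH adjustment across the tested features (one family
#' per cell type and trait).
#'
#' @param values Feature-by-donor matrix (rows = tested feature subset).
#' @param trait Named numeric vector of trait values (names = donor ids), or
#'   unnamed and aligned to columns.
#' @param cell_type,trait_name Labels stored in the output.
#' @return Data frame: feature_id, cell_type, trait, rho, p, q, n_used.
#' @export
spearman_assoc <- function(values, trait, cell_type = "group",
                           trait_name = "trait") {
  values <- unclass(values)
  if (!is.null(names(trait))) {
    donors <- intersect(colnames(values), names(trait))
    values <- values[, donors, drop = FALSE]
    trait <- trait[donors]
  }
  ok <- !is.na(trait)
  values <- values[, ok, drop = FALSE]
  trait <- trait[ok]
  n <- length(trait)
  if (n < 8) stop("need at least 8 donors with both values")
  if (length(unique(trait)) < 2) {
    rho <- rep(NaN, nrow(values))
  } else {
    rho <- suppressWarnings(
      as.vector(stats::cor(t(values), trait, method = "spearman")))
  }
  tt <- rho * sqrt((n - 2) / pmax(1 - rho ^ 2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(
    feature_id = rownames(values),
    cell_type = cell_type,
    trait = trait_name,
    rho = rho,
    p = p,
    q = bh_adjust(p),
    n_used = n,
    row.names = NULL
  )
}

#' Fill gaps in a daily series by linear interpolation
#'
#' Interior runs of NA are filled linearly between the flanking observed
#' values; leading/trailing gaps take the nearest observed value. Observed
#' points are preserved exactly.
#'
#' @param x Numeric vector with NA gaps.
#' @return Gap-free numeric vector of the same length.
#' @export
interpolate_missing <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) stop("all values missing")
  if (length(obs) == length(x)) return(x)
  if (length(obs) == 1) return(rep(x[obs], length(x)))
  stats::approx(obs, x[obs], xout = seq_along(x), rule = 2)$y
}

#' Correlate promoter/body methylation with gene expression
#'
#' For each CpG mapped to a gene in the requested region class, computes the
#' Spearman correlation of its M values with the gene's log2 expression
#' across donors, classifies it as positively / negatively / not correlated
#' at BH-adjusted p < `alpha` (BH across the CpG set of the region class),
#' and reports class proportions. Promoters are CpGs annotated to TSS1500,
#' TSS200, 5'UTR or first exon; gene bodies are body and 3'UTR.
#'
#' @param meth CpG-by-donor M-value matrix (rows = CpG subset of interest).
#' @param expr Gene-by-donor log2 expression matrix.
#' @param cpg_map Data frame with columns `feature_id` (CpG), `gene`,
#'   `gene_element`.
#' @param region One of `"promoter"`, `"body"`.
#' @param alpha FDR level for the positive/negative classification.
#' @return List with `table` (per-CpG rho, p, q, class) and `proportions`
#'   (named vector over positive/negative/none).
#' @export
meth_expr_link <- function(meth, expr, cpg_map, region = c("promoter", "body"),
                           alpha = 0.05) {
  region <- match.arg(region)
  elements <- if (region == "promoter")
    c("TSS1500", "TSS200", "5UTR", "first_exon") else c("body", "3UTR")
  meth <- unclass(meth); expr <- unclass(expr)
  map <- cpg_map[cpg_map$feature_id %in% rownames(meth) &
                 cpg_map$gene_element %in% elements &
                 !is.na(cpg_map$gene), , drop = FALSE]
  map <- map[map$gene %in% rownames(expr), , drop = FALSE]
  n_skipped <- sum(!(cpg_map$feature_id %in% map$feature_id) &
                   cpg_map$feature_id %in% rownames(meth))
  if (nrow(map) == 0) stop("no mappable CpGs in the requested region class")
  donors <- intersect(colnames(meth), colnames(expr))
  rho <- p <- numeric(nrow(map))
  n <- length(donors)
  for (i in seq_len(nrow(map))) {
    m <- meth[map$feature_id[i], donors]
    e <- expr[map$gene[i], donors]
    rho[i] <- suppressWarnings(stats::cor(m, e, method = "spearman"))
    tt <- rho[i] * sqrt((n - 2) / max(1 - rho[i] ^ 2, .Machine$double.eps))
    p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  q <- bh_adjust(p)
  class <- ifelse(!is.na(q) & q < alpha,
                  ifelse(rho > 0, "positive", "negative"), "none")
  tab <- data.frame(feature_id = map$feature_id, gene = map$gene,
                    region = region, rho = rho, p = p, q = q,
                    class = class, row.names = NULL)
  props <- c(positive = mean(class == "positive"),
             negative = mean(class == "negative"),
             none = mean(class == "none"))
  list(table = tab, proportions = props, n_skipped = n_skipped)
}

#' Binned mean profile of one variable ordered by another
#'
#' Sorts features ascending by the ordering metric (ties stable by feature
#' id), partitions them into consecutive bins of `bin_size` (the last bin
#' may be smaller), and returns the per-bin means of both variables in bin
#' order.
#'
#' @param order_metric Numeric vector (e.g. gene-level MV).
#' @param response Numeric vector aligned to `order_metric` (e.g. EV).
#' @param bin_size Features per bin.
#' @param feature_id Optional ids used for stable tie-breaking.
#' @return Data frame: bin, n, order_mean, response_mean.
#' @export
binned_profile <- function(order_metric, response, bin_size = 100,
                           feature_id = NULL) {
  n <- length(order_metric)
  if (n == 0) stop("empty input")
  if (length(response) != n) stop("vectors must be aligned")
  if (is.null(feature_id)) feature_id <- seq_len(n)
  ord <- order(order_metric, feature_id)
  bins <- ceiling(seq_len(n) / bin_size)
  om <- order_metric[ord]; rs <- response[ord]
  data.frame(
    bin = unique(bins),
    n = as.vector(table(bins)),
    order_mean = as.vector(tapply(om, bins, mean)),
    response_mean = as.vector(tapply(rs, bins, mean)),
    row.names = NULL
  )
}
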