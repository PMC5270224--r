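#' Construct an omics matrix
#'
#' A thin container for a feature-by-sample numeric matrix carrying its value
#' scale. Rows are features, columns are samples; dimnames are the feature and
#' sample identifiers and must be unique.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   complete dimnames.
#' @param scale One of `"counts"`, `"log2_expression"`, `"m_value"`,
#'   `"beta_value"`.
#' @return An `omics_matrix`: the input matrix with a `scale` attribute.
#' @export
omics_matrix <- function(values,
                         scale = c("counts", "log2_expression",
                                   "m_value", "beta_value")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (scale == "beta_value" &&
      any(values < 0 | values > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  if (scale == "counts" && any(values < 0, na.rm = TRUE))
    stop("counts must be nonnegative")
  structure(values, scale = scale, class = c("omics_matrix", class(values)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              attr(x, "scale"), nrow(x), ncol(x)))
  invisible(x)
}

omics_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("not an omics_matrix: missing scale attribute")
  s
}

# rebuild wrapper after arithmetic that strips attributes
as_omics <- function(values, scale) {
  omics_matrix(unclass(values), scale = scale)
}

#' Log-transform read counts
#'
#' Converts nonnegative read counts to expression log counts via
#' `log2(x + 1)`.
#'
#' @param counts An `omics_matrix` on the `counts` scale.
#' @return An `omics_matrix` on the `log2_expression` scale.
#' @export
log_transform <- function(counts) {
  if (omics_scale(counts) != "counts")
    stop("log_transform expects an omics_matrix on the 'counts' scale")
  if (any(counts < 0, na.rm = TRUE))
    stop("negative counts")
  as_omics(log2(unclass(counts) + 1), "log2_expression")
}

#' Convert methylation beta values to M values
#'
#' `M = log2(beta / (1 - beta))`. Beta values of exactly 0 or 1 are clamped
#' to `[eps, 1 - eps]` before conversion so the transform stays finite.
#'
#' @param beta An `omics_matrix` on the `beta_value` scale.
#' @param eps Clamp margin for boundary beta values.
#' @return An `omics_matrix` on the `m_value` scale.
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (omics_scale(beta) != "beta_value")
    stop("beta_to_m expects an omics_matrix on the 'beta_value' scale")
  b <- unclass(beta)
  if (any(b < 0 | b > 1, na.rm = TRUE))
    stop("beta values outside [0, 1]")
  b <- pmin(pmax(b, eps), 1 - eps)
  as_omics(log2(b / (1 - b)), "m_value")
}

#' Convert methylation M values to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (2^M + 1)`.
#'
#' @param m An `omics_matrix` on the `m_value` scale.
#' @return An `omics_matrix` on the `beta_value` scale.
#' @export
m_to_beta <- function(m) {
  if (omics_scale(m) != "m_value")
    stop("m_to_beta expects an omics_matrix on the 'm_value' scale")
  x <- 2 ^ unclass(m)
  as_omics(x / (x + 1), "beta_value")
}

#' Filter genes by robust expression and biotype
#'
#' Keeps a gene iff it is expressed (raw count >= `min_count`) in at least
#' `min_prop` of the samples in EVERY cell type, and its biotype is
#' `protein_coding`.
#'
#' @param counts_list Named list of count `omics_matrix` objects, one per cell
#'   type, sharing the same feature universe.
#' @param annotation Data frame with columns `feature_id` and `biotype`.
#' @param min_prop Minimum proportion of expressed samples per cell type.
#' @param min_count Raw count at or above which a gene counts as expressed.
#' @return Character vector of kept feature ids (in input order).
#' @export
filter_genes <- function(counts_list, annotation,
                         min_prop = 0.5, min_count = 1) {
  if (!is.list(counts_list) || length(counts_list) < 1)
    stop("'counts_list' must be a non-empty list of matrices")
  if (!all(c("feature_id", "biotype") %in% names(annotation)))
    stop("annotation must contain 'feature_id' and 'biotype' columns")
  ids <- rownames(counts_list[[1]])
  for (m in counts_list)
    if (!identical(rownames(m), ids))
      stop("cell types must share the same feature universe")
  expressed_everywhere <- Reduce(`&`, lapply(counts_list, function(m) {
    rowMeans(unclass(m) >= min_count) >= min_prop
  }))
  biotype <- annotation$biotype[match(ids, annotation$feature_id)]
  keep <- expressed_everywhere & !is.na(biotype) & biotype == "protein_coding"
  ids[keep]
}

# the six 450K-style probe exclusion rules, each a logical vector over probes
probe_drop_flags <- function(annotation, detection_p, bead_count,
                             detection_p_max = 0.01,
                             bead_min = 3, bead_frac = 0.05,
                             snp_maf_min = 0.05) {
  list(
    detection_p  = apply(detection_p >= detection_p_max, 1, any),
    bead_count   = rowMeans(bead_count < bead_min) >= bead_frac,
    sex_chrom    = annotation$chromosome %in% c("chrX", "chrY", "X", "Y"),
    ambiguous    = as.logical(annotation$ambiguous_map),
    non_cg       = !as.logical(annotation$cg_probe),
    snp_nearby   = as.logical(annotation$snp_within_2bp) &
                   !is.na(annotation$snp_maf) & annotation$snp_maf >= snp_maf_min
  )
}

#' Filter methylation probes by quality-control criteria
#'
#' Drops a probe if ANY of six criteria holds: (1) detection P >= 0.01 in at
#' least one sample; (2) bead count < 3 in at least 5% of samples; (3) maps to
#' a sex chromosome; (4) ambiguous genomic mapping; (5) non-CG probe;
#' (6) a SNP with MAF >= 0.05 within 2 bp of the interrogated CG.
#'
#' @param meth An `omics_matrix` of methylation values (rows = probes).
#' @param annotation Data frame with one row per probe: `feature_id`,
#'   `chromosome`, `ambiguous_map`, `cg_probe`, `snp_within_2bp`, `snp_maf`.
#' @param detection_p,bead_count Probe-by-sample matrices of detection
#'   p-values and bead counts, aligned to `meth` rows.
#' @return List with `kept` (character vector of surviving probe ids),
#'   `dropped` (ids removed) and `drop_counts` (named integer vector, probes
#'   failing each criterion; a probe may count under several criteria).
#' @export
filter_probes <- function(meth, annotation, detection_p, bead_count) {
  ids <- rownames(meth)
  need <- c("feature_id", "chromosome", "ambiguous_map", "cg_probe",
            "snp_within_2bp", "snp_maf")
  miss <- setdiff(need, names(annotation))
  if (length(miss))
    stop("annotation missing QC columns: ", paste(miss, collapse = ", "))
  if (!identical(rownames(detection_p), ids) ||
      !identical(rownames(bead_count), ids))
    stop("detection_p and bead_count must be aligned to the probe matrix")
  ann <- annotation[match(ids, annotation$feature_id), , drop = FALSE]
  if (anyNA(ann$feature_id))
    stop("annotation missing rows for some probes")
  flags <- probe_drop_flags(ann, detection_p, bead_count)
  drop <- Reduce(`|`, flags)
  list(kept = ids[!drop],
       dropped = ids[drop],
       drop_counts = vapply(flags, sum, integer(1)))
}
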