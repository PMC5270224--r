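#' Pipeline configuration
#'
#' Bundles the simulation block and all stage parameters driving
#' [run_pipeline()].
#'
#' @param sim A [sim_config()] describing the cohort to simulate (or `NULL`
#'   if `cohort` is passed to [run_pipeline()] directly).
#' @param alpha FDR level of the combined decision rule.
#' @param rel_delta Minimum EV/MV difference relative to the pooled range.
#' @param lfc_min Minimum |log2 fold change| for sex-specific DE.
#' @param r_threshold Pearson threshold of the co-expression network.
#' @param min_module_size Minimum network module size.
#' @param bin_size Features per bin in MV-EV profiles.
#' @param n_resamples Draws for resampling enrichment.
#' @param n_common Size of the rank-based common list; `NULL` uses the
#'   rounded mean of the specific/shared list sizes.
#' @param seed Seed for stages with randomness (enrichment resampling).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            alpha = 0.05, rel_delta = 0.10,
                            lfc_min = 1, r_threshold = 0.6,
                            min_module_size = 5, bin_size = 100,
                            n_resamples = 1000, n_common = NULL,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

cell_pairs <- function(cells) {
  list(c(cells[1], cells[2]), c(cells[1], cells[3]), c(cells[2], cells[3]))
}

# all three pairwise contrasts + classification for one assay
classify_assay <- function(vts, cells, alpha, rel_delta) {
  pr <- cell_pairs(cells)
  contrasts <- lapply(pr, function(p) {
    contrast_cells(vts[[p[1]]], vts[[p[2]]], p,
                   alpha = alpha, rel_delta = rel_delta)
  })
  names(contrasts) <- vapply(pr, paste, character(1), collapse = "_vs_")
  cls <- classify_features(contrasts[[1]]$call, contrasts[[2]]$call,
                           contrasts[[3]]$call, cells,
                           contrasts[[1]]$feature_id)
  list(contrasts = contrasts, classification = cls)
}

#' Per-label classification counts
#'
#' @param classification Data frame from [classify_features()].
#' @param common Optional common-list feature ids (counted separately; the
#'   common list is not part of the disjoint labels).
#' @return Data frame `label`, `n`; labels sum to the feature total
#'   (excluding the separate `common` row).
#' @export
summarize_counts <- function(classification, common = NULL) {
  tab <- table(classification$label)
  out <- data.frame(label = names(tab), n = as.integer(tab),
                    row.names = NULL)
  out <- out[order(out$label == "none", out$label), ]
  rownames(out) <- NULL
  if (!is.null(common))
    out <- rbind(out, data.frame(label = "common (rank-based)",
                                 n = length(common)))
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the differential-variability pipeline end to end
#'
#' Simulates (or accepts) a paired cohort, then executes: per-cell-type
#' variability scoring -> paired moderated contrasts and the combined rule
#' -> mutually exclusive classification -> rank-based common list ->
#' sex-specific DE -> trait and seasonal correlation screens ->
#' promoter/body methylation-expression correlation and MV-EV binned
#' profiles -> annotation enrichment of hypervariable CpGs -> co-expression
#' network modules of hypervariable genes. Deterministic given the
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optionally, a pre-built `synthetic_cohort` (overrides
#'   `config$sim`).
#' @param out_dir If non-NULL, result tables and a `manifest.yaml` recording
#'   every parameter are written there as TSV.
#' @return List of stage results (see vignette).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$sim)) stop("no cohort and no simulation block")
    cohort <- simulate_cohort(config$sim)
  }
  cells <- cohort$config$cell_types
  trt <- simulate_traits(cohort)
  res <- list(cohort = cohort, traits = trt)

  # variability + contrasts + classification per assay
  assays <- list(expression = cohort$expression)
  if (length(cohort$methylation))
    assays$methylation <- cohort$methylation
  for (assay in names(assays)) {
    vts <- lapply(assays[[assay]], variability_table)
    for (k in names(vts)) vts[[k]]$table$cell_type <- k
    ca <- classify_assay(vts, cells, config$alpha, config$rel_delta)
    sizes <- table(ca$classification$label)
    sizes <- sizes[names(sizes) != "none"]
    n_common <- if (!is.null(config$n_common)) config$n_common
                else if (length(sizes)) round(mean(sizes)) else 0
    common <- if (n_common >= 1)
      rank_common(lapply(vts, `[[`, "table"), n_common) else character(0)
    res[[assay]] <- list(variability = vts, contrasts = ca$contrasts,
                         classification = ca$classification,
                         common = common,
                         counts = summarize_counts(ca$classification, common))
  }

  # sex-specific differential expression per cell type
  dsn <- cohort$design
  res$sex_de <- lapply(cells, function(k) {
    d <- dsn[dsn$cell_type == k, ]
    m <- cohort$expression[[k]]
    sex_diff_expression(m, d$sex[match(colnames(m), d$donor_id)],
                        lfc_min = config$lfc_min)
  })
  names(res$sex_de) <- cells

  # trait + seasonal correlation screen on cell-type-specific HVGs
  cls <- res$expression$classification
  traits_df <- trt$traits
  weather <- trt$weather
  weather$tmin <- interpolate_missing(weather$tmin)
  weather$tmax <- interpolate_missing(weather$tmax)
  donor_tab <- unique(dsn[, c("donor_id", "collection_date")])
  widx <- match(donor_tab$collection_date, weather$date)
  for (w in c("tmin", "tmax", "daylight_hours"))
    traits_df[[w]] <- weather[[w]][widx][match(traits_df$donor_id,
                                               donor_tab$donor_id)]
  trait_names <- setdiff(names(traits_df), "donor_id")
  res$associations <- list()
  for (k in cells) {
    ids <- cls$feature_id[cls$label == paste0("specific:", k)]
    if (length(ids) == 0) next
    m <- unclass(cohort$expression[[k]])[ids, , drop = FALSE]
    res$associations[[k]] <- do.call(rbind, lapply(trait_names, function(tn) {
      tv <- stats::setNames(traits_df[[tn]], traits_df$donor_id)
      spearman_assoc(m, tv, cell_type = k, trait_name = tn)
    }))
  }

  if (length(cohort$methylation)) {
    # methylation-expression links of hypervariable CpGs
    mcls <- res$methylation$classification
    hvp <- mcls$feature_id[mcls$label != "none"]
    res$meth_expr <- list()
    if (length(hvp) >= 3) {
      k <- cells[which.max(vapply(cells, function(k)
        sum(mcls$label == paste0("specific:", k)), numeric(1)))]
      for (region in c("promoter", "body")) {
        link <- try(meth_expr_link(
          unclass(cohort$methylation[[k]])[hvp, , drop = FALSE],
          cohort$expression[[k]], cohort$cpg_annotation,
          region = region, alpha = config$alpha), silent = TRUE)
        if (!inherits(link, "try-error")) res$meth_expr[[region]] <- link
      }
    }

    # gene-level MV (mean over promoter CpGs) against EV, binned
    ann <- cohort$cpg_annotation
    prom <- ann[ann$gene_element %in%
                  c("TSS1500", "TSS200", "5UTR", "first_exon") &
                !is.na(ann$gene), ]
    k1 <- cells[1]
    mv_tab <- res$methylation$variability[[k1]]$table
    mv_by_cpg <- stats::setNames(mv_tab$ev, mv_tab$feature_id)
    gene_mv <- tapply(mv_by_cpg[prom$feature_id], prom$gene, mean,
                      na.rm = TRUE)
    ev_tab <- res$expression$variability[[k1]]$table
    shared_genes <- intersect(names(gene_mv), ev_tab$feature_id)
    if (length(shared_genes) >= 2) {
      ev_g <- ev_tab$ev[match(shared_genes, ev_tab$feature_id)]
      res$mv_ev_profile <- binned_profile(
        unname(gene_mv[shared_genes]), ev_g,
        bin_size = min(config$bin_size, length(shared_genes)),
        feature_id = shared_genes)
    }

    # annotation enrichment of the largest specific HVP set
    n_spec <- vapply(cells, function(k)
      sum(mcls$label == paste0("specific:", k)), numeric(1))
    if (max(n_spec) >= 1) {
      k <- cells[which.max(n_spec)]
      hvp_k <- mcls$feature_id[mcls$label == paste0("specific:", k)]
      bg <- ann$feature_id
      cons <- consensus_state_table(cohort$cpg_states)
      state_by_cpg <- cons$consensus[match(bg, cons$region_id)]
      res$enrichment <- list(
        genomic_feature = enrich_categories(
          hvp_k, bg, ann$genomic_feature,
          n_resamples = config$n_resamples, seed = config$seed),
        gene_element = enrich_categories(
          hvp_k, bg, ann$gene_element,
          n_resamples = config$n_resamples, seed = config$seed + 100L),
        chromatin_state = enrich_categories(
          hvp_k, bg, state_by_cpg,
          n_resamples = config$n_resamples, seed = config$seed + 200L)
      )
    }
  }

  # co-expression network of the largest specific HVG set
  n_spec_g <- vapply(cells, function(k)
    sum(cls$label == paste0("specific:", k)), numeric(1))
  if (max(n_spec_g) >= 3) {
    k <- cells[which.max(n_spec_g)]
    hvg_k <- cls$feature_id[cls$label == paste0("specific:", k)]
    ev_tab <- res$expression$variability[[k]]$table
    ev_k <- stats::setNames(ev_tab$ev, ev_tab$feature_id)[hvg_k]
    g <- build_network(unclass(cohort$expression[[k]])[hvg_k, , drop = FALSE],
                       r_threshold = config$r_threshold, ev = ev_k)
    res$network <- list(graph = g,
                        modules = detect_modules(g, config$min_module_size))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(cohort$design, file.path(out_dir, "sample_sheet.tsv"))
    write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
    for (assay in intersect(c("expression", "methylation"), names(res))) {
      a <- res[[assay]]
      vt_all <- do.call(rbind, lapply(a$variability, `[[`, "table"))
      write_tsv(vt_all, file.path(out_dir,
                                  paste0(assay, "_variability.tsv")))
      ct_all <- do.call(rbind, a$contrasts)
      write_tsv(ct_all, file.path(out_dir, paste0(assay, "_contrasts.tsv")))
      write_tsv(a$classification,
                file.path(out_dir, paste0(assay, "_classification.tsv")))
      write_tsv(a$counts, file.path(out_dir, paste0(assay, "_counts.tsv")))
      writeLines(a$common, file.path(out_dir, paste0(assay, "_common.txt")))
    }
    if (!is.null(res$network))
      write_network(res$network$graph,
                    file.path(out_dir, "network_edges.tsv"))
    manifest <- list(
      package = "hypervar",
      version = as.character(utils::packageVersion("hypervar")),
      parameters = config[setdiff(names(config), "sim")],
      sim = if (!is.null(config$sim))
        lapply(unclass(config$sim), function(x)
          if (inherits(x, "Date")) as.character(x) else x)
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(res)
}
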