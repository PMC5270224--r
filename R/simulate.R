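#' Configuration for the synthetic paired cohort
#'
#' Defines the statistical structure the generator emulates: paired donors
#' across three cell types, a negative mean-variance trend on the log2
#' expression scale, a bimodal methylation baseline on the M-value scale,
#' injected cell-type-specific / shared / common hypervariable features,
#' optional cis-genotype-driven variance, and sex / age / seasonal / trait
#' covariate effects.
#'
#' @param n_donors Number of donors (paired across all cell types).
#' @param n_genes,n_cpgs Number of expression features and CpG sites
#'   (`n_cpgs = 0` skips the methylation assay).
#' @param cell_types Labels of the three cell types.
#' @param mean_variance Parameters `a`, `b`, `c` of the expression trend
#'   `v(mu) = a * exp(-b * mu) + c` on the log2 scale.
#' @param feature_sdlog SD of the lognormal per-feature variance effect,
#'   shared across cell types so that the null is exactly calibrated.
#' @param meth_variance Parameters `a`, `s`, `c` of the M-value trend
#'   `v(mu) = a * exp(-(mu / s)^2) + c` (variance maximal at intermediate
#'   methylation).
#' @param injected_sets List of injections, each
#'   `list(assay = "expression"|"methylation", ids = <feature indices>,
#'   cells = <subset of cell_types>, inflation = <factor >= 1>)`. One cell
#'   type = specific, two = shared, three = common hypervariability.
#' @param genetic_fraction Fraction of each injected expression set whose
#'   extra variance is driven by a biallelic cis variant (additive mean shift
#'   per alternate allele) instead of residual noise.
#' @param maf Minor allele frequency of the simulated cis variants.
#' @param sex_effect_genes `list(ids =, logfc =)`: genes with a male-vs-female
#'   mean shift.
#' @param trait_effect_features List of
#'   `list(id =, trait =, rho =, cell_type =)`: donor traits generated to
#'   reach a target Spearman correlation with a feature.
#' @param seasonal_features `list(ids =, amplitude =)`: genes with a
#'   sinusoidal annual component keyed to the collection date.
#' @param age_effect_cpgs `list(ids =, slope =)`: CpGs whose M value drifts
#'   linearly with donor age (slope per year).
#' @param weather_missing Fraction of weather days set missing.
#' @param dropout Fraction of (donor, cell type) samples removed, for
#'   complete-pair handling tests.
#' @param n_state_replicates Biological replicates for chromatin-state calls.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_donors = 125,
                       n_genes = 2000,
                       n_cpgs = 1000,
                       cell_types = c("monocyte", "neutrophil", "tcell"),
                       mean_variance = list(a = 2, b = 0.4, c = 0.05),
                       feature_sdlog = 0.4,
                       meth_variance = list(a = 0.3, s = 3, c = 0.05),
                       injected_sets = list(),
                       genetic_fraction = 0,
                       maf = 0.3,
                       sex_effect_genes = NULL,
                       trait_effect_features = list(),
                       seasonal_features = NULL,
                       age_effect_cpgs = NULL,
                       weather_missing = 0.05,
                       dropout = 0,
                       n_state_replicates = 6,
                       seed = 1) {
  if (n_donors < 4) stop("n_donors must be at least 4")
  if (length(cell_types) != 3 || anyDuplicated(cell_types))
    stop("exactly 3 distinct cell types required")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  for (set in injected_sets) {
    if (!all(c("assay", "ids", "cells", "inflation") %in% names(set)))
      stop("each injected set needs assay, ids, cells, inflation")
    if (set$inflation < 1) stop("variance_inflation must be >= 1")
    if (!all(set$cells %in% cell_types)) stop("unknown cell type in injection")
    n_max <- if (set$assay == "expression") n_genes else n_cpgs
    if (any(set$ids < 1 | set$ids > n_max))
      stop("injected feature ids out of range")
  }
  structure(as.list(environment()), class = "sim_config")
}

injection_label <- function(cells, cell_types) {
  cells <- cell_types[cell_types %in% cells]
  if (length(cells) == 3) return("common")
  if (length(cells) == 2) return(paste0("shared:", paste(cells, collapse = "+")))
  paste0("specific:", cells)
}

# per-cell-type variance inflation vectors and truth rows for one assay
build_inflation <- function(config, assay, n_feat, ids_all) {
  infl <- sapply(config$cell_types, function(k) rep(1, n_feat),
                 simplify = FALSE)
  truth <- list()
  for (set in config$injected_sets) {
    if (set$assay != assay) next
    for (k in set$cells) infl[[k]][set$ids] <- set$inflation
    truth[[length(truth) + 1]] <- data.frame(
      feature_id = ids_all[set$ids],
      assay = assay,
      label = injection_label(set$cells, config$cell_types),
      inflation = set$inflation,
      genetic = FALSE,
      row.names = NULL
    )
  }
  list(inflation = infl,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate a paired multi-cell-type cohort
#'
#' Generates log2 expression and M-value methylation matrices for every cell
#' type over the same donors, with known ground-truth hypervariable features.
#' Baseline per-feature means and variances are shared across cell types
#' (variance = trend at the mean times a lognormal feature effect), so with
#' no injections the paired null holds exactly. Injected features have their
#' variance multiplied by the configured inflation in the designated cell
#' types; a configurable fraction of injected expression features realize
#' that extra variance through a Hardy-Weinberg cis genotype shifting the
#' donor mean additively.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort` list: `expression` and `methylation` (named
#'   lists of `omics_matrix`, donors as columns), `design` (sample sheet),
#'   `gene_annotation`, `cpg_annotation`, `cpg_states`, `truth` and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ct <- config$cell_types
  nd <- config$n_donors

  donors <- sprintf("D%03d", seq_len(nd))
  sex <- sample(c("male", "female"), nd, replace = TRUE, prob = c(0.46, 0.54))
  age <- sample(20:75, nd, replace = TRUE)
  date0 <- as.Date("2012-01-01")
  collection_date <- date0 + sample(0:364, nd, replace = TRUE)
  design <- do.call(rbind, lapply(ct, function(k) {
    data.frame(sample_id = paste(donors, k, sep = "_"),
               donor_id = donors, cell_type = k,
               sex = sex, age = age,
               collection_date = collection_date,
               row.names = NULL)
  }))

  day_of_year <- as.integer(format(collection_date, "%j"))
  season <- sin(2 * pi * (day_of_year - 80) / 365.25)

  # --- expression -----------------------------------------------------------
  ng <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(ng))
  mv <- config$mean_variance
  mu_g <- stats::runif(ng, 0, 12)
  feat_eff <- stats::rlnorm(ng, 0, config$feature_sdlog)
  base_v <- (mv$a * exp(-mv$b * mu_g) + mv$c) * feat_eff

  inj <- build_inflation(config, "expression", ng, gene_ids)
  truth <- inj$truth

  # cis-genetic mechanism for a fraction of each injected expression set
  gen_shift <- sapply(ct, function(k) matrix(0, 0, 0), simplify = FALSE)
  shift <- sapply(ct, function(k) matrix(0, ng, nd), simplify = FALSE)
  genetic_ids <- integer(0)
  if (config$genetic_fraction > 0) {
    for (set in config$injected_sets) {
      if (set$assay != "expression" || set$inflation <= 1) next
      n_gen <- round(config$genetic_fraction * length(set$ids))
      if (n_gen < 1) next
      ids_gen <- sort(sample(set$ids, n_gen))
      genetic_ids <- c(genetic_ids, ids_gen)
      p <- config$maf
      for (i in ids_gen) {
        g <- stats::rbinom(nd, 2, p)
        beta <- sqrt((set$inflation - 1) * base_v[i] / (2 * p * (1 - p)))
        for (k in set$cells) {
          shift[[k]][i, ] <- shift[[k]][i, ] + beta * (g - 2 * p)
          inj$inflation[[k]][i] <- 1  # variance comes from the genotype
        }
      }
    }
    if (!is.null(truth))
      truth$genetic <- truth$feature_id %in% gene_ids[genetic_ids]
  }

  if (!is.null(config$sex_effect_genes)) {
    se <- config$sex_effect_genes
    male <- as.numeric(sex == "male")
    for (k in ct)
      shift[[k]][se$ids, ] <- shift[[k]][se$ids, , drop = FALSE] +
        outer(rep_len(se$logfc, length(se$ids)), male)
  }
  if (!is.null(config$seasonal_features)) {
    sf <- config$seasonal_features
    for (k in ct)
      shift[[k]][sf$ids, ] <- shift[[k]][sf$ids, , drop = FALSE] +
        outer(rep_len(sf$amplitude, length(sf$ids)), season)
  }

  expression <- sapply(ct, function(k) {
    sdm <- sqrt(base_v * inj$inflation[[k]])
    y <- mu_g + shift[[k]] +
      matrix(stats::rnorm(ng * nd), ng, nd) * sdm
    dimnames(y) <- list(gene_ids, donors)
    omics_matrix(y, "log2_expression")
  }, simplify = FALSE)

  gene_annotation <- data.frame(
    feature_id = gene_ids,
    biotype = sample(c("protein_coding", "lincRNA"), ng,
                     replace = TRUE, prob = c(0.9, 0.1)),
    chromosome = paste0("chr", sample(1:22, ng, replace = TRUE)),
    row.names = NULL
  )

  # --- methylation ----------------------------------------------------------
  methylation <- list()
  cpg_annotation <- NULL
  cpg_states <- NULL
  if (config$n_cpgs > 0) {
    np <- config$n_cpgs
    cpg_ids <- sprintf("cg%07d", seq_len(np))
    comp <- sample(1:3, np, replace = TRUE, prob = c(0.45, 0.45, 0.10))
    beta0 <- numeric(np)
    beta0[comp == 1] <- stats::rbeta(sum(comp == 1), 1, 10)
    beta0[comp == 2] <- stats::rbeta(sum(comp == 2), 10, 1)
    beta0[comp == 3] <- stats::rbeta(sum(comp == 3), 2, 2)
    beta0 <- pmin(pmax(beta0, 1e-4), 1 - 1e-4)
    mu_m <- log2(beta0 / (1 - beta0))
    mvp <- config$meth_variance
    feat_eff_m <- stats::rlnorm(np, 0, config$feature_sdlog)
    base_vm <- (mvp$a * exp(-(mu_m / mvp$s) ^ 2) + mvp$c) * feat_eff_m

    inj_m <- build_inflation(config, "methylation", np, cpg_ids)
    if (!is.null(inj_m$truth)) truth <- rbind(truth, inj_m$truth)

    shift_m <- sapply(ct, function(k) matrix(0, np, nd), simplify = FALSE)
    if (!is.null(config$age_effect_cpgs)) {
      ae <- config$age_effect_cpgs
      dev_age <- age - mean(age)
      for (k in ct)
        shift_m[[k]][ae$ids, ] <- shift_m[[k]][ae$ids, , drop = FALSE] +
          outer(rep_len(ae$slope, length(ae$ids)), dev_age)
    }

    methylation <- sapply(ct, function(k) {
      sdm <- sqrt(base_vm * inj_m$inflation[[k]])
      y <- mu_m + shift_m[[k]] +
        matrix(stats::rnorm(np * nd), np, nd) * sdm
      dimnames(y) <- list(cpg_ids, donors)
      omics_matrix(y, "m_value")
    }, simplify = FALSE)

    injected_cpg <- rep(FALSE, np)
    for (set in config$injected_sets)
      if (set$assay == "methylation") injected_cpg[set$ids] <- TRUE

    feat_cats <- c("island", "shore", "shelf", "open_sea")
    genomic_feature <- character(np)
    # injected CpGs emulate the reported annotation skew:
    # depleted at islands, concentrated away from them
    genomic_feature[!injected_cpg] <-
      sample(feat_cats, sum(!injected_cpg), replace = TRUE,
             prob = c(0.32, 0.23, 0.10, 0.35))
    if (any(injected_cpg))
      genomic_feature[injected_cpg] <-
        sample(feat_cats, sum(injected_cpg), replace = TRUE,
               prob = c(0.06, 0.16, 0.13, 0.65))
    elements <- c("TSS1500", "TSS200", "5UTR", "first_exon",
                  "body", "3UTR", "intergenic")
    gene_element <- sample(elements, np, replace = TRUE,
                           prob = c(0.12, 0.10, 0.08, 0.07, 0.33, 0.05, 0.25))
    mapped_gene <- ifelse(gene_element == "intergenic", NA_character_,
                          sample(gene_ids, np, replace = TRUE))
    cpg_annotation <- data.frame(
      feature_id = cpg_ids,
      chromosome = paste0("chr", sample(1:22, np, replace = TRUE)),
      genomic_feature = genomic_feature,
      gene_element = gene_element,
      gene = mapped_gene,
      row.names = NULL
    )

    states <- c("promoter", "enhancer", "elongation", "polycomb", "other")
    nrep <- config$n_state_replicates
    base_state <- character(np)
    base_state[!injected_cpg] <-
      sample(states, sum(!injected_cpg), replace = TRUE,
             prob = c(0.25, 0.15, 0.15, 0.15, 0.30))
    if (any(injected_cpg))
      base_state[injected_cpg] <-
        sample(states, sum(injected_cpg), replace = TRUE,
               prob = c(0.10, 0.45, 0.10, 0.10, 0.25))
    # injected CpGs flip state more often across replicates (dynamic chromatin)
    flip_prob <- ifelse(injected_cpg, 0.25, 0.04)
    rep_state <- matrix(rep(base_state, nrep), np, nrep)
    flip <- matrix(stats::runif(np * nrep) < flip_prob, np, nrep)
    rep_state[flip] <- sample(states, sum(flip), replace = TRUE)
    cpg_states <- data.frame(
      region_id = rep(cpg_ids, nrep),
      replicate_id = rep(sprintf("rep%d", seq_len(nrep)), each = np),
      state = as.vector(rep_state),
      row.names = NULL
    )
  }

  if (config$dropout > 0) {
    n_drop <- round(config$dropout * nrow(design))
    drop_rows <- sample(nrow(design), n_drop)
    for (i in drop_rows) {
      k <- design$cell_type[i]; d <- design$donor_id[i]
      keep <- setdiff(colnames(expression[[k]]), d)
      expression[[k]] <- as_omics(unclass(expression[[k]])[, keep,
                                  drop = FALSE], "log2_expression")
      if (length(methylation))
        methylation[[k]] <- as_omics(unclass(methylation[[k]])[, keep,
                                     drop = FALSE], "m_value")
    }
    design <- design[-drop_rows, , drop = FALSE]
  }

  if (is.null(truth))
    truth <- data.frame(feature_id = character(0), assay = character(0),
                        label = character(0), inflation = numeric(0),
                        genetic = logical(0))

  structure(list(
    expression = expression,
    methylation = methylation,
    design = design,
    gene_annotation = gene_annotation,
    cpg_annotation = cpg_annotation,
    cpg_states = cpg_states,
    truth = truth,
    config = config
  ), class = "synthetic_cohort")
}

#' Simulate donor traits and a daily weather series
#'
#' Per-donor quantitative traits (demographics and cellular parameters) plus
#' a seasonal weather series (sinusoid + noise) with a configurable fraction
#' of missing days. Traits named in `trait_effect_features` are generated by
#' a Gaussian copula to reach the target Spearman correlation with the
#' designated feature.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param config The cohort's [sim_config()]; defaults to `cohort$config`.
#' @return List with `traits` (data frame, one row per donor) and `weather`
#'   (data frame: date, tmin, tmax, daylight_hours; NA on missing days).
#' @export
simulate_traits <- function(cohort, config = cohort$config) {
  set.seed(config$seed + 1L)
  des <- unique(cohort$design[, c("donor_id", "sex", "age",
                                  "collection_date")])
  nd <- nrow(des)
  traits <- data.frame(
    donor_id = des$donor_id,
    age = des$age,
    bmi = stats::rnorm(nd, 26.5, 4),
    alcohol_units = stats::rpois(nd, 6),
    neutrophil_percentage = stats::rnorm(nd, 55, 8),
    neutrophil_granularity = stats::rnorm(nd, 150, 10),
    monocyte_count = stats::rnorm(nd, 0.5, 0.12),
    row.names = NULL
  )
  for (te in config$trait_effect_features) {
    k <- if (!is.null(te$cell_type)) te$cell_type else config$cell_types[1]
    x <- unclass(cohort$expression[[k]])[te$id, des$donor_id]
    # Gaussian copula: Pearson rho on normal scores realizing Spearman target
    rho_p <- 2 * sin(pi * te$rho / 6)
    z <- stats::qnorm((rank(x) - 0.5) / nd)
    traits[[te$trait]] <- rho_p * z +
      sqrt(1 - rho_p ^ 2) * stats::rnorm(nd)
  }
  dates <- seq(as.Date("2012-01-01"), as.Date("2012-12-30"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  tmax <- 14 + 8 * sin(2 * pi * (doy - 100) / 365.25) +
    stats::rnorm(length(dates), 0, 2)
  tmin <- tmax - 6 + stats::rnorm(length(dates), 0, 1.2)
  daylight <- 12.2 + 4.4 * sin(2 * pi * (doy - 80) / 365.25)
  weather <- data.frame(date = dates, tmin = tmin, tmax = tmax,
                        daylight_hours = daylight, row.names = NULL)
  if (config$weather_missing > 0) {
    gap <- stats::runif(length(dates)) < config$weather_missing
    weather$tmin[gap] <- NA
    weather$tmax[gap] <- NA
  }
  list(traits = traits, weather = weather)
}

#' Recovery metrics against the injected ground truth
#'
#' Compares a classification table with the generator's truth table.
#' Positives are features classified specific or shared; truth positives are
#' injected specific/shared features of the same assay.
#'
#' @param classification Data frame `feature_id`, `label` from
#'   [classify_features()].
#' @param truth The cohort's truth table (optionally pre-filtered by assay).
#' @return List: `sensitivity`, `precision`, `label_accuracy` (fraction of
#'   correctly recovered features carrying exactly the injected label) and
#'   `per_class` (data frame of per-label sensitivity).
#' @export
truth_eval <- function(classification, truth) {
  truth <- truth[grepl("^(specific|shared):", truth$label), , drop = FALSE]
  called <- classification$feature_id[classification$label != "none"]
  truth_pos <- truth$feature_id
  hit <- intersect(called, truth_pos)
  sens <- if (length(truth_pos)) length(hit) / length(truth_pos) else NA_real_
  prec <- if (length(called)) length(hit) / length(called) else NA_real_
  lab_call <- classification$label[match(hit, classification$feature_id)]
  lab_true <- truth$label[match(hit, truth$feature_id)]
  lab_acc <- if (length(hit)) mean(lab_call == lab_true) else NA_real_
  per_class <- do.call(rbind, lapply(split(truth, truth$label), function(tr) {
    h <- intersect(called, tr$feature_id)
    data.frame(label = tr$label[1],
               n_injected = nrow(tr),
               n_recovered = length(h),
               sensitivity = length(h) / nrow(tr),
               row.names = NULL)
  }))
  list(sensitivity = sens, precision = prec, label_accuracy = lab_acc,
       per_class = per_class)
}
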