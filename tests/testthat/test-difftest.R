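test_that("BH adjustment matches the step-up rule and its brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(14)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), bh_brute_force(p))
  }
  # NA p-values excluded from the family and propagated
  p <- c(0.01, NA, 0.03)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_brute_force(p[c(1, 3)]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("paired deviation test reproduces the textbook one-sample t without moderation", {
  # z = [1,2,3,4]: t = 2.5 / (1.29099/2) = 3.873, df = 3
  a <- mat_named(c(1, 2, 3, 4), 1, 4)
  b <- mat_named(rep(0, 4), 1, 4)
  res <- paired_diffvar_test(a, b, d0 = 0)
  expect_equal(res$mean_absdev_diff, 2.5)
  expect_equal(res$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-res$t, df = 3), tolerance = 1e-12)
  # identical deviations give t = 0, p = 1
  res0 <- paired_diffvar_test(a, a, d0 = 0)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(paired_diffvar_test(a[, 1:3, drop = FALSE],
                                   b[, 1:3, drop = FALSE]),
               "4 complete donor pairs")
})

test_that("d0 = 0 equals the classical paired t on random features", {
  set.seed(15)
  a <- mat_named(abs(rnorm(200)), 20, 10)
  b <- mat_named(abs(rnorm(200)), 20, 10)
  res <- paired_diffvar_test(a, b, d0 = 0)
  for (i in seq_len(20)) {
    tt <- t.test(a[i, ], b[i, ], paired = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("the paired test is invariant to joint donor permutation and pairs by donor id", {
  set.seed(16)
  a <- mat_named(abs(rnorm(300)), 30, 10)
  b <- mat_named(abs(rnorm(300)), 30, 10)
  res1 <- paired_diffvar_test(a, b)
  perm <- sample(colnames(a))
  res2 <- paired_diffvar_test(a[, perm], b[, perm])
  expect_equal(res1$t, res2$t)
  expect_equal(res1$p, res2$p)
  # donors missing one sample are dropped from the pairing
  b_sub <- b[, -(1:2)]
  expect_message(res3 <- paired_diffvar_test(a, b_sub), "dropping 2 donors")
  expect_identical(attr(res3, "n_pairs"), 8L)
})

test_that("combined decision enforces FDR, EV-difference and sign agreement jointly", {
  # pooled EV range [0, 2] so delta = 0.2
  ev_a <- c(2, 1.0, 1.5, 0.25, 1)
  ev_b <- c(0, 0.75, 1.0, 0.00, 1)
  q <- c(0.01, 0.01, 0.2, 0.01, 0.01)
  mad_diff <- c(1, 1, 1, -1, 0)
  call <- combined_decision(q, ev_a, ev_b, mad_diff)
  expect_equal(attr(call, "delta"), 0.2)
  expect_identical(as.vector(call),
                   c("up_in_a",  # q ok, ev_diff 2 >= 0.2, sign agrees
                     "up_in_a",  # ev_diff 0.25 >= 0.2
                     "none",     # fails alpha
                     "none",     # ev_diff up but deviation difference negative
                     "none"))    # ev_diff 0 < delta
  # ev_diff below delta fails even at tiny q (second feature fixes the range)
  expect_identical(as.vector(
    combined_decision(c(0.01, 0.5), c(0.15, 2), c(0, 0), c(1, 1)))[1],
    "none")
  expect_warning(combined_decision(0.01, 1, 1, 1), "degenerate")
})

test_that("classification matches an independent truth table on all 27 call combinations", {
  cells <- c("A", "B", "C")
  combos <- expand.grid(ab = c("up_in_a", "up_in_b", "none"),
                        ac = c("up_in_a", "up_in_b", "none"),
                        bc = c("up_in_a", "up_in_b", "none"),
                        stringsAsFactors = FALSE)
  # oracle written from the decision rule's verbal definition:
  # up(X, Y) = X called hypervariable in the contrast containing X and Y
  up <- function(x, y, row) {
    key <- paste(sort(c(x, y)), collapse = "")
    call <- switch(key, AB = row$ab, AC = row$ac, BC = row$bc)
    first <- sort(c(x, y))[1]
    (call == "up_in_a" && x == first) || (call == "up_in_b" && x != first)
  }
  oracle <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    row <- combos[i, ]
    lab <- "none"
    others <- function(x) setdiff(cells, x)
    for (x in cells)
      if (all(vapply(others(x), function(y) up(x, y, row), logical(1))))
        lab <- paste0("specific:", x)
    if (lab == "none") {
      for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
        z <- setdiff(cells, pair)
        if (up(pair[1], z, row) && up(pair[2], z, row))
          lab <- paste0("shared:", pair[1], "+", pair[2])
      }
    }
    oracle[i] <- lab
  }
  got <- classify_features(combos$ab, combos$ac, combos$bc, cells,
                           sprintf("f%02d", seq_len(nrow(combos))))
  expect_identical(got$label, oracle)
  # spec examples: up in both contrasts involving A => specific:A
  one <- classify_features("up_in_a", "up_in_a", "none", cells, "f1")
  expect_identical(one$label, "specific:A")
  two <- classify_features("none", "up_in_a", "up_in_a", cells, "f1")
  expect_identical(two$label, "shared:A+B")
  # disjointness: exactly one label per feature by construction
  expect_identical(nrow(got), nrow(combos))
})

test_that("rank-based common list follows the worst-rank rule with documented tie-breaks", {
  # 4 features with constructed per-ranking positions
  mk <- function(mad_r, ev_r) {
    # values whose descending ranks equal the requested ranks
    data.frame(feature_id = c("f1", "f2", "f3", "f4"),
               mad = 5 - mad_r, ev = 5 - ev_r)
  }
  vt <- list(
    ct1 = mk(c(1, 2, 3, 4), c(2, 1, 3, 4)),
    ct2 = mk(c(1, 3, 2, 4), c(2, 3, 1, 4)),
    ct3 = mk(c(2, 1, 3, 4), c(1, 2, 3, 4))
  )
  # max-ranks: f1 = 2, f2 = 3, f3 = 3, f4 = 4; f3 has smaller mean rank
  # than f2 (13/6 < 14/6)... recompute: f2 mean = (2+1+3+3+1+2)/6 = 2,
  # f3 mean = (3+3+2+1+3+3)/6 = 2.5 -> tie broken toward f2
  expect_identical(rank_common(vt, 2), c("f1", "f2"))
  # a feature ranked first everywhere is always selected
  expect_identical(rank_common(vt, 1), "f1")
  # strictly increasing transform of EV leaves the selection unchanged
  vt2 <- lapply(vt, function(tab) { tab$ev <- exp(tab$ev); tab })
  expect_identical(rank_common(vt2, 3), rank_common(vt, 3))
  expect_error(rank_common(vt, 5), "between 1")
})

test_that("sex-specific DE detects injected shifts and reduces to the pooled t", {
  set.seed(17)
  n <- 60
  vals <- mat_named(rnorm(100 * 2 * n, sd = 0.5), 100, 2 * n)
  sex <- rep(c("male", "female"), each = n)
  vals[1:5, sex == "male"] <- vals[1:5, sex == "male"] + 2  # logFC = 2
  de <- sex_diff_expression(vals, sex, lfc_min = 1)
  expect_true(all(de$significant[1:5]))
  expect_true(all(abs(de$logFC[1:5] - 2) < 0.5))
  expect_lt(sum(de$significant[-(1:5)]), 3)
  # identical group means: logFC 0, never significant
  flat <- mat_named(rep(1:10, 2 * n), 10, 2 * n)
  de0 <- sex_diff_expression(flat, sex, lfc_min = 0, d0 = 0)
  expect_equal(de0$logFC, rep(0, 10))
  expect_false(any(de0$significant))
  # moderation disabled equals the classical pooled two-sample t
  de_raw <- sex_diff_expression(vals, sex, d0 = 0)
  for (i in c(1, 50, 100)) {
    tt <- t.test(vals[i, sex == "male"], vals[i, sex == "female"],
                 var.equal = TRUE)
    expect_equal(de_raw$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de_raw$p[i], tt$p.value, tolerance = 1e-10)
  }
  expect_error(sex_diff_expression(vals, rep("male", 2 * n)), "both sexes")
  # age ceiling subsets the donors
  age <- rep(c(30, 70), n)
  de_y <- sex_diff_expression(vals, sex, age = age, age_max = 50)
  expect_true(all(de_y$significant[1:5]))
})

test_that("swapping the cell types in a contrast flips statistics and calls symmetrically", {
  co <- simulate_cohort(sim_config(
    n_genes = 400, n_cpgs = 0, n_donors = 40,
    injected_sets = list(list(assay = "expression", ids = 1:30,
                              cells = "monocyte", inflation = 5)),
    seed = 18))
  vts <- lapply(co$expression, variability_table)
  fwd <- contrast_cells(vts[[1]], vts[[2]], c("monocyte", "neutrophil"))
  rev <- contrast_cells(vts[[2]], vts[[1]], c("neutrophil", "monocyte"))
  expect_equal(fwd$ev_diff, -rev$ev_diff)
  expect_equal(fwd$mean_absdev_diff, -rev$mean_absdev_diff)
  expect_equal(fwd$q, rev$q)
  expect_identical(fwd$call == "up_in_a", rev$call == "up_in_b")
})
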