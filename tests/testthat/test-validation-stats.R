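test_that("percent agreement rounds half-up to one decimal", {
  expect_equal(percent_agreement(52, 52), 100.0)
  expect_equal(percent_agreement(46, 52), 88.5)   # 88.4615 rounds up
  expect_equal(percent_agreement(45, 52), 86.5)
  expect_equal(percent_agreement(49, 52), 94.2)
  expect_equal(percent_agreement(51, 52), 98.1)
  # half-up at an exact .x5 boundary (base round() would give 93.8)
  expect_equal(round_half_up(93.85, 1), 93.9)
  expect_equal(percent_agreement(1877, 2000), 93.9)  # 93.85 exactly
  expect_error(percent_agreement(1, 0), "positive")
})

test_that("level-wise agreement classifies agree / not-at-level / disagree", {
  ont <- tiny_ontology()
  ref <- tibble::tibble(id = 1:4, region_id = c(6, 7, 5, 8))
  # identical allocations agree everywhere they exist
  tab <- agreement_by_level(ref, ref, ont, levels = 1:4)
  expect_s3_class(tab, "agreement_table")
  expect_true(all(tab$disagreement == 0))
  expect_true(all(tab$sum_of_agreement == 4))
  expect_true(all(tab$sum_of_agreement_pct == 100.0))
  # at level 4 the thalamus and callosum spheres are "not at this level"
  expect_equal(tab$not_at_level[tab$level == 4], 2)

  # allocations diverging only at the deepest level agree above it
  tst <- ref
  tst$region_id[1] <- 7  # motor -> visual: same cortex parent
  tab2 <- agreement_by_level(ref, tst, ont, levels = 1:4)
  expect_equal(tab2$disagreement, c(0, 0, 0, 1))
  expect_equal(tab2$agreement[tab2$level == 3], 4)

  # a reference sphere deeper than the test allocation disagrees at depth
  tst2 <- ref
  tst2$region_id[2] <- 4  # visual reported only as cortex
  tab3 <- agreement_by_level(ref, tst2, ont, levels = 1:4)
  expect_equal(tab3$disagreement[tab3$level == 4], 1)

  expect_error(agreement_by_level(ref, tst[1:3, ], ont), "same sphere ids")
})

test_that("agreement can only be lost with depth", {
  # agreement at level k+1 implies agreement at level k (ancestors of
  # matching ancestors match), so the agreement count is non-increasing and
  # the not-at-level count non-decreasing with depth; the sum of agreement
  # is additionally non-increasing whenever spheres whose reference branch
  # terminates early agreed at their terminal level, as in rater data where
  # "not at this level" spheres were correctly allocated as far as the tree
  # goes
  ont <- tiny_ontology()
  leaves <- c(5, 6, 7, 8)
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    ref <- tibble::tibble(id = seq_len(n),
                          region_id = sample(leaves, n, replace = TRUE))
    tst <- tibble::tibble(id = seq_len(n),
                          region_id = sample(c(leaves, 2:4), n,
                                             replace = TRUE))
    tab <- agreement_by_level(ref, tst, ont, levels = 1:4)
    expect_true(all(diff(tab$agreement) <= 0))
    expect_true(all(diff(tab$not_at_level) >= 0))
    expect_equal(tab$agreement + tab$not_at_level + tab$disagreement,
                 tab$total)

    # force agreement at shallow reference terminals; then the sum of
    # agreement is monotone non-increasing
    tst2 <- tst
    shallow <- ref$region_id %in% c(5, 8)
    tst2$region_id[shallow] <- ref$region_id[shallow]
    tab2 <- agreement_by_level(ref, tst2, ont, levels = 1:4)
    expect_true(all(diff(tab2$sum_of_agreement) <= 0))
  }
  # the bundled validation tables satisfy the monotone pattern as printed
  bf <- validation_agreement_counts("blockface")
  expect_true(all(diff(bf$sum_of_agreement[order(bf$level)]) <= 0))
})

test_that("bundled validation counts reproduce the published percentages", {
  alloc <- summarize_allocation_counts(validation_allocation_counts())
  expect_equal(alloc$overall$agreement, 995)
  expect_equal(alloc$overall$agreement_pct, 93.9)
  iso <- alloc$regions[alloc$regions$region == "isocortex", ]
  expect_equal(iso$proportion_pct, 38.2)
  thal <- alloc$regions[alloc$regions$region == "thalamus and midbrain", ]
  expect_equal(thal$proportion_pct, 25.4)

  bf <- validation_agreement_counts("blockface")
  expect_equal(bf$sum_of_agreement_pct[bf$level_label == "7"], 94.2)
  expect_equal(bf$sum_of_agreement_pct[bf$level_label == "10"], 86.5)
  expect_equal(bf$sum_of_agreement_pct[bf$level_label == "1/2"], 98.1)
  hs <- validation_agreement_counts("histology")
  expect_equal(hs$sum_of_agreement_pct[hs$level_label == "7"], 88.5)
  expect_true(all(bf$total == 52))
})

test_that("pearson_r matches the closed-form computation", {
  # hand-derived case
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(pearson_r(x, y)$r, pearson_by_hand(x, y)$r)
  # perfect linear relations
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1.0)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1.0)
  # random fixtures against the independent formula
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    a <- rnorm(n); b <- rnorm(n) + 0.5 * a
    got <- pearson_r(a, b)
    ref <- pearson_by_hand(a, b)
    expect_equal(got$r, ref$r, tolerance = 1e-10)
    expect_equal(got$statistic, ref$t, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
    expect_equal(got$r_squared, ref$r^2, tolerance = 1e-10)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("t tests follow the paired and pooled-variance conventions", {
  # identical paired samples: t = 0, p = 1 by definition
  r0 <- t_test_counts(c(3, 5, 7), c(3, 5, 7), mode = "paired")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # constant nonzero differences are degenerate
  expect_error(t_test_counts(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5),
                             mode = "paired"),
               "zero variance")
  # independent test matches the hand-computed pooled-variance statistic
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- t_test_counts(a, b, mode = "independent")
  expect_equal(got$statistic, pooled_t_by_hand(a, b), tolerance = 1e-12)
  expect_equal(got$df, 4)
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(sample(3:20, 1), 1); b <- rnorm(sample(3:20, 1))
    got <- t_test_counts(a, b, mode = "independent")
    expect_equal(got$statistic, pooled_t_by_hand(a, b), tolerance = 1e-10)
  }
  # Welch flag departs from pooled variance when variances differ
  a <- c(1, 2, 3, 10); b <- c(4, 4.1, 4.2)
  expect_false(isTRUE(all.equal(
    t_test_counts(a, b, "independent", welch = TRUE)$df, 5)))
  # paired t equals the one-sample t on differences
  a <- c(5, 7, 9, 4); b <- c(4, 6, 10, 2)
  got <- t_test_counts(a, b, mode = "paired")
  d <- a - b
  expect_equal(got$statistic, mean(d) / (sd(d) / sqrt(length(d))))
  expect_error(t_test_counts(1:3, 1:4, mode = "paired"), "equal lengths")
  expect_error(t_test_counts(1, 1:5, mode = "independent"), "at least 2")
})

test_that("sectioning loss percentage mirrors the count arithmetic", {
  expect_equal(loss_percentage(200, 185), 7.5)
  expect_equal(loss_percentage(100, 100), 0.0)
  expect_equal(loss_percentage(100, 0), 100.0)
  expect_warning(got <- loss_percentage(100, 110), "negative")
  expect_equal(got, -10)
  expect_error(loss_percentage(0, 0), "positive")
})
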