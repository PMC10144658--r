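test_that("association direction is sum-zero and finds a planted taxon", {
  clr <- get_filtered_clr(1)
  set.seed(4)
  fac <- stats::rnorm(nrow(clr))
  dir <- association_direction(clr, fac, "noise")
  expect_equal(sum(dir$v), 0, tolerance = 1e-9)
  expect_equal(dir$n, nrow(clr))
  # factor equal to one clr column: that column dominates the direction
  taxon <- colnames(clr)[10]
  dir2 <- association_direction(clr, unclass(clr)[, taxon], taxon)
  expect_equal(names(which.max(dir2$v)), taxon)
  expect_error(association_direction(clr, rep(1, nrow(clr))), "constant")
  # two-level categorical: difference of group mean clr vectors
  grp <- rep(c("lo", "hi"), length.out = nrow(clr))
  dir3 <- association_direction(clr, grp, "grp")
  manual <- colMeans(unclass(clr)[grp == "hi", ]) -
    colMeans(unclass(clr)[grp == "lo", ])
  expect_equal(unname(dir3$v), unname(manual), tolerance = 1e-12)
})

test_that("nearest balance solves small cases exactly", {
  nb <- nearest_balance(c(a = 1, b = -1))
  expect_equal(nb$numerator, "a")
  expect_equal(nb$denominator, "b")
  expect_equal(attr(nb, "cosine"), 1, tolerance = 1e-12)
  # v = (2, 1, -3): the 2-vs-1 split beats the 1-vs-1 splits
  nb2 <- nearest_balance(c(t1 = 2, t2 = 1, t3 = -3))
  expect_setequal(nb2$numerator, c("t1", "t2"))
  expect_equal(nb2$denominator, "t3")
  expect_gt(attr(nb2, "cosine"), 0.98)
  expect_error(nearest_balance(c(a = 0, b = 0)), "degenerate")
})

test_that("nearest balance matches brute force on random directions", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(2:8, 1)
    v <- random_direction(n)
    fast <- nearest_balance(v)
    slow <- brute_force_nearest_balance(v)
    expect_equal(attr(fast, "cosine"), attr(slow, "cosine"),
                 tolerance = 1e-12)
    expect_setequal(fast$numerator, slow$numerator)
    expect_setequal(fast$denominator, slow$denominator)
  }
  expect_error(brute_force_nearest_balance(random_direction(13)), "n <= 12")
})

test_that("ties are broken identically in the scan and the oracle", {
  # exactly tied components: the shared rule (taxon id order, smaller
  # balance preferred) must give identical sides
  tied <- list(c(b = 1, a = 1, d = -1, c = -1),
               c(x = 2, y = 2, z = -4),
               c(p = 1, q = 0, r = -1, s = 0))
  for (v in tied) {
    fast <- nearest_balance(v)
    slow <- brute_force_nearest_balance(v)
    expect_identical(fast$numerator, slow$numerator)
    expect_identical(fast$denominator, slow$denominator)
    expect_equal(attr(fast, "cosine"), attr(slow, "cosine"),
                 tolerance = 1e-12)
  }
})

test_that("flipping the factor sign swaps numerator and denominator", {
  set.seed(23)
  for (i in 1:10) {
    v <- random_direction(sample(4:30, 1))
    nb <- nearest_balance(v)
    nb_flip <- nearest_balance(-v)
    expect_setequal(nb_flip$numerator, nb$denominator)
    expect_setequal(nb_flip$denominator, nb$numerator)
  }
  # and through the full data path
  clr <- get_filtered_clr(1)
  f <- get_cohort(1)$metadata$parameters[, "factor_planted"]
  d1 <- association_direction(clr, f)
  d2 <- association_direction(clr, -f)
  expect_equal(d1$v, -d2$v, tolerance = 1e-12)
})

test_that("cross-validated balance recovers a strong planted effect", {
  coh <- get_cohort(5)
  clrf <- get_filtered_clr(5)
  f <- coh$metadata$parameters[, "factor_planted"]
  rb <- cross_validated_balance(clrf, f, analysis_config(seed = 5),
                                "factor_planted")
  tr <- coh$truth$balances$factor_planted
  expect_false(rb$empty)
  expect_true(all(tr$numerator %in% rb$balance$numerator))
  expect_true(all(tr$denominator %in% rb$balance$denominator))
  expect_true(all(rb$counts$numerator_count <= rb$cv_iterations))
  # a taxon never lands on both sides of the final balance
  expect_length(intersect(rb$balance$numerator, rb$balance$denominator), 0)
  tab <- balance_membership_table(rb)
  expect_true(all(tab$reproducibility > 0.9))
  expect_true(all(tab$coefficient[tab$side == "numerator"] > 0))
  expect_true(all(tab$coefficient[tab$side == "denominator"] < 0))
})

test_that("cross-validated balance is deterministic and correlates with
           the factor in the right direction", {
  coh <- get_cohort(6)
  clrf <- get_filtered_clr(6)
  f <- coh$metadata$parameters[, "factor_planted"]
  cfg <- analysis_config(seed = 99)
  rb1 <- cross_validated_balance(clrf, f, cfg, "factor_planted")
  rb2 <- cross_validated_balance(clrf, f, cfg, "factor_planted")
  expect_identical(rb1$counts, rb2$counts)
  expect_identical(rb1$balance, rb2$balance)
  bv <- balance_values(clrf, rb1$balance)
  expect_gt(stats::cor(bv, f), 0)  # numerator side = positive association
})

test_that("null factors yield at most a handful of reproducible taxa", {
  # under a null factor the reproducibility screen cannot certify the
  # planted 14-taxon structure: at most a few spurious taxa clear the
  # >90/100 bar, and runs where one side stays empty are flagged, not
  # errors
  clrf <- get_filtered_clr(7)
  for (s in 1:5) {
    f <- with(list(), { set.seed(1000 + s); stats::rnorm(nrow(clrf)) })
    rb <- cross_validated_balance(clrf, f, analysis_config(seed = s), "null")
    n_pass <- sum(rb$counts$numerator_count > rb$cv_threshold) +
      sum(rb$counts$denominator_count > rb$cv_threshold)
    expect_lte(n_pass, 6)
    if (rb$empty) {
      expect_null(rb$balance)
      expect_equal(nrow(balance_membership_table(rb)), 0)
    }
  }
  # an unreachable threshold always produces the flagged empty result
  coh <- get_cohort(7)
  f2 <- coh$metadata$parameters[, "factor_planted"]
  cfg <- analysis_config(cv_iterations = 20, cv_threshold = 20, seed = 7)
  rb2 <- cross_validated_balance(clrf, f2, cfg, "unreachable")
  expect_true(rb2$empty)
})
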