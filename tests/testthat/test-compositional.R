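test_that("clr transform matches closed forms and is scale-invariant", {
  ct <- count_table(matrix(c(5, 5, 5, 5), 1, 4,
                           dimnames = list("s1", paste0("t", 1:4))))
  expect_equal(unname(clr_transform(ct)[1, ]), rep(0, 4))
  # counts (1, 0) with pseudocount 0.5 -> clr of (1, 0.5)
  ct2 <- count_table(matrix(c(1, 0), 1, 2,
                            dimnames = list("s1", c("a", "b"))))
  expect_equal(unname(clr_transform(ct2, 0.5)[1, ]),
               c(log(2) / 2, -log(2) / 2), tolerance = 1e-12)
  m <- matrix(c(3, 1, 6, 30, 10, 60), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  v <- clr_transform(count_table(m))
  expect_equal(unname(v[1, ]), unname(v[2, ]), tolerance = 1e-12)
  expect_equal(unname(rowSums(v)), c(0, 0), tolerance = 1e-9)
  expect_error(clr_transform(count_table(
    matrix(c(0, 0), 1, 2, dimnames = list("s1", c("a", "b"))))), "all-zero")
  expect_error(clr_transform(m, pseudocount = 0), "positive")
})

test_that("clr rows of simulated data are sum-zero", {
  clr <- clr_transform(get_cohort(1)$counts)
  expect_true(all(abs(rowSums(clr)) < 1e-9))
})

test_that("Aitchison distance matches the closed form and clr Euclidean", {
  comp <- rbind(x = c(0.5, 0.5), y = c(0.8, 0.2))
  colnames(comp) <- c("a", "b")
  d <- aitchison_distance(clr_transform(comp))
  expect_equal(d["x", "y"], sqrt(2) * log(2), tolerance = 1e-12)
  expect_equal(unname(diag(d)), c(0, 0))
  clr <- clr_transform(get_cohort(1)$counts)
  d2 <- aitchison_distance(clr)
  expect_equal(d2[3, 7],
               sqrt(sum((clr[3, ] - clr[7, ])^2)), tolerance = 1e-9)
  expect_equal(d2, t(d2))
})

test_that("Aitchison distance is perturbation-invariant", {
  set.seed(91)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    x <- stats::runif(k); y <- stats::runif(k); z <- stats::runif(k)
    perturb <- function(a, b) { p <- a * b; p / sum(p) }
    comp1 <- rbind(x / sum(x), y / sum(y))
    comp2 <- rbind(perturb(x, z), perturb(y, z))
    dimnames(comp1) <- dimnames(comp2) <-
      list(c("u", "v"), paste0("t", 1:k))
    d1 <- aitchison_distance(clr_transform(comp1))
    d2 <- aitchison_distance(clr_transform(comp2))
    expect_equal(d1["u", "v"], d2["u", "v"], tolerance = 1e-9)
  }
})

test_that("rarefaction conserves depth and is a no-op at exact depth", {
  coh <- get_cohort(3)
  rare <- coopbalance::rarefy(coh$counts, 10459, seed = 8)
  expect_true(all(rowSums(rare$counts) == 10459))
  expect_true(all(rare$counts <= coh$counts$counts))
  exact <- count_table(matrix(c(3, 7), 1, 2,
                              dimnames = list("s1", c("a", "b"))))
  expect_equal(coopbalance::rarefy(exact, 10, seed = 1)$counts,
               exact$counts)
  expect_error(coopbalance::rarefy(exact, 11, seed = 1), "s1")
  # determinism
  r2 <- coopbalance::rarefy(coh$counts, 10459, seed = 8)
  expect_identical(rare$counts, r2$counts)
})

test_that("rarefaction is hypergeometric in expectation", {
  ct <- count_table(matrix(c(30, 70), 1, 2,
                           dimnames = list("s1", c("a", "b"))))
  draws <- vapply(1:200, function(s)
    coopbalance::rarefy(ct, 50, seed = s)$counts[1, "a"], 1)
  # taxon a: proportion 0.3 of 100 reads, draw 50 without replacement
  expected <- 0.3 * 50
  se <- sqrt(50 * 0.3 * 0.7 * (100 - 50) / (100 - 1)) / sqrt(200)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("Shannon and Chao1 match closed forms", {
  even8 <- count_table(matrix(rep(5, 8), 1, 8,
                              dimnames = list("s1", paste0("t", 1:8))))
  expect_equal(unname(shannon(even8, base = 2)), 3)
  expect_equal(unname(shannon(even8, base = exp(1))),
               3 * log(2), tolerance = 1e-12)
  single <- count_table(matrix(9, 1, 1, dimnames = list("s1", "t1")))
  expect_equal(unname(shannon(single)), 0)
  # S_obs = 10, F1 = 2, F2 = 1 -> 10 + 2*1/(2*2) = 10.5
  cts <- c(1, 1, 2, 5, 5, 5, 5, 5, 5, 5)
  tab <- count_table(matrix(cts, 1, dimnames = list("s1", paste0("t", 1:10))))
  expect_equal(unname(chao1(tab)), 10.5)
  no_singletons <- count_table(matrix(c(2, 3, 4), 1,
                                      dimnames = list("s1", paste0("t", 1:3))))
  expect_equal(unname(chao1(no_singletons)), 3)
})

test_that("Shannon agrees with vegan and Chao1 dominates observed richness", {
  skip_if_not_installed("vegan")
  coh <- get_cohort(1)
  rare <- coopbalance::rarefy(coh$counts, "min", seed = 1)
  sh <- shannon(rare, base = exp(1))
  sh_vegan <- vegan::diversity(rare$counts, index = "shannon")
  expect_equal(unname(sh), unname(sh_vegan), tolerance = 1e-9)
  expect_true(all(chao1(rare) >= rowSums(rare$counts > 0)))
  div <- diversity_table(rare)
  expect_true(all(div$shannon >= 0))
  expect_equal(div$depth, unname(rowSums(rare$counts)))
})

test_that("balance coefficients are unit-norm, sum-zero, and both value
           formulas agree", {
  taxa <- paste0("t", 1:10)
  bal <- balance(taxa[1:3], taxa[4:10])
  b <- balance_coefficients(bal, taxa)
  expect_equal(sum(b^2), 1, tolerance = 1e-12)
  expect_equal(sum(b), 0, tolerance = 1e-12)
  clr <- clr_transform(get_cohort(1)$counts)
  set.seed(12)
  for (i in 1:20) {
    sides <- sample(colnames(clr), sample(4:20, 1))
    cut <- sample(seq(1, length(sides) - 1), 1)
    bal <- balance(sides[seq_len(cut)], sides[-seq_len(cut)])
    direct <- balance_values(clr, bal)
    via_dot <- as.vector(unclass(clr)[, colnames(clr)] %*%
                           balance_coefficients(bal, colnames(clr)))
    expect_equal(unname(direct), via_dot, tolerance = 1e-9)
  }
  # p = q = 1 at relative abundance (0.8, 0.2): sqrt(1/2) * ln 4
  comp <- matrix(c(0.8, 0.2), 1, dimnames = list("s", c("a", "b")))
  bv <- balance_values(clr_transform(comp), balance("a", "b"))
  expect_equal(unname(bv), sqrt(0.5) * log(4), tolerance = 1e-12)
  expect_error(balance("a", "a"), "overlap")
  expect_error(balance(character(0), "b"), "non-empty")
})

test_that("balance values are invariant to per-sample count scaling", {
  m <- matrix(c(10, 20, 30, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  clr <- clr_transform(count_table(m))
  bv <- balance_values(clr, balance("a", c("b", "c")))
  expect_equal(bv[["s1"]], bv[["s2"]], tolerance = 1e-12)
})

test_that("PCoA on Aitchison distances is an exact Euclidean embedding", {
  comp <- rbind(c(0.2, 0.3, 0.5), c(0.1, 0.6, 0.3), c(0.4, 0.4, 0.2))
  dimnames(comp) <- list(c("s1", "s2", "s3"), c("a", "b", "c"))
  clr <- clr_transform(comp)
  d <- aitchison_distance(clr)
  ord <- pcoa_biplot(d, clr, n_axes = 2)
  d_embed <- as.matrix(stats::dist(ord$coordinates))
  expect_equal(unname(d_embed), unname(d), tolerance = 1e-9)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_lte(sum(ord$variance_explained), 1 + 1e-12)
})

test_that("PCoA reproduces clr PCA scores up to sign, arrows rank taxa", {
  clr <- get_filtered_clr(1)
  d <- aitchison_distance(clr)
  ord <- pcoa_biplot(d, clr, n_axes = 2)
  expect_true(all(ord$eigenvalues > -1e-9 * max(ord$eigenvalues)))
  pca <- stats::prcomp(unclass(clr), center = TRUE, scale. = FALSE)
  for (k in 1:2) {
    r <- abs(stats::cor(ord$coordinates[, k], pca$x[, k]))
    expect_gt(r, 1 - 1e-9)
  }
  expect_equal(nrow(ord$arrows), ncol(clr))
  top <- names(ord$taxon_rank)[1]
  expect_equal(sum(ord$arrows[top, ]^2), max(rowSums(ord$arrows^2)))
})
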