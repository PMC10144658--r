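make_meta <- function(params, group = NULL) {
  ids <- rownames(params)
  if (is.null(group)) group <- rep("A", nrow(params))
  pg <- stats::setNames(rep("grp1", ncol(params)), colnames(params))
  sample_metadata(stats::setNames(group, ids), params, pg)
}

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(2)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("parameter de-duplication clusters by connected components", {
  n <- 60
  set.seed(31)
  z <- stats::rnorm(n)
  params <- cbind(par_a = z, par_b = z + stats::rnorm(n, 0, 1e-6))
  rownames(params) <- sprintf("s%02d", 1:n)
  scr <- dedup_parameters(make_meta(params), "grp1")
  expect_length(scr$retained, 1)
  expect_equal(nrow(scr$dropped), 1)
  # chain a-b, b-c correlated, a-c weaker: still one component
  a <- stats::rnorm(n)
  b <- sign(a) * abs(a)^0.7 + stats::rnorm(n, 0, 0.12)
  c_ <- sign(b) * abs(b)^0.7 + stats::rnorm(n, 0, 0.12)
  chain <- cbind(pa = a, pb = b, pc = c_)
  rownames(chain) <- rownames(params)
  sp <- stats::cor(chain, method = "spearman")
  # construction sanity for the chain shape
  expect_gt(sp["pa", "pb"], 0.8)
  expect_gt(sp["pb", "pc"], 0.8)
  scr2 <- dedup_parameters(make_meta(chain), "grp1")
  expect_length(scr2$retained, 1)
  expect_setequal(scr2$dropped$parameter,
                  setdiff(c("pa", "pb", "pc"), scr2$retained))
  # independent parameters are all retained
  ind <- matrix(stats::rnorm(n * 3), n,
                dimnames = list(rownames(params), c("x", "y", "z")))
  scr3 <- dedup_parameters(make_meta(ind), "grp1")
  expect_length(scr3$retained, 3)
  # representative = fewest missing values
  withna <- cbind(full = z, holey = z + stats::rnorm(n, 0, 1e-6))
  withna[1:5, "holey"] <- NA
  rownames(withna) <- rownames(params)
  scr4 <- dedup_parameters(make_meta(withna), "grp1")
  expect_equal(scr4$retained, "full")
})

test_that("alpha association recovers exact and null relations", {
  set.seed(7)
  div <- stats::setNames(stats::rnorm(40, 5), sprintf("s%02d", 1:40))
  res <- suppressWarnings(alpha_assoc(div, unname(div),
                                      factor_name = "self"))
  expect_lt(res$p, 1e-20)
  expect_equal(res$statistic, 1, tolerance = 1e-9)
  # categorical with identical group means: F near 0 on a constructed set
  div2 <- stats::setNames(rep(c(1, 2, 3, 4), 10), sprintf("s%02d", 1:40))
  grp <- rep(c("a", "b"), each = 20)
  res2 <- alpha_assoc(div2, grp)
  expect_lt(res2$statistic, 1e-12)
  expect_error(alpha_assoc(div, rep(1, 40)), "constant")
  expect_error(alpha_assoc(div[1:5], unname(div[1:5])), ">= 10")
})

test_that("permutation beta test matches vegan adonis2 on F and R2", {
  skip_if_not_installed("vegan")
  coh <- get_cohort(3)
  rare <- coopbalance::rarefy(coh$counts, "min", seed = 1)
  d <- aitchison_distance(clr_transform(rare))
  grp <- coh$metadata$group
  mine <- permutation_beta_test(d, grp, n_perm = 199, seed = 5, "group")
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, data = data.frame(g = grp),
                        permutations = 199)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-9)
  expect_equal(mine$r2, ref$R2[1], tolerance = 1e-9)
  f <- coh$metadata$parameters[, "factor_planted"]
  mine2 <- permutation_beta_test(d, f, n_perm = 199, seed = 5, "f")
  ref2 <- vegan::adonis2(stats::as.dist(d) ~ f, data = data.frame(f = f),
                         permutations = 199)
  expect_equal(mine2$statistic, ref2$F[1], tolerance = 1e-9)
  expect_equal(mine2$r2, ref2$R2[1], tolerance = 1e-9)
  expect_equal(mine2$p, 1 / 200)  # planted effect: every permutation beaten
})

test_that("the categorical engine equals the continuous engine on 0/1
           coding", {
  coh <- get_cohort(3)
  rare <- coopbalance::rarefy(coh$counts, "min", seed = 1)
  d <- aitchison_distance(clr_transform(rare))
  two <- rep(c("u", "v"), length.out = nrow(d))
  cat_res <- permutation_beta_test(d, two, n_perm = 99, seed = 7, "two")
  num_res <- permutation_beta_test(d, as.numeric(two == "v"),
                                   n_perm = 99, seed = 7, "two")
  expect_equal(cat_res$statistic, num_res$statistic, tolerance = 1e-9)
  expect_equal(cat_res$r2, num_res$r2, tolerance = 1e-9)
  expect_equal(cat_res$p, num_res$p)
})

test_that("a saturated grouping explains all distance variance", {
  d <- aitchison_distance(get_filtered_clr(1)[1:12, ])
  each_own <- paste0("g", 1:12)
  res <- permutation_beta_test(d, each_own, n_perm = 19, seed = 1, "sat")
  expect_equal(res$r2, 1, tolerance = 1e-9)
})

test_that("coop balance associations recover a constructed slope and
           respect sign flips", {
  coh <- get_cohort(9)
  clrf <- get_filtered_clr(9)
  net <- infer_network(clrf, analysis_config(seed = 9))
  part <- louvain_coops(net, seed = 9)
  expect_gt(length(part$communities), 0)
  bal <- coop_balance(part, names(part$communities)[1])
  bv <- balance_values(clrf, bal)
  slopes <- vapply(1:10, function(s) {
    set.seed(300 + s)
    f <- 0.8 * as.vector(scale(bv)) + sqrt(1 - 0.8^2) * stats::rnorm(length(bv))
    res <- coop_balance_assoc(clrf, part, f, "constructed")
    res$statistic[res$feature == paste0("coop:", names(part$communities)[1])]
  }, 1)
  expect_lt(abs(mean(slopes) - 0.8), 0.1)
  set.seed(41)
  f <- stats::rnorm(nrow(clrf))
  r1 <- coop_balance_assoc(clrf, part, f, "f")
  r2 <- coop_balance_assoc(clrf, part, -f, "f")
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  # null factors rarely show big standardised slopes at this n
  null_slopes <- vapply(1:20, function(s) {
    set.seed(500 + s)
    max(abs(coop_balance_assoc(clrf, part,
                               stats::rnorm(nrow(clrf)), "null")$statistic))
  }, 1)
  expect_gte(mean(null_slopes < 0.25), 0.95)
})

test_that("per-taxon clr screen ranks a planted single-taxon effect first", {
  clrf <- get_filtered_clr(2)
  target <- colnames(clrf)[25]
  set.seed(77)
  f <- unclass(clrf)[, target] + stats::rnorm(nrow(clrf), 0, 0.3)
  res <- taxon_clr_assoc(clrf, f, "planted", rank = "genus")
  expect_equal(nrow(res), ncol(clrf))
  expect_equal(res$feature[which.min(res$p)],
               paste0("taxon:genus:", target))
  expect_true(all(res$q >= res$p - 1e-12))
  # null factors: the per-screen BH family keeps the any-discovery
  # rate near its nominal 5%
  hits <- vapply(1:30, function(s) {
    set.seed(600 + s)
    min(taxon_clr_assoc(clrf, stats::rnorm(nrow(clrf)), "null")$q)
  }, 1)
  expect_gte(mean(hits > 0.05), 0.9)
})
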