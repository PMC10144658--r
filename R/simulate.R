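#' Synthetic cohorts with planted ground truth
#'
#' The generator emulates a three-group, 178-sample genus-level 16S
#' cohort: latent log-abundances are multivariate normal with
#' block-correlated "cooperative" genera, per-sample read depths vary,
#' counts are multinomial, planted factors act on the latent clr vector
#' along a chosen balance, and clinical parameters come in highly
#' correlated clusters plus pure-noise nulls. Every planted structure is
#' exported as ground truth for recovery tests.
#'
#' @name synthetic_data_module
NULL

#' Describe a planted factor-balance effect
#'
#' @param factor_name name of the factor in the metadata.
#' @param numerator,denominator disjoint genus indices (1-based into the
#'   scenario's genus list) forming the planted balance.
#' @param beta effect size in clr units per SD of the factor.
#' @param group parameter group the factor is filed under.
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(factor_name, numerator, denominator, beta,
                           group = "planted") {
  if (length(intersect(numerator, denominator)) > 0)
    stop("planted numerator and denominator overlap")
  structure(list(factor_name = factor_name, numerator = as.integer(numerator),
                 denominator = as.integer(denominator), beta = beta,
                 group = group), class = "planted_effect")
}

#' Define a synthetic cohort scenario
#'
#' Defaults mirror the emulated cohort: groups A/N/S of 48/46/86
#' samples, 120 genera, multinomial depths uniform on
#' `[10459, 40000]` (the lower end being the emulated study's minimum
#' depth), four correlated genus blocks (sizes 12/10/8/6, within-block
#' latent correlation 0.7), one planted 7+7-genus balance effect at
#' `beta = 2` on an immune-group factor, and per-group parameter
#' clusters (pairwise Spearman above 0.8) plus null parameters.
#'
#' @param group_sizes named integer vector of samples per group.
#' @param n_genera number of genera.
#' @param depth_range integer range for uniform per-sample depths.
#' @param coop_blocks list of integer vectors of genus indices; each
#'   block shares a latent factor giving within-block correlation
#'   `rho_block`.
#' @param rho_block within-block latent correlation.
#' @param planted_effects list of [planted_effect()]s; may be empty for
#'   a null cohort.
#' @param parameter_spec named list (per parameter group) of lists with
#'   `clusters` (integer vector of cluster sizes) and `n_null`.
#' @param cluster_noise_sd noise SD added to the cluster latent before
#'   the monotone transforms (0.3 keeps pairwise Spearman above 0.8 at
#'   n = 178).
#' @param mu_sd SD of baseline mean log-abundances; 2 gives a
#'   stool-like rank-abundance curve (one dominant genus around 20%,
#'   long tail).
#' @param seed integer seed.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(group_sizes = c(A = 48, N = 46, S = 86),
                               n_genera = 120,
                               depth_range = c(10459, 40000),
                               coop_blocks = list(1:12, 13:22, 23:30, 31:36),
                               rho_block = 0.7,
                               planted_effects = list(
                                 planted_effect("factor_planted",
                                                numerator = 41:47,
                                                denominator = 51:57,
                                                beta = 2, group = "immune")),
                               parameter_spec = list(
                                 immune = list(clusters = c(3L), n_null = 4L),
                                 cardiovascular = list(clusters = c(3L, 2L),
                                                       n_null = 4L),
                                 endothelial = list(clusters = integer(0),
                                                    n_null = 2L),
                                 metabolites = list(clusters = c(3L),
                                                    n_null = 4L)),
                               cluster_noise_sd = 0.3,
                               mu_sd = 2,
                               seed = 1L) {
  if (any(group_sizes < 2)) stop("every group needs >= 2 samples")
  blocks_flat <- unlist(coop_blocks)
  if (anyDuplicated(blocks_flat) > 0) stop("coop blocks must be disjoint")
  if (length(blocks_flat) > 0 && max(blocks_flat) > n_genera)
    stop("coop block genus index out of range")
  for (ef in planted_effects) {
    if (max(c(ef$numerator, ef$denominator)) > n_genera)
      stop("planted effect genus index out of range (factor ",
           ef$factor_name, ")")
  }
  structure(list(group_sizes = group_sizes, n_genera = n_genera,
                 depth_range = depth_range, coop_blocks = coop_blocks,
                 rho_block = rho_block, planted_effects = planted_effects,
                 parameter_spec = parameter_spec,
                 cluster_noise_sd = cluster_noise_sd, mu_sd = mu_sd,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

genus_names <- function(n) sprintf("Genus_%03d", seq_len(n))

synthetic_lineages <- function(n) {
  g <- genus_names(n)
  lin <- empty_lineages(g)
  # nested hierarchy: 3 genera per family, 2 families per order, and so
  # on up to the phylum
  i <- seq_len(n) - 1
  lin$kingdom <- "Bacteria"
  lin$phylum <- sprintf("Phylum_%d", i %/% 30 + 1)
  lin$class <- sprintf("Class_%02d", i %/% 15 + 1)
  lin$order <- sprintf("Order_%02d", i %/% 6 + 1)
  lin$family <- sprintf("Family_%02d", i %/% 3 + 1)
  lin$genus <- g
  lin
}

#' Simulate a count table from a scenario
#'
#' Latent per-sample log-abundances are `mu + z` with `z` multivariate
#' normal (unit variances; within-block correlation `rho_block` via a
#' shared latent factor). Each planted effect adds
#' `beta * f_std * b` to the latent vector, where `b` is the planted
#' balance's unit coefficient vector and `f_std` the standardised
#' factor; counts are multinomial at a per-sample uniform depth.
#'
#' @param s a [synthetic_scenario()].
#' @return list with `counts` (a [count_table()]) and `truth` (a
#'   `ground_truth` list: `coops`, `balances`, `factor_values`,
#'   `null_factors`, `depths`).
#' @export
simulate_counts <- function(s) {
  n <- sum(s$group_sizes)
  p <- s$n_genera
  genera <- genus_names(p)
  samples <- sprintf("S%03d", seq_len(n))
  mu <- with_seed(derive_seed(s$seed, "baseline_mu"),
                  sort(stats::rnorm(p, 0, s$mu_sd), decreasing = TRUE))
  # block-structured latent correlation via shared factors
  z <- with_seed(derive_seed(s$seed, "latent"), {
    e <- matrix(stats::rnorm(n * p), n, p)
    for (blk in s$coop_blocks) {
      u <- stats::rnorm(n)
      e[, blk] <- sqrt(s$rho_block) * u +
        sqrt(1 - s$rho_block) * e[, blk, drop = FALSE]
    }
    e
  })
  lat <- sweep(z, 2, mu, "+")
  factor_values <- list()
  for (ef in s$planted_effects) {
    f <- with_seed(derive_seed(s$seed, paste0("factor/", ef$factor_name)),
                   stats::rnorm(n))
    factor_values[[ef$factor_name]] <- stats::setNames(f, samples)
    b <- balance_coefficients(
      balance(genera[ef$numerator], genera[ef$denominator]), genera)
    f_std <- (f - mean(f)) / stats::sd(f)
    lat <- lat + ef$beta * outer(f_std, unname(b))
  }
  depths <- with_seed(derive_seed(s$seed, "depths"),
                      sample(seq(s$depth_range[1], s$depth_range[2]), n,
                             replace = TRUE))
  counts <- with_seed(derive_seed(s$seed, "multinomial"), {
    out <- matrix(0, n, p, dimnames = list(samples, genera))
    for (i in seq_len(n)) {
      pr <- exp(lat[i, ] - max(lat[i, ]))
      out[i, ] <- stats::rmultinom(1, depths[i], pr / sum(pr))[, 1]
    }
    out
  })
  truth <- structure(list(
    coops = lapply(s$coop_blocks, function(blk) genera[blk]),
    balances = stats::setNames(lapply(s$planted_effects, function(ef)
      list(numerator = genera[ef$numerator],
           denominator = genera[ef$denominator], beta = ef$beta)),
      vapply(s$planted_effects, function(ef) ef$factor_name, "")),
    factor_values = factor_values,
    null_factors = character(0),
    depths = stats::setNames(depths, samples)), class = "ground_truth")
  list(counts = count_table(counts, synthetic_lineages(p)), truth = truth)
}

#' Simulate clinical metadata for a scenario
#'
#' Planted factors are copied from the ground truth. Each specified
#' cluster's parameters are monotone transforms (identity, scaled
#' exponential, cube) of one latent standard normal plus noise of SD
#' `cluster_noise_sd`; null parameters are independent standard normals.
#' Group labels follow `group_sizes` in sample order.
#'
#' @param s a [synthetic_scenario()].
#' @param truth the `ground_truth` from [simulate_counts()] (carries the
#'   planted factor values); its `null_factors` field is filled in.
#' @return list with `metadata` (a [sample_metadata()]) and the updated
#'   `truth`.
#' @export
simulate_metadata <- function(s, truth) {
  n <- sum(s$group_sizes)
  samples <- sprintf("S%03d", seq_len(n))
  group <- stats::setNames(rep(names(s$group_sizes), s$group_sizes), samples)
  transforms <- list(function(x) x,
                     function(x) exp(x / 2),
                     function(x) x^3,
                     function(x) x + 0.1 * x^3,
                     function(x) -1 / (1 + exp(-x)))
  cols <- list()
  pgroups <- character(0)
  null_names <- character(0)
  for (gname in names(s$parameter_spec)) {
    spec <- s$parameter_spec[[gname]]
    for (ci in seq_along(spec$clusters)) {
      h <- with_seed(derive_seed(s$seed, paste0("cluster/", gname), ci),
                     stats::rnorm(n))
      for (k in seq_len(spec$clusters[ci])) {
        eps <- with_seed(
          derive_seed(s$seed, paste0("cluster_noise/", gname, "/", ci), k),
          stats::rnorm(n, 0, s$cluster_noise_sd))
        tr <- transforms[[(k - 1) %% length(transforms) + 1]]
        nm <- sprintf("%s_c%d_p%d", gname, ci, k)
        cols[[nm]] <- tr(h + eps)
        pgroups[nm] <- gname
      }
    }
    nn <- spec$n_null %||% 0L
    for (k in seq_len(nn)) {
      nm <- sprintf("%s_null%d", gname, k)
      cols[[nm]] <- with_seed(derive_seed(s$seed, paste0("null/", gname), k),
                              stats::rnorm(n))
      pgroups[nm] <- gname
      null_names <- c(null_names, nm)
    }
  }
  for (ef in s$planted_effects) {
    cols[[ef$factor_name]] <- unname(truth$factor_values[[ef$factor_name]])
    pgroups[ef$factor_name] <- ef$group
  }
  params <- if (length(cols) > 0) {
    m <- do.call(cbind, cols)
    rownames(m) <- samples
    m
  } else NULL
  truth$null_factors <- null_names
  list(metadata = sample_metadata(group, params, pgroups), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full cohort (counts + metadata + truth)
#'
#' @param s a [synthetic_scenario()].
#' @return list with `counts`, `metadata`, `truth`.
#' @export
simulate_cohort <- function(s) {
  cs <- simulate_counts(s)
  md <- simulate_metadata(s, cs$truth)
  list(counts = cs$counts, metadata = md$metadata, truth = md$truth)
}

#' Write a simulated cohort to disk
#'
#' Counts TSV, metadata TSV and ground-truth JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$counts, file.path(out_dir, "counts.tsv"))
  write_metadata(cohort$metadata, file.path(out_dir, "metadata.tsv"))
  truth <- cohort$truth
  truth$factor_values <- lapply(truth$factor_values, as.list)
  truth$depths <- as.list(truth$depths)
  jsonlite::write_json(unclass(truth),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
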