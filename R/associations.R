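#' Association screens
#'
#' The statistical layer: parameter de-duplication by Spearman
#' clustering, linear models for alpha diversity and balances,
#' a permutation engine for beta diversity (PERMANOVA for categorical
#' factors, distance-based redundancy analysis for continuous ones),
#' per-rank clr association screens, and Benjamini-Hochberg FDR control
#' applied within parameter group and feature family.
#'
#' @name association_module
NULL

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment: `q_(i) = min_{j >= i} m p_(j) / j`,
#' clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' De-duplicate highly correlated parameters
#'
#' Builds a graph on the parameters of one parameter group with an edge
#' wherever `|Spearman rho| > rho` (pairwise complete observations);
#' connected components are clusters of interchangeable measurements,
#' and the member with the fewest missing values (ties broken
#' alphabetically) represents each cluster.
#'
#' @param m a [sample_metadata()].
#' @param group parameter-group name; `NULL` uses all parameters.
#' @param rho correlation threshold (strict `>`).
#' @return a `parameter_screen`: list with `group`, `retained`,
#'   `dropped` (data.frame parameter -> representative).
#' @export
dedup_parameters <- function(m, group = NULL, rho = 0.8) {
  pars <- if (is.null(group)) colnames(m$parameters) else
    names(m$parameter_groups)[m$parameter_groups == group]
  if (length(pars) == 0) stop("no parameters in group: ", group)
  x <- m$parameters[, pars, drop = FALSE]
  k <- length(pars)
  comp <- seq_len(k)  # union-find over parameter indices
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (k > 1) {
    rho_mat <- suppressWarnings(
      stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      if (!is.na(rho_mat[i, j]) && abs(rho_mat[i, j]) > rho) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  clusters <- split(pars, roots)
  n_missing <- colSums(is.na(x))
  retained <- character(0)
  dropped <- list()
  for (cl in clusters) {
    rep_par <- cl[order(n_missing[cl], cl)][1]
    retained <- c(retained, rep_par)
    for (d in setdiff(cl, rep_par))
      dropped[[length(dropped) + 1]] <- data.frame(
        parameter = d, representative = rep_par, stringsAsFactors = FALSE)
  }
  structure(list(group = if (is.null(group)) "all" else group,
                 retained = sort(retained),
                 dropped = if (length(dropped) > 0) do.call(rbind, dropped)
                 else data.frame(parameter = character(),
                                 representative = character(),
                                 stringsAsFactors = FALSE)),
            class = "parameter_screen")
}

assoc_row <- function(feature, factor_name, statistic, r2, p, n,
                      parameter_group = NA_character_) {
  data.frame(feature = feature, factor = factor_name,
             parameter_group = parameter_group, statistic = statistic,
             r2 = r2, p = p, n = n, stringsAsFactors = FALSE)
}

#' Alpha-diversity association
#'
#' Ordinary least squares of a per-sample diversity value on a
#' continuous factor (reports the slope), or a one-way group model for a
#' categorical factor (reports the F statistic).
#'
#' @param div named numeric vector of per-sample diversity (e.g. a
#'   column of [diversity_table()]).
#' @param fac factor vector along the same samples; NAs dropped.
#' @param feature,factor_name labels for the result row.
#' @return one-row data.frame: `feature`, `factor`, `parameter_group`,
#'   `statistic`, `r2`, `p`, `n`.
#' @export
alpha_assoc <- function(div, fac, feature = "alpha", factor_name = "factor") {
  keep <- !is.na(fac) & !is.na(div)
  div <- div[keep]; fac <- fac[keep]
  n <- length(div)
  if (n < 10) stop("alpha_assoc needs >= 10 complete cases")
  if (is.numeric(fac)) {
    if (stats::sd(fac) == 0) stop("factor is constant")
    fit <- stats::lm(div ~ fac)
    sm <- summary(fit)
    assoc_row(feature, factor_name, stat = unname(stats::coef(fit)[2]),
              r2 = sm$r.squared, p = sm$coefficients[2, 4], n = n)
  } else {
    fac <- factor(fac)
    if (nlevels(fac) < 2) stop("factor is constant")
    fit <- stats::lm(div ~ fac)
    an <- stats::anova(fit)
    assoc_row(feature, factor_name, stat = an$`F value`[1],
              r2 = summary(fit)$r.squared, p = an$`Pr(>F)`[1], n = n)
  }
}

#' Permutation test for beta diversity (PERMANOVA / dbRDA)
#'
#' One engine for categorical and continuous factors. The factor is
#' coded into a model matrix X (dummy coding for categorical), the
#' distance matrix is Gower-centred (`G = -C D^2 C / 2`), the model sum
#' of squares is `tr(H G H)` for the hat matrix H of X, and significance
#' comes from permuting sample labels: `p = (1 + #{F_perm >= F}) /
#' (1 + n_perm)`.
#'
#' @param d symmetric distance matrix with sample names.
#' @param fac factor vector along the rows of `d`; NAs dropped.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param factor_name label for the result row.
#' @return one-row data.frame as in [alpha_assoc()], with `statistic` =
#'   pseudo-F; the method (PERMANOVA or dbRDA) is appended to `feature`.
#' @export
permutation_beta_test <- function(d, fac, n_perm = 999, seed = 1L,
                                  factor_name = "factor") {
  d <- as.matrix(d)
  keep <- which(!is.na(fac))
  if (length(keep) < 10) stop("permutation_beta_test needs >= 10 complete cases")
  d <- d[keep, keep, drop = FALSE]
  fac <- fac[keep]
  n <- nrow(d)
  categorical <- !is.numeric(fac)
  if (categorical) {
    fac <- factor(fac)
    if (nlevels(fac) < 2) stop("factor is constant")
    X <- stats::model.matrix(~fac)[, -1, drop = FALSE]
  } else {
    if (stats::sd(fac) == 0) stop("factor is constant")
    X <- matrix(fac, ncol = 1)
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular model matrix for factor ", factor_name)
  G <- -0.5 * d^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  H <- tcrossprod(Q)
  ss_total <- sum(diag(G))
  ss_model <- sum(H * G)
  df_m <- qx$rank
  df_r <- n - 1 - df_m
  f_obs <- (ss_model / df_m) / ((ss_total - ss_model) / df_r)
  # F is monotone in ss_model (ss_total and dfs fixed), so compare
  # permuted model sums of squares directly
  exceed <- 0L
  with_seed(derive_seed(seed, paste0("beta_perm/", factor_name)), {
    for (i in seq_len(n_perm)) {
      pidx <- sample.int(n)
      if (sum(H * G[pidx, pidx]) >= ss_model) exceed <- exceed + 1L
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  assoc_row(feature = if (categorical) "beta:PERMANOVA" else "beta:dbRDA",
            factor_name, stat = f_obs, r2 = ss_model / ss_total, p = p, n = n)
}

#' Coop-balance associations with a factor
#'
#' For every cooperative, the coop balance values (coop genera over all
#' other filtered genera) and the factor are both standardised and the
#' least-squares slope (equal to their Pearson correlation, hence
#' comparable across factors) is reported with its p-value.
#'
#' @param c a `clr_matrix` over the filtered genus universe.
#' @param part a `coop_partition`.
#' @param fac factor vector along the samples of `c`; NAs dropped.
#' @param factor_name label for result rows.
#' @return data.frame with one row per coop (zero-variance balances are
#'   skipped with a warning).
#' @export
coop_balance_assoc <- function(c, part, fac, factor_name = "factor") {
  universe <- igraph::V(part$graph)$name
  rows <- list()
  for (coop_id in names(part$communities)) {
    bal <- coop_balance(part, coop_id, universe)
    bv <- balance_values(c, bal)
    keep <- !is.na(fac)
    bvk <- bv[keep]; fk <- fac[keep]
    if (stats::sd(bvk) == 0) {
      warning("zero-variance balance for ", coop_id, "; skipped")
      next
    }
    if (is.numeric(fk)) {
      ct <- stats::cor.test(bvk, fk, method = "pearson")
      rows[[coop_id]] <- assoc_row(
        feature = paste0("coop:", coop_id), factor_name,
        stat = unname(ct$estimate), r2 = unname(ct$estimate)^2,
        p = ct$p.value, n = length(bvk))
    } else {
      fit <- stats::lm(bvk ~ factor(fk))
      an <- stats::anova(fit)
      rows[[coop_id]] <- assoc_row(
        feature = paste0("coop:", coop_id), factor_name,
        stat = an$`F value`[1], r2 = summary(fit)$r.squared,
        p = an$`Pr(>F)`[1], n = length(bvk))
    }
  }
  if (length(rows) == 0)
    return(assoc_row(character(0), character(0), numeric(0), numeric(0),
                     numeric(0), integer(0))[0, ])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-taxon clr association screen
#'
#' Univariate linear model of each taxon's clr abundance on the factor
#' (standardised slope for continuous factors, one-way F for
#' categorical), with BH adjustment across the taxa of the screen.
#'
#' @param c a `clr_matrix` (one taxonomic rank).
#' @param fac factor vector along the samples; NAs dropped.
#' @param factor_name label for result rows.
#' @param rank optional rank label prefixed to the feature name.
#' @return data.frame with one row per taxon, including a `q` column.
#' @export
taxon_clr_assoc <- function(c, fac, factor_name = "factor", rank = NULL) {
  keep <- !is.na(fac)
  x <- unclass(c)[keep, , drop = FALSE]
  fk <- fac[keep]
  n <- nrow(x)
  prefix <- if (is.null(rank)) "taxon" else paste0("taxon:", rank)
  rows <- lapply(colnames(x), function(taxon) {
    y <- x[, taxon]
    if (stats::sd(y) == 0)
      return(assoc_row(paste0(prefix, ":", taxon), factor_name,
                       stat = 0, r2 = 0, p = 1, n = n))
    if (is.numeric(fk)) {
      ct <- stats::cor.test(y, fk, method = "pearson")
      assoc_row(paste0(prefix, ":", taxon), factor_name,
                stat = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                p = ct$p.value, n = n)
    } else {
      fit <- stats::lm(y ~ factor(fk))
      an <- stats::anova(fit)
      assoc_row(paste0(prefix, ":", taxon), factor_name,
                stat = an$`F value`[1], r2 = summary(fit)$r.squared,
                p = an$`Pr(>F)`[1], n = n)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
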