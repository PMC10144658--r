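#' Nearest-balance selection
#'
#' The nearest balance of a factor is the balance (normalised log-ratio
#' of a numerator taxon set to a denominator taxon set) whose unit
#' coefficient vector has maximal cosine similarity with the factor's
#' association direction in clr space. Because balance coefficients are
#' constant within each side, the optimal numerator for fixed side sizes
#' (p, q) consists of the p largest components of the direction and the
#' optimal denominator of the q smallest, so the search reduces to a
#' scan over (p, q) on the sorted direction.
#'
#' @name nearest_balance_module
NULL

#' Association direction of a factor in clr space
#'
#' For a continuous factor, the per-taxon sample covariance between the
#' clr column and the standardised factor (proportional to per-taxon
#' least-squares slopes). For a two-level categorical factor, the
#' difference of group mean clr vectors. Either way the vector sums to
#' zero because clr rows do.
#'
#' @param c a `clr_matrix` (samples x taxa).
#' @param fac numeric or two-level categorical vector along the samples
#'   of `c`; `NA` entries are dropped (complete-case analysis).
#' @param factor_name label carried through to results.
#' @return an `association_direction`: list with `v` (named per-taxon
#'   vector), `factor_name`, `n`.
#' @export
association_direction <- function(c, fac, factor_name = "factor") {
  keep <- !is.na(fac)
  x <- unclass(c)[keep, , drop = FALSE]
  fac <- fac[keep]
  n <- nrow(x)
  if (n < 10) stop("association_direction needs >= 10 complete cases")
  if (is.numeric(fac)) {
    if (stats::sd(fac) == 0) stop("factor is constant")
    z <- (fac - mean(fac)) / stats::sd(fac)
    v <- as.vector(crossprod(x - rep(colMeans(x), each = n), z)) / (n - 1)
  } else {
    lev <- unique(as.character(fac))
    if (length(lev) != 2)
      stop("categorical factors must have exactly 2 levels here (got ",
           length(lev), ")")
    v <- colMeans(x[fac == lev[2], , drop = FALSE]) -
      colMeans(x[fac == lev[1], , drop = FALSE])
  }
  structure(list(v = stats::setNames(as.numeric(v), colnames(c)),
                 factor_name = factor_name, n = n),
            class = "association_direction")
}

as_direction_vector <- function(v) {
  if (inherits(v, "association_direction")) v <- v$v
  if (is.null(names(v))) names(v) <- paste0("t", seq_along(v))
  v
}

# Canonical taxon order for the balance search: decreasing component
# value, ties by taxon id. Both the scan and the brute-force oracle
# operate in this order so tie-breaking is shared.
canonical_order <- function(v) order(-v, names(v), method = "radix")

# Compare two candidate balances represented by (cosine, p, q, and the
# position sets in canonical order). Preference: higher cosine; then
# fewer taxa in total; then a smaller numerator; then numerator
# positions as early as possible; then denominator positions as late as
# possible. The scan's top-p/bottom-q candidate is maximal under this
# order among all equal-cosine candidates.
candidate_better <- function(cand, best) {
  if (is.null(best)) return(TRUE)
  if (cand$cos != best$cos) return(cand$cos > best$cos)
  st_c <- length(cand$P) + length(cand$Q)
  st_b <- length(best$P) + length(best$Q)
  if (st_c != st_b) return(st_c < st_b)
  if (length(cand$P) != length(best$P)) return(length(cand$P) < length(best$P))
  cmp <- function(a, b) {  # lexicographic on integer vectors
    d <- a - b
    nz <- which(d != 0)
    if (length(nz) == 0) 0 else sign(d[nz[1]])
  }
  pc <- cmp(sort(cand$P), sort(best$P))
  if (pc != 0) return(pc < 0)
  qc <- cmp(sort(cand$Q, decreasing = TRUE), sort(best$Q, decreasing = TRUE))
  if (qc != 0) return(qc > 0)
  FALSE
}

balance_from_positions <- function(taxa_sorted, P, Q, cosv) {
  structure(list(numerator = taxa_sorted[P], denominator = taxa_sorted[Q],
                 cosine = cosv), class = c("nearest_balance_fit"))
}

#' Find the balance nearest to an association direction
#'
#' Maximises cosine similarity between the balance coefficient vector
#' and the direction `v` over all (numerator, denominator) pairs, by
#' scanning side sizes (p, q) on the sorted direction. Ties in `v` are
#' broken by taxon id; ties between (p, q) candidates prefer smaller
#' balances.
#'
#' @param v an [association_direction()] or a named numeric vector
#'   (need not be normalised: the result is scale-invariant).
#' @return a [balance()] with an extra `cosine` attribute giving the
#'   achieved cosine similarity.
#' @export
nearest_balance <- function(v) {
  v <- as_direction_vector(v)
  n <- length(v)
  if (n < 2 || max(v) - min(v) <= 0)
    stop("direction is degenerate (all components equal)")
  ord <- canonical_order(v)
  vs <- v[ord]
  taxa_sorted <- names(v)[ord]
  nv <- sqrt(sum(v^2))
  cum_top <- cumsum(vs)            # sum of top-p components
  cum_bot <- cumsum(rev(vs))       # sum of bottom-q components
  best_cos <- -Inf
  tied <- list()                   # (p, q) pairs achieving best_cos exactly
  for (p in seq_len(n - 1)) {
    q <- seq_len(n - p)
    coef_num <- sqrt(q / (p * (p + q)))
    coef_den <- sqrt(p / (q * (p + q)))
    cosv <- (coef_num * cum_top[p] - coef_den * cum_bot[q]) / nv
    m <- max(cosv)
    if (m > best_cos) {
      best_cos <- m
      tied <- lapply(which(cosv == m), function(qi) c(p, q[qi]))
    } else if (m == best_cos) {
      tied <- c(tied, lapply(which(cosv == m), function(qi) c(p, q[qi])))
    }
  }
  best <- NULL
  for (pq in tied) {
    cand <- list(cos = best_cos, P = seq_len(pq[1]),
                 Q = seq(n - pq[2] + 1, n))
    if (candidate_better(cand, best)) best <- cand
  }
  out <- balance(taxa_sorted[best$P], taxa_sorted[best$Q])
  # recompute the cosine from the final membership (ascending index
  # order) so it is bit-identical to a direct evaluation of the same
  # balance
  p <- length(best$P); q <- length(best$Q)
  attr(out, "cosine") <- (sqrt(q / (p * (p + q))) * sum(vs[best$P]) -
                            sqrt(p / (q * (p + q))) * sum(vs[best$Q])) / nv
  out
}

#' Exhaustive nearest-balance search (test oracle)
#'
#' Enumerates every assignment of taxa to numerator / denominator /
#' excluded (3^n assignments, both sides non-empty) and returns the
#' cosine-optimal balance under the same tie-breaking rule as
#' [nearest_balance()]. Exponential; refuses n > 12.
#'
#' @param v an [association_direction()] or named numeric vector.
#' @return a [balance()] with a `cosine` attribute.
#' @export
brute_force_nearest_balance <- function(v) {
  v <- as_direction_vector(v)
  n <- length(v)
  if (n > 12) stop("brute force limited to n <= 12 taxa")
  if (n < 2 || max(v) - min(v) <= 0)
    stop("direction is degenerate (all components equal)")
  ord <- canonical_order(v)
  vs <- v[ord]
  taxa_sorted <- names(v)[ord]
  nv <- sqrt(sum(v^2))
  M <- as.matrix(expand.grid(rep(list(0:2), n)))
  in_num <- M == 1
  in_den <- M == 2
  p <- rowSums(in_num)
  q <- rowSums(in_den)
  ok <- p >= 1 & q >= 1
  s_num <- in_num %*% vs
  s_den <- in_den %*% vs
  cosv <- (sqrt(q / (p * (p + q))) * s_num -
             sqrt(p / (q * (p + q))) * s_den) / nv
  best <- NULL
  for (i in which(ok & cosv >= max(cosv[ok]) - 1e-12)) {
    cand <- list(cos = cosv[i], P = which(in_num[i, ]), Q = which(in_den[i, ]))
    if (candidate_better(cand, best)) best <- cand
  }
  out <- balance(taxa_sorted[best$P], taxa_sorted[best$Q])
  attr(out, "cosine") <- best$cos
  out
}

#' Cross-validated (reproducible) nearest balance
#'
#' Draws `cv_iterations` random half-sample subsets (floor(n/2) of the
#' complete cases, without replacement), finds the nearest balance of
#' the factor in each, and tallies on which side each taxon lands. Taxa
#' assigned to the numerator in more than `cv_threshold` iterations (or
#' to the denominator in more than `cv_threshold`) form the final
#' reproducible balance. If no taxon passes on one of the sides the
#' result is flagged empty rather than an error.
#'
#' @param c a `clr_matrix`.
#' @param fac factor vector along the samples of `c` (NAs dropped).
#' @param config an [analysis_config()]; uses `cv_iterations`,
#'   `cv_threshold` and `seed`.
#' @param factor_name label used in outputs and for seed derivation.
#' @return a `reproducible_balance`: list with `counts` (data.frame of
#'   per-taxon side tallies), `balance` (a [balance()] or `NULL`),
#'   `coefficients` (full-data association direction restricted to the
#'   final taxa), `empty` flag, `n`, `cv_iterations`, `cv_threshold`.
#' @export
cross_validated_balance <- function(c, fac, config = analysis_config(),
                                    factor_name = "factor") {
  keep <- which(!is.na(fac))
  if (length(keep) < 20)
    stop("cross_validated_balance needs >= 20 complete cases")
  x <- unclass(c)[keep, , drop = FALSE]
  fac <- fac[keep]
  n <- nrow(x)
  half <- floor(n / 2)
  taxa <- colnames(x)
  tally_num <- stats::setNames(integer(length(taxa)), taxa)
  tally_den <- tally_num
  for (it in seq_len(config$cv_iterations)) {
    idx <- with_seed(derive_seed(config$seed, paste0("cv_nb/", factor_name), it),
                     sample.int(n, half, replace = FALSE))
    fit <- tryCatch({
      dir_it <- association_direction(x[idx, , drop = FALSE], fac[idx],
                                      factor_name)
      nearest_balance(dir_it)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    tally_num[fit$numerator] <- tally_num[fit$numerator] + 1L
    tally_den[fit$denominator] <- tally_den[fit$denominator] + 1L
  }
  num_final <- taxa[tally_num > config$cv_threshold]
  den_final <- taxa[tally_den > config$cv_threshold]
  full_dir <- association_direction(x, fac, factor_name)
  empty <- length(num_final) == 0 || length(den_final) == 0
  bal <- if (!empty) balance(num_final, den_final) else NULL
  final_taxa <- c(num_final, den_final)
  structure(list(
    counts = data.frame(taxon = taxa,
                        numerator_count = unname(tally_num),
                        denominator_count = unname(tally_den),
                        stringsAsFactors = FALSE),
    balance = bal,
    coefficients = full_dir$v[final_taxa],
    empty = empty,
    n = n,
    cv_iterations = config$cv_iterations,
    cv_threshold = config$cv_threshold,
    factor_name = factor_name), class = "reproducible_balance")
}

#' @export
print.reproducible_balance <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("reproducible_balance (%s): no reproducible balance (n=%d)\n",
                x$factor_name, x$n))
  } else {
    cat(sprintf("reproducible_balance (%s): %d + %d taxa, n=%d\n",
                x$factor_name, length(x$balance$numerator),
                length(x$balance$denominator), x$n))
  }
  invisible(x)
}

#' Export a reproducible balance as a tidy membership table
#'
#' One row per taxon in the final balance: side, reproducibility
#' fraction over the CV iterations, and the full-data association
#' coefficient (the data behind the balance bar plots).
#'
#' @param rb a `reproducible_balance`.
#' @return data.frame with columns `taxon`, `side`, `reproducibility`,
#'   `coefficient`.
#' @export
balance_membership_table <- function(rb) {
  if (rb$empty)
    return(data.frame(taxon = character(), side = character(),
                      reproducibility = numeric(), coefficient = numeric(),
                      stringsAsFactors = FALSE))
  rows <- rbind(
    data.frame(taxon = rb$balance$numerator, side = "numerator",
               stringsAsFactors = FALSE),
    data.frame(taxon = rb$balance$denominator, side = "denominator",
               stringsAsFactors = FALSE))
  cnt <- rb$counts
  rownames(cnt) <- cnt$taxon
  rows$reproducibility <- ifelse(
    rows$side == "numerator",
    cnt[rows$taxon, "numerator_count"],
    cnt[rows$taxon, "denominator_count"]) / rb$cv_iterations
  rows$coefficient <- unname(rb$coefficients[rows$taxon])
  rows[order(rows$side == "denominator", -rows$coefficient), ]
}
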