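#' Compositional transforms and diversity
#'
#' The centred log-ratio (clr) maps each sample's composition into a
#' sum-zero Euclidean space; all of the package's statistics (Aitchison
#' distance, balances, association directions) live in that geometry.
#'
#' @name compositional
NULL

#' Rarefy a count table
#'
#' Subsamples every sample without replacement down to exactly `depth`
#' reads (multivariate hypergeometric draw), deterministically for a
#' given seed.
#'
#' @param t a [count_table()].
#' @param depth integer target depth, or `"min"` for the smallest sample
#'   total.
#' @param seed integer seed.
#' @return a rarefied [count_table()].
#' @export
rarefy <- function(t, depth = "min", seed = 1L) {
  totals <- rowSums(t$counts)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  short <- sample_ids(t)[totals < depth]
  if (length(short) > 0)
    stop("samples with fewer reads than the rarefaction depth (", depth,
         "): ", paste(short, collapse = ", "))
  out <- t$counts
  nt <- ncol(out)
  for (i in seq_len(nrow(out))) {
    if (totals[i] == depth) next
    pool <- rep.int(seq_len(nt), out[i, ])
    drawn <- with_seed(derive_seed(seed, "rarefy", i),
                       sample(pool, depth, replace = FALSE))
    out[i, ] <- tabulate(drawn, nbins = nt)
  }
  count_table(out, t$lineages)
}

#' Centred log-ratio transform
#'
#' Zero counts are replaced by `pseudocount`, each sample is closed to
#' proportions, logs are taken and the per-sample mean log (log
#' geometric mean) is subtracted, so every row sums to zero.
#'
#' @param t a [count_table()] or a non-negative matrix (samples x taxa).
#' @param pseudocount positive replacement for zeros (default 0.5, in
#'   count units).
#' @return a `clr_matrix`: a numeric matrix (samples x taxa) of class
#'   `clr_matrix` whose rows sum to zero.
#' @export
clr_transform <- function(t, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  x <- if (inherits(t, "count_table")) t$counts else as.matrix(t)
  if (any(rowSums(x) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  x[x == 0] <- pseudocount
  lp <- log(x / rowSums(x))
  v <- lp - rowMeans(lp)
  class(v) <- c("clr_matrix", class(v))
  v
}

#' Aitchison distance matrix
#'
#' Pairwise Euclidean distance between clr rows; the compositional
#' metric used for beta diversity and ordination.
#'
#' @param c a `clr_matrix` from [clr_transform()].
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
aitchison_distance <- function(c) {
  as.matrix(stats::dist(unclass(c), method = "euclidean"))
}

#' Shannon diversity
#'
#' `-sum(pi * log(pi))` over non-zero proportions per sample; base 2 by
#' default (bits).
#'
#' @param t a [count_table()]; should normally be rarefied first (a
#'   message is emitted when sample depths are unequal).
#' @param base logarithm base.
#' @return named numeric vector, one value per sample.
#' @export
shannon <- function(t, base = 2) {
  totals <- rowSums(t$counts)
  if (length(unique(totals)) > 1)
    msg("shannon: sample depths are unequal; rarefaction is recommended")
  apply(t$counts, 1, function(r) {
    p <- r[r > 0] / sum(r)
    -sum(p * log(p, base = base))
  })
}

#' Chao1 richness estimate
#'
#' `S_obs + F1*(F1-1) / (2*(F2+1))` per sample, where F1 and F2 are the
#' singleton and doubleton counts.
#'
#' @param t a [count_table()] of integer (rarefied) counts.
#' @return named numeric vector, one value per sample.
#' @export
chao1 <- function(t) {
  apply(t$counts, 1, function(r) {
    s_obs <- sum(r > 0)
    f1 <- sum(r == 1)
    f2 <- sum(r == 2)
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  })
}

#' Per-sample alpha-diversity table
#'
#' @param t a [count_table()] (rarefied).
#' @param base Shannon logarithm base.
#' @return data.frame with columns `sample`, `shannon`, `chao1`,
#'   `depth`.
#' @export
diversity_table <- function(t, base = 2) {
  data.frame(sample = sample_ids(t),
             shannon = unname(shannon(t, base = base)),
             chao1 = unname(chao1(t)),
             depth = unname(rowSums(t$counts)),
             stringsAsFactors = FALSE)
}

#' Define a balance between two disjoint taxon sets
#'
#' A balance is a normalised log-contrast: numerator set P (size p) gets
#' coefficient `+sqrt(q/(p(p+q)))`, denominator set Q (size q) gets
#' `-sqrt(p/(q(p+q)))`, all other taxa 0. The coefficient vector has
#' unit Euclidean norm and zero sum, so the per-sample balance value is
#' its dot product with the sample's clr row.
#'
#' @param numerator,denominator non-empty, disjoint character vectors of
#'   taxon ids.
#' @return a `balance` object.
#' @export
balance <- function(numerator, denominator) {
  if (length(numerator) == 0 || length(denominator) == 0)
    stop("balance numerator and denominator must be non-empty")
  if (length(intersect(numerator, denominator)) > 0)
    stop("balance numerator and denominator overlap")
  structure(list(numerator = as.character(numerator),
                 denominator = as.character(denominator)),
            class = "balance")
}

#' @export
print.balance <- function(x, ...) {
  cat(sprintf("balance: %d taxa / %d taxa\n  num: %s\n  den: %s\n",
              length(x$numerator), length(x$denominator),
              paste(x$numerator, collapse = ", "),
              paste(x$denominator, collapse = ", ")))
  invisible(x)
}

#' Balance coefficient vector over a taxon universe
#'
#' @param bal a [balance()].
#' @param taxa character vector of all taxon ids (must contain both
#'   sides).
#' @return named numeric vector over `taxa`; unit norm, zero sum.
#' @export
balance_coefficients <- function(bal, taxa) {
  missing <- setdiff(c(bal$numerator, bal$denominator), taxa)
  if (length(missing) > 0)
    stop("balance taxa absent from universe: ",
         paste(missing, collapse = ", "))
  p <- length(bal$numerator)
  q <- length(bal$denominator)
  b <- stats::setNames(rep(0, length(taxa)), taxa)
  b[bal$numerator] <- sqrt(q / (p * (p + q)))
  b[bal$denominator] <- -sqrt(p / (q * (p + q)))
  b
}

#' Per-sample balance values
#'
#' Computed as `sqrt(pq/(p+q)) * (mean log over P - mean log over Q)`
#' on the clr rows, which is identical to the dot product of the clr row
#' with the balance coefficient vector.
#'
#' @param c a `clr_matrix`.
#' @param bal a [balance()].
#' @return named numeric vector, one value per sample.
#' @export
balance_values <- function(c, bal) {
  p <- length(bal$numerator)
  q <- length(bal$denominator)
  missing <- setdiff(c(bal$numerator, bal$denominator), colnames(c))
  if (length(missing) > 0)
    stop("balance taxa absent from clr matrix: ",
         paste(missing, collapse = ", "))
  num_mean <- rowMeans(c[, bal$numerator, drop = FALSE])
  den_mean <- rowMeans(c[, bal$denominator, drop = FALSE])
  sqrt(p * q / (p + q)) * (num_mean - den_mean)
}
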