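#' Principal-coordinates biplot on the Aitchison distance
#'
#' Classical metric scaling of the Gower-centred `-D^2/2` matrix.
#' Because the Aitchison distance is the Euclidean distance between clr
#' rows, the embedding is exact (no meaningfully negative eigenvalues)
#' and the scores coincide with a clr PCA up to sign. Taxon arrows are
#' the covariances of each clr column with the retained axes; taxa are
#' ranked by their summed squared covariance (the variance along the
#' retained plane they explain).
#'
#' @param d symmetric distance matrix (e.g. [aitchison_distance()]).
#' @param c the `clr_matrix` the distances were computed from, used for
#'   the taxon arrows; may be `NULL` to skip arrows.
#' @param n_axes number of axes to retain.
#' @return an `ordination_result` list: `coordinates` (samples x axes),
#'   `eigenvalues` (all, non-increasing), `variance_explained`
#'   (proportion per retained axis; negative eigenvalues clipped at 0 in
#'   the denominator), `arrows` (taxa x axes, ranked), `taxon_rank`.
#' @export
pcoa_biplot <- function(d, c = NULL, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n_axes >= n) stop("n_axes must be smaller than the number of samples")
  G <- -0.5 * d^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- eig$values
  pos <- which(ev > 1e-9 * max(abs(ev)))
  if (length(pos) < n_axes) n_axes <- length(pos)
  neg_mag <- if (any(ev < 0)) max(-ev[ev < 0]) else 0
  if (neg_mag > max(ev[seq_len(n_axes)]))
    stop("distance matrix is strongly non-Euclidean: dominant negative ",
         "eigenvalue exceeds retained positive ones")
  coords <- eig$vectors[, seq_len(n_axes), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_axes)]), n_axes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  ev_clip <- pmax(ev, 0)
  arrows <- NULL
  taxon_rank <- NULL
  if (!is.null(c)) {
    cc <- scale(unclass(c), center = TRUE, scale = FALSE)
    sc <- scale(coords, center = TRUE, scale = FALSE)
    arrows <- crossprod(cc, sc) / (n - 1)  # cov(clr_j, axis_k)
    taxon_rank <- order(rowSums(arrows^2), decreasing = TRUE)
    names(taxon_rank) <- colnames(c)[taxon_rank]
  }
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 variance_explained = ev_clip[seq_len(n_axes)] / sum(ev_clip),
                 arrows = arrows,
                 taxon_rank = taxon_rank),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result: %d samples, %d axes (%s of variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = " + ")))
  invisible(x)
}
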