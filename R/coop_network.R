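#' Co-abundance cooperatives
#'
#' Genus "cooperatives" (coops) are communities of a sparse co-abundance
#' graph: per-genus L1-penalised neighbourhood regressions on clr data
#' (Meinshausen-Buhlmann style), aggregated over random subsamples into
#' edge selection frequencies, with the penalty chosen by a stability
#' (StARS-type) criterion, and community detection by Louvain modularity
#' optimisation on the stability-weighted graph.
#'
#' @name coop_network_module
NULL

#' Prevalence/abundance filter for genera
#'
#' Keeps genera with more than `min_reads` reads in more than
#' `min_samples` samples (strict inequalities on both counts).
#'
#' @param t a genus-level [count_table()].
#' @param min_reads,min_samples filter thresholds.
#' @return the filtered [count_table()].
#' @export
filter_genera <- function(t, min_reads = 20, min_samples = 10) {
  keep <- colSums(t$counts > min_reads) > min_samples
  if (!any(keep))
    stop("no genera pass the filter (> ", min_reads, " reads in > ",
         min_samples, " samples)")
  subset_taxa_ct(t, which(keep))
}

# Adjacency (upper-triangle logical vector) of the OR-rule graph at each
# lambda, from per-node lasso fits on `x` (samples x genera).
neighbourhood_edges <- function(x, lambda_path) {
  p <- ncol(x)
  n_lam <- length(lambda_path)
  sel <- array(FALSE, dim = c(p, p, n_lam))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(x[, -j, drop = FALSE], x[, j],
                          family = "gaussian", lambda = lambda_path,
                          standardize = FALSE, intercept = TRUE)
    beta <- as.matrix(fit$beta)  # (p-1) x n_fitted
    n_fit <- ncol(beta)
    others <- seq_len(p)[-j]
    for (l in seq_len(n_lam)) {
      bcol <- beta[, min(l, n_fit)]
      sel[j, others[bcol != 0], l] <- TRUE
    }
  }
  # OR rule: edge if either regression selects the other genus
  lapply(seq_len(n_lam), function(l) {
    a <- sel[, , l] | t(sel[, , l])
    a[upper.tri(a)]
  })
}

#' Infer the genus co-abundance network
#'
#' For each genus, an L1-penalised regression of its clr column on all
#' other genera over a geometric lambda path of `n_lambda` values from
#' lambda_max down to `lambda_min * lambda_max`; edges by the OR rule.
#' The fits are repeated on `n_subsamples` random subsamples (fraction
#' `subsample_frac` of the samples, without replacement, keyed to sorted
#' sample ids so the result is invariant to input row order). The
#' penalty is chosen by the StARS criterion: the densest lambda on the
#' path whose monotonised average edge instability `mean(2*f*(1-f))`
#' stays at or below 0.05. Edges whose selection frequency at the chosen
#' lambda reaches `stability_threshold` are kept, weighted by that
#' frequency.
#'
#' @param c a `clr_matrix` of the filtered genera (samples x genera).
#' @param config an [analysis_config()].
#' @return an igraph graph over all input genera with edge attribute
#'   `weight` (selection frequency) and graph attributes
#'   `lambda_selected`, `lambda_path`, `instability`.
#' @export
infer_network <- function(c, config = analysis_config()) {
  x <- unclass(c)
  if (nrow(x) < 30) stop("network inference needs >= 30 samples (got ",
                         nrow(x), ")")
  x <- x[order(rownames(x)), , drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  genera <- colnames(x)
  S <- stats::cov(x) * (n - 1) / n
  lam_max <- max(abs(S[upper.tri(S)]))
  lambda_path <- exp(seq(log(lam_max), log(config$lambda_min * lam_max),
                         length.out = config$n_lambda))
  n_sub <- floor(config$subsample_frac * n)
  n_pairs <- p * (p - 1) / 2
  freq <- matrix(0, nrow = n_pairs, ncol = config$n_lambda)
  for (b in seq_len(config$n_subsamples)) {
    idx <- with_seed(derive_seed(config$seed, "network_subsample", b),
                     sample.int(n, n_sub, replace = FALSE))
    edges_b <- neighbourhood_edges(x[idx, , drop = FALSE], lambda_path)
    for (l in seq_len(config$n_lambda))
      freq[, l] <- freq[, l] + edges_b[[l]]
  }
  freq <- freq / config$n_subsamples
  instab <- colMeans(2 * freq * (1 - freq))
  instab_mono <- cummax(instab)  # path runs sparse -> dense
  ok <- which(instab_mono <= 0.05)
  sel <- if (length(ok) > 0) max(ok) else 1L
  keep <- freq[, sel] >= config$stability_threshold
  ut <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  el <- ut[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genera)
  if (nrow(el) > 0)
    g <- igraph::add_edges(g, t(cbind(el[, 1], el[, 2])),
                           weight = freq[keep, sel])
  g <- igraph::set_graph_attr(g, "lambda_selected", lambda_path[sel])
  g <- igraph::set_graph_attr(g, "lambda_path", lambda_path)
  g <- igraph::set_graph_attr(g, "instability", instab)
  g
}

#' Derive cooperatives from a co-abundance graph
#'
#' Louvain modularity optimisation on the stability-weighted graph,
#' restarted `n_restarts` times with derived seeds (best modularity
#' kept). Communities with a single genus are reported as singletons,
#' not coops. Coops are named after their most abundant member genus
#' (`<Genus>-coop`) when abundances are supplied, otherwise after the
#' first member alphabetically.
#'
#' @param g igraph graph from [infer_network()].
#' @param abundance optional named numeric vector of mean (relative)
#'   abundance per genus, used for coop naming.
#' @param seed integer seed.
#' @param n_restarts Louvain restarts.
#' @return a `coop_partition`: list with `graph`, `communities` (named
#'   list of genus vectors), `singletons`, `modularity`.
#' @export
louvain_coops <- function(g, abundance = NULL, seed = 1L, n_restarts = 10L) {
  genera <- igraph::V(g)$name
  if (igraph::ecount(g) == 0) {
    return(structure(list(graph = g, communities = list(),
                          singletons = genera, modularity = 0),
                     class = "coop_partition"))
  }
  best <- NULL
  best_mod <- -Inf
  for (r in seq_len(n_restarts)) {
    cl <- with_seed(derive_seed(seed, "louvain", r),
                    igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
    m <- igraph::modularity(cl)
    if (m > best_mod) {
      best_mod <- m
      best <- cl
    }
  }
  member_sets <- split(genera, igraph::membership(best))
  sizes <- lengths(member_sets)
  coops <- member_sets[sizes >= 2]
  singles <- unlist(member_sets[sizes < 2], use.names = FALSE)
  nm <- vapply(coops, function(members) {
    lead <- if (!is.null(abundance)) {
      members[which.max(abundance[members])]
    } else sort(members)[1]
    paste0(lead, "-coop")
  }, character(1))
  # stable ordering: by leading-genus name
  ord <- order(nm)
  coops <- coops[ord]
  names(coops) <- make.unique(nm[ord], sep = "_")
  structure(list(graph = g, communities = coops,
                 singletons = sort(singles), modularity = best_mod),
            class = "coop_partition")
}

#' @export
print.coop_partition <- function(x, ...) {
  cat(sprintf("coop_partition: %d coops (%s), %d singleton genera, modularity %.3f\n",
              length(x$communities),
              paste(sprintf("%s n=%d", names(x$communities),
                            lengths(x$communities)), collapse = "; "),
              length(x$singletons), x$modularity))
  invisible(x)
}

#' Represent a cooperative as a balance
#'
#' Numerator: the coop's genera; denominator: all other genera of the
#' filtered universe.
#'
#' @param part a `coop_partition`.
#' @param coop_id name of the coop in `part$communities`.
#' @param universe character vector of all filtered genera (defaults to
#'   the graph's vertex set).
#' @return a [balance()].
#' @export
coop_balance <- function(part, coop_id, universe = NULL) {
  if (!coop_id %in% names(part$communities))
    stop("unknown coop: ", coop_id)
  if (is.null(universe)) universe <- igraph::V(part$graph)$name
  members <- part$communities[[coop_id]]
  rest <- setdiff(universe, members)
  if (length(rest) == 0)
    stop("coop covers the whole genus universe; denominator is empty")
  balance(members, rest)
}

#' Export a network as an edge-list table
#'
#' @param g igraph graph from [infer_network()].
#' @return data.frame with columns `genus_a`, `genus_b`, `stability`.
#' @export
network_edge_table <- function(g) {
  if (igraph::ecount(g) == 0)
    return(data.frame(genus_a = character(), genus_b = character(),
                      stability = numeric(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  data.frame(genus_a = el[, 1], genus_b = el[, 2],
             stability = igraph::E(g)$weight, stringsAsFactors = FALSE)
}
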