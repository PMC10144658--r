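# Shared fixture builders. Cohorts are cached by (seed, beta) because
# several files exercise the same simulated data.

.fixture_cache <- new.env(parent = emptyenv())

cohort_scenario <- function(seed, beta = 2) {
  # beta = 0 keeps the factor in the metadata as a pure null
  effects <- list(planted_effect("factor_planted", numerator = 41:47,
                                 denominator = 51:57, beta = beta,
                                 group = "immune"))
  synthetic_scenario(seed = seed, planted_effects = effects)
}

get_cohort <- function(seed, beta = 2) {
  key <- sprintf("cohort_%d_%g", seed, beta)
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, simulate_cohort(cohort_scenario(seed, beta)),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# filtered clr matrix of a cohort (the nearest-balance / coop
# universe; unrarefied, as in the pipeline)
get_filtered_clr <- function(seed, beta = 2) {
  key <- sprintf("clr_%d_%g", seed, beta)
  if (!exists(key, envir = .fixture_cache)) {
    coh <- get_cohort(seed, beta)
    filt <- filter_genera(coh$counts)
    assign(key, clr_transform(filt), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_count_table <- function() {
  m <- matrix(c(5, 0, 3,
                2, 7, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("taxA", "taxB", "taxC")))
  lin <- data.frame(kingdom = "Bacteria",
                    phylum = c("P1", "P1", "P2"),
                    genus = c("taxA", "taxB", "taxC"),
                    row.names = colnames(m), stringsAsFactors = FALSE)
  count_table(m, lin)
}

random_direction <- function(n, names_prefix = "t") {
  v <- stats::rnorm(n)
  stats::setNames(v - mean(v), paste0(names_prefix, seq_len(n)))
}

# adjusted Rand index between two label vectors (independent of the
# package's own code; used as the clustering-recovery oracle)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# ARI of a coop partition against the planted blocks, over the planted
# genera present in the partition's universe
coop_recovery_ari <- function(part, truth_coops) {
  universe <- igraph::V(part$graph)$name
  members <- unlist(truth_coops)
  present <- members[members %in% universe]
  true_lab <- rep(seq_along(truth_coops), lengths(truth_coops))
  names(true_lab) <- members
  inferred <- stats::setNames(rep(NA_character_, length(present)), present)
  for (cn in names(part$communities))
    inferred[intersect(part$communities[[cn]], present)] <- cn
  nas <- is.na(inferred)
  inferred[nas] <- paste0("singleton_", seq_len(sum(nas)))
  adjusted_rand(true_lab[present], inferred)
}
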