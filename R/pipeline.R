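#' End-to-end association pipeline
#'
#' Orchestrates the full analysis on a count table plus metadata:
#' sample intersection, rarefaction, alpha diversity, Aitchison beta
#' diversity with permutation tests, parameter de-duplication, the
#' co-abundance network and its cooperatives, coop-balance and per-rank
#' clr association screens with BH control per parameter group and
#' feature family, and cross-validated nearest-balance analysis of the
#' factors linked to overall composition.
#'
#' @name pipeline_module
NULL

# BH within parameter group (q column added; group NA treated as its
# own family).
add_group_fdr <- function(df) {
  if (nrow(df) == 0) {
    df$q <- numeric(0)
    return(df)
  }
  key <- ifelse(is.na(df$parameter_group), "__na__", df$parameter_group)
  df$q <- NA_real_
  for (g in unique(key)) {
    ix <- which(key == g)
    df$q[ix] <- bh_fdr(df$p[ix])
  }
  df
}

factor_list <- function(meta, screens) {
  out <- list(list(name = "group", values = meta$group,
                   parameter_group = "study_group"))
  for (sc in screens) {
    for (par in sc$retained) {
      out[[length(out) + 1]] <- list(name = par,
                                     values = meta$parameters[, par],
                                     parameter_group = sc$group)
    }
  }
  out
}

#' Run the full pipeline
#'
#' @param config an [analysis_config()].
#' @param count_path count table file (TSV, or BIOM JSON if the file
#'   extension is `.biom` or `.json`).
#' @param metadata_path metadata TSV.
#' @param out_dir output directory; result tables (TSV) and a
#'   machine-readable `run_log.json` are written there.
#' @param group_spec named character vector mapping parameter names to
#'   parameter groups (parameters left out are screened as
#'   `"ungrouped"`).
#' @return invisibly, a list of the in-memory results (`alpha`, `beta`,
#'   `coop`, `taxa`, `nearest_balances`, `partition`, `screens`).
#' @export
run_pipeline <- function(config, count_path, metadata_path, out_dir,
                         group_spec = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- if (grepl("\\.(biom|json)$", count_path)) "biom-json" else "tsv"
  counts <- read_count_table(count_path, fmt)
  meta <- read_metadata(metadata_path, group_spec)
  shared <- intersect_samples(counts, meta)
  counts <- shared$counts
  meta <- shared$metadata

  genus_tab <- aggregate_to_rank(counts, "genus")
  rare <- rarefy(genus_tab, config$rarefaction_depth,
                 seed = derive_seed(config$seed, "rarefaction"))
  div <- diversity_table(rare)
  clr_all <- clr_transform(rare, config$pseudocount)
  d_ait <- aitchison_distance(clr_all)

  screens <- lapply(unique(meta$parameter_groups), function(g)
    dedup_parameters(meta, g, config$dedup_rho))
  factors <- factor_list(meta, screens)

  alpha_rows <- list()
  beta_rows <- list()
  for (fc in factors) {
    for (metric in c("shannon", "chao1")) {
      row <- alpha_assoc(stats::setNames(div[[metric]], div$sample),
                         fc$values, feature = paste0("alpha:", metric),
                         factor_name = fc$name)
      row$parameter_group <- fc$parameter_group
      alpha_rows[[length(alpha_rows) + 1]] <- row
    }
    row <- permutation_beta_test(d_ait, fc$values,
                                 n_perm = config$n_permutations,
                                 seed = config$seed, factor_name = fc$name)
    row$parameter_group <- fc$parameter_group
    beta_rows[[length(beta_rows) + 1]] <- row
  }
  alpha_res <- add_group_fdr(do.call(rbind, alpha_rows))
  beta_res <- add_group_fdr(do.call(rbind, beta_rows))

  # network, coop and nearest-balance stages run on the unrarefied
  # filtered genus table: the clr transform is scale-invariant, so
  # subsampling reads would only discard information (rarefaction is
  # kept for the diversity metrics, where depth matters)
  filt <- filter_genera(genus_tab, config$min_reads, config$min_samples)
  clr_filt <- clr_transform(filt, config$pseudocount)
  net <- infer_network(clr_filt, config)
  mean_abund <- colMeans(sweep(filt$counts, 1, rowSums(filt$counts), "/"))
  part <- louvain_coops(net, abundance = mean_abund, seed = config$seed)

  coop_rows <- list()
  for (fc in factors) {
    res <- coop_balance_assoc(clr_filt, part, fc$values,
                              factor_name = fc$name)
    if (nrow(res) > 0) {
      res$parameter_group <- fc$parameter_group
      coop_rows[[length(coop_rows) + 1]] <- res
    }
  }
  coop_res <- add_group_fdr(do.call(rbind, coop_rows))

  ranks <- intersect(c("phylum", "class", "order", "family", "genus",
                       "species"), available_ranks(rare))
  taxa_rows <- list()
  for (rk in ranks) {
    tab_rk <- if (rk == "genus") genus_tab else
      aggregate_to_rank(genus_tab, rk)
    clr_rk <- clr_transform(tab_rk, config$pseudocount)
    for (fc in factors) {
      res <- taxon_clr_assoc(clr_rk, fc$values, factor_name = fc$name,
                             rank = rk)
      res$parameter_group <- fc$parameter_group
      taxa_rows[[length(taxa_rows) + 1]] <- res
    }
  }
  taxa_res <- do.call(rbind, taxa_rows)
  # refine q: BH within parameter group x rank family (pooled across
  # the group's factors), replacing the per-screen adjustment
  taxa_res$rank <- sub("^taxon:([^:]+):.*$", "\\1", taxa_res$feature)
  fam <- paste(taxa_res$parameter_group, taxa_res$rank, sep = "|")
  for (f in unique(fam)) {
    ix <- which(fam == f)
    taxa_res$q[ix] <- bh_fdr(taxa_res$p[ix])
  }

  # nearest-balance analysis: factors whose composition-level (beta)
  # association survives FDR; if none does, the single best-p factor is
  # explored, flagged as such
  cont_beta <- beta_res[beta_res$factor != "group", , drop = FALSE]
  nb_factors <- cont_beta$factor[cont_beta$q < config$fdr_alpha]
  nb_flag <- "significant"
  if (length(nb_factors) == 0 && nrow(cont_beta) > 0) {
    nb_factors <- cont_beta$factor[which.min(cont_beta$p)]
    nb_flag <- "exploratory"
  }
  nb_results <- list()
  nb_tables <- list()
  for (fn in nb_factors) {
    rb <- cross_validated_balance(clr_filt, meta$parameters[, fn], config,
                                  factor_name = fn)
    nb_results[[fn]] <- rb
    tab <- balance_membership_table(rb)
    if (nrow(tab) > 0) {
      tab <- cbind(factor = fn, tab, selection = nb_flag)
    }
    nb_tables[[fn]] <- tab
  }
  nb_table <- if (length(nb_tables) > 0) {
    do.call(rbind, nb_tables[vapply(nb_tables, nrow, 1L) > 0])
  } else NULL
  if (is.null(nb_table))
    nb_table <- data.frame(factor = character(), taxon = character(),
                           side = character(), reproducibility = numeric(),
                           coefficient = numeric(), selection = character(),
                           stringsAsFactors = FALSE)

  write_tsv_table(alpha_res, file.path(out_dir, "alpha_associations.tsv"))
  write_tsv_table(beta_res, file.path(out_dir, "beta_associations.tsv"))
  coop_out <- data.frame(coop = sub("^coop:", "", coop_res$feature),
                         factor = coop_res$factor,
                         parameter_group = coop_res$parameter_group,
                         coefficient = coop_res$statistic,
                         p = coop_res$p, FDR = coop_res$q, n = coop_res$n,
                         stringsAsFactors = FALSE)
  write_tsv_table(coop_out, file.path(out_dir, "coop_associations.tsv"))
  write_tsv_table(taxa_res, file.path(out_dir, "taxon_associations.tsv"))
  write_tsv_table(nb_table, file.path(out_dir, "nearest_balance.tsv"))
  coop_members <- if (length(part$communities) > 0) {
    data.frame(coop = rep(names(part$communities),
                          lengths(part$communities)),
               genus = unlist(part$communities, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else data.frame(coop = character(), genus = character(),
                    stringsAsFactors = FALSE)
  write_tsv_table(coop_members, file.path(out_dir, "coop_members.tsv"))
  write_tsv_table(network_edge_table(net),
                  file.path(out_dir, "network_edges.tsv"))
  screen_tab <- do.call(rbind, lapply(screens, function(sc)
    rbind(data.frame(group = sc$group, parameter = sc$retained,
                     representative = sc$retained, retained = TRUE,
                     stringsAsFactors = FALSE),
          if (nrow(sc$dropped) > 0)
            data.frame(group = sc$group, parameter = sc$dropped$parameter,
                       representative = sc$dropped$representative,
                       retained = FALSE, stringsAsFactors = FALSE))))
  write_tsv_table(screen_tab, file.path(out_dir, "parameter_screen.tsv"))
  jsonlite::write_json(
    list(config = unclass(config),
         n_samples = length(sample_ids(counts)),
         n_genera_filtered = ncol(filt$counts),
         rarefaction_depth = sum(rare$counts[1, ]),
         n_coops = length(part$communities),
         nb_factors = as.list(nb_factors),
         nb_selection = nb_flag),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(alpha = alpha_res, beta = beta_res, coop = coop_res,
                 taxa = taxa_res, nearest_balances = nb_results,
                 partition = part, screens = screens, network = net,
                 diversity = div, clr_filtered = clr_filt))
}
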