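# End-to-end orchestration: join per-gene calls, features and diversity
# statistics into one gene report and run the hv vs non-hv comparison
# battery with per-family Benjamini-Hochberg correction.

#' Analysis configuration
#'
#' Fixed thresholds of the analysis (entropy rule, coverage filter, cluster
#' and pair gaps, window geometry, tail fraction, permutation replicates)
#' plus the master seed and an exclusion list for unmappable genes.
#'
#' @param entropy_threshold entropy cutoff in bits (default 1.5).
#' @param min_positions positions above the cutoff required for an hv call
#'   (default 10).
#' @param min_coverage minimum reads per cytosine (default 5).
#' @param cluster_max_gap cluster chaining gap in bp (default 50000).
#' @param pair_max_gap neighbor-pair gap in bp (default 2000).
#' @param window,step sliding-window size and step in bp (defaults 300, 75).
#' @param R permutation replicates (default 10000).
#' @param n_bins covariate bins for matched permutation tests (default 10).
#' @param seed master seed.
#' @param exclude gene ids excluded from feature analyses (e.g. unmappable).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(entropy_threshold = 1.5, min_positions = 10L,
                            min_coverage = 5L, cluster_max_gap = 50000L,
                            pair_max_gap = 2000L, window = 300L, step = 75L,
                            R = 10000L, n_bins = 10L, seed = 1L,
                            exclude = character(0)) {
  cfg <- as.list(environment())
  stopifnot(entropy_threshold > 0, min_positions > 0, min_coverage > 0,
            cluster_max_gap > 0, pair_max_gap > 0, window > 0, step > 0, R > 0)
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full analysis pipeline on simulated or supplied inputs
#'
#' Stages: per-gene entropy profiles and hv classification from the clade
#' alignments; TPM, gene-body CG methylation (replicate-pooled, weighted by
#' site counts), nearest-TE distance and cluster assignment from the feature
#' inputs; per-gene diversity statistics (pi, theta, Tajima's D, piN/piS)
#' from the codon alignments; then the comparison battery.
#'
#' @param nlrome result of [simulate_nlrome()] (or an equivalently shaped
#'   list of per-gene alignments plus truth/ids).
#' @param features result of [simulate_feature_tables()] (or equivalently
#'   shaped real inputs).
#' @param config an `analysis_config`.
#' @return list of class `nlr_pipeline_result`: `gene_table` (one row per
#'   gene), `tests` (battery results), `config`.
#' @export
run_pipeline <- function(nlrome, features, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  gene_ids <- names(nlrome$genes)
  if (is.null(gene_ids)) stop("nlrome$genes must be a named list")

  calls <- lapply(gene_ids, function(g) {
    pro <- entropy_profile(nlrome$genes[[g]]$protein_aln,
                           nlrome$genes[[g]]$focal_id, gene_id = g)
    classify_hv(pro, threshold = config$entropy_threshold,
                min_positions = config$min_positions)
  })
  hv_tab <- do.call(rbind, calls)

  div <- lapply(gene_ids, function(g) {
    aln <- nlrome$genes[[g]]$codon_aln
    ds <- diversity_stats(aln)
    cd <- pin_pis(aln)
    data.frame(gene_id = g, n_hap = ds$n, L = ds$L, S = ds$S,
               pi = ds$pi_per_site, theta_w = ds$theta_w_per_site,
               tajimas_d = ds$tajimas_d, pi_n = cd$pi_n, pi_s = cd$pi_s,
               pin_pis = cd$ratio, stringsAsFactors = FALSE)
  })
  div_tab <- do.call(rbind, div)

  tpm <- counts_to_tpm(features$counts)
  expr <- data.frame(gene_id = rownames(features$counts$counts),
                     log2_tpm = tpm$log2_mean_tpm, stringsAsFactors = FALSE)

  meth_reps <- lapply(features$meth_calls, gene_methylation,
                      genes = features$genes, context = "CG",
                      min_coverage = config$min_coverage)
  pct_mat <- do.call(cbind, lapply(meth_reps, `[[`, "pct_meth"))
  n_mat <- do.call(cbind, lapply(meth_reps, `[[`, "n_sites"))
  meth <- data.frame(gene_id = meth_reps[[1]]$gene_id,
                     pct_mCG = pool_replicates_weighted(pct_mat, n_mat),
                     n_CG_sites = rowSums(n_mat), stringsAsFactors = FALSE)

  te <- nearest_te_distance(features$genes, features$tes)
  cl <- assign_clusters(features$genes, max_gap = config$cluster_max_gap)

  tab <- Reduce(function(a, b) merge(a, b, by = "gene_id", all.x = TRUE, sort = FALSE),
                list(hv_tab[c("gene_id", "label", "mean_entropy", "n_high")],
                     expr, meth, te, cl, div_tab))
  tab <- tab[match(gene_ids, tab$gene_id), ]
  rownames(tab) <- NULL
  tab$excluded <- tab$gene_id %in% config$exclude

  tests <- compare_groups_report(tab, R = config$R, seed = config$seed,
                                 n_bins = config$n_bins)
  structure(list(gene_table = tab, tests = tests, config = config),
            class = "nlr_pipeline_result")
}

battery_row <- function(family, test, feature, statistic, p) {
  data.frame(family = family, test = test, feature = feature,
             statistic = statistic, p_value = p, stringsAsFactors = FALSE)
}

#' hv vs non-hv comparison battery
#'
#' Runs the standard comparisons on a joined gene table: unpaired Wilcoxon
#' rank-sum tests of every feature and diversity statistic between hv and
#' non-hv genes; Fisher's exact association of hv status with cluster
#' membership and with genic TE presence; Kruskal-Wallis robustness checks
#' across cluster-status subsets within each group; and, when genome-wide
#' background values are supplied, permutation enrichment (plain and
#' covariate-matched on CG site counts) plus empirical-tail count tests.
#' Benjamini-Hochberg correction is applied within each family of tests.
#'
#' @param gene_table per-gene table with columns `label`, features and
#'   diversity statistics (as built by [run_pipeline()]).
#' @param R permutation replicates.
#' @param seed master seed (child seeds per permutation test).
#' @param n_bins covariate bins for the matched methylation enrichment.
#' @param background optional list of genome-wide values with elements among
#'   `expression`, `methylation`, `cg_sites`, `pi`, `tajimas_d` (named
#'   numeric vectors over background genes).
#' @return data.frame: `family`, `test`, `feature`, `statistic`, `p_value`,
#'   `q_value` (BH within family), `signif` tier (ns/*/**/***).
#' @export
compare_groups_report <- function(gene_table, R = 10000L, seed = 1L,
                                  n_bins = 10L, background = NULL) {
  use <- if ("excluded" %in% names(gene_table)) !gene_table$excluded
         else rep(TRUE, nrow(gene_table))
  tab <- gene_table[use, , drop = FALSE]
  hv <- tab$label == "hv"
  rows <- list()
  if (any(hv) && any(!hv)) {
    for (feat in c("log2_tpm", "pct_mCG", "te_distance", "pi", "tajimas_d",
                   "pi_n", "pi_s", "pin_pis")) {
      if (!feat %in% names(tab)) next
      x <- tab[[feat]][hv]
      y <- tab[[feat]][!hv]
      if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) next
      fam <- if (feat %in% c("log2_tpm", "pct_mCG", "te_distance")) "features" else "popgen"
      rows[[length(rows) + 1L]] <- battery_row(
        fam, "wilcoxon", feat, stats::median(x, na.rm = TRUE) - stats::median(y, na.rm = TRUE),
        wilcoxon_rank_sum(x, y))
    }
    if ("cluster_id" %in% names(tab)) {
      clustered <- tab$cluster_id != "singleton"
      ct <- table(factor(hv, c(TRUE, FALSE)), factor(clustered, c(TRUE, FALSE)))
      rows[[length(rows) + 1L]] <- battery_row(
        "association", "fisher", "cluster_membership", NA_real_, fisher_exact_2x2(ct))
      for (grp in c(TRUE, FALSE)) {
        for (feat in c("log2_tpm", "pct_mCG", "te_distance")) {
          if (!feat %in% names(tab)) next
          g1 <- tab[[feat]][hv == grp & clustered]
          g2 <- tab[[feat]][hv == grp & !clustered]
          if (sum(!is.na(g1)) < 2 || sum(!is.na(g2)) < 2) next
          kw <- kruskal_wallis(list(g1[!is.na(g1)], g2[!is.na(g2)]))
          rows[[length(rows) + 1L]] <- battery_row(
            "robustness", "kruskal_wallis",
            paste0(feat, "_", if (grp) "hv" else "nonhv", "_by_cluster"),
            kw$statistic, kw$p_value)
        }
      }
    }
    if ("te_within_genic" %in% names(tab)) {
      ct <- table(factor(hv, c(TRUE, FALSE)),
                  factor(tab$te_within_genic, c(TRUE, FALSE)))
      rows[[length(rows) + 1L]] <- battery_row(
        "association", "fisher", "te_within_genic", NA_real_, fisher_exact_2x2(ct))
    }
  }
  if (!is.null(background)) {
    hv_ids <- tab$gene_id[hv]
    feats <- stats::setNames(tab$log2_tpm, tab$gene_id)
    if (!is.null(background$expression)) {
      r <- perm_diff_test(c(feats, background$expression), hv_ids,
                          names(background$expression), stat = "mean", R = R,
                          seed = derive_seed(seed, "enrich_expr"),
                          direction = "greater")
      rows[[length(rows) + 1L]] <- battery_row("enrichment", "perm_diff_mean",
                                               "expression", r$observed, r$p_addone)
    }
    if (!is.null(background$methylation) && !is.null(background$cg_sites)) {
      meths <- stats::setNames(tab$pct_mCG, tab$gene_id)
      covar <- c(stats::setNames(tab$n_CG_sites, tab$gene_id), background$cg_sites)
      r <- matched_perm_diff_test(c(meths, background$methylation),
                                  hv_ids[!is.na(meths[hv_ids])],
                                  names(background$methylation), covar,
                                  n_bins = n_bins, stat = "mean", R = R,
                                  seed = derive_seed(seed, "enrich_meth"),
                                  direction = "less")
      rows[[length(rows) + 1L]] <- battery_row("enrichment", "matched_perm_diff_mean",
                                               "methylation", r$observed, r$p_addone)
    }
    if (!is.null(background$pi)) {
      vals <- c(stats::setNames(tab$pi, tab$gene_id), background$pi)
      r <- tail_count_test(vals, tab$gene_id, names(background$pi), tail = "top5",
                           R = R, seed = derive_seed(seed, "tail_pi"))
      rows[[length(rows) + 1L]] <- battery_row("tails", "tail_count_top5", "pi",
                                               r$observed, r$p_addone)
    }
    if (!is.null(background$tajimas_d)) {
      vals <- c(stats::setNames(tab$tajimas_d, tab$gene_id), background$tajimas_d)
      ok_ids <- tab$gene_id[!is.na(tab$tajimas_d)]
      r <- tail_count_test(vals, ok_ids, names(background$tajimas_d), tail = "top5",
                           R = R, seed = derive_seed(seed, "tail_d"))
      rows[[length(rows) + 1L]] <- battery_row("tails", "tail_count_top5", "tajimas_d",
                                               r$observed, r$p_addone)
    }
  }
  if (!length(rows)) stop("no runnable comparisons in the battery")
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (fam in unique(out$family)) {
    sel <- out$family == fam
    out$q_value[sel] <- bh_adjust(out$p_value[sel])
  }
  out$signif <- cut(out$q_value, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", "ns"))
  out
}

#' Write the per-gene report table
#'
#' Tab-separated with stable column order, NA encoded as ".", and header
#' comment lines recording the package version, seed and a configuration
#' hash.
#'
#' @param report `nlr_pipeline_result` or a non-empty gene table data.frame.
#' @param path output file.
#' @param config optional `analysis_config` (taken from the result object if
#'   present).
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(report, path, config = NULL) {
  if (inherits(report, "nlr_pipeline_result")) {
    config <- report$config
    report <- report$gene_table
  }
  if (!is.data.frame(report) || nrow(report) == 0L) stop("empty gene report")
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("nlrdiversity"))
  seed <- if (!is.null(config)) config$seed else NA
  cfg_hash <- if (!is.null(config)) {
    sprintf("%08x", sum(utf8ToInt(paste(deparse(config), collapse = "")) *
                          (seq_along(utf8ToInt(paste(deparse(config), collapse = ""))) %% 97 + 1)) %% 0xFFFFFFFF)
  } else "none"
  writeLines(sprintf("# nlrdiversity %s; seed=%s; config_hash=%s", ver, seed, cfg_hash), con)
  out <- report
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v)) v <- ifelse(is.na(v), ".", format(v, digits = 12, trim = TRUE))
    out[[j]] <- ifelse(is.na(v), ".", as.character(v))
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene report table written by [write_gene_table()]
#'
#' @param path TSV file.
#' @return data.frame with "." decoded back to NA and numeric columns
#'   restored.
#' @export
read_gene_table <- function(path) {
  utils::read.delim(path, comment.char = "#", na.strings = ".",
                    stringsAsFactors = FALSE)
}
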