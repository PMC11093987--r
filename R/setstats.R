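# Gene-set comparison machinery: single-sample rank scores, plain /
# covariate-matched / tail-count permutation tests, and thin wrappers around
# the standard rank and contingency tests.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Deterministic child seed from a master seed
#'
#' One master seed per run; per-test child streams are derived
#' deterministically so results do not depend on execution order.
#'
#' @param master integer master seed.
#' @param k child index (>= 0) or a short string tag.
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, k) {
  if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
  x <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(k)
  as.integer(x %% 2147483646) + 1L
}

set_test_result <- function(statistic_name, observed, null, direction, R, seed,
                            extra = NULL) {
  b <- switch(direction,
    greater = sum(null >= observed),
    less = sum(null <= observed),
    `two-sided` = sum(abs(null) >= abs(observed)))
  res <- list(statistic_name = statistic_name, observed = observed,
              null_mean = mean(null), p_raw = b / R,
              p_addone = (b + 1) / (R + 1), R = R, seed = seed,
              direction = direction)
  structure(c(res, extra), class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf("%s: observed = %.4g, null mean = %.4g, p = %.4g (add-one %.4g, %s, R = %d)\n",
              x$statistic_name, x$observed, x$null_mean, x$p_raw, x$p_addone,
              x$direction, x$R))
  invisible(x)
}

#' Single-sample rank-based gene-set score
#'
#' Ranks all genes of one sample ascending (ties get mean ranks), takes the
#' mean rank of the set and rescales it to [0, 1] by the theoretically
#' minimal and maximal achievable mean ranks, min = (m+1)/2 and
#' max = n - (m-1)/2. A set occupying the top m ranks scores 1, the bottom m
#' ranks 0.
#'
#' @param values named numeric vector (gene -> value) for one sample.
#' @param gene_set character vector of member gene ids (>= 2, all present).
#' @return list of class `rank_score`: `mean_rank`, `normalized_score`,
#'   `n`, `m`.
#' @export
rank_set_score <- function(values, gene_set) {
  missing_ids <- setdiff(gene_set, names(values))
  if (length(missing_ids)) {
    stop("set gene(s) absent from values: ", paste(missing_ids, collapse = ", "))
  }
  if (length(gene_set) < 2) stop("gene set must have at least 2 members")
  n <- length(values)
  m <- length(gene_set)
  r <- rank(values, ties.method = "average")
  mean_rank <- mean(r[gene_set])
  lo <- (m + 1) / 2
  hi <- n - (m - 1) / 2
  structure(list(mean_rank = mean_rank,
                 normalized_score = (mean_rank - lo) / (hi - lo),
                 n = n, m = m),
            class = "rank_score")
}

#' Permutation p-value for a rank-based set score
#'
#' The null distribution is the normalized score of R gene sets of the same
#' size sampled uniformly without replacement from all genes; the p-value is
#' the fraction of null scores >= the observed score.
#'
#' @inheritParams rank_set_score
#' @param R permutation replicates (default 10000).
#' @param seed integer seed; identical seeds reproduce results exactly.
#' @return `set_test_result` with the observed normalized score.
#' @export
perm_pvalue_set_score <- function(values, gene_set, R = 10000L, seed = 1L) {
  if (R < 100) warning("fewer than 100 permutation replicates")
  obs <- rank_set_score(values, gene_set)
  n <- length(values)
  m <- length(gene_set)
  r <- rank(values, ties.method = "average")
  lo <- (m + 1) / 2
  hi <- n - (m - 1) / 2
  null <- with_seed(seed, vapply(seq_len(R), function(i) {
    (mean(r[sample.int(n, m)]) - lo) / (hi - lo)
  }, numeric(1)))
  set_test_result("rank_set_score", obs$normalized_score, null,
                  direction = "greater", R = as.integer(R), seed = seed)
}

# shared engine: stratified relabeling null for a difference-of-statistic
# test; with a single bin this is the plain permutation test.
perm_engine <- function(feature, set_ids, background_ids, bin_of_pool,
                        stat, R, seed, direction, statistic_name) {
  stat_fun <- switch(stat, mean = mean, median = stats::median,
                     stop("stat must be mean or median"))
  pool_ids <- c(set_ids, background_ids)
  v <- feature[pool_ids]
  na_drop <- sum(is.na(v))
  keep <- !is.na(v)
  is_set <- c(rep(TRUE, length(set_ids)), rep(FALSE, length(background_ids)))[keep]
  bin_of_pool <- bin_of_pool[keep]
  v <- v[keep]
  m <- sum(is_set)
  if (m < 3) stop("set must have at least 3 genes with values")
  obs <- stat_fun(v[is_set]) - stat_fun(v[!is_set])
  bins_used <- sort(unique(bin_of_pool[is_set]))
  for (b in bins_used) {
    if (!any(bin_of_pool == b & !is_set)) {
      stop("covariate bin ", b, " has set genes but no background candidates")
    }
  }
  k_set <- vapply(bins_used, function(b) sum(is_set & bin_of_pool == b), integer(1))
  bin_members <- lapply(bins_used, function(b) which(bin_of_pool == b))
  npool <- length(v)
  null <- with_seed(seed, vapply(seq_len(R), function(i) {
    idx <- unlist(lapply(seq_along(bins_used), function(bi) {
      mem <- bin_members[[bi]]
      mem[sample.int(length(mem), k_set[bi])]
    }), use.names = FALSE)
    in_null <- logical(npool)
    in_null[idx] <- TRUE
    stat_fun(v[in_null]) - stat_fun(v[!in_null])
  }, numeric(1)))
  set_test_result(statistic_name, obs, null, direction, as.integer(R), seed,
                  extra = list(n_na_dropped = na_drop, n_set = m,
                               n_background = npool - m))
}

#' Permutation test for a difference in means or medians
#'
#' Observed statistic: stat(set) - stat(background). Null: R relabelings
#' drawing |set| genes without replacement from set plus background. NA
#' feature values are dropped and counted. Both the raw p (which may be 0)
#' and the add-one estimator (b+1)/(R+1) are reported.
#'
#' @param feature named numeric vector (gene -> value).
#' @param set_ids,background_ids disjoint gene id vectors.
#' @param stat `"mean"` or `"median"`.
#' @param R permutation replicates (default 10000).
#' @param seed integer seed.
#' @param direction `"greater"`, `"less"` or `"two-sided"`.
#' @return `set_test_result`.
#' @export
perm_diff_test <- function(feature, set_ids, background_ids,
                           stat = c("mean", "median"), R = 10000L, seed = 1L,
                           direction = c("greater", "less", "two-sided")) {
  stat <- match.arg(stat)
  direction <- match.arg(direction)
  bins <- rep(1L, length(set_ids) + length(background_ids))
  perm_engine(feature, set_ids, background_ids, bins, stat, R, seed, direction,
              paste0("perm_diff_", stat))
}

#' Covariate-matched permutation test
#'
#' As [perm_diff_test()], but the genes are stratified into `n_bins`
#' covariate quantile bins (bin edges from the background covariate
#' distribution) and every null draw samples, within each bin, as many genes
#' as the observed set has there. This controls for confounders such as the
#' number of measured CG sites per gene. With `n_bins = 1` the test reduces
#' exactly to [perm_diff_test()] (same seed, same draws).
#'
#' @inheritParams perm_diff_test
#' @param covariate named numeric vector (gene -> covariate), available for
#'   all set and background genes.
#' @param n_bins number of covariate quantile bins (default 10).
#' @return `set_test_result`.
#' @export
matched_perm_diff_test <- function(feature, set_ids, background_ids, covariate,
                                   n_bins = 10L, stat = c("mean", "median"),
                                   R = 10000L, seed = 1L,
                                   direction = c("greater", "less", "two-sided")) {
  stat <- match.arg(stat)
  direction <- match.arg(direction)
  pool_ids <- c(set_ids, background_ids)
  missing_cov <- pool_ids[!pool_ids %in% names(covariate) | is.na(covariate[pool_ids])]
  if (length(missing_cov)) {
    stop("covariate missing for gene(s): ", paste(missing_cov, collapse = ", "))
  }
  if (n_bins < 1) stop("n_bins must be >= 1")
  edges <- unique(stats::quantile(covariate[background_ids],
                                  probs = seq(0, 1, length.out = n_bins + 1),
                                  type = 7, names = FALSE))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  if (length(edges) < 2) edges <- c(-Inf, Inf)
  bins <- as.integer(cut(covariate[pool_ids], breaks = edges, include.lowest = TRUE))
  perm_engine(feature, set_ids, background_ids, bins, stat, R, seed, direction,
              paste0("matched_perm_diff_", stat))
}

#' Permutation test for the number of set genes in an empirical tail
#'
#' Observed statistic: number of set genes strictly beyond the background's
#' 95th percentile (tail "top5") or 5th percentile ("bottom5"). Null: tail
#' counts of R random same-size gene sets drawn from the background.
#'
#' @param values named numeric vector over background (and set) genes.
#' @param set_ids,background_ids gene id vectors; the background defines the
#'   empirical quantile.
#' @param tail `"top5"` or `"bottom5"`.
#' @inheritParams perm_diff_test
#' @return `set_test_result`, with `expected_count = m * 0.05` attached.
#' @export
tail_count_test <- function(values, set_ids, background_ids,
                            tail = c("top5", "bottom5"), R = 10000L, seed = 1L,
                            direction = c("greater", "less", "two-sided")) {
  tail <- match.arg(tail)
  direction <- match.arg(direction)
  bg <- values[background_ids]
  bg <- bg[!is.na(bg)]
  if (!length(bg)) stop("empty background")
  sv <- values[set_ids]
  sv <- sv[!is.na(sv)]
  m <- length(sv)
  if (m < 3) stop("set must have at least 3 genes with values")
  fl <- empirical_tail_flags(sv, bg, tail)
  obs <- sum(fl$flags)
  count_tail <- if (tail == "top5") function(x) sum(x > fl$threshold)
                else function(x) sum(x < fl$threshold)
  nbg <- length(bg)
  null <- with_seed(seed, vapply(seq_len(R), function(i) {
    count_tail(bg[sample.int(nbg, m)])
  }, numeric(1)))
  set_test_result(paste0("tail_count_", tail), obs, null, direction,
                  as.integer(R), seed,
                  extra = list(expected_count = m * 0.05, threshold = fl$threshold))
}

#' Unpaired Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction (stats::wilcox.test).
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- (length(x) + length(y)) <= 12 && no_ties
  stats::wilcox.test(x, y, alternative = alternative, exact = use_exact,
                     correct = TRUE)$p.value
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (stats::kruskal.test); every group needs at least 2 values.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- vapply(groups, function(g) sum(!is.na(g)), integer(1))
  if (any(sizes < 2)) stop("every group needs at least 2 values")
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than the
#' observed table's, at fixed margins (stats::fisher.test).
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be non-negative integers")
  }
  stats::fisher.test(table)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (stats::p.adjust, method "BH"), values validated
#' to lie in [0, 1]. NA entries propagate as NA.
#'
#' @param pvals numeric vector of p-values.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
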