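#' Convert counts to TPM and replicate-mean log2(TPM + 1)
#'
#' Per sample: rate_g = count_g / length_g; TPM_g = 1e6 * rate_g / sum(rates).
#' Expression summaries average TPM across replicate samples first and then
#' take log2(mean + 1).
#'
#' @param counts a `count_matrix`.
#' @return list: `tpm` (genes x samples), `mean_tpm`, `log2_mean_tpm`
#'   (log2 of replicate-mean TPM + 1).
#' @export
counts_to_tpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  rate <- counts$counts / counts$lengths
  totals <- colSums(rate)
  if (any(totals == 0)) {
    warning("sample(s) with all-zero counts: ",
            paste(colnames(counts$counts)[totals == 0], collapse = ", "))
    totals[totals == 0] <- 1  # leaves the all-zero column at TPM 0
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  mean_tpm <- rowMeans(tpm)
  list(tpm = tpm, mean_tpm = mean_tpm, log2_mean_tpm = log2(mean_tpm + 1))
}

#' Gene-body methylation from per-cytosine calls
#'
#' Per cytosine with coverage >= `min_coverage`, percent methylation is
#' 100 * methylated / total. Symmetric CG partners (position i on "+", i+1 on
#' "-") that both pass the filter are averaged into one site; if only one
#' strand passes, it is used alone. Site percentages are then averaged,
#' unweighted, across the annotated gene span (strand-agnostic). Genes with
#' no qualifying site get NA.
#'
#' @param calls `methylation_calls` table.
#' @param genes `annotation_set` of gene spans.
#' @param context methylation context to summarize (default "CG"; symmetric
#'   merging only applies to CG).
#' @param min_coverage minimum reads per cytosine (default 5).
#' @return data.frame: `gene_id`, `pct_meth`, `n_sites`.
#' @export
gene_methylation <- function(calls, genes, context = "CG", min_coverage = 5L) {
  stopifnot(inherits(calls, "data.frame"), inherits(genes, "annotation_set"))
  cc <- calls[calls$context == context & calls$count_total >= min_coverage, , drop = FALSE]
  if (nrow(cc)) {
    cc$pct <- 100 * cc$count_methylated / cc$count_total
    if (context == "CG") {
      # anchor each symmetric pair at the "+"-strand coordinate
      key_pos <- ifelse(cc$strand == "-", cc$pos - 1L, cc$pos)
      key <- paste(cc$chrom, key_pos)
      agg <- stats::aggregate(pct ~ key, data = data.frame(key = key, pct = cc$pct),
                              FUN = mean)
      first <- !duplicated(key)
      site <- data.frame(chrom = cc$chrom[first], pos = key_pos[first],
                         key = key[first], stringsAsFactors = FALSE)
      site$pct <- agg$pct[match(site$key, agg$key)]
    } else {
      site <- data.frame(chrom = cc$chrom, pos = cc$pos, pct = cc$pct,
                         stringsAsFactors = FALSE)
    }
  } else {
    site <- data.frame(chrom = character(0), pos = integer(0), pct = numeric(0))
  }
  gn <- genes[genes$kind == "gene", , drop = FALSE]
  site_gr <- GenomicRanges::GRanges(site$chrom, IRanges::IRanges(site$pos, site$pos))
  gene_gr <- as_granges(gn)
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, ignore.strand = TRUE)
  pct <- rep(NA_real_, nrow(gn))
  n_sites <- integer(nrow(gn))
  if (length(hits)) {
    by_gene <- split(site$pct[S4Vectors::queryHits(hits)], S4Vectors::subjectHits(hits))
    idx <- as.integer(names(by_gene))
    pct[idx] <- vapply(by_gene, mean, numeric(1))
    n_sites[idx] <- lengths(by_gene)
  }
  data.frame(gene_id = gn$id, pct_meth = pct, n_sites = n_sites,
             stringsAsFactors = FALSE)
}

#' Pool per-replicate methylation weighted by site counts
#'
#' pooled = sum(pct_r * n_r) / sum(n_r) over replicates with n_sites > 0;
#' NA replicates are skipped, and all-NA genes stay NA.
#'
#' @param pct matrix or data.frame of per-replicate percentages (genes x
#'   replicates), NA where a replicate had no qualifying site.
#' @param n_sites matching matrix of per-replicate site counts.
#' @return numeric vector of pooled percentages.
#' @export
pool_replicates_weighted <- function(pct, n_sites) {
  pct <- as.matrix(pct)
  n_sites <- as.matrix(n_sites)
  stopifnot(identical(dim(pct), dim(n_sites)))
  vapply(seq_len(nrow(pct)), function(i) {
    ok <- !is.na(pct[i, ]) & n_sites[i, ] > 0
    if (!any(ok)) return(NA_real_)
    sum(pct[i, ok] * n_sites[i, ok]) / sum(n_sites[i, ok])
  }, numeric(1))
}

#' Distance from each gene to its nearest transposable element
#'
#' Distance 0 when any TE interval overlaps the annotated gene span (1-based
#' inclusive overlap, strand ignored); otherwise the minimal number of bases
#' strictly between the gene span and a TE on the same chromosome. Genes on
#' chromosomes without TEs get NA with a warning.
#'
#' @param genes `annotation_set` of gene spans.
#' @param tes `annotation_set` of transposable elements.
#' @return data.frame: `gene_id`, `te_distance` (bp), `te_within_genic`.
#' @export
nearest_te_distance <- function(genes, tes) {
  gn <- genes[genes$kind == "gene", , drop = FALSE]
  te <- tes[tes$kind == "transposable_element", , drop = FALSE]
  gene_gr <- as_granges(gn)
  te_gr <- as_granges(te)
  d <- rep(NA_real_, nrow(gn))
  if (nrow(te)) {
    # disjoint chromosome sets are legitimate here; the per-gene NA warning
    # below is the informative one
    hit <- suppressWarnings(
      GenomicRanges::distanceToNearest(gene_gr, te_gr, ignore.strand = TRUE))
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  }
  if (anyNA(d)) {
    warning(sum(is.na(d)), " gene(s) on chromosome(s) without TEs: distance NA")
  }
  data.frame(gene_id = gn$id, te_distance = d,
             te_within_genic = !is.na(d) & d == 0, stringsAsFactors = FALSE)
}

#' Assign NLR genes to physical clusters
#'
#' Single-linkage chaining per chromosome: adjacent genes whose inter-gene
#' gap (bases strictly between spans; overlapping genes have gap 0) is at
#' most `max_gap` share a cluster, inclusively at the boundary. Clusters of
#' size 1 are singletons. The result is invariant to input order.
#'
#' @param nlr_genes `annotation_set` of NLR gene spans.
#' @param max_gap maximum inter-gene gap in bp (default 50000).
#' @return data.frame: `gene_id`, `cluster_id` (e.g. "cluster_1" or
#'   "singleton"), `cluster_size`, ordered as the input.
#' @export
assign_clusters <- function(nlr_genes, max_gap = 50000L) {
  gn <- nlr_genes[nlr_genes$kind == "gene", , drop = FALSE]
  gr <- as_granges(gn)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  cl <- integer(nrow(gn))
  cl[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  size <- table(cl)
  csize <- as.integer(size[as.character(cl)])
  data.frame(gene_id = gn$id,
             cluster_id = ifelse(csize > 1L, paste0("cluster_", cl), "singleton"),
             cluster_size = csize, stringsAsFactors = FALSE)
}

#' Paired hv / non-hv neighboring NLRs
#'
#' Returns two-member clusters containing exactly one hv and one non-hv gene
#' whose inter-gene gap is at most `max_pair_gap` bp, or whose members are
#' directly adjacent in the supplied full gene annotation (no other gene
#' strictly between them).
#'
#' @param nlr_genes `annotation_set` of NLR gene spans.
#' @param clusters result of [assign_clusters()] on the same genes.
#' @param hv_labels named character vector (gene_id -> "hv" / "non-hv").
#' @param max_pair_gap maximum gap in bp (default 2000).
#' @param all_genes optional `annotation_set` of all genes, used for the
#'   direct-adjacency alternative.
#' @return data.frame: `hv_gene`, `nonhv_gene`, `gap_bp`, `cluster_id`.
#' @export
neighbor_pairs <- function(nlr_genes, clusters, hv_labels, max_pair_gap = 2000L,
                           all_genes = NULL) {
  gn <- nlr_genes[nlr_genes$kind == "gene", , drop = FALSE]
  out <- data.frame(hv_gene = character(0), nonhv_gene = character(0),
                    gap_bp = numeric(0), cluster_id = character(0),
                    stringsAsFactors = FALSE)
  two <- clusters[clusters$cluster_size == 2L & clusters$cluster_id != "singleton", ]
  for (cid in unique(two$cluster_id)) {
    ids <- two$gene_id[two$cluster_id == cid]
    labs <- hv_labels[ids]
    if (length(ids) != 2L || anyNA(labs) || !setequal(labs, c("hv", "non-hv"))) next
    rows <- gn[match(ids, gn$id), ]
    gap <- max(0, max(rows$start) - min(rows$end) - 1L)
    adjacent <- FALSE
    if (!is.null(all_genes)) {
      ag <- all_genes[all_genes$kind == "gene" & all_genes$chrom == rows$chrom[1], ]
      between <- ag$start > min(rows$end) & ag$end < max(rows$start) &
        !ag$id %in% ids
      adjacent <- !any(between)
    }
    if (gap <= max_pair_gap || adjacent) {
      out <- rbind(out, data.frame(
        hv_gene = ids[labs == "hv"], nonhv_gene = ids[labs == "non-hv"],
        gap_bp = gap, cluster_id = cid, stringsAsFactors = FALSE))
    }
  }
  out
}
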