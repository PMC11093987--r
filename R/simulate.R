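# Synthetic-data generator: neutral coalescent haplotypes, codon clades with
# tunable nonsynonymous acceptance, a full synthetic pan-NLRome with hv /
# non-hv truth labels, and per-gene feature tables (counts, methylation
# calls, TE placements). Time follows the ms convention: with k lineages the
# coalescence rate is k(k-1)/2 in units of 4N generations and mutations are
# Poisson with mean (theta/2) x total branch length, so E[pi_total] = theta
# and E[S] = theta * a1.

#' Simulation configuration
#'
#' Defaults mirror the study design: 132 NLR genes of which 35 are hv-like,
#' clade alignments over 24 accessions, and group effects of +2 log2
#' fold-change in expression, -40 percentage points of CG methylation, and
#' TE-overlap probabilities of 0.6 (hv-like) vs 0.1 (non-hv-like).
#'
#' @param n_genes number of simulated NLR genes.
#' @param hv_fraction fraction of genes that are hv-like.
#' @param n_accessions haplotypes per clade alignment.
#' @param n_codons codons per gene.
#' @param theta_low,theta_high per-gene population mutation parameter for
#'   non-hv-like and hv-like genes.
#' @param omega_low,omega_high nonsynonymous acceptance probability per group.
#' @param expr_log2fc hv expression effect in log2 fold change.
#' @param expr_baseline_mu negative-binomial mean count for non-hv genes.
#' @param expr_size negative-binomial size (inverse dispersion).
#' @param n_expr_replicates RNA count replicates.
#' @param meth_level_nonhv,meth_level_hv per-group CG methylation level (0-1).
#' @param n_cg_pairs symmetric CG pairs per gene body.
#' @param coverage_mean Poisson mean read coverage per cytosine.
#' @param n_meth_replicates bisulfite replicates.
#' @param te_overlap_prob_hv,te_overlap_prob_nonhv probability that a TE
#'   overlaps the gene span.
#' @param te_mean_dist_hv,te_mean_dist_nonhv mean TE gap (bp) when not
#'   overlapping.
#' @param gene_width gene span width (bp) on the toy chromosome.
#' @param cluster_gap,singleton_gap inter-gene gaps (bp) used for clustered
#'   and dispersed neighbors.
#' @param cluster_prob probability that the gap after a gene is the tight
#'   (clustered) one.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 132L, hv_fraction = 35 / 132,
                       n_accessions = 24L, n_codons = 250L,
                       theta_low = 4, theta_high = 300,
                       omega_low = 0.2, omega_high = 0.9,
                       expr_log2fc = 2, expr_baseline_mu = 50, expr_size = 10,
                       n_expr_replicates = 4L,
                       meth_level_nonhv = 0.6, meth_level_hv = 0.2,
                       n_cg_pairs = 30L, coverage_mean = 10,
                       n_meth_replicates = 2L,
                       te_overlap_prob_hv = 0.6, te_overlap_prob_nonhv = 0.1,
                       te_mean_dist_hv = 1000, te_mean_dist_nonhv = 3000,
                       gene_width = 3000L, cluster_gap = 5000L,
                       singleton_gap = 80000L, cluster_prob = 0.3,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(hv_fraction >= 0, hv_fraction <= 1,
            theta_low > 0, theta_high > 0,
            omega_low >= 0, omega_low <= 1, omega_high >= 0, omega_high <= 1,
            coverage_mean > 0, n_accessions >= 2, n_codons >= 10)
  class(cfg) <- "sim_config"
  cfg
}

# coalescent tree for n lineages; assumes RNG already seeded.
# Returns node table (2n-1 nodes, leaves 1..n): parent, branch length (time to
# parent), node time, and the leaf sets below each node.
sim_coalescent_tree <- function(n) {
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  node_time <- numeric(n_nodes)
  leaves_below <- vector("list", n_nodes)
  for (i in seq_len(n)) leaves_below[[i]] <- i
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample(length(active), 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    parent[c(a, b)] <- nxt
    node_time[nxt] <- t
    leaves_below[[nxt]] <- c(leaves_below[[a]], leaves_below[[b]])
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  branch_len <- node_time[parent] - node_time
  branch_len[n_nodes] <- 0  # root
  list(n = n, parent = parent, node_time = node_time,
       branch_length = branch_len, leaves_below = leaves_below,
       total_length = sum(branch_len, na.rm = TRUE), tmrca = t)
}

#' Simulate haplotypes on a neutral coalescent genealogy
#'
#' Infinite-sites mutations: Poisson((theta/2) * total branch length) in
#' number, placed uniformly on branches and assigned distinct positions in
#' 1..L (up to 100 re-draws per collision, then an error advising larger L).
#'
#' @param n haplotypes (>= 2).
#' @param theta population mutation parameter (> 0).
#' @param L sequence length in sites hosting the mutations.
#' @param seed integer seed.
#' @return `haplotype_matrix` with extra elements `total_branch_length` and
#'   `tmrca`.
#' @export
simulate_genealogy_haplotypes <- function(n, theta, L, seed = 1L) {
  stopifnot(n >= 2, L >= 1, theta > 0)
  with_seed(seed, {
    tree <- sim_coalescent_tree(n)
    n_mut <- stats::rpois(1, theta / 2 * tree$total_length)
    branches <- which(!is.na(tree$parent))
    sites <- integer(0)
    mat <- matrix(0L, nrow = n, ncol = n_mut)
    pos <- integer(n_mut)
    if (n_mut > 0) {
      picked <- sample(branches, n_mut, replace = TRUE,
                       prob = tree$branch_length[branches])
      for (mi in seq_len(n_mut)) {
        site <- sample.int(L, 1L)
        tries <- 0L
        while (site %in% sites) {
          tries <- tries + 1L
          if (tries > 100L) {
            stop("could not place ", n_mut, " distinct mutations in L = ", L,
                 " sites; increase L")
          }
          site <- sample.int(L, 1L)
        }
        sites <- c(sites, site)
        pos[mi] <- site
        mat[tree$leaves_below[[picked[mi]]], mi] <- 1L
      }
      ord <- order(pos)
      mat <- mat[, ord, drop = FALSE]
      pos <- pos[ord]
    }
    ids <- sprintf("hap_%02d", seq_len(n))
    rownames(mat) <- ids
    structure(list(mat = mat, positions = pos, sample_ids = ids,
                   n_records = n_mut, n_dropped_nonbiallelic = 0L,
                   n_dropped_missing = 0L, n_het_sites = 0L,
                   total_branch_length = tree$total_length, tmrca = tree$tmrca),
              class = "haplotype_matrix")
  })
}

# one mutation proposal/acceptance on a codon vector; returns updated codons
propose_mutation <- function(codons, omega) {
  for (try in 1:1000) {
    ci <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    base <- strsplit(codons[ci], "")[[1]]
    alt <- sample(setdiff(NUCS, base[pos]), 1L)
    newb <- base
    newb[pos] <- alt
    new_codon <- paste(newb, collapse = "")
    if (is_stop_codon(new_codon)) next  # stop-creating proposals re-drawn
    aa_old <- Biostrings::GENETIC_CODE[[codons[ci]]]
    aa_new <- Biostrings::GENETIC_CODE[[new_codon]]
    if (aa_old == aa_new || stats::runif(1) < omega) codons[ci] <- new_codon
    return(codons)  # rejected nonsynonymous proposals leave the sequence as-is
  }
  stop("could not draw a non-stop mutation proposal")
}

#' Simulate a codon clade alignment with tunable omega
#'
#' Mutations are placed on a neutral coalescent genealogy as in
#' [simulate_genealogy_haplotypes()] (recurrent hits allowed) and applied
#' down the tree: each mutation proposes a random single-nucleotide change
#' in a random codon; synonymous proposals are always accepted,
#' nonsynonymous ones with probability `omega`, and stop-creating proposals
#' are re-drawn. The root is a random stop-free codon sequence.
#'
#' @param n sequences.
#' @param theta population mutation parameter for the gene.
#' @param omega nonsynonymous acceptance probability in [0, 1].
#' @param n_codons codons per sequence (>= 10).
#' @param seed integer seed.
#' @return list: `codon_aln` and `protein_aln` (`nlr_alignment`s), `n_mutations`.
#' @export
simulate_codon_clade <- function(n, theta, omega, n_codons, seed = 1L) {
  stopifnot(n >= 2, theta > 0, omega >= 0, omega <= 1, n_codons >= 10)
  with_seed(seed, {
    tree <- sim_coalescent_tree(n)
    n_mut <- stats::rpois(1, theta / 2 * tree$total_length)
    branches <- which(!is.na(tree$parent))
    mut_branch <- if (n_mut > 0) {
      sample(branches, n_mut, replace = TRUE,
             prob = tree$branch_length[branches])
    } else integer(0)
    mut_per_branch <- tabulate(mut_branch, nbins = 2L * n - 1L)
    sense <- sense_codons()
    root <- sample(sense, n_codons, replace = TRUE)
    children <- split(seq_len(2L * n - 2L), tree$parent[seq_len(2L * n - 2L)])
    leaf_seqs <- vector("list", n)
    descend <- function(node, codons) {
      for (m in seq_len(mut_per_branch[node])) codons <- propose_mutation(codons, omega)
      if (node <= n) {
        leaf_seqs[[node]] <<- codons
      } else {
        for (ch in children[[as.character(node)]]) descend(ch, codons)
      }
    }
    root_node <- 2L * n - 1L
    for (ch in children[[as.character(root_node)]]) descend(ch, root)
    ids <- sprintf("acc_%02d", seq_len(n))
    codon_seqs <- vapply(leaf_seqs, paste, character(1), collapse = "")
    prot_seqs <- vapply(leaf_seqs, function(cd) {
      paste(Biostrings::GENETIC_CODE[cd], collapse = "")
    }, character(1))
    list(codon_aln = new_alignment(ids, codon_seqs, "codon"),
         protein_aln = new_alignment(ids, prot_seqs, "protein"),
         n_mutations = n_mut)
  })
}

#' Simulate a pan-NLRome with known hv / non-hv truth
#'
#' Draws `round(n_genes * hv_fraction)` hv-like genes (theta_high,
#' omega_high) and the rest non-hv-like (theta_low, omega_low), one codon
#' clade per gene via [simulate_codon_clade()]. Accession `acc_01` is the
#' focal sequence of every gene. Optionally writes per-gene protein FASTA
#' files and a truth TSV.
#'
#' @param config a `sim_config`.
#' @param dir optional output directory for FASTA + truth.tsv.
#' @return list: `genes` (named list with `codon_aln`, `protein_aln`,
#'   `focal_id`), `truth` (data.frame gene_id, group, theta, omega).
#' @export
simulate_nlrome <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_hv <- round(config$n_genes * config$hv_fraction)
  groups <- rep(c("hv-like", "non-hv-like"), c(n_hv, config$n_genes - n_hv))
  gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
  genes <- vector("list", config$n_genes)
  names(genes) <- gene_ids
  for (i in seq_len(config$n_genes)) {
    hv <- groups[i] == "hv-like"
    clade <- simulate_codon_clade(
      n = config$n_accessions,
      theta = if (hv) config$theta_high else config$theta_low,
      omega = if (hv) config$omega_high else config$omega_low,
      n_codons = config$n_codons,
      seed = derive_seed(config$seed, i))
    genes[[i]] <- list(codon_aln = clade$codon_aln,
                       protein_aln = clade$protein_aln, focal_id = "acc_01")
  }
  truth <- data.frame(
    gene_id = gene_ids, group = groups,
    theta = ifelse(groups == "hv-like", config$theta_high, config$theta_low),
    omega = ifelse(groups == "hv-like", config$omega_high, config$omega_low),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (g in gene_ids) {
      write_fasta(genes[[g]]$protein_aln, file.path(dir, paste0(g, "_protein.fasta")))
      write_fasta(genes[[g]]$codon_aln, file.path(dir, paste0(g, "_codon.fasta")))
    }
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(genes = genes, truth = truth)
}

#' Simulate per-gene feature tables (counts, methylation, TEs)
#'
#' Genes are laid end to end on a toy chromosome "Chr1". Counts are negative
#' binomial with a +`expr_log2fc` log2 fold-change for hv-like genes;
#' methylation calls are binomial draws at symmetric CG pairs with Poisson
#' coverage; TE placements overlap the gene span with a group-specific
#' probability and otherwise sit at an exponential gap downstream.
#'
#' @param config a `sim_config`.
#' @return list: `counts` (`count_matrix`), `meth_calls` (list of
#'   `methylation_calls` replicates), `genes` and `tes` (`annotation_set`s),
#'   `truth` (per-gene ground truth incl. the generator-ledger methylation
#'   recomputation), `ledger` (totals of emitted reads/sites/TEs).
#' @export
simulate_feature_tables <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  n_hv <- round(n * config$hv_fraction)
  groups <- rep(c("hv-like", "non-hv-like"), c(n_hv, n - n_hv))
  gene_ids <- sprintf("gene_%03d", seq_len(n))
  if (min(config$cluster_gap, config$singleton_gap) < 1000L) {
    stop("inter-gene gaps too small for non-overlapping TE placement")
  }

  with_seed(derive_seed(config$seed, "features"), {
    hv <- groups == "hv-like"
    gaps_after <- ifelse(stats::runif(n) < config$cluster_prob,
                         config$cluster_gap, config$singleton_gap)
    starts <- 1L + cumsum(c(0L, (config$gene_width + gaps_after)[-n]))
    ends <- starts + config$gene_width - 1L
    genes <- annotation_set("Chr1", starts, ends, gene_ids, kind = "gene",
                            strand = "+")
    mu <- config$expr_baseline_mu * 2^(config$expr_log2fc * hv)
    cnt <- matrix(stats::rnbinom(n * config$n_expr_replicates,
                                 mu = rep(mu, config$n_expr_replicates),
                                 size = config$expr_size),
                  nrow = n, ncol = config$n_expr_replicates,
                  dimnames = list(gene_ids,
                                  sprintf("rep_%d", seq_len(config$n_expr_replicates))))
    counts <- count_matrix(cnt, stats::setNames(rep(config$gene_width, n), gene_ids))

    level <- ifelse(hv, config$meth_level_hv, config$meth_level_nonhv)
    meth_calls <- vector("list", config$n_meth_replicates)
    truth_pct <- matrix(NA_real_, n, config$n_meth_replicates)
    truth_nsites <- matrix(0L, n, config$n_meth_replicates)
    for (r in seq_len(config$n_meth_replicates)) {
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        plus_pos <- starts[i] + 10L + (seq_len(config$n_cg_pairs) - 1L) * 50L
        pos <- as.vector(rbind(plus_pos, plus_pos + 1L))
        strand <- rep(c("+", "-"), config$n_cg_pairs)
        cov <- stats::rpois(length(pos), config$coverage_mean)
        meth <- stats::rbinom(length(pos), cov, level[i])
        rows[[i]] <- data.frame(chrom = "Chr1", pos = pos, strand = strand,
                                context = "CG", count_methylated = meth,
                                count_total = cov, stringsAsFactors = FALSE)
        # generator ledger: same filter/merge arithmetic, computed directly
        ok <- cov >= 5L
        pct <- 100 * meth / cov
        site_pct <- vapply(seq_len(config$n_cg_pairs), function(p) {
          idx <- c(2L * p - 1L, 2L * p)
          use <- idx[ok[idx]]
          if (!length(use)) NA_real_ else mean(pct[use])
        }, numeric(1))
        truth_nsites[i, r] <- sum(!is.na(site_pct))
        truth_pct[i, r] <- if (truth_nsites[i, r]) mean(site_pct, na.rm = TRUE) else NA_real_
      }
      tab <- do.call(rbind, rows)
      class(tab) <- c("methylation_calls", "data.frame")
      meth_calls[[r]] <- tab
    }

    overlap_p <- ifelse(hv, config$te_overlap_prob_hv, config$te_overlap_prob_nonhv)
    overlaps <- stats::runif(n) < overlap_p
    gap <- ifelse(overlaps, 0,
                  1 + round(stats::rexp(n, 1 / ifelse(hv, config$te_mean_dist_hv,
                                                      config$te_mean_dist_nonhv))))
    gap <- pmin(gap, gaps_after - 400L)  # keep each TE before the next gene
    te_start <- ifelse(overlaps, starts + 500L, ends + gap + 1L)
    te_end <- te_start + 299L
    tes <- annotation_set("Chr1", te_start, te_end,
                          sprintf("AT1TE%05d", seq_len(n)),
                          kind = "transposable_element", strand = "+")

    truth <- data.frame(
      gene_id = gene_ids, group = groups, expr_mu = mu,
      meth_level = level, te_overlap = overlaps, te_gap = gap,
      pct_meth_truth = pool_replicates_weighted(truth_pct, truth_nsites),
      n_sites_truth = rowSums(truth_nsites), stringsAsFactors = FALSE)
    ledger <- list(total_counts = sum(cnt),
                   total_cytosine_rows = sum(vapply(meth_calls, nrow, integer(1))),
                   total_meth_reads = sum(vapply(meth_calls, function(x)
                     sum(x$count_total), numeric(1))),
                   n_tes = nrow(tes))
    list(counts = counts, meth_calls = meth_calls, genes = genes, tes = tes,
         truth = truth, ledger = ledger)
  })
}
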