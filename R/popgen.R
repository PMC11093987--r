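# Diversity statistics on haplotype 0/1 matrices or nucleotide alignments.
# Gaps and N are missing states: they are skipped in pairwise comparisons and
# never make a site segregating, but per-site normalization always uses the
# full alignment / CDS length L.

# returns list(n, L, S, pi_total) from sequences or a haplotype matrix
pairwise_core <- function(x, L = NULL) {
  if (inherits(x, "haplotype_matrix")) {
    m <- x$mat
    n <- nrow(m)
    if (is.null(L)) L <- ncol(m)
    if (ncol(m)) {
      c1 <- colSums(m)
      c0 <- n - c1
      S <- sum(c1 > 0L & c1 < n)
      pi_total <- sum(c1 * c0) / choose(n, 2)
    } else {
      S <- 0L
      pi_total <- 0
    }
    return(list(n = n, L = L, S = S, pi_total = pi_total))
  }
  seqs <- if (inherits(x, "nlr_alignment")) x$seqs else toupper(as.character(x))
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be aligned")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  n <- nrow(m)
  if (is.null(L)) L <- ncol(m)
  ok <- m != "-" & m != "N"
  S <- sum(apply(m, 2, function(col) {
    a <- unique(col[col != "-" & col != "N"])
    length(a) >= 2L
  }))
  tot <- 0
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        use <- ok[i, ] & ok[j, ]
        tot <- tot + sum(m[i, use] != m[j, use])
      }
    }
  }
  list(n = n, L = L, S = S, pi_total = tot / choose(n, 2))
}

#' Tajima (1989) constants for a sample of n haplotypes
#'
#' @param n number of haplotypes (>= 2).
#' @return named list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Diversity summary: pi, S, Watterson's theta, Tajima's D
#'
#' Computes the full summary from a nucleotide alignment, character vector of
#' aligned sequences, or a `haplotype_matrix`. `pi_total` is the average
#' pairwise difference count over all C(n,2) pairs (gap/N columns skipped in
#' each comparison); per-site values divide by the full length `L`
#' (monomorphic and gap-containing columns included). Tajima's D is `NA`
#' (undefined, never 0) when S = 0, and requires n >= 3.
#'
#' @param x alignment, aligned sequence vector, or `haplotype_matrix`.
#' @param L sites considered for per-site normalization; defaults to the
#'   alignment/matrix column count (for VCF-derived matrices pass the CDS
#'   length so monomorphic positions are counted).
#' @return object of class `diversity_stats`: `n`, `L`, `S`, `pi_total`,
#'   `pi_per_site`, `theta_w_total`, `theta_w_per_site`, `tajimas_d`,
#'   `constants`.
#' @export
diversity_stats <- function(x, L = NULL) {
  core <- pairwise_core(x, L)
  if (core$n < 2) stop("need at least 2 haplotypes")
  k <- tajima_constants(core$n)
  theta_total <- core$S / k$a1
  D <- NA_real_
  if (core$n >= 3 && core$S >= 1) {
    v <- k$e1 * core$S + k$e2 * core$S * (core$S - 1)
    num <- core$pi_total - theta_total
    # at n = 3 the variance constants vanish identically; a zero numerator
    # over a zero variance is reported as D = 0, anything else as undefined
    D <- if (v > 0) num / sqrt(v) else if (abs(num) < 1e-12) 0 else NA_real_
  }
  structure(list(n = core$n, L = core$L, S = core$S,
                 pi_total = core$pi_total, pi_per_site = core$pi_total / core$L,
                 theta_w_total = theta_total, theta_w_per_site = theta_total / core$L,
                 tajimas_d = D, constants = k),
            class = "diversity_stats")
}

#' Nucleotide diversity (pi)
#' @inheritParams diversity_stats
#' @return `diversity_stats` (errors if n < 2).
#' @export
nucleotide_diversity <- function(x, L = NULL) diversity_stats(x, L)

#' Watterson's theta and segregating sites
#' @inheritParams diversity_stats
#' @return `diversity_stats`.
#' @export
watterson_theta <- function(x, L = NULL) diversity_stats(x, L)

#' Tajima's D
#' @inheritParams diversity_stats
#' @return `diversity_stats`; `tajimas_d` is NA when S = 0 (undefined).
#' @export
tajimas_d <- function(x, L = NULL) {
  core_n <- if (inherits(x, "haplotype_matrix")) nrow(x$mat)
            else if (inherits(x, "nlr_alignment")) length(x$ids) else length(x)
  if (core_n < 3) stop("Tajima's D requires n >= 3 haplotypes")
  diversity_stats(x, L)
}

#' Diversity statistics for a gene from VCF haplotypes
#'
#' Same estimators as [diversity_stats()], with `L` set to the CDS length so
#' that monomorphic positions (absent from the SNP matrix) enter the
#' per-site normalization.
#'
#' @param h `haplotype_matrix` from [read_vcf_region()] over the gene's CDS.
#' @param cds_length CDS length in bp.
#' @return `diversity_stats`.
#' @export
stats_from_vcf_gene <- function(h, cds_length) {
  stopifnot(inherits(h, "haplotype_matrix"), cds_length >= 1)
  diversity_stats(h, L = cds_length)
}

#' Empirical-distribution tail flags
#'
#' Flags genes whose statistic lies strictly beyond the empirical 95th (tail
#' "top5") or 5th ("bottom5") percentile of a genome-wide background
#' distribution. Quantiles use linear interpolation between order statistics.
#'
#' @param gene_values named numeric vector (gene -> value).
#' @param background numeric vector of genome-wide values (length >= 100).
#' @param tail `"top5"` or `"bottom5"`.
#' @return list: `flags` (named logical), `threshold`, `tail`.
#' @export
empirical_tail_flags <- function(gene_values, background, tail = c("top5", "bottom5")) {
  tail <- match.arg(tail)
  background <- background[!is.na(background)]
  if (!length(background)) stop("empty background distribution")
  if (length(background) < 100) warning("background smaller than 100 values")
  thr <- unname(stats::quantile(background, if (tail == "top5") 0.95 else 0.05,
                                type = 7, names = FALSE))
  flags <- if (tail == "top5") gene_values > thr else gene_values < thr
  list(flags = flags, threshold = thr, tail = tail)
}

#' Joint balancing-selection flag
#'
#' A gene is flagged as a balancing-selection candidate when it is strictly
#' in the top 5% of both the pi and the Tajima's D genome-wide empirical
#' distributions.
#'
#' @param pi_values,d_values named numeric vectors over the same genes.
#' @param pi_background,d_background genome-wide background distributions.
#' @return list: `flags` (named logical), `pi_threshold`, `d_threshold`.
#' @export
balancing_selection_flags <- function(pi_values, d_values, pi_background, d_background) {
  stopifnot(identical(names(pi_values), names(d_values)))
  a <- empirical_tail_flags(pi_values, pi_background, "top5")
  b <- empirical_tail_flags(d_values, d_background, "top5")
  flags <- a$flags & b$flags
  flags[is.na(flags)] <- FALSE
  list(flags = flags, pi_threshold = a$threshold, d_threshold = b$threshold)
}

#' Majority-vote domain labels on alignment columns
#'
#' Each alignment column is labeled with the plurality domain class among
#' non-gap sequences, from per-sequence domain intervals given in each
#' sequence's own ungapped coordinates (residues for protein alignments,
#' nucleotides for codon/nucleotide alignments). Ties and unannotated
#' majorities give "none".
#'
#' @param aln `nlr_alignment`.
#' @param intervals data.frame with columns `seq_id`, `domain` (one of CC,
#'   TIR, NBARC, LRR), `start`, `end` (1-based inclusive, ungapped).
#' @return list: `column_labels` (character, one per column), `columns`
#'   (named list of column-index vectors per label, "none" included).
#' @export
domain_columns <- function(aln, intervals) {
  stopifnot(inherits(aln, "nlr_alignment"),
            all(c("seq_id", "domain", "start", "end") %in% names(intervals)))
  classes <- c("CC", "TIR", "NBARC", "LRR")
  if (!all(intervals$domain %in% classes)) {
    stop("domain must be one of ", paste(classes, collapse = ", "))
  }
  m <- aln_matrix(aln)
  ncol_aln <- ncol(m)
  # per-sequence label per column
  lab <- matrix(NA_character_, nrow = nrow(m), ncol = ncol_aln)
  for (i in seq_len(nrow(m))) {
    id <- rownames(m)[i]
    nongap <- which(m[i, ] != "-")
    seq_lab <- rep("none", length(nongap))  # ungapped coordinate -> label
    iv <- intervals[intervals$seq_id == id, , drop = FALSE]
    if (nrow(iv) && any(iv$end > length(nongap))) {
      stop("domain interval beyond sequence length for ", id)
    }
    for (r in seq_len(nrow(iv))) {
      seq_lab[iv$start[r]:iv$end[r]] <- iv$domain[r]
    }
    lab[i, nongap] <- seq_lab
  }
  column_labels <- vapply(seq_len(ncol_aln), function(j) {
    v <- lab[, j]
    v <- v[!is.na(v)]
    if (!length(v)) return("none")
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) return("none")  # tie
    names(tab)[1]
  }, character(1))
  cols <- lapply(c(classes, "none"), function(cl) which(column_labels == cl))
  names(cols) <- c(classes, "none")
  list(column_labels = column_labels, columns = cols)
}

#' Sliding-window diversity along a focal CDS
#'
#' Windows of `window` bp advance by `step` bp along the focal sequence's
#' ungapped CDS coordinates (starts 1, 1+step, ... while the full window
#' fits; incomplete tail windows are dropped). The statistic is computed on
#' the alignment columns carrying the focal positions of each window, with
#' per-site normalization by the window size.
#'
#' @param aln nucleotide or codon `nlr_alignment`.
#' @param focal_id focal sequence id.
#' @param stat `"pi"` (per site) or `"tajimas_d"`.
#' @param window,step window size and step in bp (defaults 300 and 75).
#' @return data.frame of class `window_track`: `start`, `end`, `midpoint`,
#'   `stat`, `value` (midpoint = start + window/2 - 1, i.e. 150 bp in for the
#'   default).
#' @export
sliding_window_stats <- function(aln, focal_id, stat = c("pi", "tajimas_d"),
                                 window = 300L, step = 75L) {
  stat <- match.arg(stat)
  stopifnot(inherits(aln, "nlr_alignment"))
  if (!focal_id %in% aln$ids) stop("focal id not in alignment: ", focal_id)
  m <- aln_matrix(aln)
  focal_cols <- which(m[focal_id, ] != "-")
  L <- length(focal_cols)
  empty <- data.frame(start = integer(0), end = integer(0), midpoint = integer(0),
                      stat = character(0), value = numeric(0))
  if (L < window) {
    warning("focal CDS (", L, " bp) shorter than window (", window, " bp)")
    class(empty) <- c("window_track", "data.frame")
    return(empty)
  }
  starts <- seq(1L, L - window + 1L, by = step)
  vals <- vapply(starts, function(s) {
    cols <- focal_cols[s:(s + window - 1L)]
    sub <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    ds <- diversity_stats(sub, L = window)
    if (stat == "pi") ds$pi_per_site else ds$tajimas_d
  }, numeric(1))
  out <- data.frame(start = starts, end = starts + window - 1L,
                    midpoint = starts + window %/% 2L - 1L,
                    stat = stat, value = vals, stringsAsFactors = FALSE)
  class(out) <- c("window_track", "data.frame")
  out
}
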