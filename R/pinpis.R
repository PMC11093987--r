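# Nei-Gojobori (1986) synonymous / nonsynonymous diversity on codon
# alignments, with no multiple-hit correction. Potential sites: per codon
# position, the fraction of the non-stop single-nucleotide changes that are
# synonymous (so syn + nonsyn fractions sum to 1 per position and potential
# sites sum to 3 per codon; excluding stop-creating changes from the
# denominator is the logged adjustment). Pairwise differences: synonymous and
# nonsynonymous counts averaged over the shortest mutational pathways between
# the two codons, excluding pathways that pass through a stop codon (if every
# pathway is blocked, all pathways are used as a fallback).

ng86_cache <- new.env(parent = emptyenv())

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# per-codon potential synonymous sites (NA for stop codons)
ng86_syn_sites <- function() {
  if (!is.null(ng86_cache$syn_sites)) return(ng86_cache$syn_sites)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  out <- stats::setNames(rep(NA_real_, 64L), codons)
  for (cd in codons) {
    if (gc[[cd]] == "*") next
    s <- 0
    base <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      alts <- setdiff(NUCS, base[pos])
      muts <- vapply(alts, function(b) {
        x <- base; x[pos] <- b; paste(x, collapse = "")
      }, character(1))
      aa <- gc[muts]
      nonstop <- aa != "*"
      if (any(nonstop)) s <- s + sum(aa[nonstop] == gc[[cd]]) / sum(nonstop)
    }
    out[cd] <- s
  }
  ng86_cache$syn_sites <- out
  out
}

# average (syn, nonsyn) differences over unblocked shortest pathways
ng86_path_diffs <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                 function(o) pos[o]))
  score_path <- function(order) {
    cur <- b1
    syn <- 0; nonsyn <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b2[p]
      aa_from <- gc[[paste(cur, collapse = "")]]
      aa_to <- gc[[paste(nxt, collapse = "")]]
      if (aa_to == "*" || aa_from == "*") return(NULL)  # blocked pathway
      if (aa_from == aa_to) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  scored <- Filter(Negate(is.null), lapply(perms, score_path))
  if (!length(scored)) {  # all pathways pass through a stop: fall back to all
    scored <- lapply(perms, function(order) {
      cur <- b1; syn <- 0; nonsyn <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- b2[p]
        if (gc[[paste(cur, collapse = "")]] == gc[[paste(nxt, collapse = "")]]) {
          syn <- syn + 1
        } else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn = syn, nonsyn = nonsyn)
    })
  }
  colMeans(do.call(rbind, scored))
}

# 61x61 lookup matrices of pathway-averaged syn / nonsyn differences
ng86_diff_tables <- function() {
  if (!is.null(ng86_cache$sd)) return(list(sd = ng86_cache$sd, nd = ng86_cache$nd))
  sense <- sense_codons()
  k <- length(sense)
  sd <- matrix(0, k, k, dimnames = list(sense, sense))
  nd <- matrix(0, k, k, dimnames = list(sense, sense))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      d <- ng86_path_diffs(sense[i], sense[j])
      sd[i, j] <- sd[j, i] <- d[["syn"]]
      nd[i, j] <- nd[j, i] <- d[["nonsyn"]]
    }
  }
  ng86_cache$sd <- sd
  ng86_cache$nd <- nd
  list(sd = sd, nd = nd)
}

#' Nonsynonymous and synonymous nucleotide diversity (piN, piS)
#'
#' Nei-Gojobori-style estimator on an in-frame codon alignment. For every
#' sequence pair, synonymous and nonsynonymous differences (pathway-averaged)
#' and potential sites (averaged over the two codons) are summed over codons
#' comparable in that pair; codon pairs containing a gap or ambiguous base
#' are skipped and counted. piN is the ratio of the pairwise-mean
#' nonsynonymous differences to the pairwise-mean nonsynonymous sites, piS
#' likewise; no multiple-hit correction is applied.
#'
#' @param codon_aln codon `nlr_alignment` (frame 0; stops only terminal).
#' @return object of class `codon_diversity`: `pi_n`, `pi_s`, `ratio`
#'   (NA when piS = 0), `syn_sites`, `nonsyn_sites` (pairwise means),
#'   `n_skipped_codon_pairs`.
#' @export
pin_pis <- function(codon_aln) {
  stopifnot(inherits(codon_aln, "nlr_alignment"))
  if (codon_aln$length %% 3L != 0L) stop("not a codon alignment")
  n <- aln_n(codon_aln)
  if (n < 2) stop("need at least 2 sequences")
  syn_sites <- ng86_syn_sites()
  tabs <- ng86_diff_tables()
  codon_rows <- lapply(codon_aln$seqs, split_codons)
  n_codons <- codon_aln$length %/% 3L
  # terminal stop allowed and ignored; internal stop is an error
  for (i in seq_len(n)) {
    aa <- Biostrings::GENETIC_CODE[codon_rows[[i]]]
    internal <- which(!is.na(aa) & aa == "*")
    if (length(internal) && any(internal < n_codons)) {
      stop("internal stop codon in ", codon_aln$ids[i], " at codon ",
           internal[internal < n_codons][1])
    }
  }
  sense <- rownames(tabs$sd)
  pair_sd <- pair_nd <- pair_ss <- pair_ns <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ci <- codon_rows[[i]]
      cj <- codon_rows[[j]]
      usable <- ci %in% sense & cj %in% sense
      skipped <- skipped + sum(!usable)
      ci <- ci[usable]
      cj <- cj[usable]
      ss <- sum((syn_sites[ci] + syn_sites[cj]) / 2)
      ns <- 3 * length(ci) - ss
      idx <- cbind(match(ci, sense), match(cj, sense))
      pair_sd <- c(pair_sd, sum(tabs$sd[idx]))
      pair_nd <- c(pair_nd, sum(tabs$nd[idx]))
      pair_ss <- c(pair_ss, ss)
      pair_ns <- c(pair_ns, ns)
    }
  }
  mean_ss <- mean(pair_ss)
  mean_ns <- mean(pair_ns)
  pi_s <- if (mean_ss > 0) mean(pair_sd) / mean_ss else 0
  pi_n <- if (mean_ns > 0) mean(pair_nd) / mean_ns else 0
  structure(list(pi_n = pi_n, pi_s = pi_s,
                 ratio = if (pi_s > 0) pi_n / pi_s else NA_real_,
                 syn_sites = mean_ss, nonsyn_sites = mean_ns,
                 n_skipped_codon_pairs = skipped),
            class = "codon_diversity")
}
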