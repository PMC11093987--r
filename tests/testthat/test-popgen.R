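test_that("pi matches hand-enumerated pairwise differences", {
  two <- c(paste(rep("A", 100), collapse = ""),
           paste(c(rep("A", 99), "T"), collapse = ""))
  expect_equal(diversity_stats(two)$pi_per_site, 0.01)
  expect_equal(diversity_stats(c("ACGT", "ACGT"))$pi_total, 0)
  # pairs: (1,2)=1, (1,3)=2, (2,3)=1 -> 4/3
  d3 <- diversity_stats(c("AAAAA", "AAAAT", "AATAT"))
  expect_equal(d3$pi_total, 4 / 3)
  expect_error(diversity_stats("AAAA"), "2 haplotypes")
})

test_that("segregating sites and Watterson's theta follow the definitions", {
  expect_equal(diversity_stats(c("AAAA", "AAAA", "AAAA"))$S, 0L)
  d3 <- diversity_stats(c("AAAAA", "AAAAT", "AATAT"))
  expect_equal(d3$S, 2L)
  expect_equal(d3$constants$a1, 1.5)
  expect_equal(d3$theta_w_total, 2 / 1.5)
  # n = 2: a1 = 1 so theta_total = S, and pi_total = S on gap-free sequences
  d2 <- diversity_stats(c("AACGT", "ATCGA"))
  expect_equal(d2$theta_w_total, d2$S)
  expect_equal(d2$pi_total, d2$S)
  # a column with one real allele plus gaps is not segregating
  dg <- diversity_stats(c("A-A", "A-A", "AGA"))
  expect_equal(dg$S, 0L)
})

test_that("Tajima's D reproduces hand-evaluated 1989 constants", {
  # n = 4, L = 10, two singleton sites carried by different haplotypes:
  # a1 = 11/6, pi_total = 1, theta = 2/a1, Var = e1*2 + e2*2 -> D = -0.7099
  m <- matrix(0L, 4, 2)
  m[1, 1] <- 1L
  m[2, 2] <- 1L
  h <- structure(list(mat = m, positions = c(2L, 5L),
                      sample_ids = paste0("h", 1:4)),
                 class = "haplotype_matrix")
  d <- diversity_stats(h, L = 10)
  k <- d$constants
  expect_equal(k$a1, 1 + 1 / 2 + 1 / 3)
  expect_equal(k$e1 * 2 + k$e2 * 2, 0.01640, tolerance = 1e-3)
  expect_equal(d$tajimas_d, -0.710, tolerance = 1e-3)

  # numerator vanishes exactly for the 3-sequence example
  expect_identical(diversity_stats(c("AAAAA", "AAAAT", "AATAT"))$tajimas_d, 0)
  # monomorphic: undefined, never coerced to zero
  expect_true(is.na(diversity_stats(c("AAA", "AAA", "AAA"))$tajimas_d))
  expect_error(tajimas_d(c("AA", "AT")), "n >= 3")
})

test_that("diversity statistics are invariant to sequence reordering", {
  h <- simulate_genealogy_haplotypes(8, 6, 500, seed = 42)
  d1 <- diversity_stats(h)
  perm <- sample(8)
  h2 <- h
  h2$mat <- h$mat[perm, , drop = FALSE]
  d2 <- diversity_stats(h2)
  expect_equal(d1$pi_total, d2$pi_total)
  expect_equal(d1$S, d2$S)
  expect_gte(d1$pi_total, 0)
  expect_gte(d1$theta_w_total, 0)
})

test_that("piN/piS reproduces the enumerated codon pair and the omega = 0 limit", {
  same <- make_aln(c("ATGAAA", "ATGAAA"), alphabet = "nucleotide")
  same$alphabet <- "codon"
  cd0 <- pin_pis(same)
  expect_equal(cd0$pi_n, 0)
  expect_equal(cd0$pi_s, 0)
  expect_true(is.na(cd0$ratio))

  # TTT vs TTC: one synonymous difference; each codon has 1/3 synonymous site
  pair <- new_alignment(c("a", "b"), c("TTT", "TTC"), "codon")
  cd <- pin_pis(pair)
  expect_equal(cd$syn_sites, 1 / 3)
  expect_equal(cd$pi_s, 3)
  expect_equal(cd$pi_n, 0)
  # potential sites partition the 3 positions per codon
  expect_equal(cd$syn_sites + cd$nonsyn_sites, 3)

  for (s in 1:5) {
    clade <- simulate_codon_clade(6, 10, 0, 30, seed = 500 + s)
    expect_equal(pin_pis(clade$codon_aln)$pi_n, 0)
  }
})

test_that("piN/piS pathway counting handles multi-step codon pairs", {
  # TTT (Phe) vs GTA (Val): 2 paths; enumerate by hand
  #  TTT -> GTT (N) -> GTA (S of GTT? GTT=Val, GTA=Val: S)   => N=1, S=1
  #  TTT -> TTA (Leu, N) -> GTA (Val, N)                     => N=2, S=0
  # average: Nd = 1.5, Sd = 0.5
  pair <- new_alignment(c("a", "b"), c("TTT", "GTA"), "codon")
  cd <- pin_pis(pair)
  tot_diffs <- cd$pi_n * cd$nonsyn_sites + cd$pi_s * cd$syn_sites
  expect_equal(tot_diffs, 2)
  expect_equal(cd$pi_n * cd$nonsyn_sites, 1.5)
  expect_equal(cd$pi_s * cd$syn_sites, 0.5)
  # internal stop is an error; gap codons are skipped and counted
  bad <- new_alignment(c("a", "b"), c("TAAAAA", "TACAAA"), "codon")
  expect_error(pin_pis(bad), "internal stop")
  gapped <- new_alignment(c("a", "b"), c("TTT---", "TTCAAA"), "codon")
  cdg <- pin_pis(gapped)
  expect_equal(cdg$n_skipped_codon_pairs, 1L)
  expect_equal(cdg$pi_s, 3)
})

test_that("domain columns follow the majority vote and partition S", {
  aln <- make_aln(c("MKLVA", "MKIVA", "M-LVA"), ids = c("a", "b", "c"))
  iv <- data.frame(seq_id = c("a", "b", "c", "a", "b"),
                   domain = c("NBARC", "NBARC", "NBARC", "LRR", "LRR"),
                   start = c(1, 1, 1, 4, 4), end = c(3, 3, 2, 5, 4))
  dm <- domain_columns(aln, iv)
  # hand vote: cols 1-2 all NBARC; col 3 NBARC (a,b) vs none(c after its 2-res
  # NBARC) -> NBARC; col 4 LRR 2 vs none 1 -> LRR; col 5 LRR(a) none(b,c) tie? no:
  # a=LRR, b=none, c=none -> none wins 2-1
  expect_equal(dm$column_labels, c("NBARC", "NBARC", "NBARC", "LRR", "none"))
  expect_error(domain_columns(aln, data.frame(seq_id = "a", domain = "LRR",
                                              start = 1, end = 99)),
               "beyond")

  # concatenating domain subsets reproduces gene-wide S exactly
  clade <- simulate_codon_clade(6, 20, 0.8, 30, seed = 9)
  caln <- clade$codon_aln
  L <- caln$length
  iv2 <- data.frame(seq_id = rep(caln$ids, each = 2),
                    domain = rep(c("NBARC", "LRR"), aln_n(caln)),
                    start = rep(c(1, 31), aln_n(caln)),
                    end = rep(c(30, 60), aln_n(caln)))
  dm2 <- domain_columns(caln, iv2)
  s_total <- diversity_stats(caln)$S
  s_parts <- sum(vapply(dm2$columns, function(cols) {
    if (!length(cols)) return(0L)
    m <- aln_matrix(caln)[, cols, drop = FALSE]
    sub <- apply(m, 1, paste, collapse = "")
    diversity_stats(sub)$S
  }, integer(1)))
  expect_equal(s_parts, s_total)
})

test_that("sliding windows follow the 300/75 geometry and recompute per slice", {
  clade <- simulate_codon_clade(6, 25, 0.8, 100, seed = 13)
  aln <- clade$codon_aln  # 300 nt
  tr <- sliding_window_stats(aln, "acc_01", "pi")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$midpoint, 150L)

  clade2 <- simulate_codon_clade(6, 25, 0.8, 125, seed = 13)  # 375 nt
  tr2 <- sliding_window_stats(clade2$codon_aln, "acc_01", "pi")
  expect_equal(tr2$start, c(1L, 76L))

  for (L in c(300L, 450L, 601L, 1000L)) {
    clade_l <- simulate_codon_clade(4, 10, 0.5, ceiling(L / 3), seed = L)
    aln_l <- clade_l$codon_aln
    n_expected <- floor((aln_l$length - 300) / 75) + 1
    expect_equal(nrow(sliding_window_stats(aln_l, "acc_01", "pi")), n_expected)
  }

  # slice-recompute oracle
  m <- aln_matrix(aln)
  for (r in seq_len(nrow(tr))) {
    cols <- tr$start[r]:tr$end[r]  # no gaps in simulated alignments
    sub <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    expect_equal(tr$value[r], diversity_stats(sub, L = 300)$pi_per_site)
  }

  short <- simulate_codon_clade(4, 5, 0.5, 30, seed = 2)$codon_aln
  expect_warning(tr0 <- sliding_window_stats(short, "acc_01", "pi"), "shorter")
  expect_equal(nrow(tr0), 0L)
})

test_that("VCF-derived statistics agree with the alignment path", {
  h0 <- structure(list(mat = matrix(0L, 6, 0), positions = integer(0),
                       sample_ids = paste0("h", 1:6)),
                  class = "haplotype_matrix")
  d0 <- stats_from_vcf_gene(h0, cds_length = 900)
  expect_equal(d0$pi_per_site, 0)
  expect_true(is.na(d0$tajimas_d))

  # 1 SNP toy: 2 carriers of 6 -> pi_total = 2*4/15
  m <- matrix(0L, 6, 1)
  m[1:2, 1] <- 1L
  h1 <- structure(list(mat = m, positions = 5L, sample_ids = paste0("h", 1:6)),
                  class = "haplotype_matrix")
  expect_equal(stats_from_vcf_gene(h1, 100)$pi_total, 8 / 15)

  # dual path: simulate haplotypes, write VCF, read back, compare
  sim <- simulate_genealogy_haplotypes(8, 5, 400, seed = 77)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_from_haplotypes(sim, f)
  back <- read_vcf_region(f, "Chr1", 1, 400)
  da <- diversity_stats(sim, L = 400)
  db <- stats_from_vcf_gene(back, 400)
  expect_equal(db$pi_per_site, da$pi_per_site)
  expect_equal(db$S, da$S)
  expect_equal(db$tajimas_d, da$tajimas_d)
})

test_that("empirical tails use interpolated quantiles with strict membership", {
  bg <- 1:100
  fl <- empirical_tail_flags(c(g1 = 99, g2 = 50), bg, "top5")
  expect_true(fl$flags[["g1"]])
  expect_false(fl$flags[["g2"]])
  thr <- unname(quantile(bg, 0.95, type = 7))
  expect_equal(fl$threshold, thr)
  expect_false(empirical_tail_flags(c(g = thr), bg, "top5")$flags[["g"]])

  expect_error(empirical_tail_flags(c(g = 1), numeric(0)), "empty")

  # joint criterion: exactly one gene in both tails
  set.seed(3)
  pis <- runif(500)
  ds <- runif(500)
  genes_pi <- c(a = 0.999, b = 0.999, c = 0.2)
  genes_d <- c(a = 0.998, b = 0.1, c = 0.997)
  out <- balancing_selection_flags(genes_pi, genes_d, pis, ds)
  brute <- (genes_pi > quantile(pis, .95, type = 7)) &
    (genes_d > quantile(ds, .95, type = 7))
  expect_equal(out$flags, brute)
  expect_equal(sum(out$flags), 1L)
})
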