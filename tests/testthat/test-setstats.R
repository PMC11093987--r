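test_that("rank set score spans [0, 1] and follows the normalization formula", {
  v <- stats::setNames(c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10), paste0("g", 1:10))
  top <- names(sort(v, decreasing = TRUE))[1:3]
  bot <- names(sort(v))[1:3]
  expect_equal(rank_set_score(v, top)$normalized_score, 1)
  expect_equal(rank_set_score(v, bot)$normalized_score, 0)
  # n = 10, m = 2, member ranks {3, 7}: (5 - 1.5) / (9.5 - 1.5)
  set2 <- names(v)[rank(v) %in% c(3, 7)]
  expect_equal(rank_set_score(v, set2)$normalized_score, 3.5 / 8)
  expect_error(rank_set_score(v, c("g1", "zz")), "zz")
  # invariant to monotone transformation of the values
  expect_equal(rank_set_score(exp(v), set2)$normalized_score,
               rank_set_score(v, set2)$normalized_score)
})

test_that("rank-score permutation p-values hit the add-one floor for a top set", {
  set.seed(1)
  v <- stats::setNames(rnorm(50), paste0("g", 1:50))
  top <- names(sort(v, decreasing = TRUE))[1:5]
  r <- perm_pvalue_set_score(v, top, R = 999, seed = 3)
  expect_equal(r$p_addone, 1 / 1000)
  r2 <- perm_pvalue_set_score(v, top, R = 999, seed = 3)
  expect_identical(r$p_raw, r2$p_raw)
  expect_identical(r$null_mean, r2$null_mean)
})

test_that("permutation difference test handles constants, power, determinism", {
  v <- stats::setNames(rep(4, 60), paste0("g", 1:60))
  r <- perm_diff_test(v, paste0("g", 1:10), paste0("g", 11:60), R = 500, seed = 2)
  expect_equal(r$observed, 0)
  expect_equal(r$p_raw, 1)

  set.seed(8)
  bg <- stats::setNames(rnorm(300), paste0("b", 1:300))
  shifted <- stats::setNames(rnorm(30, mean = 3), paste0("s", 1:30))
  rp <- perm_diff_test(c(shifted, bg), names(shifted), names(bg),
                       R = 10000, seed = 4, direction = "greater")
  expect_lte(rp$p_addone, 0.001)
  expect_equal(rp$p_addone, (rp$p_raw * rp$R + 1) / (rp$R + 1))

  rp2 <- perm_diff_test(c(shifted, bg), names(shifted), names(bg),
                        R = 10000, seed = 4, direction = "greater")
  expect_identical(rp$p_raw, rp2$p_raw)
  expect_error(perm_diff_test(v, paste0("g", 1:2), paste0("g", 3:60)), "at least 3")
})

test_that("matched test with one bin reduces exactly to the plain test", {
  set.seed(10)
  v <- stats::setNames(rnorm(80), paste0("g", 1:80))
  cv <- stats::setNames(runif(80), names(v))
  sid <- paste0("g", 1:15)
  bid <- paste0("g", 16:80)
  plain <- perm_diff_test(v, sid, bid, R = 800, seed = 6)
  one_bin <- matched_perm_diff_test(v, sid, bid, cv, n_bins = 1, R = 800, seed = 6)
  expect_identical(plain$p_raw, one_bin$p_raw)
  expect_identical(plain$null_mean, one_bin$null_mean)
})

test_that("matched null draws are restricted to the set's covariate bins", {
  # all set genes in the top covariate bin; their feature values and those of
  # the same-bin background are constant, so every stratified null relabeling
  # reproduces the observed statistic exactly (p_raw = 1). Unrestricted
  # sampling would mix in the wildly different values from the other bins.
  cv <- stats::setNames(c(rep(100, 20), rep(0, 80)), paste0("g", 1:100))
  v <- stats::setNames(c(rep(5, 20), rep(1000, 80)), names(cv))
  sid <- paste0("g", 1:10)
  bid <- paste0("g", 11:100)
  r <- matched_perm_diff_test(v, sid, bid, cv, n_bins = 5, R = 300, seed = 9,
                              direction = "greater")
  expect_equal(r$p_raw, 1)
  # a set bin left without background candidates (here: after NA dropping)
  # is an error naming the bin
  cv3 <- stats::setNames(c(rep(95, 10), 1:90), paste0("g", 1:100))
  v3 <- stats::setNames(rnorm(100), names(cv3))
  v3[cv3 > 45 & !names(v3) %in% paste0("g", 1:10)] <- NA
  expect_error(matched_perm_diff_test(v3, paste0("g", 1:10), paste0("g", 11:100),
                                      cv3, n_bins = 2, R = 100, seed = 1),
               "no background")
})

test_that("matched test absorbs a constructed covariate confounder", {
  set.seed(99)
  n <- 300
  cv <- stats::setNames(runif(n), paste0("g", 1:n))
  # feature is a deterministic step function of the covariate decile
  feat <- as.numeric(cut(cv, stats::quantile(cv, seq(0, 1, 0.1)),
                         include.lowest = TRUE))
  names(feat) <- names(cv)
  sid <- sample(names(cv)[cv > 0.5], 30)
  bid <- setdiff(names(cv), sid)
  naive <- perm_diff_test(feat, sid, bid, R = 2000, seed = 5, direction = "greater")
  matched <- matched_perm_diff_test(feat, sid, bid, cv, n_bins = 10, R = 2000,
                                    seed = 5, direction = "greater")
  expect_lte(naive$p_addone, 0.01)
  expect_gte(matched$p_addone, 0.05)
})

test_that("tail-count test matches a brute-force scan and its expectation", {
  bg <- stats::setNames(as.numeric(1:1000), paste0("b", 1:1000))
  sv <- stats::setNames(c(999.5, 998.5, 500, 200, 10.2), paste0("s", 1:5))
  r <- tail_count_test(c(bg, sv), names(sv), names(bg), tail = "top5",
                       R = 500, seed = 11)
  thr <- unname(stats::quantile(bg, 0.95, type = 7))
  expect_equal(r$observed, sum(sv > thr))
  expect_equal(r$expected_count, 5 * 0.05)

  all_in <- stats::setNames(rep(1000.5, 20), paste0("t", 1:20))
  r2 <- tail_count_test(c(bg, all_in), names(all_in), names(bg), tail = "top5",
                        R = 999, seed = 12)
  expect_equal(r2$p_addone, 1 / 1000)

  set.seed(13)
  rand_set <- sample(names(bg), 20)
  r3 <- tail_count_test(bg, rand_set, setdiff(names(bg), rand_set),
                        tail = "top5", R = 2000, seed = 14)
  expect_equal(r3$null_mean, 20 * 0.05, tolerance = 0.15)
})

test_that("wilcoxon wrapper is exact on small tie-free samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2)), 1)
  # enumeration oracle for a 2 + 3 case: all C(5,2) splits of the ranks
  x <- c(1, 5)
  y <- c(2, 3, 4)
  splits <- utils::combn(5, 2)
  w_all <- apply(splits, 2, function(ix) sum(ix) - 3)  # rank-sum - m(m+1)/2
  w_obs <- sum(rank(c(x, y))[1:2]) - 3
  p_enum <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  expect_equal(wilcoxon_rank_sum(x, y), min(1, p_enum))
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("kruskal-wallis wrapper matches a hand-ranked toy", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r <- kruskal_wallis(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # groups (1,2), (3,4), (5,6): H = 12/(6*7) * sum n_i (Ri - 3.5)^2 = 32/7
  toy <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(toy$statistic, 12 / 42 * (2 * 4 + 0 + 2 * 4))
  # 2-group case agrees in direction with the rank-sum test
  set.seed(4)
  a <- rnorm(12)
  b <- rnorm(12, 2)
  expect_lt(kruskal_wallis(list(a, b))$p_value, 0.05)
  expect_lt(wilcoxon_rank_sum(a, b), 0.05)
  expect_error(kruskal_wallis(list(1, c(1, 2))), "at least 2 values")
})

test_that("fisher wrapper matches the hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  t1 <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_exact_2x2(t1), fisher_exact_2x2(t(t1)))
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 2, 2), 2)), "non-negative")
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(21)
  p <- runif(40)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
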