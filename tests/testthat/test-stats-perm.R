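test_that("permutation test is exact on enumerable cases", {
  # identical multisets: every permutation ties
  r <- permutation_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1)
  expect_true(r$exhaustive)
  # brute-force enumeration oracle over all C(6,3) = 20 splits, written
  # independently of the implementation (bitmask loop)
  x <- c(1, 2, 3); y <- c(101, 102, 103)
  pooled <- c(x, y)
  obs <- mean(x) - mean(y)
  count <- 0L; total <- 0L
  for (mask in 0:63) {
    sel <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (sum(sel) != 3L) next
    total <- total + 1L
    tstar <- mean(pooled[sel]) - mean(pooled[!sel])
    if (abs(tstar) >= abs(obs) - 1e-12) count <- count + 1L
  }
  expect_equal(total, 20L)
  r2 <- permutation_test(x, y)
  expect_equal(r2$p, count / total)
  expect_equal(r2$p, 0.1)
  # degenerate samples: p = 1 with a note, not an error
  r3 <- permutation_test(c(5, 5), c(5, 5, 5))
  expect_equal(r3$p, 1)
  expect_match(r3$note, "degenerate")
  expect_error(permutation_test(1, c(1, 2)), ">= 2")
})

test_that("sampled p-values converge to the exhaustive values", {
  set.seed(11)
  x <- rnorm(8); y <- rnorm(9) + 0.8
  exact <- permutation_test(x, y, n_perm = 1e5)     # C(17,8) = 24310: exhaustive
  expect_true(exact$exhaustive)
  sampled <- permutation_test(x, y, n_perm = 1600, seed = 2)
  expect_false(sampled$exhaustive)
  se <- sqrt(exact$p * (1 - exact$p) / 1600)
  expect_lt(abs(sampled$p - exact$p), 3 * se + 1 / 1600)
  # determinism under fixed seed
  expect_identical(permutation_test(x, y, seed = 7)$p,
                   permutation_test(x, y, seed = 7)$p)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(0.03), 0.03)                  # single p unchanged
  # q_i = p_i * 4 / i, monotonized from the top: all become 0.04
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))    # equal ps unchanged
  # hand example with a cap and reordering
  p <- c(0.9, 0.01, 0.04)
  # sorted: 0.01*3/1 = 0.03, 0.04*3/2 = 0.06, 0.9*3/3 = 0.9
  expect_equal(bh_fdr(p), c(0.9, 0.03, 0.06))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # properties: pointwise >= input, idempotent, monotone in added values
  set.seed(3)
  ps <- runif(12)
  q <- bh_fdr(ps)
  expect_true(all(q >= ps))
  # order preservation on sorted inputs
  expect_false(is.unsorted(bh_fdr(sort(ps))))
  q2 <- bh_fdr(c(ps, 0.999))
  expect_true(all(q2[1:12] >= q))
})

test_that("compare_periods respects symmetry and determinism", {
  set.seed(5)
  tab <- expand.grid(recording = paste0("r", 1:6),
                     period = c("pre", "mti", "post"),
                     feature = c("a", "b"), stringsAsFactors = FALSE)
  tab$value <- rnorm(nrow(tab))
  tab$value[tab$period == "mti" & tab$feature == "a"] <-
    tab$value[tab$period == "mti" & tab$feature == "a"] + 3
  res1 <- compare_periods(tab, seed = 9)
  res2 <- compare_periods(tab, seed = 9)
  expect_identical(res1, res2)
  # label swap pre <-> post: p invariant, sign of change flips
  tab_sw <- tab
  tab_sw$period <- c(post = "pre", mti = "mti", pre = "post")[tab$period]
  res_sw <- compare_periods(tab_sw, seed = 9)
  i1 <- res1$feature == "a" & res1$pair == "post-pre"
  i2 <- res_sw$feature == "a" & res_sw$pair == "post-pre"
  expect_equal(res_sw$mean_change[i2], -res1$mean_change[i1])
  expect_equal(res_sw$p[i2], res1$p[i1])
  # the injected effect is found where it was injected
  expect_true(res1$significant[res1$feature == "a" & res1$pair == "mti-pre"])
  # FDR groups attach adjusted values only inside the group
  resf <- compare_periods(tab, seed = 9, fdr_groups = list(g = c("a", "b")))
  expect_true(all(!is.na(resf$p_adjusted)))
  expect_true(all(resf$p_adjusted >= resf$p))
})

test_that("per-comparison seeds are order-independent", {
  set.seed(8)
  tab <- expand.grid(recording = paste0("r", 1:8),
                     period = c("pre", "mti"),
                     feature = c("f1", "f2"), stringsAsFactors = FALSE)
  tab$value <- rnorm(nrow(tab))
  full <- compare_periods(tab, pairs = list(c("mti", "pre")), seed = 4)
  only2 <- compare_periods(tab[tab$feature == "f2", ],
                           pairs = list(c("mti", "pre")), seed = 4)
  expect_equal(full$p[full$feature == "f2"], only2$p)
})
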