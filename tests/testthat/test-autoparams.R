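mat_from_upper <- function(vals, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- vals
  m + t(m)
}

test_that("corr_cut is the tight 5 percent upper-tail rank statistic", {
  # 100 distinct upper-triangle values 1..100 -> cut 95 (5 values above)
  n <- 15 # choose(15,2) = 105; use first 100 then pad with low values
  vals <- c(1:100, rep(0.5, 5))
  corr <- mat_from_upper(vals, n)
  expect_equal(corr_cut(corr), 95)

  # 20 distinct values -> 19th smallest (1 value above = 5 %)
  n2 <- 8 # choose(8,2) = 28 -> use 20 distinct + 8 repeats of the smallest
  vals2 <- c(seq(10, 200, by = 10), rep(10, 8))
  corr2 <- mat_from_upper(vals2, n2)
  expect_equal(corr_cut(corr2), 190)

  # constant matrix returns the constant with a warning
  expect_warning(cc <- corr_cut(mat_from_upper(rep(2, 3), 3)), "constant")
  expect_equal(cc, 2)

  # tightness property on random matrices
  set.seed(11)
  for (i in 1:20) {
    m <- mat_from_upper(runif(choose(10, 2)), 10)
    cut <- corr_cut(m)
    v <- m[upper.tri(m)]
    expect_lte(mean(v > cut), 0.05)
    below <- sort(unique(v))
    prev <- rev(below[below < cut])[1]
    if (!is.na(prev)) expect_gt(mean(v > prev), 0.05)
  }
})

test_that("MCP literally divides the neighbour sum by eight", {
  v <- 1.6
  cp <- matrix(v, 12, 12)
  diag(cp) <- 0
  mcp <- mcp_profile(cp)
  expect_equal(mcp[6], v) # interior: 8 neighbours
  expect_equal(mcp[1], v / 2) # terminus: 4 neighbours, still divided by 8
})

test_that("cp_cut places the threshold at the p_ss quantile of the MCP", {
  # constructed CP matrix whose MCP profile is exactly {1, 2, 3, 4}
  cp <- matrix(0, 4, 4)
  cp[1, 3] <- 2
  cp[1, 4] <- 6
  cp[2, 3] <- 6
  cp[2, 4] <- 10
  cp[3, 4] <- 16
  cp <- cp + t(cp)
  expect_equal(suppressWarnings(mcp_profile(cp)), c(1, 2, 3, 4))
  ss_stable <- data.frame(
    p_alpha = c(1, 1, 0, 0), p_beta = 0, p_turn = 0,
    type = c("alpha", "alpha", "other", "other")
  )
  got <- suppressWarnings(cp_cut(cp, ss_stable))
  expect_equal(got$p_ss, 0.5)
  expect_equal(got$cp_cut, 3) # two of four MCP values lie below 3

  # p_ss = 0: cp_cut falls back to min(MCP) with a warning
  cp12 <- matrix(1.6, 12, 12)
  diag(cp12) <- 0
  ss_none <- data.frame(p_alpha = rep(0, 12), p_beta = 0, p_turn = 0)
  expect_warning(got0 <- cp_cut(cp12, ss_none), "cp_cut set to min")
  expect_equal(got0$cp_cut, 0.8) # terminal MCP: 4 neighbour terms over 8
})

test_that("int_cut keeps the largest cutoff preserving the maximal component", {
  # chain of 6 residues, one bridge edge at 0.60: LCC maximal through 0.60
  n <- 6
  int <- matrix(0, n, n)
  for (i in 1:5) int[i, i + 1] <- 0.9
  int[3, 4] <- 0.60
  int <- pmax(int, t(int))
  got <- int_cut(int)
  expect_equal(got$int_cut, 0.60)
  expect_equal(got$curve$lcc[got$curve$cutoff <= 0.60], rep(6L, 8))

  # all strengths 1: plateau over the whole grid
  all1 <- matrix(1, 4, 4)
  diag(all1) <- 0
  expect_equal(int_cut(all1)$int_cut, 1.00)

  # degenerate all-zero matrix
  expect_warning(gz <- int_cut(matrix(0, 4, 4)), "degenerate")
  expect_equal(gz$int_cut, 1.00)

  # LCC(c) is non-increasing in c on random matrices
  set.seed(12)
  for (i in 1:10) {
    m <- mat_from_upper(runif(choose(9, 2)), 9)
    lcc <- int_cut(m)$curve$lcc
    expect_true(all(diff(lcc) <= 0))
  }
})

test_that("mpl_cut maximises the reduction of the largest component", {
  # designed curve: LCC {4:10, 5:10, 6:4, 7:4, 8:4} -> largest drop at 6
  edges <- rbind(
    data.frame(i = 1:9, j = 2:10, max_path_len = 5L),
    data.frame(i = 1:3, j = 2:4, max_path_len = 8L)
  )
  got <- mpl_cut(edges, n_nodes = 10)
  expect_equal(got$mpl_cut, 6L)
  expect_equal(got$curve$lcc, c(10L, 10L, 4L, 4L, 4L))

  # equal reductions everywhere: tie resolved to the smallest n
  e2 <- data.frame(i = 1:4, j = 2:5, max_path_len = 4:7)
  got2 <- mpl_cut(e2, n_nodes = 6)
  expect_true(all(-diff(got2$curve$lcc) == 1))
  expect_equal(got2$mpl_cut, 5L)

  # constant curve: smallest n with a zero-reduction warning
  e3 <- data.frame(i = 1:3, j = 2:4, max_path_len = 30L)
  expect_warning(got3 <- mpl_cut(e3, n_nodes = 5), "zero-reduction")
  expect_equal(got3$mpl_cut, 5L)

  expect_error(
    mpl_cut(data.frame(i = integer(0), j = integer(0), max_path_len = integer(0)), 5),
    "undefined-threshold"
  )
})

test_that("threshold tuning is deterministic", {
  set.seed(13)
  corr <- mat_from_upper(runif(choose(12, 2)), 12)
  cp <- mat_from_upper(runif(choose(12, 2), 0, 3), 12)
  int <- mat_from_upper(runif(choose(12, 2)), 12)
  ss <- data.frame(
    p_alpha = rep(c(1, 0), 6), p_beta = 0, p_turn = 0,
    type = rep(c("alpha", "other"), 6)
  )
  p1 <- tune_parameters(corr, cp, int, ss)
  p2 <- tune_parameters(corr, cp, int, ss)
  expect_identical(p1$corr_cut, p2$corr_cut)
  expect_identical(p1$cp_cut, p2$cp_cut)
  expect_identical(p1$int_cut, p2$int_cut)
})
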