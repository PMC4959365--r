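test_that("mode counting follows the cumulative variance rule", {
  expect_equal(modes_needed(c(4, 1), 0.8), 1) # 4/5 = 0.8, inclusive
  expect_equal(modes_needed(rep(1, 30), 0.8), 24) # 24/30 = 0.8
  expect_equal(modes_needed(c(10, 0, 0), 0.8), 1)
  expect_error(modes_needed(c(0, 0), 0.8), "zero total variance")

  # ensemble moving along a single direction: rank-1 covariance
  base <- matrix(rnorm(12), 4, 3)
  dir <- matrix(rnorm(12), 4, 3)
  frames <- lapply(seq(-1, 1, length.out = 9), function(a) base + a * dir)
  ens <- ca_ensemble_from_coords(frames)
  modes <- suppressWarnings(compute_pca_modes(ens))
  expect_equal(modes$n, 1)
  expect_equal(modes$variance_fraction_explained, 1.0, tolerance = 1e-10)
})

test_that("LFA correlations match Eq.-style closed forms and a naive loop", {
  # complete orthonormal mode set: Corr = 3 * identity
  set.seed(5)
  base <- matrix(rnorm(18), 6, 3)
  frames <- lapply(1:40, function(i) base + matrix(rnorm(18, sd = 0.3), 6, 3))
  ens <- superpose(ca_ensemble_from_coords(frames))
  modes <- suppressWarnings(compute_pca_modes(ens, n_modes = 18))
  corr <- compute_lfa_correlations(modes)
  expect_equal(unclass(corr), 3 * diag(6), tolerance = 1e-8, ignore_attr = TRUE)

  # single uniform mode: all entries equal 1/N
  nres <- 5
  uni <- list(
    vectors = matrix(1 / sqrt(3 * nres), 3 * nres, 1),
    values = 1, n = 1L, n_residues = nres,
    variance_fraction_explained = 1
  )
  class(uni) <- "commap_modes"
  expect_equal(unclass(compute_lfa_correlations(uni)),
    matrix(1 / nres, nres, nres),
    tolerance = 1e-12, ignore_attr = TRUE
  )

  # arbitrary orthonormal modes equal the brute-force triple loop
  set.seed(6)
  v <- random_orthonormal(3 * 7, 4)
  md <- structure(
    list(
      vectors = v, values = rep(1, 4), n = 4L, n_residues = 7,
      variance_fraction_explained = 0.9
    ),
    class = "commap_modes"
  )
  expect_equal(unclass(compute_lfa_correlations(md)), brute_lfa(v, 7),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("LFA self-correlations are bounded by the mode-set completeness", {
  set.seed(7)
  for (k in c(2, 9, 15)) {
    v <- random_orthonormal(3 * 5, k)
    md <- structure(
      list(
        vectors = v, values = rep(1, k), n = k, n_residues = 5,
        variance_fraction_explained = 1
      ),
      class = "commap_modes"
    )
    d <- diag(compute_lfa_correlations(md))
    expect_true(all(d >= -1e-10 & d <= 3 + 1e-10))
  }
  v <- random_orthonormal(15, 15)
  md <- structure(
    list(
      vectors = v, values = rep(1, 15), n = 15L, n_residues = 5,
      variance_fraction_explained = 1
    ),
    class = "commap_modes"
  )
  expect_equal(diag(compute_lfa_correlations(md)), rep(3, 5), tolerance = 1e-10)
})

test_that("seed pruning keeps the more fluctuating of close seeds", {
  rmsf <- rep(1, 20)
  rmsf[10] <- 2.0
  rmsf[13] <- 1.0
  got <- prune_seeds(c(10, 13), rmsf)
  expect_equal(got$res_index, 10) # separation 3 < 6: keep higher RMSF

  got2 <- prune_seeds(c(10, 16), rmsf)
  expect_equal(got2$res_index, c(10, 16)) # separation 6 is allowed

  got3 <- prune_seeds(7, rmsf)
  expect_equal(got3$res_index, 7)

  # pruned sets always respect the pairwise separation invariant
  set.seed(8)
  for (i in 1:20) {
    cand <- sample(60, 15)
    r <- runif(60)
    kept <- prune_seeds(cand, r)$res_index
    if (length(kept) > 1) expect_true(min(diff(sort(kept))) >= 6)
  }
})

test_that("minimum distances average the per-frame atom-pair minima", {
  # two single-atom residues 5 A apart in every frame
  m <- rbind(c(0, 0, 0), c(5, 0, 0))
  ens <- ca_ensemble_from_coords(list(m, m))
  d <- compute_min_distances(ens)
  expect_equal(d[1, 2], 5.0)
  expect_equal(diag(d), rep(0, 2))

  # per-frame minima {3, 5} average to 4
  m2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  ens2 <- ca_ensemble_from_coords(list(m, m2))
  expect_equal(compute_min_distances(ens2)[1, 2], 4.0)

  # multi-atom residues against the naive loop oracle
  set.seed(9)
  atoms <- data.frame(
    eleno = 1:7, elety = c("CA", "CB", "CA", "CB", "CG", "CA", "CB"),
    resid = "ALA", chain = "A",
    resno = c(1, 1, 2, 2, 2, 3, 3), insert = "", stringsAsFactors = FALSE
  )
  frames <- lapply(1:4, function(i) matrix(rnorm(21, sd = 3), 7, 3))
  ens3 <- atom_ensemble(atoms, frames)
  expect_equal(unclass(compute_min_distances(ens3)), brute_min_dist(ens3),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("communication propensity is the population variance of CA distances", {
  m <- rbind(c(0, 0, 0), c(3, 0, 0))
  ens_same <- ca_ensemble_from_coords(list(m, m, m))
  expect_equal(unclass(compute_communication_propensity(ens_same)),
    matrix(0, 2, 2),
    ignore_attr = TRUE
  )

  # distances alternating {3, 5, 3, 5}: population variance 1.0
  m5 <- rbind(c(0, 0, 0), c(5, 0, 0))
  ens_alt <- ca_ensemble_from_coords(list(m, m5, m, m5))
  expect_equal(compute_communication_propensity(ens_alt)[1, 2], 1.0)

  set.seed(10)
  frames <- lapply(1:15, function(i) matrix(rnorm(18, sd = 2), 6, 3))
  ens_rnd <- ca_ensemble_from_coords(frames)
  got <- compute_communication_propensity(ens_rnd)
  ref <- brute_cp(ens_rnd)
  expect_lt(max(abs(got - ref)) / max(ref), 1e-10)
})

test_that("interaction strengths count frames with at least one contact", {
  # two apolar single-atom residues: in contact (3 A) in 3 of 10 frames
  near <- rbind(c(0, 0, 0), c(3, 0, 0))
  far <- rbind(c(0, 0, 0), c(10, 0, 0))
  atoms <- data.frame(
    eleno = 1:2, elety = c("CB", "CB"), resid = "ALA", chain = "A",
    resno = 1:2, insert = "", stringsAsFactors = FALSE
  )
  frames <- c(replicate(3, near, simplify = FALSE), replicate(7, far, simplify = FALSE))
  ens <- atom_ensemble(atoms, frames)
  expect_equal(compute_interaction_strengths(ens)[1, 2], 0.3)
  expect_equal(compute_interaction_strengths(atom_ensemble(atoms, replicate(4, near,
    simplify = FALSE
  )))[1, 2], 1.0)

  # two distinct atom pairs active in disjoint halves: union gives 1.0
  atoms2 <- data.frame(
    eleno = 1:4, elety = c("CB", "CG", "CB", "CG"), resid = "ALA",
    chain = "A", resno = c(1, 1, 2, 2), insert = "", stringsAsFactors = FALSE
  )
  fa <- rbind(c(0, 0, 0), c(0, 20, 0), c(3, 0, 0), c(40, 20, 0)) # CB1-CB2 close
  fb <- rbind(c(0, 0, 0), c(0, 20, 0), c(40, 0, 0), c(3, 20, 0)) # CG1-CG2 close
  ens2 <- atom_ensemble(atoms2, c(
    replicate(5, fa, simplify = FALSE),
    replicate(5, fb, simplify = FALSE)
  ))
  expect_equal(compute_interaction_strengths(ens2)[1, 2], 1.0)

  # adding a duplicate frame moves INT by at most 1/F
  before <- compute_interaction_strengths(ens)[1, 2]
  ens_dup <- atom_ensemble(atoms, c(frames, frames[1]))
  after <- compute_interaction_strengths(ens_dup)[1, 2]
  expect_lte(abs(after - before), 1 / 10)
})
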