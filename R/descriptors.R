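# Residue-based dynamic descriptors: principal component modes of the
# C-alpha fluctuations, local-feature-analysis (LFA) correlations, seed
# residues, inter-residue minimum distances and communication propensities.

#' Number of modes needed to reach a cumulative variance fraction
#'
#' @param values eigenvalues, non-increasing.
#' @param fraction target cumulative fraction (inclusive).
#' @return smallest mode count whose cumulative eigenvalue fraction reaches
#'   `fraction`.
#' @export
modes_needed <- function(values, fraction) {
  vals <- pmax(values, 0)
  tot <- sum(vals)
  if (tot <= 0) stop("degenerate-covariance error: zero total variance")
  cs <- cumsum(vals) / tot
  which(cs >= fraction - 1e-12)[1]
}

#' Principal component modes of the C-alpha coordinate covariance
#'
#' Eigendecomposition of the covariance of the C-alpha coordinates of a
#' superposed ensemble.  The number of retained modes `n` is the smallest
#' count explaining at least `target_fraction` of the total atomic
#' fluctuations.
#'
#' @param ens a superposed `commap_ensemble`.
#' @param target_fraction fraction of total variance the retained modes must
#'   explain (default 0.8).
#' @param n_modes optional override of the retained mode count.
#' @return `commap_modes`: list with `vectors` (3N x n orthonormal
#'   eigenvectors, coordinate order x1,y1,z1,x2,...), `values` (all 3N
#'   eigenvalues, Angstrom^2, non-increasing), `n` and
#'   `variance_fraction_explained`.
#' @export
compute_pca_modes <- function(ens, target_fraction = 0.8, n_modes = NULL) {
  stopifnot(inherits(ens, "commap_ensemble"))
  inds <- atom2xyz_inds(ca_atoms(ens$top))
  x <- ens$xyz[, inds, drop = FALSE]
  nres <- length(inds) / 3L
  if (nrow(x) <= ncol(x)) {
    warning(
      "only ", nrow(x), " frames for ", ncol(x), " degrees of freedom; ",
      "the covariance is rank-deficient and the modes may be poorly sampled"
    )
  }
  cv <- stats::cov(x)
  e <- eigen(cv, symmetric = TRUE)
  tot <- sum(pmax(e$values, 0))
  if (tot < 1e-10) {
    stop("degenerate-covariance error: the ensemble shows no atomic fluctuation")
  }
  n <- if (is.null(n_modes)) {
    modes_needed(e$values, target_fraction)
  } else {
    as.integer(n_modes)
  }
  structure(
    list(
      vectors = e$vectors[, seq_len(n), drop = FALSE],
      values = e$values,
      n = n,
      variance_fraction_explained = sum(pmax(e$values[seq_len(n)], 0)) / tot,
      n_residues = nres
    ),
    class = "commap_modes"
  )
}

#' Local feature analysis correlation matrix
#'
#' `Corr(i, j)` is the sum over the three coordinate components and over the
#' retained modes of the products of eigenvector loadings of residues i and j.
#' With a complete orthonormal mode set the matrix equals three times the
#' identity; restricting to the essential modes leaves the sparse residual
#' correlation patterns that delimit regions of concerted motion.
#'
#' @param modes a `commap_modes`.
#' @return symmetric N x N matrix of class `commap_corr`.
#' @export
compute_lfa_correlations <- function(modes) {
  stopifnot(inherits(modes, "commap_modes"))
  v <- modes$vectors
  nres <- modes$n_residues
  out <- matrix(0, nres, nres)
  for (d in 1:3) {
    vd <- v[seq(d, 3L * nres, by = 3L), , drop = FALSE]
    out <- out + tcrossprod(vd)
  }
  structure((out + t(out)) / 2, class = c("commap_corr", "matrix"))
}

#' Greedy LFA seed candidates
#'
#' Standard LFA sparsification of the correlation output: the first seed is
#' the residue with the largest output variance `Corr(i, i)`; each following
#' seed maximises the residual variance left after linear reconstruction of
#' its output from the current seed set (Schur complement on the correlation
#' matrix).
#'
#' @param corr LFA correlation matrix.
#' @param n number of seeds requested (capped at N).
#' @return integer vector of residue indices, in selection order.
#' @export
lfa_seed_candidates <- function(corr, n) {
  nres <- nrow(corr)
  n <- min(n, nres)
  seeds <- integer(0)
  resid_var <- diag(corr)
  for (k in seq_len(n)) {
    cand <- setdiff(seq_len(nres), seeds)
    pick <- cand[which.max(resid_var[cand])]
    if (resid_var[pick] <= 1e-10) break
    seeds <- c(seeds, pick)
    cmm <- corr[seeds, seeds, drop = FALSE]
    # ridge keeps the solve well posed when seed outputs are collinear
    inv <- solve(cmm + diag(1e-10, length(seeds)))
    rec <- corr[, seeds, drop = FALSE] %*% inv
    resid_var <- diag(corr) - rowSums(rec * corr[, seeds, drop = FALSE])
  }
  seeds
}

#' Prune seeds closer than a minimum sequence separation
#'
#' When two seeds lie fewer than `min_separation` residues apart in the same
#' chain, only the one with the highest fluctuation is retained.
#'
#' @param candidates integer residue indices.
#' @param rmsf per-residue fluctuation score (C-alpha RMSF, Angstrom).
#' @param residues residue table (for chain assignment); `NULL` treats all
#'   residues as one chain.
#' @param min_separation minimum allowed sequence separation (default 6).
#' @return data.frame with columns `res_index` and `rmsf`, sorted by index.
#' @export
prune_seeds <- function(candidates, rmsf, residues = NULL, min_separation = 6) {
  if (!length(candidates)) {
    return(data.frame(res_index = integer(0), rmsf = numeric(0)))
  }
  chain <- if (is.null(residues)) rep("A", max(candidates)) else residues$chain
  ord <- candidates[order(-rmsf[candidates], candidates)]
  kept <- integer(0)
  for (s in ord) {
    close <- any(
      chain[kept] == chain[s] & abs(kept - s) < min_separation
    )
    if (!isTRUE(close)) kept <- c(kept, s)
  }
  kept <- sort(kept)
  data.frame(res_index = kept, rmsf = rmsf[kept])
}

#' Select seed residues from the LFA correlations
#'
#' Combines greedy LFA sparsification (up to `n` = number of retained modes
#' seeds) with the sequence-separation pruning rule.
#'
#' @param modes `commap_modes`.
#' @param corr LFA correlation matrix.
#' @param ens the superposed ensemble (for the RMSF fluctuation score).
#' @param min_separation minimum sequence separation between seeds.
#' @return data.frame of class `commap_seeds` with `res_index` and `rmsf`.
#' @export
select_seeds <- function(modes, corr, ens, min_separation = 6) {
  cand <- lfa_seed_candidates(corr, modes$n)
  rmsf <- ca_rmsf(ens)
  out <- prune_seeds(cand, rmsf,
    residues = ens$top$residues,
    min_separation = min_separation
  )
  class(out) <- c("commap_seeds", "data.frame")
  out
}

# Frame-wise minimum over atom pairs of two residue groups, reduced with pmin.
.group_min_rows <- function(d, idx_list) {
  t(vapply(
    idx_list,
    function(ix) {
      if (length(ix) == 1L) d[ix, ] else do.call(pmin, asplit(d[ix, , drop = FALSE], 1))
    },
    numeric(ncol(d))
  ))
}

#' Inter-residue minimum distance matrix
#'
#' For every residue pair, the smallest distance between any pair of atoms of
#' the two residues, computed per frame and averaged over the set of
#' conformations.
#'
#' @param ens a `commap_ensemble`.
#' @return symmetric N x N matrix (Angstrom), zero diagonal, class
#'   `commap_dist`.
#' @export
compute_min_distances <- function(ens) {
  stopifnot(inherits(ens, "commap_ensemble"))
  top <- ens$top
  nres <- n_residues(ens)
  idx <- split(seq_len(nrow(top$atoms)), top$atoms$res_index)
  single <- all(lengths(idx) == 1L)
  acc <- matrix(0, nres, nres)
  for (f in seq_len(n_frames(ens))) {
    d <- frame_dist(xyz2mat(ens$xyz[f, ]))
    if (single) {
      acc <- acc + d
    } else {
      tmp <- .group_min_rows(d, idx) # nres x natom
      acc <- acc + t(.group_min_rows(t(tmp), idx))
    }
  }
  out <- acc / n_frames(ens)
  diag(out) <- 0
  dimnames(out) <- NULL
  structure((out + t(out)) / 2, class = c("commap_dist", "matrix"))
}

#' Communication propensity matrix
#'
#' `CP(i, j)` is the variance over the ensemble (population variance, divide
#' by the number of frames) of the distance between the C-alpha atoms of
#' residues i and j.  Small values indicate efficient signal transmission.
#'
#' @param ens a `commap_ensemble`.
#' @return symmetric N x N matrix (Angstrom^2), zero diagonal, class
#'   `commap_cp`.
#' @export
compute_communication_propensity <- function(ens) {
  stopifnot(inherits(ens, "commap_ensemble"))
  ca <- ca_atoms(ens$top)
  nres <- length(ca)
  nf <- n_frames(ens)
  inds <- atom2xyz_inds(ca)
  mean_d <- matrix(0, nres, nres)
  for (f in seq_len(nf)) {
    mean_d <- mean_d + frame_dist(xyz2mat(ens$xyz[f, inds]))
  }
  mean_d <- mean_d / nf
  acc <- matrix(0, nres, nres)
  for (f in seq_len(nf)) {
    dev <- frame_dist(xyz2mat(ens$xyz[f, inds])) - mean_d
    acc <- acc + dev * dev
  }
  out <- acc / nf
  diag(out) <- 0
  dimnames(out) <- NULL
  structure((out + t(out)) / 2, class = c("commap_cp", "matrix"))
}

#' Export a residue-pair matrix as CSV with author residue numbers
#'
#' @param m matrix (N x N).
#' @param top `commap_topology` supplying author numbering.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_matrix_csv <- function(m, top, file) {
  lab <- paste0(
    top$residues$chain, top$residues$resno,
    ifelse(top$residues$insert == "", "", top$residues$insert)
  )
  out <- as.data.frame(unclass(m))
  colnames(out) <- lab
  rownames(out) <- lab
  utils::write.csv(out, file)
  invisible(file)
}
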