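# Communication components: independent cliques grown from LFA seeds and
# communication pathways enumerated under interaction / propensity
# constraints.

#' Grow an independent clique from a seed residue
#'
#' Greedy extension: candidates are residues whose minimum distance to at
#' least one current member is below `d_cut`; at each step the candidate
#' maximising the updated mean pairwise correlation of the clique is added,
#' and the extension terminates when no candidate keeps that mean at or
#' above `corr_cut`.  Ties are resolved by the smallest minimum distance to
#' the clique, then by the lowest residue index.
#'
#' The acceptance statistic is the mean of the correlations over unordered
#' distinct member pairs (`normalization = "pair"`), which keeps the
#' criterion scale-free in the clique size; `"literal"` instead divides the
#' full double sum over ordered member pairs (diagonal included) by the
#' member count.
#'
#' @param seed residue index.
#' @param corr LFA correlation matrix.
#' @param dist minimum distance matrix.
#' @param corr_cut correlation threshold.
#' @param d_cut distance cutoff in Angstrom (default 3.7, strict).
#' @param normalization `"pair"` (default) or `"literal"`.
#' @return object of class `commap_clique`: list with sorted `members`,
#'   `seed` and `mean_corr` (the final acceptance statistic).
#' @export
grow_clique <- function(seed, corr, dist, corr_cut, d_cut = 3.7,
                        normalization = c("pair", "literal")) {
  normalization <- match.arg(normalization)
  n <- nrow(corr)
  members <- seed
  pair_sum <- 0 # sum over unordered distinct pairs
  stat <- function(psum, k) {
    if (normalization == "pair") {
      if (k < 2) {
        return(NA_real_)
      }
      psum / (k * (k - 1) / 2)
    } else {
      (2 * psum + sum(diag(corr)[members])) / k
    }
  }
  repeat {
    near <- dist[, members, drop = FALSE] < d_cut
    cand <- setdiff(which(rowSums(near) > 0), members)
    if (!length(cand)) break
    gains <- colSums(corr[members, cand, drop = FALSE])
    k1 <- length(members) + 1L
    scores <- vapply(seq_along(cand), function(ci) {
      m2 <- c(members, cand[ci])
      psum <- pair_sum + gains[ci]
      if (normalization == "pair") {
        psum / (k1 * (k1 - 1) / 2)
      } else {
        (2 * psum + sum(diag(corr)[m2])) / k1
      }
    }, 1)
    best <- max(scores)
    if (best < corr_cut) break
    tied <- cand[scores >= best - 1e-12]
    if (length(tied) > 1) {
      mind <- apply(dist[tied, members, drop = FALSE], 1, min)
      tied <- tied[mind <= min(mind) + 1e-12]
    }
    add <- min(tied)
    pair_sum <- pair_sum + sum(corr[members, add])
    members <- c(members, add)
  }
  structure(
    list(
      members = sort(members), seed = seed,
      mean_corr = stat(pair_sum, length(members))
    ),
    class = "commap_clique"
  )
}

#' Grow one clique per seed and collapse duplicates
#'
#' @param seeds a `commap_seeds` data.frame (or integer vector of residue
#'   indices).
#' @param corr,dist,corr_cut,d_cut,normalization passed to [grow_clique()].
#' @return list of `commap_clique` objects with distinct residue sets
#'   (k <= number of seeds).
#' @export
build_cliques <- function(seeds, corr, dist, corr_cut, d_cut = 3.7,
                          normalization = c("pair", "literal")) {
  normalization <- match.arg(normalization)
  idx <- if (is.data.frame(seeds)) seeds$res_index else as.integer(seeds)
  cliques <- lapply(idx, grow_clique,
    corr = corr, dist = dist,
    corr_cut = corr_cut, d_cut = d_cut, normalization = normalization
  )
  keys <- vapply(cliques, function(cl) paste(cl$members, collapse = ","), "")
  cliques[!duplicated(keys)]
}

#' Enumerate communication pathways
#'
#' A communication pathway is a simple path in which two consecutive
#' residues (i) are not sequence-adjacent (separation of at least 2 within a
#' chain), (ii) form stable non-covalent interactions
#' (`INT >= int_cut`) and (iii) communicate efficiently (`CP <= cp_cut`);
#' in addition, every pair of residues of the path must communicate
#' efficiently (transitivity).  A depth-first search rooted at every
#' residue explores neighbours in ascending index order, prunes any
#' extension violating the all-pairs propensity constraint, and caps the
#' path length at `max_depth` residues.
#'
#' Rather than storing every pathway, the enumerator retains (a) each edge
#' used by at least one valid pathway, annotated with the residue count of
#' the longest such pathway, and (b) the set of residue pairs co-occurring
#' in at least one pathway, which later decides segment-pair linkage.
#'
#' @param int_matrix interaction strength matrix.
#' @param cp communication propensity matrix.
#' @param int_cut,cp_cut thresholds.
#' @param max_depth maximum number of residues in an enumerated path
#'   (default 30).
#' @param residues optional residue table for chain assignment.
#' @return object of class `commap_pathways`: list with `edges`
#'   (data.frame `i`, `j`, `max_path_len`), `copath` (N x N logical) and
#'   the thresholds used.
#' @export
enumerate_pathways <- function(int_matrix, cp, int_cut, cp_cut,
                               max_depth = 30L, residues = NULL) {
  n <- nrow(int_matrix)
  chain <- if (is.null(residues)) rep("A", n) else residues$chain
  seq_sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  same_chain <- outer(chain, chain, "==")
  nonadj <- !(same_chain & seq_sep < 2)
  comm <- cp <= cp_cut
  allowed <- nonadj & int_matrix >= int_cut & comm
  diag(allowed) <- FALSE
  nbrs <- lapply(seq_len(n), function(i) which(allowed[i, ]))

  maxlen <- matrix(0L, n, n)
  copath <- matrix(FALSE, n, n)
  path <- integer(max_depth)
  onpath <- rep(FALSE, n)

  dfs <- function(v, depth) {
    path[depth] <<- v
    onpath[v] <<- TRUE
    if (depth >= 2L) {
      mem <- path[seq_len(depth - 1L)]
      copath[cbind(mem, v)] <<- TRUE
      copath[cbind(v, mem)] <<- TRUE
      ep <- cbind(path[seq_len(depth - 1L)], path[2:depth])
      upd <- maxlen[ep] < depth
      if (any(upd)) {
        maxlen[ep[upd, , drop = FALSE]] <<- depth
        maxlen[ep[upd, c(2, 1), drop = FALSE]] <<- depth
      }
    }
    if (depth < max_depth) {
      for (w in nbrs[[v]]) {
        if (onpath[w]) next
        # transitivity: w must communicate efficiently with every member
        if (!all(comm[w, path[seq_len(depth)]])) next
        dfs(w, depth + 1L)
      }
    }
    onpath[v] <<- FALSE
  }
  for (root in seq_len(n)) dfs(root, 1L)

  hits <- which(maxlen > 0 & upper.tri(maxlen), arr.ind = TRUE)
  edges <- data.frame(
    i = hits[, 1], j = hits[, 2],
    max_path_len = maxlen[hits]
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  # post-hoc invariant: every retained edge satisfies all three conditions
  if (nrow(edges)) {
    stopifnot(all(allowed[cbind(edges$i, edges$j)]), all(edges$max_path_len >= 2))
  }
  structure(
    list(
      edges = edges, copath = copath, n = n,
      int_cut = int_cut, cp_cut = cp_cut, max_depth = max_depth
    ),
    class = "commap_pathways"
  )
}
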