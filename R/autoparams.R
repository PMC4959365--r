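# Automated set-up of the four analysis thresholds: the LFA correlation
# cutoff, the communication propensity cutoff (via the modified
# communication propensity MCP), the interaction strength cutoff and the
# minimum path length cutoff.

#' LFA correlation threshold
#'
#' Smallest matrix value such that at most a `tail` fraction of the
#' considered entries (off-diagonal upper triangle) lie strictly above it;
#' with the default tail, 5 percent of the correlation values are higher
#' than the returned cutoff.
#'
#' @param corr LFA correlation matrix (N >= 2).
#' @param tail upper-tail fraction (default 0.05).
#' @return the threshold value.
#' @export
corr_cut <- function(corr, tail = 0.05) {
  stopifnot(nrow(corr) >= 2)
  v <- corr[upper.tri(corr)]
  if (max(v) - min(v) < 1e-14) {
    warning("constant correlation matrix; returning its value as the cutoff")
    return(v[1])
  }
  vals <- sort(unique(v))
  frac_above <- vapply(vals, function(c) mean(v > c), 1)
  vals[which(frac_above <= tail)[1]]
}

#' Modified communication propensity profile
#'
#' `MCP(i)` averages the communication propensities of residue i with its
#' sequence neighbours within four positions on either side, always dividing
#' by 8; at chain termini fewer terms exist and the MCP is accordingly
#' down-weighted.
#'
#' @param cp communication propensity matrix.
#' @return numeric vector of length N.
#' @export
mcp_profile <- function(cp) {
  n <- nrow(cp)
  vapply(seq_len(n), function(i) {
    j <- setdiff(max(1, i - 4):min(n, i + 4), i)
    sum(cp[i, j]) / 8
  }, 1)
}

#' Communication propensity threshold
#'
#' First evaluates `p_ss`, the proportion of residues in a well-defined
#' secondary structure (alpha, beta or turn) in more than half of the
#' conformations; the cutoff is then the smallest MCP value below which at
#' least that proportion of the MCP distribution lies.  Residues forming
#' stable secondary structures are thereby deemed to communicate
#' efficiently with their sequence neighbours.
#'
#' @param cp communication propensity matrix.
#' @param ss a `commap_ss` persistence profile.
#' @return list with `cp_cut`, `p_ss` and the `mcp` profile.
#' @export
cp_cut <- function(cp, ss) {
  n <- nrow(cp)
  if (n < 9) warning("fewer than 9 residues; the MCP window is truncated everywhere")
  occupancy <- ss$p_alpha + ss$p_beta + ss$p_turn
  p_ss <- mean(occupancy > 0.5)
  mcp <- mcp_profile(cp)
  if (p_ss == 0) {
    warning("no residue holds a stable secondary structure; cp_cut set to min(MCP)")
    return(list(cp_cut = min(mcp), p_ss = p_ss, mcp = mcp))
  }
  vals <- sort(unique(mcp))
  frac_below <- vapply(vals, function(c) mean(mcp < c), 1)
  list(cp_cut = vals[which(frac_below >= p_ss)[1]], p_ss = p_ss, mcp = mcp)
}

# Size of the largest connected component of a graph on n nodes given an
# edge list (2-column matrix); isolated nodes count as components of size 1.
.lcc_size <- function(n, edges) {
  if (!nrow(edges)) {
    return(as.integer(min(n, 1L)))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  as.integer(max(igraph::components(g)$csize))
}

#' Interaction strength threshold
#'
#' Scans cutoff values on a grid, builds for each the residue adjacency
#' graph with edges where the interaction strength reaches the cutoff, and
#' records the size of the largest connected component (LCC).  The returned
#' threshold is the largest cutoff for which the LCC size is maximal.
#'
#' @param int_matrix interaction strength matrix.
#' @param grid cutoff grid (default 0.25 to 1.00 in steps of 0.05).
#' @return list with `int_cut` and the scan table `curve` (`cutoff`, `lcc`).
#' @export
int_cut <- function(int_matrix, grid = seq(0.25, 1.00, by = 0.05)) {
  n <- nrow(int_matrix)
  stopifnot(n >= 2)
  grid <- round(grid, 10) # guard against accumulated floating-point drift
  lcc <- vapply(grid, function(c) {
    hits <- which(int_matrix >= c & upper.tri(int_matrix), arr.ind = TRUE)
    .lcc_size(n, hits)
  }, 1L)
  if (all(lcc <= 1L)) {
    warning("degenerate interaction scan: every cutoff yields singletons")
  }
  list(
    int_cut = max(grid[lcc == max(lcc)]),
    curve = data.frame(cutoff = grid, lcc = lcc)
  )
}

#' Minimum path length threshold
#'
#' For each minimum supporting-path length n in `n_range`, the largest
#' connected component over the pathway edges whose longest supporting path
#' comprises at least n residues is recorded; the threshold is the n at
#' which the reduction of the LCC size relative to n - 1 is largest (ties
#' resolved toward the smallest n).
#'
#' @param pathway_edges data.frame with columns `i`, `j`, `max_path_len`
#'   (a `commap_pathways` object or a PCN's `pathway_edges` both qualify).
#' @param n_nodes number of residues in the network.
#' @param n_range candidate minimum path lengths (default 4 to 8).
#' @return list with `mpl_cut` and the scan table `curve` (`n`, `lcc`).
#' @export
mpl_cut <- function(pathway_edges, n_nodes, n_range = 4:8) {
  if (inherits(pathway_edges, "commap_pathways")) {
    pathway_edges <- pathway_edges$edges
  }
  if (is.null(pathway_edges) || !nrow(pathway_edges)) {
    stop("undefined-threshold error: the network has no pathway edges")
  }
  lcc <- vapply(n_range, function(n) {
    keep <- pathway_edges$max_path_len >= n
    .lcc_size(n_nodes, cbind(pathway_edges$i, pathway_edges$j)[keep, , drop = FALSE])
  }, 1L)
  red <- -diff(lcc)
  if (all(red == 0)) {
    warning("zero-reduction scan: the LCC size does not depend on the path length")
  }
  list(
    mpl_cut = n_range[-1][which.max(red)],
    curve = data.frame(n = n_range, lcc = lcc)
  )
}

#' Auto-tune all thresholds for one replicate
#'
#' @param corr,cp,int_matrix,ss the descriptor matrices and persistence
#'   profile of one replicate.
#' @param overrides named list overriding any of `corr_cut`, `cp_cut`,
#'   `int_cut` (`mpl_cut` is tuned later, on the assembled network).
#' @return object of class `commap_parameters`: thresholds plus scan curves.
#' @export
tune_parameters <- function(corr, cp, int_matrix, ss, overrides = list()) {
  cc <- overrides$corr_cut %||% corr_cut(corr)
  cpres <- cp_cut(cp, ss)
  ic <- int_cut(int_matrix)
  structure(
    list(
      corr_cut = cc,
      cp_cut = overrides$cp_cut %||% cpres$cp_cut,
      p_ss = cpres$p_ss,
      mcp = cpres$mcp,
      int_cut = overrides$int_cut %||% ic$int_cut,
      int_curve = ic$curve,
      mpl_cut = overrides$mpl_cut,
      mpl_curve = NULL
    ),
    class = "commap_parameters"
  )
}

#' @export
print.commap_parameters <- function(x, ...) {
  cat("Auto-tuned thresholds:\n")
  cat(sprintf("  corr_cut = %.6g\n", x$corr_cut))
  cat(sprintf("  cp_cut   = %.6g A^2 (p_ss = %.3f)\n", x$cp_cut, x$p_ss))
  cat(sprintf("  int_cut  = %.2f\n", x$int_cut))
  cat(sprintf(
    "  mpl_cut  = %s\n",
    if (is.null(x$mpl_cut)) "<undefined>" else x$mpl_cut
  ))
  invisible(x)
}

#' Export parameters and scan curves as a JSON report
#'
#' @param params a `commap_parameters`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_parameters_json <- function(params, file) {
  jsonlite::write_json(
    list(
      corr_cut = params$corr_cut, cp_cut = params$cp_cut,
      p_ss = params$p_ss, int_cut = params$int_cut,
      mpl_cut = params$mpl_cut, int_curve = params$int_curve,
      mpl_curve = params$mpl_curve
    ),
    file,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(file)
}
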