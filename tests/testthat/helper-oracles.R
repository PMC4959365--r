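# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity by the most literal route
# (naive loops, exhaustive enumeration, union-find) and share no code with
# the package internals.

# LFA correlations by naive triple loop over coordinate components and modes.
brute_lfa <- function(vectors, nres) {
  out <- matrix(0, nres, nres)
  nmodes <- ncol(vectors)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      s <- 0
      for (d in 1:3) {
        for (r in seq_len(nmodes)) {
          s <- s + vectors[3 * (i - 1) + d, r] * vectors[3 * (j - 1) + d, r]
        }
      }
      out[i, j] <- s
    }
  }
  out
}

# Minimum distance matrix by naive loops.
brute_min_dist <- function(ens) {
  top <- ens$top
  nres <- nrow(top$residues)
  nf <- nrow(ens$xyz)
  out <- matrix(0, nres, nres)
  for (f in seq_len(nf)) {
    m <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    for (i in seq_len(nres - 1)) {
      for (j in seq(i + 1, nres)) {
        ai <- which(top$atoms$res_index == i)
        aj <- which(top$atoms$res_index == j)
        best <- Inf
        for (a in ai) {
          for (b in aj) {
            best <- min(best, sqrt(sum((m[a, ] - m[b, ])^2)))
          }
        }
        out[i, j] <- out[i, j] + best
      }
    }
  }
  out <- out / nf
  out + t(out)
}

# Communication propensity by naive two-pass population variance.
brute_cp <- function(ens) {
  ca <- which(ens$top$atoms$elety == "CA")
  nres <- length(ca)
  nf <- nrow(ens$xyz)
  getd <- function(f, i, j) {
    m <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    sqrt(sum((m[ca[i], ] - m[ca[j], ])^2))
  }
  out <- matrix(0, nres, nres)
  for (i in seq_len(nres - 1)) {
    for (j in seq(i + 1, nres)) {
      d <- vapply(seq_len(nf), getd, 1, i = i, j = j)
      out[i, j] <- mean((d - mean(d))^2)
    }
  }
  out + t(out)
}

# Exhaustive simple-path enumeration respecting the pathway constraints.
# Returns edge max-path-length matrix and co-path incidence matrix.
brute_paths <- function(int_matrix, cp, int_cut, cp_cut, max_depth = 30L) {
  n <- nrow(int_matrix)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  comm <- cp <= cp_cut
  allowed <- sep >= 2 & int_matrix >= int_cut & comm
  diag(allowed) <- FALSE
  maxlen <- matrix(0L, n, n)
  copath <- matrix(FALSE, n, n)
  record <- function(path) {
    L <- length(path)
    for (k in seq_len(L - 1)) {
      a <- path[k]
      b <- path[k + 1]
      maxlen[a, b] <<- max(maxlen[a, b], L)
      maxlen[b, a] <<- maxlen[a, b]
    }
    prs <- t(combn(path, 2))
    copath[prs] <<- TRUE
    copath[prs[, c(2, 1), drop = FALSE]] <<- TRUE
  }
  extend <- function(path) {
    v <- path[length(path)]
    for (w in seq_len(n)) {
      if (w %in% path) next
      if (!allowed[v, w]) next
      if (!all(comm[w, path])) next
      record(c(path, w))
      if (length(path) + 1L < max_depth) extend(c(path, w))
    }
  }
  for (root in seq_len(n)) extend(root)
  list(maxlen = maxlen, copath = copath)
}

# Connected components by plain union-find on an edge list.
brute_components <- function(n, edges) {
  parent <- seq_len(n)
  findr <- function(x) {
    r <- x
    while (parent[r] != r) r <- parent[r]
    r
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- findr(edges[k, 1])
      b <- findr(edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), findr, 1L)
  split(seq_len(n), roots)
}

# Random orthonormal loading matrix (3N x k) for property tests.
random_orthonormal <- function(nrow, k) {
  qr.Q(qr(matrix(rnorm(nrow * k), nrow, k)))[, seq_len(k), drop = FALSE]
}

# Minimal C-alpha-only ensemble from an explicit frames x residues x 3 array.
ca_ensemble_from_coords <- function(coords_list) {
  n <- nrow(coords_list[[1]])
  top <- build_topology(
    data.frame(
      eleno = seq_len(n), elety = "CA", resid = "GLY", chain = "A",
      resno = seq_len(n), insert = "", stringsAsFactors = FALSE
    ),
    ref_coords = NULL
  )
  xyz <- do.call(rbind, lapply(coords_list, function(m) as.numeric(t(m))))
  commap:::new_ensemble(xyz, top)
}

# Ensemble with arbitrary atom records (for interaction tests).
atom_ensemble <- function(atoms, coords_list, bonds = NULL) {
  top <- build_topology(atoms, ref_coords = coords_list[[1]])
  if (!is.null(bonds)) top$bonds <- bonds
  xyz <- do.call(rbind, lapply(coords_list, function(m) as.numeric(t(m))))
  commap:::new_ensemble(xyz, top)
}
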