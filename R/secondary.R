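# Secondary-structure persistence profiles.
#
# Assignment follows the DSSP hydrogen-bond pattern rules: a backbone
# C=O(i)...H-N(j) hydrogen bond is scored with the Kabsch-Sander
# electrostatic energy and accepted below -0.5 kcal/mol; helices are runs of
# consecutive n-turns (3-, 4- and 5-turns -> G, H, I), beta structure comes
# from parallel/antiparallel bridge patterns (B/E), and turns (T) are the
# residues spanned by isolated n-turns.  The eight states are collapsed to
# alpha (H, G, I), beta (E, B), turn (T) and other.

shiftmat <- function(x, di, dj) {
  n <- nrow(x)
  out <- matrix(FALSE, n, n)
  si <- seq_len(n) + di
  sj <- seq_len(n) + dj
  oki <- si >= 1 & si <= n
  okj <- sj >= 1 & sj <= n
  out[oki, okj] <- x[si[oki], sj[okj]]
  out
}

# Backbone H-bond matrix for one frame: entry (i, j) is TRUE when the C=O of
# residue i accepts from the N-H of residue j.
.ks_hbonds <- function(cN, cH, cC, cO) {
  n <- nrow(cN)
  dm <- function(p, q) {
    # entry (i, j) = |p_i - q_j|
    out <- matrix(NA_real_, n, n)
    okp <- which(stats::complete.cases(p))
    okq <- which(stats::complete.cases(q))
    if (length(okp) && length(okq)) {
      pp <- p[okp, , drop = FALSE]
      qq <- q[okq, , drop = FALSE]
      d2 <- outer(rowSums(pp^2), rep(1, length(okq))) +
        outer(rep(1, length(okp)), rowSums(qq^2)) - 2 * pp %*% t(qq)
      out[okp, okq] <- sqrt(pmax(d2, 0))
    }
    out
  }
  # rows: acceptor residue i (C, O); cols: donor residue j (N, H)
  e <- 27.888 * (1 / dm(cO, cN) + 1 / dm(cC, cH) - 1 / dm(cO, cH) - 1 / dm(cC, cN))
  e[!is.finite(e)] <- Inf
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  e[sep < 2] <- Inf
  e < -0.5
}

# Collapse one frame to per-residue classes "alpha"/"beta"/"turn"/"other".
.dssp_frame <- function(cN, cH, cC, cO) {
  n <- nrow(cN)
  hb <- .ks_hbonds(cN, cH, cC, cO)
  tns <- lapply(3:5, function(k) {
    t_k <- rep(FALSE, n)
    i <- seq_len(n - k)
    t_k[i] <- hb[cbind(i, i + k)]
    t_k
  })
  names(tns) <- c("t3", "t4", "t5")
  helix <- function(t_k, span) {
    marked <- rep(FALSE, n)
    start <- which(c(FALSE, t_k[-n] & t_k[-1]))
    for (i in start) marked[i:min(n, i + span - 1L)] <- TRUE
    marked
  }
  isH <- helix(tns$t4, 4L)
  isG <- helix(tns$t3, 3L)
  isI <- helix(tns$t5, 5L)

  tb <- t(hb)
  par <- (shiftmat(hb, -1, 0) & shiftmat(tb, 1, 0)) |
    (shiftmat(tb, 0, -1) & shiftmat(hb, 0, 1))
  anti <- (hb & tb) | (shiftmat(hb, -1, 1) & shiftmat(tb, 1, -1))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  bridgepair <- (par | anti) & sep >= 3
  isB <- apply(bridgepair, 1, any) | apply(bridgepair, 2, any)

  inturn <- rep(FALSE, n)
  for (k in 3:5) {
    at <- which(tns[[paste0("t", k)]])
    for (i in at) {
      span <- seq(i + 1L, min(n, i + k - 1L))
      inturn[span] <- TRUE
    }
  }
  ifelse(isH, "alpha",
    ifelse(isB, "beta",
      ifelse(isG | isI, "alpha",
        ifelse(inturn, "turn", "other")
      )
    )
  )
}

#' Secondary-structure persistence profile of an ensemble
#'
#' Per residue, the fraction of conformations assigned to the alpha, beta
#' and turn classes by the DSSP-style hydrogen-bond pattern rules, plus the
#' assigned type (the class with the maximal persistence; ties broken with
#' priority alpha > beta > turn; `other` when all three are zero).
#' Residues lacking any of the four backbone heavy atoms (N, CA, C, O) get
#' zero persistences and type `other`, with a warning.
#'
#' Amide hydrogens are taken from the topology when bonded to the backbone
#' nitrogen, otherwise placed at 1.0 A from N opposite the preceding
#' carbonyl (the DSSP convention); the first residue of a chain has no
#' donor.
#'
#' @param ens a `commap_ensemble`.
#' @param top topology (defaults to the ensemble's).
#' @return data.frame of class `commap_ss` with columns `res_index`,
#'   `resno`, `chain`, `p_alpha`, `p_beta`, `p_turn`, `type`.
#' @export
assign_secondary_structure <- function(ens, top = ens$top) {
  stopifnot(inherits(ens, "commap_ensemble"))
  a <- top$atoms
  nres <- nrow(top$residues)
  nf <- n_frames(ens)
  idx_of <- function(name) {
    out <- rep(NA_integer_, nres)
    hit <- which(a$elety == name)
    out[a$res_index[hit]] <- hit
    out
  }
  iN <- idx_of("N")
  iCA <- idx_of("CA")
  iC <- idx_of("C")
  iO <- idx_of("O")
  iH <- rep(NA_integer_, nres)
  for (h in which(a$elety %in% c("H", "HN"))) iH[a$res_index[h]] <- h
  complete <- !is.na(iN) & !is.na(iCA) & !is.na(iC) & !is.na(iO)
  if (!all(complete)) {
    warning(
      sum(!complete), " residue(s) lack backbone atoms; ",
      "their persistences are set to 0 and type to 'other'"
    )
  }
  counts <- matrix(0, nres, 3, dimnames = list(NULL, c("alpha", "beta", "turn")))
  if (sum(complete) >= 5) {
    chain <- top$residues$chain
    prev_ok <- c(FALSE, complete[-nres]) & complete &
      c(FALSE, chain[-nres] == chain[-1])
    getc <- function(m, ix) {
      out <- matrix(NA_real_, nres, 3)
      ok <- !is.na(ix)
      out[ok, ] <- m[ix[ok], , drop = FALSE]
      out
    }
    for (f in seq_len(nf)) {
      m <- xyz2mat(ens$xyz[f, ])
      cN <- getc(m, iN)
      cC <- getc(m, iC)
      cO <- getc(m, iO)
      cH <- getc(m, iH)
      place <- which(is.na(iH) & prev_ok)
      if (length(place)) {
        dir <- m[iC[place - 1L], , drop = FALSE] - m[iO[place - 1L], , drop = FALSE]
        dir <- dir / sqrt(rowSums(dir^2))
        cH[place, ] <- cN[place, ] + dir
      }
      cN[!complete, ] <- NA
      cls <- .dssp_frame(cN, cH, cC, cO)
      for (k in colnames(counts)) {
        counts[, k] <- counts[, k] + (cls == k & complete)
      }
    }
  }
  p <- counts / nf
  type <- apply(p, 1, function(row) {
    if (all(row == 0)) {
      "other"
    } else {
      c("alpha", "beta", "turn")[which.max(row)]
    }
  })
  out <- data.frame(
    res_index = top$residues$res_index,
    resno = top$residues$resno,
    chain = top$residues$chain,
    p_alpha = p[, "alpha"],
    p_beta = p[, "beta"],
    p_turn = p[, "turn"],
    type = type,
    stringsAsFactors = FALSE
  )
  class(out) <- c("commap_ss", "data.frame")
  out
}
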