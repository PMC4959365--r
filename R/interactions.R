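# Non-covalent interaction detection (hydrogen bonds and hydrophobic
# contacts) and per-residue-pair interaction strength (persistence) matrices.
#
# H-bond geometric criteria: donor-acceptor distance <= 3.9 A, hydrogen-
# acceptor distance <= 2.5 A, and D-H-A, H-A-AA and D-A-AA angles all
# >= 90 degrees (AA = acceptor antecedent).  Hydrophobic contacts: two
# apolar atoms (C or S not covalently bonded to N or O) strictly closer
# than 3.9 A.  Donors are N/O atoms carrying a hydrogen; acceptors are
# N, O or S atoms.

#' Precompute the interaction context of a topology
#'
#' Identifies donors (with their hydrogens), acceptors (with their
#' antecedents) and apolar atoms, and tabulates covalent exclusions.
#' When `hydrogens = "place"` and an amide nitrogen carries no hydrogen,
#' a backbone amide hydrogen is placed geometrically at evaluation time
#' (1.0 A from N along the bisector of the C'(-1)-N-CA directions).
#'
#' @param top a `commap_topology`.
#' @param hydrogens `"require"` (default) or `"place"`.
#' @return a list used by [detect_interactions()].
#' @export
interaction_context <- function(top, hydrogens = c("require", "place")) {
  hydrogens <- match.arg(hydrogens)
  a <- top$atoms
  nat <- nrow(a)
  bonded <- matrix(FALSE, nat, nat)
  if (nrow(top$bonds)) {
    bonded[top$bonds] <- TRUE
    bonded[top$bonds[, c(2, 1), drop = FALSE]] <- TRUE
  }
  hmates <- lapply(seq_len(nat), function(i) {
    which(bonded[i, ] & a$element == "H")
  })
  heavymates <- lapply(seq_len(nat), function(i) {
    which(bonded[i, ] & a$element != "H")
  })
  donors <- which(a$element %in% c("N", "O") & lengths(hmates) > 0)
  virtual_h <- NULL
  if (hydrogens == "place") {
    bareN <- which(a$elety == "N" & lengths(hmates) == 0)
    rows <- lapply(bareN, function(i) {
      ri <- a$res_index[i]
      ca <- which(a$res_index == ri & a$elety == "CA")
      cprev <- which(a$res_index == ri - 1L & a$elety == "C")
      if (length(ca) == 1 && length(cprev) == 1) c(i, cprev, ca) else NULL
    })
    virtual_h <- do.call(rbind, rows)
    if (!is.null(virtual_h)) donors <- sort(union(donors, virtual_h[, 1]))
  }
  npol <- which(a$element %in% c("N", "O"))
  if (length(npol) && !length(donors) && hydrogens == "require") {
    if (!any(a$element == "H")) {
      stop(
        "configuration error: no hydrogens in the topology; add hydrogens ",
        "to the input or use hydrogens = \"place\" for backbone amides"
      )
    }
  }
  acceptors <- which(a$element %in% c("N", "O", "S"))
  apolar <- which(
    a$element %in% c("C", "S") &
      !vapply(heavymates, function(m) any(a$element[m] %in% c("N", "O")), TRUE)
  )
  list(
    atoms = a, bonded = bonded, hmates = hmates, heavymates = heavymates,
    donors = donors, acceptors = acceptors, apolar = apolar,
    virtual_h = virtual_h
  )
}

.interaction_class <- function(bb_i, bb_j) {
  ifelse(bb_i & bb_j, "bb-bb", ifelse(!bb_i & !bb_j, "sc-sc", "bb-sc"))
}

#' Detect non-covalent interactions in one conformation
#'
#' @param x a `commap_structure`, a `commap_ensemble` frame (pass `frame`),
#'   or an A x 3 coordinate matrix (then `top` is required).
#' @param top topology (taken from `x` when it carries one).
#' @param context optional precomputed [interaction_context()].
#' @param frame frame number when `x` is an ensemble.
#' @param hydrogens `"require"` or `"place"`, see [interaction_context()].
#' @return data.frame with columns `atom_i`, `atom_j`, `kind`
#'   (`hbond`/`hydrophobic`) and `class` (`bb-bb`/`bb-sc`/`sc-sc`).
#'   Only inter-residue, non-covalent pairs are reported.
#' @export
detect_interactions <- function(x, top = NULL, context = NULL, frame = 1L,
                                hydrogens = c("require", "place")) {
  hydrogens <- match.arg(hydrogens)
  if (inherits(x, "commap_ensemble")) {
    top <- x$top
    coords <- xyz2mat(x$xyz[frame, ])
  } else if (inherits(x, "commap_structure")) {
    top <- x$top
    coords <- xyz2mat(x$xyz)
  } else {
    coords <- x
    if (is.null(top)) stop("a topology is required with raw coordinates")
  }
  ctx <- context %||% interaction_context(top, hydrogens = hydrogens)
  a <- ctx$atoms
  d <- frame_dist(coords)
  res <- a$res_index

  hb <- NULL
  if (length(ctx$donors) && length(ctx$acceptors)) {
    vh <- list()
    if (!is.null(ctx$virtual_h)) {
      for (r in seq_len(nrow(ctx$virtual_h))) {
        i <- ctx$virtual_h[r, 1]
        u1 <- unitv(coords[i, ] - coords[ctx$virtual_h[r, 2], ])
        u2 <- unitv(coords[i, ] - coords[ctx$virtual_h[r, 3], ])
        vh[[as.character(i)]] <- coords[i, ] + unitv(u1 + u2)
      }
    }
    sub <- d[ctx$donors, ctx$acceptors, drop = FALSE]
    hits <- which(sub <= 3.9, arr.ind = TRUE)
    rows <- vector("list", nrow(hits))
    for (r in seq_len(nrow(hits))) {
      di <- ctx$donors[hits[r, 1]]
      ai <- ctx$acceptors[hits[r, 2]]
      if (di == ai || res[di] == res[ai] || ctx$bonded[di, ai]) next
      hcoords <- lapply(ctx$hmates[[di]], function(h) coords[h, ])
      key <- as.character(di)
      if (!is.null(vh[[key]])) hcoords <- c(hcoords, list(vh[[key]]))
      ok <- FALSE
      for (hc in hcoords) {
        if (vnorm(hc - coords[ai, ]) > 2.5) next
        if (angle3(coords[di, ], hc, coords[ai, ]) < 90) next
        ante <- ctx$heavymates[[ai]]
        if (!length(ante)) {
          ok <- TRUE
          break
        }
        for (aa in ante) {
          if (angle3(hc, coords[ai, ], coords[aa, ]) >= 90 &&
            angle3(coords[di, ], coords[ai, ], coords[aa, ]) >= 90) {
            ok <- TRUE
            break
          }
        }
        if (ok) break
      }
      if (ok) rows[[r]] <- c(di, ai)
    }
    hb <- do.call(rbind, rows)
  }

  ph <- NULL
  if (length(ctx$apolar) > 1) {
    sub <- d[ctx$apolar, ctx$apolar, drop = FALSE]
    hits <- which(sub < 3.9 & upper.tri(sub), arr.ind = TRUE)
    if (nrow(hits)) {
      i <- ctx$apolar[hits[, 1]]
      j <- ctx$apolar[hits[, 2]]
      keep <- res[i] != res[j] & !ctx$bonded[cbind(i, j)]
      ph <- cbind(i, j)[keep, , drop = FALSE]
    }
  }

  out <- rbind(
    if (!is.null(hb) && nrow(hb)) {
      data.frame(
        atom_i = hb[, 1], atom_j = hb[, 2], kind = "hbond",
        class = .interaction_class(a$backbone[hb[, 1]], a$backbone[hb[, 2]]),
        stringsAsFactors = FALSE
      )
    },
    if (!is.null(ph) && nrow(ph)) {
      data.frame(
        atom_i = ph[, 1], atom_j = ph[, 2], kind = "hydrophobic",
        class = .interaction_class(a$backbone[ph[, 1]], a$backbone[ph[, 2]]),
        stringsAsFactors = FALSE
      )
    }
  )
  if (is.null(out)) {
    out <- data.frame(
      atom_i = integer(0), atom_j = integer(0),
      kind = character(0), class = character(0)
    )
  }
  out
}

#' Interaction strength (persistence) matrix
#'
#' `INT(i, j)` is the fraction of conformations in which at least one
#' qualifying non-covalent interaction is formed between some atom pair of
#' residues i and j, optionally restricted to an interaction class.
#'
#' @param ens a `commap_ensemble`.
#' @param class_filter one of `"all"`, `"bb-bb"`, `"bb-sc"`, `"sc-sc"` or
#'   `"sidechain"` (= `bb-sc` plus `sc-sc`).
#' @param hydrogens `"require"` or `"place"`, see [interaction_context()].
#' @return symmetric N x N matrix with values in `[0, 1]`, class
#'   `commap_int`; the class filter is kept in attribute
#'   `interaction_class`.
#' @export
compute_interaction_strengths <- function(ens,
                                          class_filter = c(
                                            "all", "bb-bb", "bb-sc",
                                            "sc-sc", "sidechain"
                                          ),
                                          hydrogens = c("require", "place")) {
  class_filter <- match.arg(class_filter)
  hydrogens <- match.arg(hydrogens)
  stopifnot(inherits(ens, "commap_ensemble"))
  ctx <- interaction_context(ens$top, hydrogens = hydrogens)
  nres <- n_residues(ens)
  nf <- n_frames(ens)
  res <- ens$top$atoms$res_index
  counts <- matrix(0L, nres, nres)
  for (f in seq_len(nf)) {
    det <- detect_interactions(xyz2mat(ens$xyz[f, ]),
      top = ens$top,
      context = ctx
    )
    if (class_filter == "sidechain") {
      det <- det[det$class %in% c("bb-sc", "sc-sc"), , drop = FALSE]
    } else if (class_filter != "all") {
      det <- det[det$class == class_filter, , drop = FALSE]
    }
    if (!nrow(det)) next
    ri <- res[det$atom_i]
    rj <- res[det$atom_j]
    lo <- pmin(ri, rj)
    hi <- pmax(ri, rj)
    pairs <- unique(cbind(lo, hi))
    counts[pairs] <- counts[pairs] + 1L
  }
  out <- counts / nf
  out <- out + t(out)
  diag(out) <- 0
  structure(out,
    class = c("commap_int", "matrix"),
    interaction_class = class_filter
  )
}
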