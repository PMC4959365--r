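# Trajectory convergence diagnostic based on reference conformations.
#
# Reference conformations are picked greedily at random: an unassigned frame
# becomes a reference and every frame within a C-alpha RMSD cutoff r is
# binned with it, until all frames are assigned.  The trajectory is then
# split into two halves and every frame of each half is regrouped with its
# nearest reference; a reference is "lone" when one half contributes fewer
# than 1 percent of the frames of its group.  The convergence criterion is
# one minus the mean, over five repeats, of the lone fraction; 1 indicates
# optimal convergence.

#' Convergence criterion from per-repeat lone-reference counts
#'
#' @param lone integer vector: lone reference count per repeat.
#' @param total integer vector: reference count per repeat.
#' @return the convergence criterion, in `[0, 1]`.
#' @export
convergence_score <- function(lone, total) {
  stopifnot(length(lone) == length(total), all(total > 0), all(lone <= total))
  1 - mean(lone / total)
}

# C-alpha RMSD of one frame against a set of frames, with pairwise
# least-squares superposition.
.ca_rmsd_to <- function(ref, xyz) {
  as.numeric(bio3d::rmsd(ref, xyz, fit = TRUE))
}

# One clustering pass: reference picking follows `order`, binning within r.
# `max_refs` allows the auto-scan to stop early once the count is known to
# exceed the target range.
.pick_references <- function(xyz, r, order, max_refs = Inf) {
  refs <- integer(0)
  assigned <- rep(FALSE, nrow(xyz))
  for (f in order) {
    if (assigned[f]) next
    refs <- c(refs, f)
    if (length(refs) > max_refs) break
    d <- .ca_rmsd_to(xyz[f, ], xyz[!assigned, , drop = FALSE])
    assigned[which(!assigned)[d < r]] <- TRUE
    assigned[f] <- TRUE
  }
  refs
}

#' Trajectory convergence diagnostic
#'
#' @param ens a `commap_ensemble` (at least 4 frames).
#' @param r C-alpha RMSD cutoff in Angstrom; `NULL` (default) auto-scans r
#'   so that the number of references falls between 2 and 7.
#' @param repeats number of random repeats (default 5).
#' @param seed RNG seed for reproducible reference picking.
#' @return object of class `commap_convergence`: `c` (the criterion), `r`,
#'   `repeats` (data.frame `repeat`, `n_references`, `n_lone`) and `seed`.
#' @export
convergence_criterion <- function(ens, r = NULL, repeats = 5L, seed = NULL) {
  stopifnot(inherits(ens, "commap_ensemble"))
  nf <- n_frames(ens)
  if (nf < 4) stop("at least 4 frames are needed for the convergence test")
  if (!is.null(r) && r <= 0) stop("parameter error: the RMSD cutoff r must be positive")
  if (!is.null(seed)) set.seed(seed)
  xyz <- ens$xyz[, atom2xyz_inds(ca_atoms(ens$top)), drop = FALSE]
  orders <- lapply(seq_len(repeats), function(k) sample.int(nf))

  if (is.null(r)) {
    count <- function(rr) {
      length(.pick_references(xyz, rr, orders[[1]], max_refs = 8L))
    }
    # bracket the scan with the spread of the data: at the largest
    # frame-to-frame RMSD a single reference captures everything
    d0 <- .ca_rmsd_to(xyz[orders[[1]][1], ], xyz)
    hi <- max(d0) * 1.01 + 1e-6
    lo <- max(min(d0[d0 > 0], hi / 1e4), hi / 1e6)
    k <- count(hi)
    if (k >= 2 && k <= 7) {
      r <- hi
    } else {
      for (it in 1:40) {
        mid <- sqrt(lo * hi)
        k <- count(mid)
        if (k >= 2 && k <= 7) {
          r <- mid
          break
        } else if (k > 7) lo <- mid else hi <- mid
      }
      if (is.null(r)) {
        stop("auto-scan failed to find an RMSD cutoff giving 2-7 references")
      }
    }
  }

  half <- rep(2L, nf)
  half[seq_len(floor(nf / 2))] <- 1L
  detail <- data.frame(
    repeat_ = seq_len(repeats), n_references = NA_integer_,
    n_lone = NA_integer_
  )
  for (k in seq_len(repeats)) {
    refs <- .pick_references(xyz, r, orders[[k]])
    d <- vapply(refs, function(f) .ca_rmsd_to(xyz[f, ], xyz), numeric(nf))
    grp <- max.col(-d, ties.method = "first")
    lone <- 0L
    for (g in seq_along(refs)) {
      tot <- sum(grp == g)
      if (tot == 0) next
      h1 <- sum(grp == g & half == 1L)
      h2 <- tot - h1
      if (h1 < 0.01 * tot || h2 < 0.01 * tot) lone <- lone + 1L
    }
    detail$n_references[k] <- length(refs)
    detail$n_lone[k] <- lone
  }
  if (length(unique(detail$n_references)) == 1 && detail$n_references[1] == 1) {
    warning("a single reference captures the whole trajectory; r may be too large")
  }
  structure(
    list(
      c = convergence_score(detail$n_lone, detail$n_references),
      r = r, repeats = detail, seed = seed
    ),
    class = "commap_convergence"
  )
}

#' @export
print.commap_convergence <- function(x, ...) {
  cat(sprintf(
    "Convergence criterion c = %.3f (r = %.3g A, %d repeats)\n",
    x$c, x$r, nrow(x$repeats)
  ))
  invisible(x)
}

#' Export a convergence report as JSON
#'
#' @param conv a `commap_convergence`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_convergence_json <- function(conv, file) {
  jsonlite::write_json(
    list(
      c = conv$c, r = conv$r, seed = conv$seed,
      repeats = conv$repeats
    ),
    file,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(file)
}
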