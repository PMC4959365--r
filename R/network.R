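# Protein Communication Network assembly and its decompositions:
# communication blocks, block relations, block mapping between two protein
# states, secondary structure elements and communicating segment pairs.

#' Assemble the Protein Communication Network
#'
#' The PCN is a coloured residue graph: a clique-based edge joins two
#' residues that share an independent clique in some replicate and whose
#' correlation in that replicate reaches its correlation cutoff; a
#' pathway-based edge joins two residues consecutive in some communication
#' pathway.  Edges are unioned over replicates; pathway edges keep the
#' maximum supporting-path length over replicates.
#'
#' @param cliques list (one element per replicate) of lists of
#'   `commap_clique`.
#' @param pathways list (one per replicate) of `commap_pathways` (may
#'   contain `NULL` entries).
#' @param corr list (one per replicate) of correlation matrices.
#' @param corr_cut numeric vector of per-replicate correlation cutoffs.
#' @param residues residue table (author numbering for reports).
#' @return object of class `commap_pcn`: `n`, `residues`, `clique_edges`
#'   (2-column matrix), `pathway_edges` (data.frame `i`, `j`,
#'   `max_path_len`) and `copath` (N x N logical).
#' @export
build_pcn <- function(cliques, pathways, corr, corr_cut, residues) {
  n <- nrow(residues)
  ce <- matrix(FALSE, n, n)
  for (r in seq_along(cliques)) {
    cm <- corr[[r]]
    cc <- corr_cut[[r]]
    for (cl in cliques[[r]]) {
      m <- cl$members
      if (length(m) < 2) next
      prs <- t(utils::combn(m, 2))
      ok <- cm[prs] >= cc
      ce[prs[ok, , drop = FALSE]] <- TRUE
    }
  }
  ce <- ce | t(ce)
  clique_edges <- which(ce & upper.tri(ce), arr.ind = TRUE)
  colnames(clique_edges) <- c("i", "j")

  maxlen <- matrix(0L, n, n)
  copath <- matrix(FALSE, n, n)
  for (pw in pathways) {
    if (is.null(pw) || !nrow(pw$edges)) next
    e <- pw$edges
    idx <- cbind(e$i, e$j)
    maxlen[idx] <- pmax(maxlen[idx], e$max_path_len)
    copath <- copath | pw$copath
  }
  maxlen <- pmax(maxlen, t(maxlen))
  hits <- which(maxlen > 0 & upper.tri(maxlen), arr.ind = TRUE)
  pathway_edges <- data.frame(
    i = hits[, 1], j = hits[, 2],
    max_path_len = maxlen[hits]
  )
  structure(
    list(
      n = n, residues = residues, clique_edges = clique_edges,
      pathway_edges = pathway_edges, copath = copath | t(copath)
    ),
    class = "commap_pcn"
  )
}

#' @export
print.commap_pcn <- function(x, ...) {
  cat(
    "Protein Communication Network: ", x$n, " residues, ",
    nrow(x$clique_edges), " clique-based edges, ",
    nrow(x$pathway_edges), " pathway-based edges\n",
    sep = ""
  )
  invisible(x)
}

#' Extract communication blocks from a PCN
#'
#' Blocks are the connected components (depth-first search) of the PCN
#' restricted to one edge colour; pathway-based blocks additionally require
#' each edge's longest supporting path to comprise at least `min_path_len`
#' residues.  Singleton components are not blocks.  Blocks are labelled
#' A, B, ... by decreasing size.
#'
#' @param pcn a `commap_pcn`.
#' @param kind `"clique"` or `"pathway"`.
#' @param min_path_len minimum supporting-path length for pathway blocks
#'   (default 4, i.e. all but very short pathways).
#' @return object of class `commap_blocks`: list with `blocks` (named list
#'   of sorted residue index vectors), `kind`, `min_path_len`.
#' @export
extract_blocks <- function(pcn, kind = c("clique", "pathway"),
                           min_path_len = 4L) {
  kind <- match.arg(kind)
  edges <- if (kind == "clique") {
    pcn$clique_edges
  } else {
    keep <- pcn$pathway_edges$max_path_len >= min_path_len
    as.matrix(pcn$pathway_edges[keep, c("i", "j"), drop = FALSE])
  }
  comps <- list()
  if (nrow(edges)) {
    g <- igraph::make_empty_graph(pcn$n, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    cc <- igraph::components(g)
    for (k in seq_len(cc$no)) {
      mem <- which(cc$membership == k)
      if (length(mem) >= 2) comps[[length(comps) + 1]] <- sort(mem)
    }
  }
  comps <- comps[order(-lengths(comps), vapply(comps, min, 1L))]
  labels <- make.unique(rep(LETTERS, length.out = max(1, length(comps))))[seq_along(comps)]
  names(comps) <- labels
  structure(
    list(
      blocks = comps, kind = kind,
      min_path_len = if (kind == "pathway") min_path_len else NA_integer_
    ),
    class = "commap_blocks"
  )
}

#' @export
print.commap_blocks <- function(x, ...) {
  cat(length(x$blocks), " ", x$kind, "-based block(s)",
    if (x$kind == "pathway") paste0(" (min path length ", x$min_path_len, ")"),
    ":\n",
    sep = ""
  )
  for (nm in names(x$blocks)) {
    cat("  ", nm, ": ", length(x$blocks[[nm]]), " residues\n", sep = "")
  }
  invisible(x)
}

#' Classify the relations between pairs of blocks of one protein state
#'
#' For each block pair the strongest applicable relation is reported, from
#' strongest to weakest: inclusion (one residue set contains the other),
#' overlap (non-empty intersection), contact (some residues of the two
#' blocks are sequence-adjacent) and interaction (some cross residue pair
#' forms a stable non-covalent interaction, `INT >= int_cut`).
#'
#' @param blocks a `commap_blocks` or plain named list of residue sets.
#' @param residues residue table (chain assignment for contacts).
#' @param int_matrix interaction strength matrix.
#' @param int_cut interaction strength threshold.
#' @return data.frame `block_a`, `block_b`, `relation`.
#' @export
classify_block_relations <- function(blocks, residues, int_matrix, int_cut) {
  bl <- if (inherits(blocks, "commap_blocks")) blocks$blocks else blocks
  nb <- length(bl)
  out <- list()
  chain <- residues$chain
  if (nb >= 2) {
    for (a in seq_len(nb - 1)) {
      for (b in seq(a + 1, nb)) {
        A <- bl[[a]]
        B <- bl[[b]]
        rel <- if (all(A %in% B) || all(B %in% A)) {
          "inclusion"
        } else if (length(intersect(A, B))) {
          "overlap"
        } else {
          adj <- outer(A, B, function(i, j) abs(i - j) == 1) &
            outer(chain[A], chain[B], "==")
          if (any(adj)) {
            "contact"
          } else if (any(int_matrix[A, B, drop = FALSE] >= int_cut)) {
            "interaction"
          } else {
            "none"
          }
        }
        out[[length(out) + 1]] <- data.frame(
          block_a = names(bl)[a], block_b = names(bl)[b], relation = rel,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(
      block_a = character(0), block_b = character(0),
      relation = character(0)
    ))
  }
  do.call(rbind, out)
}

#' Overlap coefficient between two residue sets
#'
#' Dice-style similarity: twice the intersection size over the sum of the
#' set sizes.
#'
#' @param a,b integer vectors of residue indices.
#' @return value in `[0, 1]`.
#' @export
block_overlap <- function(a, b) {
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Map communication blocks between two protein states
#'
#' Computes the full overlap matrix between the blocks of two states (e.g.
#' wild type and mutant) and reports counterpart pairs: blocks X and X' are
#' counterparts when each yields the maximum overlap with the other over
#' all blocks of the other state and the overlap exceeds 60 percent.
#'
#' @param blocks_a,blocks_b `commap_blocks` or named lists of residue sets.
#' @return object of class `commap_block_mapping`: `overlap` matrix and
#'   `counterparts` data.frame (`name_a`, `name_b`, `size_a`, `size_b`,
#'   `overlap`).
#' @export
map_blocks <- function(blocks_a, blocks_b) {
  ba <- if (inherits(blocks_a, "commap_blocks")) blocks_a$blocks else blocks_a
  bb <- if (inherits(blocks_b, "commap_blocks")) blocks_b$blocks else blocks_b
  o <- matrix(0, length(ba), length(bb), dimnames = list(names(ba), names(bb)))
  for (i in seq_along(ba)) {
    for (j in seq_along(bb)) o[i, j] <- block_overlap(ba[[i]], bb[[j]])
  }
  rows <- list()
  if (length(ba) && length(bb)) {
    for (i in seq_along(ba)) {
      j <- which.max(o[i, ])
      if (which.max(o[, j]) == i && o[i, j] > 0.60) {
        rows[[length(rows) + 1]] <- data.frame(
          name_a = names(ba)[i], name_b = names(bb)[j],
          size_a = length(ba[[i]]), size_b = length(bb[[j]]),
          overlap = o[i, j], stringsAsFactors = FALSE
        )
      }
    }
  }
  counterparts <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      name_a = character(0), name_b = character(0),
      size_a = integer(0), size_b = integer(0), overlap = numeric(0)
    )
  }
  structure(list(overlap = o, counterparts = counterparts),
    class = "commap_block_mapping"
  )
}

#' Identify secondary structure elements
#'
#' An SSE is a maximal run of at least `min_len` consecutive residues (in
#' one chain) sharing the same assigned secondary structure type among
#' alpha, beta and turn.
#'
#' @param ss a `commap_ss` persistence profile.
#' @param min_len minimum SSE length (default 3).
#' @return data.frame `label`, `type`, `start`, `end` (internal residue
#'   indices) with the member indices in attribute `members` (named list).
#' @export
identify_sses <- function(ss, min_len = 3L) {
  n <- nrow(ss)
  runs <- rle(paste(ss$type, ss$chain, sep = "|"))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  type <- sub("\\|.*", "", runs$values)
  keep <- runs$lengths >= min_len & type %in% c("alpha", "beta", "turn")
  cnt <- c(alpha = 0L, beta = 0L, turn = 0L)
  pre <- c(alpha = "H", beta = "S", turn = "T")
  out <- list()
  members <- list()
  for (k in which(keep)) {
    cnt[type[k]] <- cnt[type[k]] + 1L
    lab <- paste0(pre[type[k]], cnt[type[k]])
    out[[length(out) + 1]] <- data.frame(
      label = lab, type = type[k], start = starts[k], end = ends[k],
      stringsAsFactors = FALSE
    )
    members[[lab]] <- seq(starts[k], ends[k])
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(
      label = character(0), type = character(0),
      start = integer(0), end = integer(0)
    )
  }
  attr(res, "members") <- members
  res
}

#' Communicating segment pairs and their communication strengths
#'
#' For each pair (A, B) of SSEs: `PR_AB` is the proportion of residues of A
#' co-occurring with some residue of B in at least one communication
#' pathway (and symmetrically `PR_BA`); `Cont_AB` counts the unordered
#' cross residue pairs that are consecutive in some pathway; the
#' communication strength is `S_AB = PR_AB * PR_BA * Cont_AB`.  Pairs with
#' zero strength are omitted.
#'
#' @param sses output of [identify_sses()].
#' @param pathways a `commap_pathways` or a `commap_pcn` (whose unioned
#'   pathway edges and co-path pairs are used).
#' @return data.frame of class `commap_segment_pairs` with columns `sse_a`,
#'   `sse_b`, `pr_ab`, `pr_ba`, `cont`, `strength`; the linked residue
#'   subsets are kept in attribute `linked` (list per pair).
#' @export
segment_pairs <- function(sses, pathways) {
  copath <- pathways$copath
  edges <- if (inherits(pathways, "commap_pcn")) {
    pathways$pathway_edges
  } else {
    pathways$edges
  }
  members <- attr(sses, "members")
  labs <- names(members)
  emat <- matrix(FALSE, nrow(copath), ncol(copath))
  if (nrow(edges)) {
    emat[cbind(edges$i, edges$j)] <- TRUE
    emat <- emat | t(emat)
  }
  out <- list()
  linked <- list()
  if (length(labs) >= 2) {
    for (a in seq_len(length(labs) - 1)) {
      for (b in seq(a + 1, length(labs))) {
        A <- members[[a]]
        B <- members[[b]]
        la <- A[rowSums(copath[A, B, drop = FALSE]) > 0]
        lb <- B[rowSums(copath[B, A, drop = FALSE]) > 0]
        cont <- sum(emat[A, B])
        pr_ab <- length(la) / length(A)
        pr_ba <- length(lb) / length(B)
        s <- pr_ab * pr_ba * cont
        if (s > 0) {
          key <- paste(labs[a], labs[b], sep = "-")
          out[[length(out) + 1]] <- data.frame(
            sse_a = labs[a], sse_b = labs[b], pr_ab = pr_ab,
            pr_ba = pr_ba, cont = cont, strength = s,
            stringsAsFactors = FALSE
          )
          linked[[key]] <- list(a = la, b = lb)
        }
      }
    }
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(
      sse_a = character(0), sse_b = character(0), pr_ab = numeric(0),
      pr_ba = numeric(0), cont = integer(0), strength = numeric(0)
    )
  }
  attr(res, "linked") <- linked
  class(res) <- c("commap_segment_pairs", "data.frame")
  res
}
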