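fake_clique <- function(members) {
  structure(list(members = members, seed = members[1], mean_corr = 1),
    class = "commap_clique"
  )
}

fake_residues <- function(n) {
  data.frame(
    res_index = seq_len(n), resno = seq_len(n), insert = "",
    resid = "GLY", chain = "A", stringsAsFactors = FALSE
  )
}

fake_pathways <- function(n, edges, maxlen, copath_pairs = NULL) {
  ml <- matrix(0L, n, n)
  cpth <- matrix(FALSE, n, n)
  ed <- NULL
  if (length(maxlen)) {
    ed <- data.frame(
      i = sapply(edges, `[`, 1), j = sapply(edges, `[`, 2),
      max_path_len = as.integer(maxlen)
    )
    cpth[cbind(ed$i, ed$j)] <- TRUE
    cpth <- cpth | t(cpth)
  } else {
    ed <- data.frame(i = integer(0), j = integer(0), max_path_len = integer(0))
  }
  for (p in copath_pairs) {
    cpth[p[1], p[2]] <- cpth[p[2], p[1]] <- TRUE
  }
  structure(list(edges = ed, copath = cpth, n = n), class = "commap_pathways")
}

test_that("the PCN unions clique and pathway edges over replicates", {
  n <- 8
  res <- fake_residues(n)
  corr_hi <- matrix(1, n, n)
  pcn <- build_pcn(
    cliques = list(list(fake_clique(1:5)), list(fake_clique(4:8))),
    pathways = list(
      fake_pathways(n, list(c(1, 3)), 3L),
      fake_pathways(n, list(c(1, 3), c(2, 6)), c(5L, 2L))
    ),
    corr = list(corr_hi, corr_hi),
    corr_cut = list(0.5, 0.5),
    residues = res
  )
  blocks <- extract_blocks(pcn, "clique")
  expect_length(blocks$blocks, 1)
  expect_equal(blocks$blocks$A, 1:8) # replicate cliques overlap into one block

  # pathway edge present in one replicate only is present in the union,
  # with the maximum supporting length over replicates
  e13 <- pcn$pathway_edges[pcn$pathway_edges$i == 1 & pcn$pathway_edges$j == 3, ]
  expect_equal(e13$max_path_len, 5L)
  expect_true(any(pcn$pathway_edges$i == 2 & pcn$pathway_edges$j == 6))

  # no components at all: edgeless PCN
  empty <- build_pcn(list(list()), list(NULL), list(corr_hi), list(0.5), res)
  expect_equal(nrow(empty$clique_edges), 0)
  expect_equal(nrow(empty$pathway_edges), 0)
  expect_length(extract_blocks(empty, "clique")$blocks, 0)
})

test_that("block extraction matches a union-find oracle on random graphs", {
  set.seed(15)
  res <- fake_residues(20)
  corr_hi <- matrix(1, 20, 20)
  for (trial in 1:100) {
    ne <- sample(0:15, 1)
    edges <- if (ne) {
      t(replicate(ne, sort(sample(20, 2))))
    } else {
      matrix(integer(0), ncol = 2)
    }
    pw <- fake_pathways(
      20, split(edges, row(edges)),
      rep(4L, nrow(edges))
    )
    pcn <- build_pcn(list(list()), list(pw), list(corr_hi), list(0.5), res)
    got <- extract_blocks(pcn, "pathway")$blocks
    ref <- brute_components(20, unique(edges))
    ref <- Filter(function(x) length(x) >= 2, ref)
    expect_setequal(
      unname(vapply(got, paste, "", collapse = ",")),
      unname(vapply(ref, paste, "", collapse = ","))
    )
  }
})

test_that("path-length filtering precedes component extraction", {
  n <- 8
  pw <- fake_pathways(
    n, list(c(1, 3), c(3, 5), c(6, 8)),
    c(2L, 2L, 7L)
  )
  pcn <- build_pcn(list(list()), list(pw), list(matrix(1, n, n)), list(0.5),
    residues = fake_residues(n)
  )
  b6 <- extract_blocks(pcn, "pathway", min_path_len = 6)
  expect_length(b6$blocks, 1)
  expect_equal(b6$blocks$A, c(6, 8))

  # nesting: blocks at a larger threshold sit inside one block at a smaller
  set.seed(16)
  for (trial in 1:20) {
    ne <- sample(5:20, 1)
    edges <- t(replicate(ne, sort(sample(15, 2))))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    pw <- fake_pathways(
      15, split(edges, row(edges)),
      sample(2:9, nrow(edges), replace = TRUE)
    )
    pcn <- build_pcn(list(list()), list(pw), list(matrix(1, 15, 15)),
      list(0.5),
      residues = fake_residues(15)
    )
    b_lo <- extract_blocks(pcn, "pathway", min_path_len = 4)$blocks
    b_hi <- extract_blocks(pcn, "pathway", min_path_len = 7)$blocks
    for (hb in b_hi) {
      containers <- Filter(function(lb) all(hb %in% lb), b_lo)
      expect_length(containers, 1)
    }
  }
})

test_that("block relations pick the strongest applicable category", {
  res <- fake_residues(20)
  int <- matrix(0, 20, 20)
  int[2, 15] <- int[15, 2] <- 0.9
  rel <- function(a, b) {
    classify_block_relations(list(X = a, Y = b), res, int, 0.7)$relation
  }
  expect_equal(rel(1:10, 3:6), "inclusion")
  expect_equal(rel(1:5, 5:9), "overlap")
  expect_equal(rel(1:5, 6:9), "contact") # 5 and 6 sequence-adjacent
  expect_equal(rel(1:3, 14:16), "interaction") # INT(2,15) above cutoff
  expect_equal(rel(1:3, 18:20), "none")
})

test_that("block mapping reproduces the Dice overlap and counterpart rule", {
  expect_equal(block_overlap(1:11, 1:12), 2 * 11 / 23)
  expect_equal(round(100 * block_overlap(1:11, 1:12)), 96)

  a <- list(X = 1:11, Y = 30:40)
  b <- list(Xp = 1:12, Yp = 60:70)
  m <- map_blocks(a, b)
  expect_equal(m$overlap["X", "Xp"], 0.9565, tolerance = 1e-4)
  expect_equal(m$counterparts$name_a, "X")
  expect_equal(m$counterparts$name_b, "Xp")

  # disjoint blocks never map; identical blocks always do
  expect_equal(nrow(map_blocks(list(A = 1:5), list(B = 6:9))$counterparts), 0)
  ident <- map_blocks(list(A = 1:5), list(B = 1:5))
  expect_equal(ident$counterparts$overlap, 1)

  # the counterpart relation is a partial matching
  set.seed(17)
  for (trial in 1:20) {
    mk <- function() {
      k <- sample(2:5, 1)
      out <- lapply(seq_len(k), function(i) sample(40, sample(3:12, 1)))
      names(out) <- paste0("B", seq_len(k))
      out
    }
    cp <- map_blocks(mk(), mk())$counterparts
    expect_equal(anyDuplicated(cp$name_a), 0)
    expect_equal(anyDuplicated(cp$name_b), 0)
    expect_true(all(cp$overlap > 0.60 | nrow(cp) == 0))
  }
})

test_that("SSE identification requires at least three equal consecutive types", {
  mk_ss <- function(types) {
    data.frame(
      res_index = seq_along(types), resno = seq_along(types), chain = "A",
      p_alpha = as.numeric(types == "alpha"),
      p_beta = as.numeric(types == "beta"),
      p_turn = as.numeric(types == "turn"),
      type = types, stringsAsFactors = FALSE
    )
  }
  expect_equal(nrow(identify_sses(mk_ss(c("alpha", "alpha", "other", "other")))), 0)
  one <- identify_sses(mk_ss(rep("alpha", 10)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 1)
  expect_equal(one$end, 10)

  pat <- identify_sses(mk_ss(c(rep("alpha", 3), "turn", rep("alpha", 3))))
  expect_equal(pat$type, c("alpha", "alpha"))
  expect_equal(pat$label, c("H1", "H2"))
})

test_that("segment pair strengths follow S = PR_AB * PR_BA * Cont", {
  n <- 20
  types <- c(rep("alpha", 10), rep("other", 2), rep("alpha", 8))
  ss <- data.frame(
    res_index = 1:n, resno = 1:n, chain = "A",
    p_alpha = as.numeric(types == "alpha"), p_beta = 0, p_turn = 0,
    type = types, stringsAsFactors = FALSE
  )
  sses <- identify_sses(ss)
  expect_equal(sses$label, c("H1", "H2"))
  A <- 1:10
  B <- 13:20

  # 5 of A and 4 of B linked; 5 consecutive cross pairs
  cross_edges <- list(c(1, 13), c(2, 14), c(3, 15), c(4, 16), c(5, 16))
  pw <- fake_pathways(n, cross_edges, rep(3L, 5))
  sp <- segment_pairs(sses, pw)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$pr_ab, 0.5)
  expect_equal(sp$pr_ba, 0.5)
  expect_equal(sp$cont, 5)
  expect_equal(sp$strength, 1.25)

  # no cross pathway: the pair is omitted
  pw0 <- fake_pathways(n, list(c(1, 3)), 2L)
  expect_equal(nrow(segment_pairs(sses, pw0)), 0)

  # all residues linked through co-path pairs, 5 direct contacts: S = 5
  co_all <- c(
    lapply(A, function(a) c(a, 13)),
    lapply(B, function(b) c(1, b))
  )
  pw_all <- fake_pathways(n, cross_edges, rep(3L, 5), copath_pairs = co_all)
  sp_all <- segment_pairs(sses, pw_all)
  expect_equal(sp_all$strength, 5)
})
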