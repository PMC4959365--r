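# End-to-end analysis: descriptors -> thresholds -> components -> PCN ->
# blocks / segment pairs, per replicate, with results unioned into one
# network.  All stages are deterministic functions of the input ensembles.

.assign_type_row <- function(pa, pb, pt) {
  p <- c(alpha = pa, beta = pb, turn = pt)
  if (all(p == 0)) "other" else names(p)[which.max(p)]
}

# Frame-weighted combination of per-replicate persistence profiles.
combine_ss <- function(ss_list, weights) {
  w <- weights / sum(weights)
  p <- Reduce(`+`, Map(function(s, wi) {
    wi * cbind(s$p_alpha, s$p_beta, s$p_turn)
  }, ss_list, w))
  out <- ss_list[[1]]
  out$p_alpha <- p[, 1]
  out$p_beta <- p[, 2]
  out$p_turn <- p[, 3]
  out$type <- vapply(
    seq_len(nrow(p)),
    function(i) .assign_type_row(p[i, 1], p[i, 2], p[i, 3]), ""
  )
  out
}

#' Run the full communication mapping pipeline
#'
#' Executes, for each replicate ensemble: superposition, principal
#' component analysis and LFA correlations, seed selection, minimum
#' distance / communication propensity / interaction strength matrices,
#' secondary-structure persistence, threshold auto-tuning, clique growth
#' and pathway enumeration.  The per-replicate components are unioned into
#' a Protein Communication Network from which communication blocks (clique-
#' based and pathway-based), block relations and communicating segment
#' pairs are extracted.
#'
#' @param ensembles a `commap_ensemble` or list of them (replicates).
#' @param overrides named list overriding any of `corr_cut`, `cp_cut`,
#'   `int_cut`, `mpl_cut` (applied to every replicate).
#' @param interaction_class INT class used for pathways (default `"all"`).
#' @param hydrogens `"require"` or `"place"`, see [interaction_context()].
#' @param max_depth pathway enumeration cap, in residues.
#' @param min_path_len minimum supporting-path length for the default
#'   pathway-based blocks (default 4).
#' @param target_fraction variance fraction for the PCA modes.
#' @param output_dir if non-`NULL`, all result tables, the parameter
#'   report, the average conformation and the PyMOL scripts are written
#'   there.
#' @return object of class `commap_result` (a list; see elements).
#' @export
run_pipeline <- function(ensembles, overrides = list(),
                         interaction_class = "all",
                         hydrogens = c("require", "place"),
                         max_depth = 30L, min_path_len = 4L,
                         target_fraction = 0.8,
                         output_dir = NULL) {
  hydrogens <- match.arg(hydrogens)
  if (inherits(ensembles, "commap_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1)
  nres <- n_residues(ensembles[[1]])
  residues <- ensembles[[1]]$top$residues

  reps <- vector("list", length(ensembles))
  for (r in seq_along(ensembles)) {
    ens <- superpose(ensembles[[r]])
    modes <- compute_pca_modes(ens, target_fraction = target_fraction)
    corr <- compute_lfa_correlations(modes)
    seeds <- select_seeds(modes, corr, ens)
    dmin <- compute_min_distances(ens)
    cp <- compute_communication_propensity(ens)
    int_all <- compute_interaction_strengths(ens,
      class_filter = interaction_class, hydrogens = hydrogens
    )
    ss <- assign_secondary_structure(ens)
    params <- tune_parameters(corr, cp, int_all, ss, overrides = overrides)
    cliques <- build_cliques(seeds, corr, dmin, params$corr_cut)
    pathways <- enumerate_pathways(int_all, cp,
      int_cut = params$int_cut,
      cp_cut = params$cp_cut, max_depth = max_depth, residues = residues
    )
    reps[[r]] <- list(
      ensemble = ens, modes = modes, corr = corr, seeds = seeds,
      dist = dmin, cp = cp, int = int_all, ss = ss, params = params,
      cliques = cliques, pathways = pathways
    )
  }

  pcn <- build_pcn(
    cliques = lapply(reps, `[[`, "cliques"),
    pathways = lapply(reps, `[[`, "pathways"),
    corr = lapply(reps, `[[`, "corr"),
    corr_cut = lapply(reps, function(x) x$params$corr_cut),
    residues = residues
  )
  mpl <- overrides$mpl_cut
  mpl_curve <- NULL
  if (is.null(mpl)) {
    scan <- tryCatch(mpl_cut(pcn$pathway_edges, nres), error = function(e) NULL)
    if (!is.null(scan)) {
      mpl <- scan$mpl_cut
      mpl_curve <- scan$curve
    }
  }
  for (r in seq_along(reps)) {
    reps[[r]]$params$mpl_cut <- mpl
    reps[[r]]$params$mpl_curve <- mpl_curve
  }

  blocks_clique <- extract_blocks(pcn, "clique")
  blocks_pathway <- extract_blocks(pcn, "pathway", min_path_len = min_path_len)
  blocks_pathway_mpl <- if (!is.null(mpl)) {
    extract_blocks(pcn, "pathway", min_path_len = mpl)
  }
  int_union <- Reduce(pmax, lapply(reps, function(x) unclass(x$int)))
  int_cut_min <- min(vapply(reps, function(x) x$params$int_cut, 1))
  prefix <- function(p, bl) {
    if (length(bl)) paste0(p, names(bl)) else character(0)
  }
  all_blocks <- c(blocks_clique$blocks, blocks_pathway$blocks)
  names(all_blocks) <- c(
    prefix("C", blocks_clique$blocks),
    prefix("P", blocks_pathway$blocks)
  )
  relations <- classify_block_relations(
    all_blocks, residues, int_union, int_cut_min
  )
  ss_comb <- combine_ss(
    lapply(reps, `[[`, "ss"),
    vapply(reps, function(x) n_frames(x$ensemble), 1)
  )
  sses <- identify_sses(ss_comb)
  segments <- segment_pairs(sses, pcn)
  average <- average_conformation(reps[[1]]$ensemble)

  result <- structure(
    list(
      replicates = reps, pcn = pcn,
      blocks_clique = blocks_clique, blocks_pathway = blocks_pathway,
      blocks_pathway_mpl = blocks_pathway_mpl,
      relations = relations, ss = ss_comb, sses = sses,
      segments = segments, average = average, residues = residues,
      mpl_cut = mpl
    ),
    class = "commap_result"
  )
  if (!is.null(output_dir)) write_result_bundle(result, output_dir)
  result
}

#' @export
print.commap_result <- function(x, ...) {
  cat("Communication mapping of", nrow(x$residues), "residues from",
    length(x$replicates), "replicate(s)\n")
  print(x$pcn)
  cat(
    "Clique-based blocks: ", length(x$blocks_clique$blocks),
    "; pathway-based blocks (>=", x$blocks_pathway$min_path_len,
    " residues): ", length(x$blocks_pathway$blocks), "\n",
    sep = ""
  )
  cat("Communicating segment pairs:", nrow(x$segments), "\n")
  invisible(x)
}

# Per-residue block assignment table with author numbering.
blocks_table <- function(blocks, residues) {
  bl <- blocks$blocks
  rows <- lapply(names(bl), function(nm) {
    data.frame(
      res_index = bl[[nm]],
      resno = residues$resno[bl[[nm]]],
      chain = residues$chain[bl[[nm]]],
      kind = blocks$kind,
      min_path_len = blocks$min_path_len,
      label = nm, stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      res_index = integer(0), resno = integer(0), chain = character(0),
      kind = character(0), min_path_len = integer(0), label = character(0)
    ))
  }
  do.call(rbind, rows)
}

#' Write all pipeline outputs to a directory
#'
#' @param result a `commap_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- result$replicates[[1]]$ensemble$top
  for (r in seq_along(result$replicates)) {
    rep <- result$replicates[[r]]
    pre <- file.path(dir, sprintf("rep%d", r))
    write_matrix_csv(rep$corr, top, paste0(pre, "_corr.csv"))
    write_matrix_csv(rep$dist, top, paste0(pre, "_dist.csv"))
    write_matrix_csv(rep$cp, top, paste0(pre, "_cp.csv"))
    write_matrix_csv(rep$int, top, paste0(pre, "_int.csv"))
    utils::write.csv(rep$ss, paste0(pre, "_ss.csv"), row.names = FALSE)
    write_parameters_json(rep$params, paste0(pre, "_parameters.json"))
  }
  bt <- rbind(
    blocks_table(result$blocks_clique, result$residues),
    blocks_table(result$blocks_pathway, result$residues),
    if (!is.null(result$blocks_pathway_mpl)) {
      blocks_table(result$blocks_pathway_mpl, result$residues)
    }
  )
  utils::write.csv(bt, file.path(dir, "blocks.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      clique_block_sizes = lengths(result$blocks_clique$blocks),
      pathway_block_sizes = lengths(result$blocks_pathway$blocks),
      mpl_cut = result$mpl_cut,
      relations = result$relations
    ),
    file.path(dir, "blocks.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  utils::write.csv(as.data.frame(result$segments),
    file.path(dir, "segment_pairs.csv"),
    row.names = FALSE
  )
  write_pdb(result$average, file.path(dir, "average.pdb"))
  write_block_pml(result$blocks_clique, result$average,
    file.path(dir, "blocks_clique.pml"),
    pdb_file = "average.pdb"
  )
  write_block_pml(result$blocks_pathway, result$average,
    file.path(dir, "blocks_pathway.pml"),
    pdb_file = "average.pdb"
  )
  if (nrow(result$segments)) {
    for (k in seq_len(nrow(result$segments))) {
      write_segment_pml(
        result$sses, result$segments[k, ], result$pcn, result$average,
        file.path(dir, sprintf(
          "segments_%s_%s.pml",
          result$segments$sse_a[k], result$segments$sse_b[k]
        )),
        pdb_file = "average.pdb"
      )
    }
  }
  invisible(dir)
}
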