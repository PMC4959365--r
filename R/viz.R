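# PyMOL (.pml) script emitters: communication blocks and communicating
# segment pairs mapped onto the protein average conformation.

.clique_palette <- c(
  "skyblue", "blue", "deepteal", "slate", "lightblue", "density",
  "purpleblue", "teal"
)
.pathway_palette <- c(
  "red", "orange", "yelloworange", "firebrick", "salmon", "raspberry",
  "brightorange", "deepsalmon"
)

.resi_selection <- function(obj, residues, idx) {
  chains <- split(residues$resno[idx], residues$chain[idx])
  paste(vapply(names(chains), function(ch) {
    sprintf(
      "(%s and chain %s and resi %s)", obj, ch,
      paste(sort(unique(chains[[ch]])), collapse = "+")
    )
  }, ""), collapse = " or ")
}

.pml_header <- function(obj, pdb_file) {
  c(
    sprintf("load %s, %s", pdb_file, obj),
    sprintf("hide everything, %s", obj),
    sprintf("show cartoon, %s", obj),
    sprintf("set cartoon_trace_atoms, 1, %s", obj),
    sprintf("color white, %s", obj)
  )
}

.pml_distance <- function(obj, name, residues, i, j) {
  c(
    sprintf(
      "distance %s, (%s and chain %s and resi %d and name CA), (%s and chain %s and resi %d and name CA)",
      name, obj, residues$chain[i], residues$resno[i],
      obj, residues$chain[j], residues$resno[j]
    ),
    sprintf("color black, %s", name),
    sprintf("hide labels, %s", name)
  )
}

#' Emit a PyMOL script colouring communication blocks
#'
#' Block residues are coloured by block (blue tones for clique-based
#' blocks, warm tones for pathway-based blocks); residues not in any block
#' stay white.  Optional inter-block non-covalent interactions are drawn as
#' thick black lines between the C-alpha atoms of the residue pairs.
#'
#' @param blocks a `commap_blocks`.
#' @param average the average `commap_structure` (for author numbering).
#' @param file output path.
#' @param pdb_file the PDB file the script loads (written alongside by
#'   [write_result_bundle()]).
#' @param interactions optional data.frame with columns `i`, `j` (internal
#'   residue indices) of inter-block interacting pairs.
#' @return `file`, invisibly.
#' @export
write_block_pml <- function(blocks, average, file, pdb_file = "average.pdb",
                            interactions = NULL) {
  residues <- average$top$residues
  obj <- sub("\\.[^.]*$", "", basename(pdb_file))
  pal <- if (blocks$kind == "clique") .clique_palette else .pathway_palette
  lines <- .pml_header(obj, pdb_file)
  bl <- blocks$blocks
  for (k in seq_along(bl)) {
    lines <- c(lines, sprintf(
      "color %s, %s", pal[(k - 1) %% length(pal) + 1],
      .resi_selection(obj, residues, bl[[k]])
    ))
  }
  if (!is.null(interactions) && nrow(interactions)) {
    lines <- c(lines, "set dash_width, 4")
    for (k in seq_len(nrow(interactions))) {
      lines <- c(lines, .pml_distance(
        obj, sprintf("block_int%d", k), residues,
        interactions$i[k], interactions$j[k]
      ))
    }
  }
  writeLines(lines, file)
  invisible(file)
}

#' Emit a PyMOL script for one communicating segment pair
#'
#' The linked residues of the two segments are highlighted and every
#' pathway-based edge crossing the two segments is drawn as a thick black
#' line.
#'
#' @param sses output of [identify_sses()].
#' @param pair one row of a [segment_pairs()] table.
#' @param pathways the `commap_pcn` or `commap_pathways` providing the
#'   pathway edges.
#' @param average the average `commap_structure`.
#' @param file output path.
#' @param pdb_file the PDB file the script loads.
#' @return `file`, invisibly.
#' @export
write_segment_pml <- function(sses, pair, pathways, average, file,
                              pdb_file = "average.pdb") {
  residues <- average$top$residues
  obj <- sub("\\.[^.]*$", "", basename(pdb_file))
  members <- attr(sses, "members")
  A <- members[[pair$sse_a]]
  B <- members[[pair$sse_b]]
  edges <- if (inherits(pathways, "commap_pcn")) {
    pathways$pathway_edges
  } else {
    pathways$edges
  }
  lines <- .pml_header(obj, pdb_file)
  if (length(A)) {
    lines <- c(lines, sprintf("color marine, %s", .resi_selection(obj, residues, A)))
  }
  if (length(B)) {
    lines <- c(lines, sprintf("color violet, %s", .resi_selection(obj, residues, B)))
  }
  if (nrow(edges)) {
    cross <- (edges$i %in% A & edges$j %in% B) | (edges$i %in% B & edges$j %in% A)
    ce <- edges[cross, , drop = FALSE]
    if (nrow(ce)) lines <- c(lines, "set dash_width, 4")
    for (k in seq_len(nrow(ce))) {
      lines <- c(lines, .pml_distance(
        obj, sprintf("seg_link%d", k), residues, ce$i[k], ce$j[k]
      ))
    }
  }
  writeLines(lines, file)
  invisible(file)
}
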