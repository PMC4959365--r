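# Residue names accepted as protein when stripping solvent/ions on load.
.protein_resids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX", "CYM", "ASH", "GLH",
  "LYN", "MSE", "ACE", "NME", "NHE"
)

# Backbone atom names (heavy + amide/alpha hydrogens).
.backbone_elety <- c(
  "N", "CA", "C", "O", "OXT", "H", "HN", "H1", "H2", "H3",
  "HA", "HA2", "HA3"
)

infer_element <- function(elety) {
  first <- sub("^[0-9']*", "", elety)
  e <- toupper(substr(first, 1, 1))
  ifelse(e == "", "X", e)
}

#' Build a topology table from per-atom records
#'
#' The topology orders residues in file order, maps every atom to exactly one
#' residue and infers covalent bonds geometrically from a reference
#' conformation (bonds are only searched within a residue and between
#' sequence-adjacent residues).
#'
#' @param atoms data.frame with columns `elety`, `resid`, `chain`, `resno`
#'   and optionally `insert` and `eleno`.
#' @param ref_coords A x 3 matrix of reference coordinates used for bond
#'   inference, or `NULL` to skip bond inference.
#' @return An object of class `commap_topology` with elements `atoms`
#'   (per-atom table including contiguous `res_index`), `residues` and
#'   `bonds` (2-column matrix of atom indices).
#' @export
build_topology <- function(atoms, ref_coords = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  atoms$insert <- as.character(atoms$insert %||% rep("", nrow(atoms)))
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$chain <- as.character(atoms$chain %||% rep("A", nrow(atoms)))
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  atoms$eleno <- atoms$eleno %||% seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms$res_index <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  atoms$element <- infer_element(atoms$elety)
  atoms$backbone <- atoms$elety %in% .backbone_elety
  first <- !duplicated(atoms$res_index)
  residues <- data.frame(
    res_index = atoms$res_index[first],
    resno = atoms$resno[first],
    insert = atoms$insert[first],
    resid = atoms$resid[first],
    chain = atoms$chain[first],
    stringsAsFactors = FALSE
  )
  bonds <- if (is.null(ref_coords)) {
    matrix(integer(0), ncol = 2)
  } else {
    infer_bonds(atoms, ref_coords)
  }
  structure(
    list(atoms = atoms, residues = residues, bonds = bonds),
    class = "commap_topology"
  )
}

# Geometric bond inference: H-X <= 1.3 A, S involved <= 2.1 A, else <= 1.9 A.
# Restricted to atoms in the same or sequence-adjacent residues.
infer_bonds <- function(atoms, coords) {
  n <- nrow(atoms)
  out <- vector("list", n)
  for (i in seq_len(n - 1)) {
    j <- which(
      atoms$res_index > atoms$res_index[i] - 2L &
        atoms$res_index < atoms$res_index[i] + 2L
    )
    j <- j[j > i]
    if (!length(j)) next
    d <- sqrt(colSums((t(coords[j, , drop = FALSE]) - coords[i, ])^2))
    ei <- atoms$element[i]
    ej <- atoms$element[j]
    cut <- ifelse(ei == "H" | ej == "H", 1.3,
      ifelse(ei == "S" | ej == "S", 2.1, 1.9)
    )
    cut[ei == "H" & ej == "H"] <- 0 # never bond H-H
    hit <- j[d <= cut & d > 0.4]
    if (length(hit)) out[[i]] <- cbind(i, hit)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) m <- matrix(integer(0), ncol = 2)
  storage.mode(m) <- "integer"
  colnames(m) <- c("i", "j")
  m
}

new_ensemble <- function(xyz, top, replicate_id = "rep1", frame_times = NULL) {
  stopifnot(inherits(top, "commap_topology"))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) < 2) {
    stop("empty-ensemble error: an ensemble needs at least 2 frames")
  }
  if (ncol(xyz) != 3L * nrow(top$atoms)) {
    stop(
      "consistency error: trajectory has ", ncol(xyz) / 3,
      " atoms but topology has ", nrow(top$atoms)
    )
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  structure(
    list(
      xyz = xyz, top = top, replicate_id = replicate_id,
      frame_times = frame_times
    ),
    class = "commap_ensemble"
  )
}

#' @export
print.commap_ensemble <- function(x, ...) {
  cat(
    "Conformational ensemble '", x$replicate_id, "': ",
    nrow(x$xyz), " frames, ", nrow(x$top$atoms), " atoms, ",
    nrow(x$top$residues), " residues\n",
    sep = ""
  )
  invisible(x)
}

n_frames <- function(ens) nrow(ens$xyz)
n_residues <- function(ens) nrow(ens$top$residues)

# Atom indices of the C-alpha atoms, in residue order.  Errors if a standard
# residue lacks a CA.
ca_atoms <- function(top) {
  ca <- which(top$atoms$elety == "CA")
  if (!all(top$residues$res_index %in% top$atoms$res_index[ca])) {
    stop("every residue must have a C-alpha atom")
  }
  ca[order(top$atoms$res_index[ca])]
}

#' Load a conformational ensemble
#'
#' Reads a multi-model PDB, or a trajectory (DCD, AMBER NetCDF, AMBER
#' mdcrd) together with a topology file (PDB or prmtop).  Non-protein atoms
#' (solvent, ions, ligands) are dropped; hydrogens are retained.
#' Coordinates are expressed in Angstrom.
#'
#' @param paths character vector of coordinate files (concatenated in order).
#' @param topology_path PDB or prmtop file providing the topology; not needed
#'   for multi-model PDB input.
#' @param frame_range optional `c(first, last)` 1-based inclusive frame
#'   window, applied after concatenation.
#' @param stride keep every `stride`-th frame of the selected window.
#' @param replicate_id label attached to the ensemble.
#' @return A list with elements `ensemble` (`commap_ensemble`) and `top`
#'   (`commap_topology`, identical to `ensemble$top`).
#' @export
load_ensemble <- function(paths, topology_path = NULL, frame_range = NULL,
                          stride = 1L, replicate_id = NULL) {
  stopifnot(length(paths) >= 1)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  ext <- tolower(tools::file_ext(paths[1]))
  if (ext %in% c("xtc", "trr")) {
    stop(
      "format error: no reader is available for .", ext, " files; ",
      "supported formats are multi-model PDB, DCD, AMBER NetCDF and mdcrd"
    )
  }
  if (ext %in% c("pdb", "ent")) {
    mods <- lapply(paths, function(p) {
      pdb <- tryCatch(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE),
        error = function(e) stop("format error reading ", p, ": ", conditionMessage(e))
      )
      pdb
    })
    nats <- vapply(mods, function(p) nrow(p$atom), 1L)
    if (length(unique(nats)) != 1) {
      stop("consistency error: input PDB files differ in atom count")
    }
    xyz <- do.call(rbind, lapply(mods, function(p) {
      if (is.matrix(p$xyz)) p$xyz else matrix(p$xyz, nrow = 1)
    }))
    atoms <- mods[[1]]$atom[, c("eleno", "elety", "resid", "chain", "resno", "insert")]
  } else {
    if (is.null(topology_path)) {
      stop("a topology file (PDB or prmtop) is required for trajectory input")
    }
    atoms <- read_topology_atoms(topology_path)
    xyz <- do.call(rbind, lapply(paths, read_traj_xyz, natom = nrow(atoms)))
    if (ncol(xyz) != 3L * nrow(atoms)) {
      stop(
        "consistency error: trajectory atom count ", ncol(xyz) / 3,
        " does not match topology (", nrow(atoms), ")"
      )
    }
  }
  atoms$insert[is.na(atoms$insert)] <- ""
  keep <- atoms$resid %in% .protein_resids
  if (!any(keep)) stop("no protein atoms found in input")
  xyz <- xyz[, atom2xyz_inds(which(keep)), drop = FALSE]
  atoms <- atoms[keep, , drop = FALSE]

  nf <- nrow(xyz)
  if (!is.null(frame_range)) {
    stopifnot(length(frame_range) == 2)
    if (frame_range[1] < 1 || frame_range[2] > nf || frame_range[1] > frame_range[2]) {
      stop("frame_range [", frame_range[1], ", ", frame_range[2],
        "] outside available frames (1..", nf, ")",
        sep = ""
      )
    }
    xyz <- xyz[seq(frame_range[1], frame_range[2]), , drop = FALSE]
  }
  xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
  if (nrow(xyz) == 0) stop("empty-ensemble error: zero frames selected")
  top <- build_topology(atoms, ref_coords = xyz2mat(xyz[1, ]))
  ens <- new_ensemble(xyz, top,
    replicate_id = replicate_id %||% basename(paths[1])
  )
  list(ensemble = ens, top = top)
}

read_topology_atoms <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    pdb$atom[, c("eleno", "elety", "resid", "chain", "resno", "insert")]
  } else if (ext %in% c("prmtop", "parm7", "top")) {
    pt <- bio3d::read.prmtop(path)
    natom <- length(pt$ATOM_NAME)
    rptr <- pt$RESIDUE_POINTER
    rlab <- pt$RESIDUE_LABEL
    resno <- rep(seq_along(rptr), diff(c(rptr, natom + 1L)))
    data.frame(
      eleno = seq_len(natom), elety = trimws(pt$ATOM_NAME),
      resid = trimws(rlab)[resno], chain = "A", resno = resno,
      insert = "", stringsAsFactors = FALSE
    )
  } else {
    stop("format error: unsupported topology format '.", ext, "'")
  }
}

read_traj_xyz <- function(path, natom) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    bio3d::read.dcd(path, verbose = FALSE)
  } else if (ext %in% c("nc", "ncdf", "netcdf")) {
    if (!requireNamespace("ncdf4", quietly = TRUE)) {
      stop("reading AMBER NetCDF requires the 'ncdf4' package")
    }
    bio3d::read.ncdf(path)
  } else if (ext %in% c("crd", "mdcrd", "x")) {
    read_mdcrd(path, natom)
  } else {
    stop("format error: unsupported trajectory format '.", ext, "'")
  }
}

# Minimal AMBER ASCII mdcrd reader: title line then whitespace-separated
# coordinates, 3*natom per frame, with an optional 3-number box line after
# each frame (auto-detected from the total count).
read_mdcrd <- function(path, natom) {
  txt <- readLines(path, warn = FALSE)
  nums <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(paste(txt[-1], collapse = " ")), "\\s+")
  )))
  nums <- nums[!is.na(nums)]
  per <- 3L * natom
  if (length(nums) %% per == 0) {
    nf <- length(nums) %/% per
    m <- matrix(nums, nrow = nf, byrow = TRUE)
  } else if (length(nums) %% (per + 3L) == 0) {
    nf <- length(nums) %/% (per + 3L)
    m <- matrix(nums, nrow = nf, byrow = TRUE)[, seq_len(per), drop = FALSE]
  } else {
    stop("format error: mdcrd length not a multiple of 3*natom")
  }
  m
}

#' Superpose an ensemble on an iteratively refined mean structure
#'
#' Each frame is least-squares fitted (Kabsch) on the selected atoms to the
#' ensemble mean; the mean is recomputed and the fit repeated until the mean
#' moves by less than `tol` (max 10 iterations).  Intra-frame geometry is
#' unchanged.
#'
#' @param ens a `commap_ensemble`.
#' @param selection atom indices used for fitting (default: all C-alpha).
#' @param tol convergence tolerance on the mean structure, in Angstrom.
#' @return the superposed ensemble.
#' @export
superpose <- function(ens, selection = NULL, tol = 1e-6) {
  stopifnot(inherits(ens, "commap_ensemble"))
  sel <- selection %||% ca_atoms(ens$top)
  if (length(sel) < 3) {
    stop("underdetermined-fit error: need at least 3 atoms to superpose")
  }
  inds <- atom2xyz_inds(sel)
  ref <- colMeans(ens$xyz)
  fitted <- ens$xyz
  for (iter in 1:10) {
    fitted <- bio3d::fit.xyz(
      fixed = ref, mobile = ens$xyz,
      fixed.inds = inds, mobile.inds = inds
    )
    newmean <- colMeans(fitted)
    delta <- max(abs(newmean[inds] - ref[inds]))
    ref <- newmean
    if (delta < tol) break
  }
  ens$xyz <- fitted
  ens
}

#' Average conformation of a superposed ensemble
#'
#' @param ens a superposed `commap_ensemble`.
#' @return a `commap_structure` (per-atom arithmetic mean of coordinates).
#' @export
average_conformation <- function(ens) {
  stopifnot(inherits(ens, "commap_ensemble"))
  structure(list(xyz = colMeans(ens$xyz), top = ens$top),
    class = "commap_structure"
  )
}

#' Per-residue C-alpha root mean square fluctuation
#'
#' @param ens a superposed `commap_ensemble`.
#' @return numeric vector of RMSF values (Angstrom), one per residue.
#' @export
ca_rmsf <- function(ens) {
  inds <- atom2xyz_inds(ca_atoms(ens$top))
  x <- ens$xyz[, inds, drop = FALSE]
  dev2 <- sweep(x, 2, colMeans(x))^2
  percoord <- colMeans(dev2)
  sqrt(colSums(matrix(percoord, nrow = 3)))
}

#' Write a structure or an ensemble as a (multi-model) PDB file
#'
#' @param x a `commap_structure` or `commap_ensemble`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(x, file) {
  top <- x$top
  xyz <- if (inherits(x, "commap_ensemble")) x$xyz else matrix(x$xyz, nrow = 1)
  con <- file(file, "w")
  on.exit(close(con))
  multi <- nrow(xyz) > 1
  for (f in seq_len(nrow(xyz))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- xyz2mat(xyz[f, ])
    a <- top$atoms
    name4 <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
      sprintf("%-4s", a$elety)
    )
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, name4, a$resid, a$chain, a$resno,
      ifelse(a$insert == "", " ", a$insert),
      m[, 1], m[, 2], m[, 3], 1, 0, a$element
    ), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
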