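# Synthetic conformational ensembles with known ground truth.
#
# The generators build small C-alpha (or minimal-backbone) pseudo-proteins
# whose statistical structure matches what the analysis assumes: locally
# concerted fluctuations within rigid domains, an anti-correlated
# inter-domain hinge, persistent short-range contacts, ideal helical
# hydrogen bonding, and exactly prescribed hydrogen-bond geometries.

.make_ca_topology <- function(n, resid = "GLY", chain = "A") {
  build_topology(
    data.frame(
      eleno = seq_len(n), elety = "CA", resid = resid, chain = chain,
      resno = seq_len(n), insert = "", stringsAsFactors = FALSE
    ),
    ref_coords = NULL
  )
}

# Zigzag C-alpha trace: consecutive residues 3.5 A apart (inside the clique
# extension cutoff), second neighbours 3.8 A apart (inside the hydrophobic
# contact cutoff but outside the clique cutoff), all further neighbours
# beyond 3.9 A.
.zigzag_trace <- function(n, origin = c(0, 0, 0)) {
  dx <- 1.9
  dy <- sqrt(3.5^2 - dx^2)
  cbind(
    origin[1] + (seq_len(n) - 1) * dx,
    origin[2] + (seq_len(n) %% 2) * dy,
    origin[3]
  )
}

#' Two-domain synthetic ensemble
#'
#' Generates a C-alpha pseudo-protein made of two spatially separated
#' domains (zigzag traces 12 A apart).  Per frame, each domain carries (i)
#' locally concerted motions: every pair of consecutive residues shares a
#' Gaussian displacement of amplitude `local_amplitude` along a fixed random
#' direction, (ii) an anti-correlated rigid hinge translation of amplitude
#' `hinge_amplitude` (the two domains move in opposite directions), and
#' (iii) independent thermal jitter of standard deviation `sigma` on every
#' coordinate.  Within-domain C-alpha distance variances are therefore much
#' smaller than cross-domain variances, consecutive residues fluctuate in a
#' concerted way, and the domains never approach each other.
#'
#' @param n_residues total residue count (default 60).
#' @param n_frames frames to generate (default 1000).
#' @param sigma thermal jitter, Angstrom (default 0.1).
#' @param domains list of two residue index vectors partitioning
#'   `1:n_residues` (default: first and second half).
#' @param local_amplitude amplitude of the concerted local motions,
#'   Angstrom (default 0.5).
#' @param hinge_amplitude amplitude of the anti-correlated hinge,
#'   Angstrom (default 0.5).
#' @param seed RNG seed (default 1); the output is bit-for-bit reproducible
#'   for a fixed seed.
#' @return a `commap_ensemble` with the domain partition in attribute
#'   `domains`.
#' @export
make_two_domain_ensemble <- function(n_residues = 60L, n_frames = 1000L,
                                     sigma = 0.1,
                                     domains = NULL,
                                     local_amplitude = 0.5,
                                     hinge_amplitude = 0.5,
                                     seed = 1L) {
  domains <- domains %||% list(
    seq_len(floor(n_residues / 2)),
    seq(floor(n_residues / 2) + 1L, n_residues)
  )
  stopifnot(setequal(unlist(domains), seq_len(n_residues)))
  set.seed(seed)
  base <- matrix(0, n_residues, 3)
  base[domains[[1]], ] <- .zigzag_trace(length(domains[[1]]))
  base[domains[[2]], ] <- .zigzag_trace(length(domains[[2]]), origin = c(0, 0, 12))

  u_hinge <- unitv(stats::rnorm(3))
  windows <- list()
  for (d in seq_along(domains)) {
    dm <- sort(domains[[d]])
    consec <- dm[which(diff(dm) == 1L)]
    for (i in consec) {
      windows[[length(windows) + 1]] <- list(
        res = c(i, i + 1L),
        dir = unitv(stats::rnorm(3))
      )
    }
  }
  hsign <- rep(1, n_residues)
  hsign[domains[[2]]] <- -1

  xyz <- matrix(0, n_frames, 3L * n_residues)
  for (f in seq_len(n_frames)) {
    disp <- matrix(stats::rnorm(3L * n_residues, sd = sigma), n_residues, 3)
    s <- stats::rnorm(1)
    disp <- disp + hinge_amplitude * s * outer(hsign, u_hinge)
    for (w in windows) {
      a <- stats::rnorm(1, sd = local_amplitude)
      disp[w$res, ] <- disp[w$res, ] + rep(a * w$dir, each = 2)
    }
    xyz[f, ] <- mat2xyz(base + disp)
  }
  ens <- new_ensemble(xyz, .make_ca_topology(n_residues),
    replicate_id = paste0("twodomain_seed", seed)
  )
  attr(ens, "domains") <- domains
  ens
}

# Ideal backbone internal coordinates.
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

# Ideal polyalanine-like backbone (N, CA, C, O + amide H) for given phi/psi.
.ideal_backbone <- function(n, phi, psi) {
  g <- .bb_geom
  N <- matrix(0, n, 3)
  CA <- matrix(0, n, 3)
  C <- matrix(0, n, 3)
  O <- matrix(0, n, 3)
  H <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n, g$ang_ca_c_n, psi)
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca, g$ang_c_n_ca, g$omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c, g$ang_n_ca_c, phi)
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, psi + 180)
  }
  for (i in seq(2, n)) {
    H[i, ] <- N[i, ] + unitv(unitv(N[i, ] - C[i - 1, ]) + unitv(N[i, ] - CA[i, ]))
  }
  list(N = N, CA = CA, C = C, O = O, H = H)
}

#' Ideal alpha-helix ensemble
#'
#' Builds an ideal helical backbone (phi = -57, psi = -47 degrees; N, CA,
#' C, O atoms plus backbone amide hydrogens placed 1.0 A from N along the
#' C'(-1)-N-CA bisector) and replicates it over frames with optional
#' Gaussian thermal jitter.
#'
#' @param n_residues helix length (default 20).
#' @param n_frames frames to generate (default 200).
#' @param sigma thermal jitter, Angstrom (default 0.05).
#' @param phi,psi backbone dihedrals in degrees.
#' @param seed RNG seed (default 1).
#' @return a `commap_ensemble`.
#' @export
make_helix_ensemble <- function(n_residues = 20L, n_frames = 200L,
                                sigma = 0.05, phi = -57, psi = -47,
                                seed = 1L) {
  set.seed(seed)
  bb <- .ideal_backbone(n_residues, phi, psi)
  rows <- list()
  coords <- list()
  for (i in seq_len(n_residues)) {
    nm <- c("N", "CA", "C", "O")
    crd <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    if (i > 1) {
      nm <- c(nm, "H")
      crd <- rbind(crd, bb$H[i, ])
    }
    rows[[i]] <- data.frame(
      eleno = NA, elety = nm, resid = "ALA", chain = "A", resno = i,
      insert = "", stringsAsFactors = FALSE
    )
    coords[[i]] <- crd
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  base <- do.call(rbind, coords)
  top <- build_topology(atoms, ref_coords = base)
  xyz <- matrix(0, n_frames, 3L * nrow(base))
  for (f in seq_len(n_frames)) {
    xyz[f, ] <- mat2xyz(base + matrix(
      stats::rnorm(length(base), sd = sigma),
      nrow(base), 3
    ))
  }
  new_ensemble(xyz, top, replicate_id = paste0("helix_seed", seed))
}

#' Construct an exact hydrogen-bond geometry
#'
#' Builds a minimal donor / hydrogen / acceptor / antecedent arrangement
#' with the requested donor-acceptor distance, hydrogen-acceptor distance
#' and D-H-A, H-A-AA and D-A-AA angles.  The donor (N) and its hydrogen
#' form residue 1; the acceptor (O) and its antecedent (C, 1.5 A from the
#' acceptor) form residue 2.  The covalent D-H and A-AA bonds are declared
#' explicitly in the topology so the geometry is free to take any value.
#'
#' @param d_da donor-acceptor distance, Angstrom.
#' @param d_ha hydrogen-acceptor distance, Angstrom.
#' @param angles length-3 vector: D-H-A, H-A-AA and D-A-AA angles in
#'   degrees.
#' @return a `commap_structure`.
#' @export
make_hbond_geometry <- function(d_da = 3.5, d_ha = 2.0,
                                angles = c(120, 120, 120)) {
  stopifnot(length(angles) == 3)
  dha <- angles[1] * pi / 180
  A <- c(0, 0, 0)
  D <- c(d_da, 0, 0)
  disc <- d_ha^2 * cos(dha)^2 - d_ha^2 + d_da^2
  if (disc < 0) stop("infeasible D-H-A triangle for the requested geometry")
  dh <- d_ha * cos(dha) + sqrt(disc)
  x <- (d_da^2 + d_ha^2 - dh^2) / (2 * d_da)
  if (d_ha^2 - x^2 < -1e-9) stop("infeasible D-H-A triangle for the requested geometry")
  y <- sqrt(max(d_ha^2 - x^2, 0))
  H <- c(x, y, 0)
  u_d <- unitv(D - A)
  u_h <- unitv(H - A)
  cth <- sum(u_d * u_h)
  rhs <- c(cos(angles[3] * pi / 180), cos(angles[2] * pi / 180))
  ab <- solve(matrix(c(1, cth, cth, 1), 2), rhs)
  vplane <- ab[1] * u_d + ab[2] * u_h
  rest <- 1 - sum(vplane^2)
  if (rest < -1e-9) stop("infeasible antecedent direction for the requested angles")
  v <- vplane + sqrt(max(rest, 0)) * unitv(pracma_cross(u_d, u_h))
  AA <- A + 1.5 * v
  atoms <- data.frame(
    eleno = 1:4, elety = c("N", "H", "O", "C"),
    resid = c("GLY", "GLY", "GLY", "GLY"), chain = "A",
    resno = c(1L, 1L, 2L, 2L), insert = "", stringsAsFactors = FALSE
  )
  top <- build_topology(atoms, ref_coords = NULL)
  top$bonds <- matrix(c(1L, 2L, 3L, 4L), ncol = 2, byrow = TRUE,
    dimnames = list(NULL, c("i", "j"))
  )
  structure(
    list(xyz = mat2xyz(rbind(D, H, A, AA)), top = top),
    class = "commap_structure"
  )
}
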