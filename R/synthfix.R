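# Synthetic inputs with known ground truth: ideal helices, aromatic ligand
# poses, forward-modelled peak lists, tensor-generated RDCs. Every generator
# is a pure function of its spec (seeded determinism); defaults describe the
# idealized forward-model null in which the only proton CSP source is the
# ligand ring current.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Fixture specification
#'
#' Bundle of parameters controlling all synthetic generators. Helix geometry
#' is parameterised by backbone dihedrals: the defaults (phi -57, psi -47
#' degrees) realize the canonical alpha-helix with ~1.5 Angstrom rise and
#' ~100 degree twist per residue. Noise defaults are zero — the generators'
#' primary role is the exact forward-model null; turn noise on explicitly
#' for robustness studies.
#'
#' @param n_residues Helix length (>= 5).
#' @param phi,psi Backbone dihedrals in degrees.
#' @param n_rings Number of benzene rings in the ligand (1 = benzene-like,
#'   2 = biphenyl-like).
#' @param ligand_position Centroid of the first ring (3-vector, Angstrom);
#'   ignored when `target_residue` is set.
#' @param ligand_axis Ring normal direction; ignored when `target_residue`
#'   is set.
#' @param target_residue Residue number near whose amide proton the ligand
#'   is placed: the first-ring centroid sits `target_distance` from that
#'   proton along the outward radial direction of the protein, ring plane
#'   perpendicular to it — the geometry of maximal ring-current shift at
#'   the target proton.
#' @param target_distance Proton-to-centroid distance in Angstrom
#'   (default 4).
#' @param perturbed_residues Residue numbers receiving an injected
#'   "conformational change" CSP in the bound peak list.
#' @param inject_ppm Injected proton CSP in ppm (>= 0, default 0.3).
#' @param noise_ppm Gaussian noise s.d. on bound-state proton shifts (ppm).
#' @param noise_hz Gaussian noise s.d. on synthetic RDCs (Hz).
#' @param seed Integer RNG seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 60L, phi = -57, psi = -47,
                         n_rings = 2L,
                         ligand_position = c(0, 0, 0),
                         ligand_axis = c(0, 0, 1),
                         target_residue = NULL, target_distance = 4,
                         perturbed_residues = integer(0), inject_ppm = 0.3,
                         noise_ppm = 0, noise_hz = 0, seed = 42L) {
  if (n_residues < 5L) .ringcsp_error("n_residues must be >= 5",
                                      "ringcsp_bad_input")
  if (!(n_rings %in% 1:2)) .ringcsp_error("n_rings must be 1 or 2",
                                          "ringcsp_bad_input")
  if (inject_ppm < 0) .ringcsp_error("inject_ppm must be >= 0",
                                     "ringcsp_bad_input")
  structure(list(n_residues = as.integer(n_residues), phi = phi, psi = psi,
                 n_rings = as.integer(n_rings),
                 ligand_position = ligand_position, ligand_axis = ligand_axis,
                 target_residue = target_residue,
                 target_distance = target_distance,
                 perturbed_residues = as.integer(perturbed_residues),
                 inject_ppm = inject_ppm, noise_ppm = noise_ppm,
                 noise_hz = noise_hz, seed = as.integer(seed)),
            class = "fixture_spec")
}

# Place atom D given A-B-C, |CD|, angle(BCD) and dihedral(ABCD), degrees.
.nerf_place <- function(a, b, c, length, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- length * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d2
}

#' Ideal helix protein
#'
#' Poly-alanine backbone (N, CA, C, O) built from ideal internal coordinates
#' (bond lengths 1.458/1.525/1.329 Angstrom, standard angles, omega 180)
#' with the spec's phi/psi dihedrals, then amide protons from
#' [build_amide_protons]. Deterministic: no randomness involved. Residues
#' numbered 1..n, chain A; the N-terminal residue carries no amide proton.
#'
#' @param spec A [fixture_spec].
#' @return A `protein_structure`.
#' @export
make_helix_protein <- function(spec = fixture_spec()) {
  n <- spec$n_residues
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_CNCa <- 121.7; a_NCaC <- 111.2; a_CaCN <- 116.2; a_CaCO <- 120.8
  N <- matrix(NA_real_, n, 3L); CA <- N; C <- N; O <- N
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(b_NCa, 0, 0)
  th <- a_NCaC * pi / 180
  C[1L, ] <- CA[1L, ] + b_CaC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- .nerf_place(N[i, ], CA[i, ], C[i, ], b_CN, a_CaCN, spec$psi)
    CA[i + 1L, ] <- .nerf_place(CA[i, ], C[i, ], N[i + 1L, ], b_NCa, a_CNCa, 180)
    C[i + 1L, ] <- .nerf_place(C[i, ], N[i + 1L, ], CA[i + 1L, ], b_CaC,
                               a_NCaC, spec$phi)
    O[i, ] <- .nerf_place(N[i + 1L, ], CA[i, ], C[i, ], b_CO, a_CaCO, 180)
  }
  O[n, ] <- .nerf_place(N[n, ], CA[n, ], C[n, ], b_CO, a_CaCO, spec$psi + 180)
  per <- function(xyz, nm) {
    data.frame(name = nm, element = substr(nm, 1L, 1L), chain = "A",
               resno = seq_len(n), resname = "ALA",
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(per(N, "N"), per(CA, "CA"), per(C, "C"), per(O, "O"))
  atoms <- atoms[order(atoms$resno), ]
  rownames(atoms) <- NULL
  st <- structure(list(source_id = "synthetic-helix", model_index = 1L,
                       atoms = atoms, amides = .amides_from_atoms(atoms)),
                  class = "protein_structure")
  build_amide_protons(st)
}

.regular_hexagon <- function(cc = 1.39) {
  ang <- (seq_len(6L) - 1L) * pi / 3
  cbind(cc * cos(ang), cc * sin(ang), 0)
}

#' Aromatic ligand pose
#'
#' Ideal benzene hexagon(s) (C-C 1.39 Angstrom) in a plane; with
#' `n_rings = 2` the second ring is coaxial, para-linked at 1.48 Angstrom
#' (a biphenyl scaffold, the classic fragment chemotype), plus a para
#' fluorine and a carboxylate carbon so the molecule is not bare rings.
#' Placement: either explicit `ligand_position`/`ligand_axis` from the spec,
#' or — when `target_residue` is set and a protein is supplied — the first
#' ring centroid sits `target_distance` from that residue's amide proton
#' along the protein's outward radial direction, ring plane perpendicular
#' to it. Rings are perceived before returning.
#'
#' @param spec A [fixture_spec].
#' @param protein Optional `protein_structure` (required for
#'   `target_residue` placement).
#' @return A `ligand_pose` with rings perceived.
#' @export
make_ring_pose <- function(spec = fixture_spec(), protein = NULL) {
  hex1 <- .regular_hexagon()
  coords <- hex1
  names_ <- sprintf("C%d", 1:6)
  if (spec$n_rings == 2L) {
    hex2 <- sweep(.regular_hexagon(), 2L, c(2 * 1.39 + 1.48, 0, 0), "+")
    coords <- rbind(coords, hex2)
    names_ <- c(names_, sprintf("C%d", 7:12))
    # para F on the far ring, carboxyl C on the near ring
    coords <- rbind(coords, c(2 * 1.39 + 1.48 + 1.39 + 1.35, 0, 0),
                    c(-(1.39 + 1.48), 0, 0))
    names_ <- c(names_, "F1", "C13")
    elements <- c(rep("C", 12L), "F", "C")
  } else {
    coords <- rbind(coords, c(1.39 + 1.48, 0, 0))
    names_ <- c(names_, "C7")
    elements <- rep("C", 7L)
  }
  axis <- .unit(spec$ligand_axis)
  pos <- spec$ligand_position
  if (!is.null(spec$target_residue)) {
    if (is.null(protein)) {
      .ringcsp_error("target_residue placement needs a protein",
                     "ringcsp_bad_input")
    }
    key <- residue_key("A", spec$target_residue)
    am <- protein$amides[key, ]
    if (is.na(am$hx)) {
      .ringcsp_error(sprintf("residue %s has no amide proton", key),
                     "ringcsp_bad_input")
    }
    # outward radial direction: away from the protein long axis at this H,
    # so the target proton sits alone on the ring axis and no other amide
    # comes closer than the target distance
    h <- c(am$hx, am$hy, am$hz)
    ncoords <- as.matrix(protein$amides[, c("nx", "ny", "nz")])
    cen <- colMeans(ncoords)
    ax <- .unit(svd(sweep(ncoords, 2L, cen))$v[, 1L])
    rad <- (h - cen) - sum((h - cen) * ax) * ax
    axis <- .unit(rad)
    pos <- h + spec$target_distance * axis
  }
  # rotate local z onto the axis
  z <- c(0, 0, 1)
  if (abs(sum(z * axis)) > 1 - 1e-12) {
    R <- if (sum(z * axis) > 0) diag(3L) else diag(c(1, -1, -1))
  } else {
    rotax <- .cross3(z, axis)
    ang <- acos(sum(z * axis)) * 180 / pi
    R <- rotation_matrix(rotax, ang)
  }
  xyz <- sweep(coords %*% t(R), 2L, pos, "+")
  atoms <- data.frame(name = names_, element = elements,
                      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                      stringsAsFactors = FALSE)
  pose <- structure(list(pose_id = 1L, atoms = atoms, rings = list(),
                         cluster_id = NA_integer_, binding_energy = NA_real_),
                    class = "ligand_pose")
  perceive_aromatic_rings(pose)
}

#' Jittered pose ensemble
#'
#' Convenience generator for ensemble-level code paths: replicates of
#' [make_ring_pose] with random small rigid displacements, cluster labels
#' and binding energies in the fragment-typical -5.7 to -4.3 kcal/mol
#' range. Deterministic for a fixed spec seed.
#'
#' @param spec A [fixture_spec].
#' @param protein Optional protein for target placement.
#' @param n_poses Number of poses.
#' @param n_clusters Number of cluster labels to assign.
#' @param jitter_sd Translation s.d. in Angstrom (default 0.5).
#' @return List of `ligand_pose` objects with `pose_id` 1..n.
#' @export
make_pose_ensemble <- function(spec = fixture_spec(), protein = NULL,
                               n_poses = 20L, n_clusters = 3L,
                               jitter_sd = 0.5) {
  base <- make_ring_pose(spec, protein)
  .with_seed(spec$seed, {
    lapply(seq_len(n_poses), function(i) {
      R <- rotation_matrix(stats::rnorm(3L), stats::runif(1L, 0, 15))
      cen <- colMeans(as.matrix(base$atoms[, c("x", "y", "z")]))
      p <- rigid_transform(base, diag(3L), -cen)
      p <- rigid_transform(p, R, cen + stats::rnorm(3L, 0, jitter_sd))
      p$pose_id <- i
      p$cluster_id <- as.integer((i - 1L) %% n_clusters + 1L)
      p$binding_energy <- stats::runif(1L, -5.7, -4.3)
      p$rings <- NULL
      perceive_aromatic_rings(p)
    })
  })
}

#' Forward-modelled peak lists
#'
#' Free-state list with fixed smooth baseline shifts; bound-state list equal
#' to baseline plus the signed ring-current shift of the supplied pose at
#' each amide proton, plus optional Gaussian noise, plus the injected
#' perturbation on `perturbed_residues` (added with the sign of the local
#' ring-current shift so the induced CSP magnitude is exactly the ring
#' contribution plus the injection). Nitrogen shifts are copied unchanged:
#' the ring model predicts proton shifts only.
#'
#' @param protein A `protein_structure` (amide protons built if needed).
#' @param pose A `ligand_pose` with rings perceived.
#' @param spec A [fixture_spec].
#' @param constants A [ring_constants] object.
#' @return List with `free` and `bound` `peak_list` objects.
#' @export
make_synthetic_peaklists <- function(protein, pose, spec = fixture_spec(),
                                     constants = ring_constants()) {
  if (any(is.na(protein$amides$hx) & protein$amides$resname != "PRO")) {
    protein <- build_amide_protons(protein)
  }
  am <- protein$amides[!is.na(protein$amides$hx), , drop = FALSE]
  keys <- rownames(am)
  base_h <- 8.3 + 0.4 * sin(0.7 * am$resno)
  base_n <- 118 + 6 * sin(0.3 * am$resno)
  entries <- function(dh, dn) {
    e <- data.frame(chain = am$chain, resno = am$resno, resname = am$resname,
                    delta_h = dh, delta_n = dn, stringsAsFactors = FALSE)
    rownames(e) <- keys
    e
  }
  shift <- simulate_pose_csp(protein, pose, constants, signed = TRUE)[keys]
  inj <- numeric(length(keys))
  sel <- am$resno %in% spec$perturbed_residues
  inj[sel] <- spec$inject_ppm * ifelse(shift[sel] >= 0, 1, -1)
  noise <- if (spec$noise_ppm > 0) {
    .with_seed(spec$seed, stats::rnorm(length(keys), 0, spec$noise_ppm))
  } else 0
  free <- structure(list(state_label = "free",
                         entries = entries(base_h, base_n),
                         ligand_concentration = 0),
                    class = "peak_list")
  bound <- structure(list(state_label = "bound",
                          entries = entries(base_h + shift + inj + noise, base_n),
                          ligand_concentration = 4e-3),
                     class = "peak_list")
  list(free = free, bound = bound)
}

#' Random traceless symmetric alignment tensor
#'
#' Five independent Saupe elements drawn uniformly in
#' `[-magnitude, magnitude]` Hz. Deterministic for a fixed seed.
#'
#' @param magnitude Half-width of the element distribution in Hz.
#' @param seed Optional RNG seed.
#' @return 3x3 symmetric traceless matrix.
#' @export
random_alignment_tensor <- function(magnitude = 10, seed = NULL) {
  draw <- function() {
    co <- stats::runif(5L, -magnitude, magnitude)
    names(co) <- c("Sxx", "Syy", "Sxy", "Sxz", "Syz")
    .saupe_matrix(as.list(co))
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Tensor-generated synthetic RDCs
#'
#' Back-calculates couplings for the protein's N-H vectors from the given
#' tensor and adds seeded Gaussian noise of s.d. `spec$noise_hz`.
#'
#' @param protein A `protein_structure`.
#' @param tensor 3x3 symmetric traceless Saupe matrix (Hz scale).
#' @param spec A [fixture_spec].
#' @return An `rdc_set`.
#' @export
make_synthetic_rdcs <- function(protein, tensor, spec = fixture_spec()) {
  v <- nh_vectors(protein)
  d <- back_calculate_rdc(tensor, v)
  if (spec$noise_hz > 0) {
    d <- d + .with_seed(spec$seed + 1L,
                        stats::rnorm(length(d), 0, spec$noise_hz))
  }
  parts <- strsplit(names(d), ":", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, character(1L), 1L),
                    resno = as.integer(vapply(parts, `[`, character(1L), 2L)),
                    rdc_hz = unname(d), stringsAsFactors = FALSE)
  rownames(out) <- names(d)
  attr(out, "state_label") <- "synthetic"
  class(out) <- c("rdc_set", "data.frame")
  out
}
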