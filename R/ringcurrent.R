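# Haigh-Mallion ring-current shifts for amide protons.
#
# For a proton p and an aromatic ring, the shift is
#     delta = -i * B * sum_bonds(jk) S_jk * (1/r_j^3 + 1/r_k^3)
# where S_jk is the signed area of the triangle (p', j', k') after projecting
# all three points onto the ring plane (positive when p' -> j' -> k' runs
# counter-clockwise about the ring normal), r_j and r_k are the unprojected
# 3D distances from the ring atoms to the proton, i is the ring-type
# intensity factor, and B the target-nucleus factor. The leading minus makes
# the shielding cone above/below the ring plane negative (upfield) and the
# in-plane belt positive, with B > 0.

#' Ring-current model constants
#'
#' Loads the target-nucleus factor B for amide protons and the per-ring-type
#' intensity table. Defaults ship in
#' `inst/extdata/ring_current_constants.csv`; B follows the SHIFTX-lineage
#' amide-proton value and is configurable — every structural property of the
#' model (symmetries, closure, far-field scaling) is independent of B.
#'
#' @param target_factor_B Target-nucleus factor (> 0; ppm with coordinates in
#'   Angstrom). `NULL` uses the packaged default.
#' @param intensity_table Named numeric vector of ring-type intensity
#'   factors; must contain `benzene = 1.00`. `NULL` uses the packaged table
#'   (benzene 1.00; heteroaromatic types configurable).
#' @param clash_distance Proton-to-ring-atom distance (Angstrom) below which
#'   a value is flagged as a steric artifact (default 0.5). Flagged values
#'   are still returned: docking programs do place ligands unphysically close
#'   to the protein, and those poses are discussed, not discarded.
#' @return A `ring_constants` list.
#' @export
ring_constants <- function(target_factor_B = NULL, intensity_table = NULL,
                           clash_distance = 0.5) {
  cfg <- utils::read.csv(system.file("extdata", "ring_current_constants.csv",
                                     package = "ringcsp"),
                         stringsAsFactors = FALSE)
  defaults <- stats::setNames(cfg$value, cfg$constant)
  B <- target_factor_B %||% unname(defaults[["target_factor_B"]])
  if (!is.numeric(B) || B <= 0) {
    .ringcsp_error("target_factor_B must be > 0", "ringcsp_bad_constants")
  }
  if (is.null(intensity_table)) {
    ik <- grep("^intensity\\.", names(defaults), value = TRUE)
    intensity_table <- stats::setNames(unname(defaults[ik]),
                                       sub("^intensity\\.", "", ik))
  }
  if (!isTRUE(all.equal(unname(intensity_table[["benzene"]]), 1.0))) {
    .ringcsp_error("intensity table must contain benzene = 1.00",
                   "ringcsp_bad_constants")
  }
  structure(list(target_factor_B = B, intensity_table = intensity_table,
                 clash_distance = clash_distance),
            class = "ring_constants")
}

#' Least-squares plane of an aromatic ring
#'
#' Centroid and unit normal of the plane through the ring atoms, with the
#' normal orientation fixed by the right-hand rule over the ring's atom
#' ordering. Reversing the atom order flips the normal; the ring-current
#' shift is invariant to that choice because bond traversal flips with it.
#'
#' @param ring An `aromatic_ring`.
#' @return List with `centroid` (3-vector, Angstrom) and `normal` (unit
#'   3-vector).
#' @export
ring_plane <- function(ring) {
  p <- ring$coords
  cen <- colMeans(p)
  sv <- svd(sweep(p, 2L, cen))
  if (sv$d[2L] < 1e-9 * sv$d[1L]) {
    .ringcsp_error("degenerate (collinear) ring atoms", "ringcsp_bad_ring")
  }
  nrm <- sv$v[, 3L]
  # Newell polygon normal gives the traversal orientation
  n <- nrow(p)
  nxt <- c(2:n, 1L)
  newell <- c(
    sum((p[, 2L] - p[nxt, 2L]) * (p[, 3L] + p[nxt, 3L])),
    sum((p[, 3L] - p[nxt, 3L]) * (p[, 1L] + p[nxt, 1L])),
    sum((p[, 1L] - p[nxt, 1L]) * (p[, 2L] + p[nxt, 2L])))
  if (sum(nrm * newell) < 0) nrm <- -nrm
  list(centroid = cen, normal = nrm)
}

#' Signed projected triangle area
#'
#' Projects two consecutive ring atoms `a`, `b` and the proton `p` onto the
#' ring plane and returns the signed area of the triangle (p', a', b'),
#' positive when the traversal p' -> a' -> b' is counter-clockwise about the
#' plane normal. Degenerate triangles return 0.
#'
#' @param a,b Positions (3-vectors, Angstrom) of consecutive ring atoms.
#' @param p Proton position.
#' @param plane A list with `centroid` and `normal`, as from [ring_plane].
#' @return Signed area in Angstrom^2.
#' @export
signed_projected_area <- function(a, b, p, plane) {
  nv <- plane$normal
  proj <- function(x) x - sum((x - plane$centroid) * nv) * nv
  u <- proj(a) - proj(p)
  v <- proj(b) - proj(p)
  0.5 * sum(nv * .cross3(u, v))
}

# Vectorised evaluator: shifts of many protons (m x 3 matrix) from one ring.
.ring_shift_many <- function(protons, ring, constants) {
  p <- ring$coords
  n <- nrow(p)
  plane <- ring_plane(ring)
  cen <- plane$centroid
  nv <- plane$normal
  m <- nrow(protons)
  dpl <- (protons - matrix(cen, m, 3L, byrow = TRUE)) %*% nv
  pp <- protons - dpl %*% t(nv)           # projected protons
  ap <- sweep(p, 2L, cen)
  ap <- p - (ap %*% nv) %*% t(nv)         # projected ring atoms (numeric hygiene)
  nxt <- c(2:n, 1L)
  G <- numeric(m)
  rmin <- rep(Inf, m)
  for (k in seq_len(n)) {
    a <- p[k, ]
    b <- p[nxt[k], ]
    ra <- sqrt((protons[, 1L] - a[1L])^2 + (protons[, 2L] - a[2L])^2 +
                 (protons[, 3L] - a[3L])^2)
    rb <- sqrt((protons[, 1L] - b[1L])^2 + (protons[, 2L] - b[2L])^2 +
                 (protons[, 3L] - b[3L])^2)
    rmin <- pmin(rmin, ra)
    u1 <- ap[k, 1L] - pp[, 1L]; u2 <- ap[k, 2L] - pp[, 2L]; u3 <- ap[k, 3L] - pp[, 3L]
    v1 <- ap[nxt[k], 1L] - pp[, 1L]; v2 <- ap[nxt[k], 2L] - pp[, 2L]; v3 <- ap[nxt[k], 3L] - pp[, 3L]
    S <- 0.5 * (nv[1L] * (u2 * v3 - u3 * v2) +
                  nv[2L] * (u3 * v1 - u1 * v3) +
                  nv[3L] * (u1 * v2 - u2 * v1))
    G <- G + S * (1 / ra^3 + 1 / rb^3)
  }
  list(shift = -ring$intensity_factor * constants$target_factor_B * G,
       clash = rmin <= constants$clash_distance)
}

#' Ring-current shift at a proton position
#'
#' Evaluates the Haigh-Mallion shift (ppm) induced by one aromatic ring at
#' one proton. Triangle areas are computed in the ring plane; the distances
#' from ring atoms to the proton are full 3D distances. The sum runs over
#' the bonds of the ring. Protons inside the clash distance are flagged via
#' the `"clash"` attribute but a value is still returned.
#'
#' @param proton Proton position (3-vector, Angstrom).
#' @param ring An `aromatic_ring`.
#' @param constants A [ring_constants] object.
#' @return Signed shift in ppm (shielding cone negative), with attribute
#'   `clash`.
#' @export
ring_current_shift <- function(proton, ring, constants = ring_constants()) {
  r <- .ring_shift_many(matrix(proton, 1L, 3L), ring, constants)
  structure(r$shift, clash = r$clash)
}

#' Simulate the CSP a pose induces on every amide proton
#'
#' Sums the signed ring-current shifts of all aromatic rings of one docked
#' pose at every amide proton of the protein, and by default reports the
#' magnitude — the experimental proton CSP is a magnitude, so simulated and
#' measured values are compared on the same scale. Residues without an amide
#' proton (prolines, N-terminus, unbuilt) are absent from the result.
#'
#' @param protein A `protein_structure` with amide protons present (see
#'   [build_amide_protons]; they are built here with defaults if missing).
#' @param pose A `ligand_pose` with rings perceived.
#' @param constants A [ring_constants] object.
#' @param signed If `TRUE`, return the signed summed shift instead of its
#'   magnitude (used by forward models and iso-shielding work).
#' @return Named numeric vector (residue key -> ppm) with attribute
#'   `clash_residues` (keys flagged for steric proximity). A pose with zero
#'   rings yields all zeros with a warning.
#' @export
simulate_pose_csp <- function(protein, pose, constants = ring_constants(),
                              signed = FALSE) {
  if (any(is.na(protein$amides$hx) & protein$amides$resname != "PRO")) {
    protein <- build_amide_protons(protein)
  }
  am <- protein$amides[!is.na(protein$amides$hx), , drop = FALSE]
  keys <- rownames(am)
  out <- stats::setNames(numeric(nrow(am)), keys)
  if (length(pose$rings) == 0L) {
    warning(sprintf("pose %s has no aromatic rings: ring-current model has no signal",
                    pose$pose_id))
    attr(out, "clash_residues") <- character(0)
    return(out)
  }
  protons <- as.matrix(am[, c("hx", "hy", "hz")])
  clash <- rep(FALSE, nrow(am))
  for (ring in pose$rings) {
    r <- .ring_shift_many(protons, ring, constants)
    out <- out + r$shift
    clash <- clash | r$clash
  }
  if (!signed) out <- abs(out)
  attr(out, "clash_residues") <- keys[clash]
  out
}

#' Simulate CSPs for a pose ensemble
#'
#' One column per pose of [simulate_pose_csp] values, preserving pose order
#' and carrying cluster / binding-energy metadata for downstream grouping.
#'
#' @param protein A `protein_structure`.
#' @param poses List of `ligand_pose` objects (rings perceived).
#' @param constants A [ring_constants] object.
#' @return A `csp_matrix`: residues x poses matrix (ppm, non-negative), row
#'   names residue keys, column names pose ids, attributes `cluster_id`,
#'   `binding_energy` and `clash` (list of flagged residue keys per pose).
#' @export
simulate_ensemble <- function(protein, poses, constants = ring_constants()) {
  if (length(poses) == 0L) {
    .ringcsp_error("need at least one pose", "ringcsp_bad_input")
  }
  if (any(is.na(protein$amides$hx) & protein$amides$resname != "PRO")) {
    protein <- build_amide_protons(protein)
  }
  cols <- lapply(poses, function(p) simulate_pose_csp(protein, p, constants))
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(poses, function(p) as.character(p$pose_id), character(1L))
  attr(m, "cluster_id") <- vapply(poses, function(p) p$cluster_id %||% NA_integer_,
                                  integer(1L))
  attr(m, "binding_energy") <- vapply(poses,
                                      function(p) p$binding_energy %||% NA_real_,
                                      numeric(1L))
  attr(m, "clash") <- lapply(cols, attr, "clash_residues")
  class(m) <- c("csp_matrix", class(m))
  m
}

#' Iso-shielding map of a ring
#'
#' Regular 2D grid of signed ring-current shifts centred on the ring
#' centroid, either in the ring plane or in the plane perpendicular to it
#' (containing the ring normal and the centroid-to-first-atom direction).
#' Grid points inside the clash distance are masked `NA`. Contouring the
#' result reproduces the classic picture: negative (shielding) cone along
#' the axis, positive (deshielding) belt in the plane.
#'
#' @param ring An `aromatic_ring`.
#' @param plane_spec `"in_plane"` or `"perpendicular"`.
#' @param extent Half-width of the grid in Angstrom.
#' @param resolution Grid spacing in Angstrom.
#' @param constants A [ring_constants] object.
#' @return An `isoshielding_grid`: list with axes `u`, `v` (Angstrom),
#'   `values` matrix (ppm, `NA` where masked) and the grid metadata.
#' @export
isoshielding_grid <- function(ring, plane_spec = c("in_plane", "perpendicular"),
                              extent = 8, resolution = 0.25,
                              constants = ring_constants()) {
  plane_spec <- match.arg(plane_spec)
  if (extent <= 0 || resolution <= 0) {
    .ringcsp_error("extent and resolution must be > 0", "ringcsp_bad_input")
  }
  pl <- ring_plane(ring)
  e1 <- .unit((ring$coords[1L, ] - pl$centroid) -
                sum((ring$coords[1L, ] - pl$centroid) * pl$normal) * pl$normal)
  e2 <- .cross3(pl$normal, e1)
  u <- seq(-extent, extent, by = resolution)
  v <- u
  grid <- as.matrix(expand.grid(u = u, v = v))
  pts <- if (plane_spec == "in_plane") {
    matrix(pl$centroid, nrow(grid), 3L, byrow = TRUE) +
      grid[, 1L] %*% t(e1) + grid[, 2L] %*% t(e2)
  } else {
    matrix(pl$centroid, nrow(grid), 3L, byrow = TRUE) +
      grid[, 1L] %*% t(e1) + grid[, 2L] %*% t(pl$normal)
  }
  r <- .ring_shift_many(pts, ring, constants)
  vals <- r$shift
  vals[r$clash] <- NA_real_
  structure(list(u = u, v = v,
                 values = matrix(vals, length(u), length(v)),
                 plane_spec = plane_spec, ring_label = ring$ring_label,
                 extent = extent, resolution = resolution),
            class = "isoshielding_grid")
}

#' @export
print.isoshielding_grid <- function(x, ...) {
  cat(sprintf("<isoshielding_grid> %s, %s plane, %.1f A extent at %.2f A: %d x %d points, range [%.4g, %.4g] ppm\n",
              x$ring_label, x$plane_spec, x$extent, x$resolution,
              length(x$u), length(x$v),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @rdname isoshielding_grid
#' @param x An `isoshielding_grid`.
#' @param levels Contour levels in ppm.
#' @param ... Passed to [graphics::contour].
#' @export
plot.isoshielding_grid <- function(x, levels = c(-1, -0.5, -0.2, -0.1, -0.05,
                                                 0.05, 0.1, 0.2, 0.5, 1), ...) {
  graphics::contour(x$u, x$v, x$values, levels = levels,
                    xlab = "u (A)",
                    ylab = if (x$plane_spec == "in_plane") "v (A)" else "axis (A)",
                    main = sprintf("Ring-current iso-shielding (%s)", x$plane_spec),
                    ...)
  invisible(x)
}

#' Write an iso-shielding grid
#'
#' Delimited matrix with a small `#`-prefixed header (ring label, plane,
#' extent, resolution); first column the u axis, remaining columns the v
#' grid values.
#'
#' @param grid An `isoshielding_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isoshielding <- function(grid, path) {
  hdr <- c(sprintf("# ring: %s", grid$ring_label),
           sprintf("# plane: %s", grid$plane_spec),
           sprintf("# extent_A: %g", grid$extent),
           sprintf("# resolution_A: %g", grid$resolution))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- cbind(u = grid$u, as.data.frame(grid$values))
  names(df)[-1L] <- sprintf("v%g", grid$v)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated CSP matrix
#'
#' Tab-delimited, rows = residues, columns = pose ids, with cluster ids on a
#' `#`-prefixed header line when present.
#'
#' @param sim A `csp_matrix` from [simulate_ensemble].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_csp_matrix <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cl <- attr(sim, "cluster_id")
  if (!is.null(cl) && any(!is.na(cl))) {
    writeLines(paste0("# cluster_id\t", paste(cl, collapse = "\t")), con)
  }
  df <- data.frame(residue = rownames(sim), unclass(sim), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
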