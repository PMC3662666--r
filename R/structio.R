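# Structure, pose, peak-list and RDC-table input/output.
#
# Protein PDB files go through bio3d. Pose ensembles are parsed here because
# per-MODEL REMARK/USER metadata (cluster, binding energy) and pdbqt atom-type
# columns are not covered by bio3d's reader.

.STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

.element_from_name <- function(name) {
  if (length(name) == 0L) return(character(0))
  s <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(s, 1L, 2L))
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
               two, toupper(substr(s, 1L, 1L)))
  # PDB amino-acid atom names never start with a two-letter element
  substr(el, 1L, 1L) <- toupper(substr(el, 1L, 1L))
  ifelse(nchar(el) == 2L, paste0(substr(el, 1L, 1L), tolower(substr(el, 2L, 2L))), el)
}

#' Read a protein structure from a PDB file
#'
#' Loads one model of a PDB file (via bio3d) and extracts, for every residue
#' carrying a backbone nitrogen, its amide group: the N position, the amide
#' proton position when present in the file, and identifiers. HETATM records
#' (ligands, waters) never contribute amides. Residue numbering is kept
#' exactly as in the file.
#'
#' @param path Path to a PDB file.
#' @param model Model number, 1-based over `MODEL` records. Single-model
#'   files have exactly model 1.
#' @return A `protein_structure`: list with `source_id`, `model_index`,
#'   `atoms` (data frame: name, element, chain, resno, resname, x, y, z) and
#'   `amides` (data frame: chain, resno, resname, nx..nz, hx..hz or `NA`,
#'   `h_built`), amides sorted by (chain, resno).
#' @export
read_protein_structure <- function(path, model = 1L) {
  if (!file.exists(path)) {
    .ringcsp_error(sprintf("file not found: %s", path), "ringcsp_missing_file")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod)) nmod <- 1L
  if (model < 1L || model > nmod) {
    .ringcsp_error(
      sprintf("model %d out of range: file has %d model(s)", model, nmod),
      "ringcsp_bad_model")
  }
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  at <- pdb$atom
  idx <- seq_len(nrow(at))
  at$x <- xyz[3L * idx - 2L]
  at$y <- xyz[3L * idx - 1L]
  at$z <- xyz[3L * idx]

  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) == 0L) {
    .ringcsp_error("no ATOM records in file", "ringcsp_parse_error")
  }
  prot$chain[is.na(prot$chain) | prot$chain == ""] <- "A"
  elem <- prot$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- .element_from_name(prot$elety[bad])

  for (ch in unique(prot$chain)) {
    if (!any(prot$elety == "N" & prot$chain == ch)) {
      .ringcsp_error(sprintf("chain %s has no backbone N atoms", ch),
                     "ringcsp_bad_chain", chain = ch)
    }
  }

  atoms <- data.frame(name = prot$elety, element = elem, chain = prot$chain,
                      resno = prot$resno, resname = prot$resid,
                      x = prot$x, y = prot$y, z = prot$z,
                      stringsAsFactors = FALSE)
  structure(
    list(source_id = sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
         model_index = as.integer(model),
         atoms = atoms,
         amides = .amides_from_atoms(atoms)),
    class = "protein_structure")
}

.amides_from_atoms <- function(atoms) {
  nrec <- atoms[atoms$name == "N", , drop = FALSE]
  nrec <- nrec[order(nrec$chain, nrec$resno), , drop = FALSE]
  key <- residue_key(atoms$chain, atoms$resno)
  nkey <- residue_key(nrec$chain, nrec$resno)
  h <- atoms[atoms$name %in% c("H", "HN") & atoms$element == "H", , drop = FALSE]
  hkey <- residue_key(h$chain, h$resno)
  m <- match(nkey, hkey)
  amides <- data.frame(
    chain = nrec$chain, resno = nrec$resno, resname = nrec$resname,
    nx = nrec$x, ny = nrec$y, nz = nrec$z,
    hx = h$x[m], hy = h$y[m], hz = h$z[m],
    h_built = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(nkey)) {
    .ringcsp_error("duplicate residue numbers within a chain",
                   "ringcsp_parse_error")
  }
  rownames(amides) <- nkey
  amides
}

#' @export
print.protein_structure <- function(x, ...) {
  nh <- sum(!is.na(x$amides$hx))
  cat(sprintf("<protein_structure> %s (model %d): %d atoms, %d amides (%d with H, %d built)\n",
              x$source_id, x$model_index, nrow(x$atoms), nrow(x$amides),
              nh, sum(x$amides$h_built)))
  invisible(x)
}

#' Write a protein structure as PDB
#'
#' Emits standard `ATOM` records (fixed-width, 3-decimal coordinates) in the
#' same dialect [read_protein_structure] consumes.
#'
#' @param structure A `protein_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_protein_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resname,
                   elety = a$name, elesy = a$element)
  invisible(path)
}

#' Build missing amide protons
#'
#' X-ray structures rarely contain hydrogens, but both the ring-current model
#' and N-H RDC back-calculation need the amide proton. For every non-proline,
#' non-N-terminal residue lacking H, the proton is placed in the
#' C(i-1)-N-CA plane along the direction opposing the bisector of the
#' C(i-1)-N and CA-N bonds, at distance `nh_length` from N. Existing protons
#' are never touched, so the operation is idempotent.
#'
#' @param structure A `protein_structure`.
#' @param nh_length N-H bond length in Angstrom (default 1.02, the standard
#'   value for shift/RDC back-calculation from crystal coordinates).
#' @return The structure with protons added (`h_built = TRUE` where placed).
#'   Residues that cannot be built (missing preceding C or CA) are skipped
#'   and listed in the `"skipped"` attribute.
#' @export
build_amide_protons <- function(structure, nh_length = 1.02) {
  am <- structure$amides
  atoms <- structure$atoms
  akey <- residue_key(atoms$chain, atoms$resno)
  skipped <- character(0)
  new_h <- list()
  for (i in seq_len(nrow(am))) {
    if (!is.na(am$hx[i]) || am$resname[i] == "PRO") next
    key_ca <- akey == rownames(am)[i] & atoms$name == "CA"
    key_cprev <- atoms$chain == am$chain[i] & atoms$resno == am$resno[i] - 1L &
      atoms$name == "C"
    if (!any(key_ca) || !any(key_cprev)) {
      if (am$resno[i] > min(am$resno[am$chain == am$chain[i]])) {
        skipped <- c(skipped, rownames(am)[i])
      }
      next
    }
    n <- c(am$nx[i], am$ny[i], am$nz[i])
    ca <- as.numeric(atoms[which(key_ca)[1L], c("x", "y", "z")])
    cp <- as.numeric(atoms[which(key_cprev)[1L], c("x", "y", "z")])
    d <- -.unit(.unit(cp - n) + .unit(ca - n))
    h <- n + nh_length * d
    am[i, c("hx", "hy", "hz")] <- h
    am$h_built[i] <- TRUE
    new_h[[length(new_h) + 1L]] <- data.frame(
      name = "H", element = "H", chain = am$chain[i], resno = am$resno[i],
      resname = am$resname[i], x = h[1L], y = h[2L], z = h[3L],
      stringsAsFactors = FALSE)
  }
  if (length(new_h)) {
    structure$atoms <- rbind(atoms, do.call(rbind, new_h))
  }
  structure$amides <- am
  attr(structure, "skipped") <- skipped
  structure
}

# ---- ligand poses -----------------------------------------------------------

.parse_atom_line <- function(line, lineno, pdbqt = FALSE) {
  x <- suppressWarnings(as.numeric(substr(line, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(line, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(line, 47L, 54L)))
  if (anyNA(c(x, y, z))) {
    .ringcsp_error(sprintf("malformed coordinate line %d: %s", lineno, line),
                   "ringcsp_parse_error", line = lineno)
  }
  name <- trimws(substr(line, 13L, 16L))
  if (pdbqt) {
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    ad <- toupper(toks[length(toks)])
    map <- stats::setNames(
      c("C", "C", "N", "N", "O", "O", "S", "S", "H", "H", "H", "F",
        "Cl", "Br", "I", "P"),
      c("A", "C", "N", "NA", "OA", "O", "S", "SA", "H", "HD", "HS", "F",
        "CL", "BR", "I", "P"))
    el <- if (ad %in% names(map)) unname(map[[ad]]) else .element_from_name(name)
  } else {
    el <- trimws(substr(line, 77L, 78L))
    if (is.na(el) || el == "") el <- .element_from_name(name)
  }
  list(name = name, element = el, x = x, y = y, z = z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a docked ligand pose ensemble
#'
#' Reads a multi-`MODEL` PDB file (or AutoDock pdbqt) holding one or more
#' docked conformations of a ligand, as produced by docking programs. Cluster
#' labels and binding energies are picked up from `REMARK`/`USER` lines
#' inside each model block when present (e.g. AutoDock's
#' `Estimated Free Energy of Binding`); otherwise they are `NA`. Rings are
#' not perceived here — call [perceive_aromatic_rings] on each pose.
#'
#' @param path Path to a PDB or pdbqt file.
#' @param format `"auto"` (by extension), `"pdb"` or `"pdbqt"`.
#' @return List of `ligand_pose` objects (`pose_id` 1..n in file order), each
#'   with an `atoms` data frame, empty `rings`, and optional `cluster_id` /
#'   `binding_energy` (kcal/mol, sign preserved).
#' @export
read_ligand_poses <- function(path, format = c("auto", "pdb", "pdbqt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    .ringcsp_error(sprintf("file not found: %s", path), "ringcsp_missing_file")
  }
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    blocks <- list(seq_along(lines))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    blocks <- Map(function(s, e) seq(s, e), starts, ends)
  }
  poses <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    ln <- blocks[[b]]
    atom_idx <- ln[grepl("^(ATOM|HETATM)", lines[ln])]
    if (length(atom_idx) == 0L) next
    rows <- lapply(atom_idx, function(i) {
      .parse_atom_line(lines[i], i, pdbqt = (format == "pdbqt"))
    })
    atoms <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
    meta <- lines[ln[grepl("^(REMARK|USER)", lines[ln])]]
    energy <- NA_real_
    epat <- "(Estimated Free Energy of Binding|VINA RESULT|Binding energy|ENERGY)"
    hit <- grep(epat, meta, ignore.case = TRUE, value = TRUE)
    if (length(hit)) {
      num <- regmatches(hit[1L], regexpr("-?[0-9]+\\.?[0-9]*", hit[1L]))
      if (length(num)) energy <- as.numeric(num)
    }
    cluster <- NA_integer_
    chit <- grep("CLUSTER", meta, ignore.case = TRUE, value = TRUE)
    if (length(chit)) {
      num <- regmatches(chit[1L], regexpr("[0-9]+", chit[1L]))
      if (length(num)) cluster <- as.integer(num)
    }
    poses[[b]] <- structure(
      list(pose_id = b, atoms = atoms, rings = list(),
           cluster_id = cluster, binding_energy = energy),
      class = "ligand_pose")
  }
  poses <- poses[!vapply(poses, is.null, logical(1L))]
  if (length(poses) == 0L) {
    .ringcsp_error("no poses found in file", "ringcsp_parse_error")
  }
  for (i in seq_along(poses)) poses[[i]]$pose_id <- i
  poses
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> id %d: %d atoms, %d ring(s)%s%s\n",
              x$pose_id, nrow(x$atoms), length(x$rings),
              if (!is.na(x$cluster_id)) sprintf(", cluster %d", x$cluster_id) else "",
              if (!is.na(x$binding_energy)) sprintf(", %.2f kcal/mol", x$binding_energy) else ""))
  invisible(x)
}

#' Write a pose ensemble as multi-MODEL PDB
#'
#' One `MODEL`/`ENDMDL` block per pose, with `REMARK CLUSTER` and
#' `REMARK ENERGY` lines when metadata is present; the dialect
#' [read_ligand_poses] reads.
#'
#' @param poses List of `ligand_pose` objects (or a single pose).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ligand_poses <- function(poses, path) {
  if (inherits(poses, "ligand_pose")) poses <- list(poses)
  out <- character(0)
  for (p in poses) {
    out <- c(out, sprintf("MODEL     %4d", p$pose_id))
    if (!is.na(p$cluster_id)) out <- c(out, sprintf("REMARK CLUSTER %d", p$cluster_id))
    if (!is.na(p$binding_energy)) {
      out <- c(out, sprintf("REMARK ENERGY %.4f kcal/mol", p$binding_energy))
    }
    a <- p$atoms
    out <- c(out, sprintf(
      "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)), substr(a$name, 1L, 4L), a$x, a$y, a$z,
      toupper(a$element)))
    out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---- aromatic ring perception ----------------------------------------------

#' Construct an aromatic ring from coordinates
#'
#' Low-level constructor enforcing the ring invariants: 5 or 6 atoms in cycle
#' order, consecutive atoms within covalent distance, and root-mean-square
#' deviation from the least-squares plane below `planarity_tol`.
#'
#' @param coords Numeric matrix (5 or 6 rows x 3) of ring-atom positions in
#'   cycle order.
#' @param intensity_factor Ring-type intensity factor (1.00 for a
#'   benzene-type carbocycle).
#' @param label Free-text ring label.
#' @param atom_indices Optional indices of the ring atoms in a parent pose.
#' @param planarity_tol,bond_cutoff Geometric tolerances in Angstrom.
#' @return An `aromatic_ring` object.
#' @export
aromatic_ring <- function(coords, intensity_factor = 1.0, label = "ring",
                          atom_indices = seq_len(nrow(coords)),
                          planarity_tol = 0.1, bond_cutoff = 1.8) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!(n %in% c(5L, 6L))) {
    .ringcsp_error("ring must have 5 or 6 atoms", "ringcsp_bad_ring")
  }
  nxt <- c(2:n, 1L)
  bl <- sqrt(rowSums((coords - coords[nxt, , drop = FALSE])^2))
  if (any(bl > bond_cutoff)) {
    .ringcsp_error("consecutive ring atoms exceed covalent distance",
                   "ringcsp_bad_ring")
  }
  cen <- colMeans(coords)
  sv <- svd(sweep(coords, 2L, cen))
  rms <- sv$d[3L] / sqrt(n)
  if (rms > planarity_tol) {
    .ringcsp_error(sprintf("ring not planar (rms %.3f A > %.3f A)", rms,
                           planarity_tol), "ringcsp_bad_ring")
  }
  structure(list(atom_indices = atom_indices, coords = coords,
                 intensity_factor = intensity_factor, ring_label = label),
            class = "aromatic_ring")
}

# All chordless cycles of length 5 or 6 in an adjacency matrix, as ordered
# vertex paths. Small-molecule graphs only; plain DFS with canonical dedup.
.find_small_rings <- function(adj, sizes = c(5L, 6L)) {
  n <- nrow(adj)
  found <- list()
  seen <- character(0)
  maxlen <- max(sizes)
  dfs <- function(path) {
    last <- path[length(path)]
    for (v in which(adj[last, ])) {
      if (v == path[1L] && length(path) %in% sizes) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          # chordless: edge count inside the cycle equals its length
          if (sum(adj[path, path]) / 2L == length(path)) {
            seen <<- c(seen, key)
            found[[length(found) + 1L]] <<- path
          }
        }
      } else if (length(path) < maxlen && !(v %in% path) && v > path[1L]) {
        dfs(c(path, v))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  found
}

#' Perceive aromatic rings in a ligand pose
#'
#' Builds a covalent graph from interatomic distances (non-hydrogen pairs
#' within `bond_cutoff`), extracts chordless rings of size 5 or 6, and keeps
#' those that are planar and composed of ring-capable elements (C, N, O, S).
#' Each retained ring gets an intensity factor from the per-ring-type table:
#' a six-membered all-carbon (benzene-type) ring is 1.00; other types use the
#' configurable table in [ring_constants]. Docking output often lacks
#' `CONECT` records, hence the distance-based graph.
#'
#' @param pose A `ligand_pose`.
#' @param planarity_tol Max RMS deviation (Angstrom) of ring atoms from their
#'   least-squares plane (default 0.1).
#' @param bond_cutoff Covalent distance cutoff in Angstrom (default 1.8).
#' @param intensity_table Named vector of ring-type intensity factors; default
#'   from [ring_constants].
#' @return The pose with its `rings` list filled (possibly empty).
#' @export
perceive_aromatic_rings <- function(pose, planarity_tol = 0.1,
                                    bond_cutoff = 1.8,
                                    intensity_table = NULL) {
  if (is.null(intensity_table)) {
    intensity_table <- ring_constants()$intensity_table
  }
  a <- pose$atoms
  heavy <- which(toupper(a$element) != "H")
  pose$rings <- list()
  if (length(heavy) < 3L) return(pose)
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  adj <- d <= bond_cutoff & d > 0.4
  cycles <- .find_small_rings(adj)
  k <- 0L
  for (cy in cycles) {
    el <- toupper(a$element[heavy[cy]])
    if (!all(el %in% c("C", "N", "O", "S"))) next
    type <- if (length(cy) == 6L) {
      if (all(el == "C")) "benzene" else "hetero6"
    } else "ring5"
    ring <- tryCatch(
      aromatic_ring(xyz[cy, , drop = FALSE],
                    intensity_factor = unname(intensity_table[[type]]),
                    label = sprintf("ring%d:%s", k + 1L, type),
                    atom_indices = heavy[cy],
                    planarity_tol = planarity_tol,
                    bond_cutoff = bond_cutoff),
      ringcsp_bad_ring = function(e) NULL)
    if (!is.null(ring)) {
      k <- k + 1L
      ring$ring_label <- sprintf("ring%d:%s", k, type)
      pose$rings[[k]] <- ring
    }
  }
  pose
}

# ---- peak lists and RDC tables ---------------------------------------------

.read_table_auto <- function(path) {
  if (!file.exists(path)) {
    .ringcsp_error(sprintf("file not found: %s", path), "ringcsp_missing_file")
  }
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE)
}

.num_col <- function(df, col, path) {
  if (!col %in% names(df)) {
    .ringcsp_error(sprintf("missing required column '%s' in %s", col, path),
                   "ringcsp_parse_error")
  }
  v <- df[[col]]
  if (!is.numeric(v)) {
    .ringcsp_error(sprintf("non-numeric values in column '%s' of %s", col, path),
                   "ringcsp_parse_error")
  }
  if (any(!is.finite(v))) {
    .ringcsp_error(sprintf("non-finite values in column '%s' of %s", col, path),
                   "ringcsp_parse_error")
  }
  v
}

#' Read an amide peak list
#'
#' Delimited text (comma or tab, autodetected) with header columns
#' `residue_number`, `delta_h`, `delta_n` and optional `chain` (default
#' `"A"`) and `residue_name`. One row per assigned backbone amide.
#'
#' @param path Input file.
#' @param state_label Label for the sample state (e.g. `"free"`, `"bound"`);
#'   defaults to the file base name.
#' @param ligand_concentration Optional molar ligand concentration, carried
#'   as metadata.
#' @return A `peak_list`: list with `state_label`, `entries` data frame
#'   (chain, resno, resname, delta_h, delta_n) keyed by (chain, resno), and
#'   `ligand_concentration`.
#' @export
read_peaklist <- function(path, state_label = NULL,
                          ligand_concentration = NA_real_) {
  df <- .read_table_auto(path)
  resno <- .num_col(df, "residue_number", path)
  dh <- .num_col(df, "delta_h", path)
  dn <- .num_col(df, "delta_n", path)
  chain <- if ("chain" %in% names(df)) as.character(df$chain) else "A"
  resname <- if ("residue_name" %in% names(df)) as.character(df$residue_name) else NA_character_
  entries <- data.frame(chain = chain, resno = as.integer(resno),
                        resname = resname, delta_h = dh, delta_n = dn,
                        stringsAsFactors = FALSE)
  key <- residue_key(entries$chain, entries$resno)
  if (anyDuplicated(key)) {
    .ringcsp_error(sprintf("duplicate residue key(s): %s",
                           paste(unique(key[duplicated(key)]), collapse = ", ")),
                   "ringcsp_duplicate_key")
  }
  rownames(entries) <- key
  structure(list(state_label = state_label %||% sub("\\.[^.]*$", "", basename(path)),
                 entries = entries,
                 ligand_concentration = ligand_concentration),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> '%s': %d residues\n", x$state_label, nrow(x$entries)))
  invisible(x)
}

#' Write a peak list
#'
#' Comma-delimited, full double precision (17 significant digits), the same
#' dialect [read_peaklist] reads.
#'
#' @param peaklist A `peak_list`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaklist, path) {
  e <- peaklist$entries
  out <- data.frame(residue_number = e$resno, chain = e$chain,
                    residue_name = e$resname,
                    delta_h = formatC(e$delta_h, digits = 17, format = "g"),
                    delta_n = formatC(e$delta_n, digits = 17, format = "g"))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a residual dipolar coupling table
#'
#' Delimited text with header columns `residue_number` and `rdc_hz`
#' (optional `chain`). Residues with overlapped or missing signals are simply
#' absent rows.
#'
#' @param path Input file.
#' @param state_label Sample-state label; defaults to the file base name.
#' @return An `rdc_set`: data frame (chain, resno, rdc_hz) with residue-key
#'   row names and a `state_label` attribute.
#' @export
read_rdc_table <- function(path, state_label = NULL) {
  df <- .read_table_auto(path)
  if (nrow(df) == 0L) {
    .ringcsp_error("no RDC entries", "ringcsp_parse_error")
  }
  resno <- .num_col(df, "residue_number", path)
  d <- .num_col(df, "rdc_hz", path)
  chain <- if ("chain" %in% names(df)) as.character(df$chain) else "A"
  out <- data.frame(chain = chain, resno = as.integer(resno), rdc_hz = d,
                    stringsAsFactors = FALSE)
  key <- residue_key(out$chain, out$resno)
  if (anyDuplicated(key)) {
    .ringcsp_error("duplicate residue key(s) in RDC table",
                   "ringcsp_duplicate_key")
  }
  rownames(out) <- key
  attr(out, "state_label") <- state_label %||% sub("\\.[^.]*$", "", basename(path))
  class(out) <- c("rdc_set", "data.frame")
  out
}

#' Write an RDC table
#'
#' @param rdcs An `rdc_set` (or data frame with chain, resno, rdc_hz).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rdc_table <- function(rdcs, path) {
  out <- data.frame(residue_number = rdcs$resno, chain = rdcs$chain,
                    rdc_hz = formatC(rdcs$rdc_hz, digits = 17, format = "g"))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
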