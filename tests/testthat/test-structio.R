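# Readers, writers, proton building and ring perception.

write_mini_pdb <- function(path, nres = 3, with_het = TRUE, models = 1) {
  fmt <- "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s"
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    k <- 0
    for (i in seq_len(nres)) {
      for (nm in c("N", "CA", "C", "O")) {
        k <- k + 1
        el <- substr(nm, 1, 1)
        lines <- c(lines, sprintf(fmt, k, nm, "ALA", "A", i,
                                  i * 3.0 + (m - 1) * 100, k * 0.5, 1.0, el))
      }
    }
    if (with_het) {
      lines <- c(lines, sub("^ATOM  ", "HETATM",
                            sprintf(fmt, k + 1, "O", "HOH", "A", 90,
                                    1.0, 2.0, 3.0, "O")))
    }
    if (models > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("protein PDB parsing extracts amides and excludes HETATM", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, nres = 10)
  st <- read_protein_structure(f)
  expect_s3_class(st, "protein_structure")
  expect_equal(nrow(st$amides), 10)
  expect_true(all(is.na(st$amides$hx)))
  expect_false(any(st$atoms$resname == "HOH"))
  expect_false("A:90" %in% rownames(st$amides))
  # amides sorted by residue number
  expect_equal(st$amides$resno, 1:10)

  expect_error(read_protein_structure(f, model = 2), class = "ringcsp_bad_model")
  expect_error(read_protein_structure(file.path(tempdir(), "nope.pdb")),
               class = "ringcsp_missing_file")
})

test_that("multi-MODEL files select the requested model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_mini_pdb(f, nres = 3, models = 2)
  st1 <- read_protein_structure(f, model = 1)
  st2 <- read_protein_structure(f, model = 2)
  expect_equal(st2$amides$nx, st1$amides$nx + 100)
  expect_equal(st2$model_index, 2L)
})

test_that("structures round-trip through PDB at fixed-width precision", {
  prot <- make_helix_protein(fixture_spec(n_residues = 12))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_protein_structure(prot, f)
  back <- read_protein_structure(f)
  expect_equal(nrow(back$atoms), nrow(prot$atoms))
  m <- merge(prot$amides, back$amides, by = c("chain", "resno"))
  expect_lt(max(abs(m$nx.x - m$nx.y), abs(m$ny.x - m$ny.y),
                abs(m$nz.x - m$nz.y)), 1e-3 + 1e-12)
  expect_lt(max(abs(m$hx.x - m$hx.y), na.rm = TRUE), 1e-3 + 1e-12)
})

strip_protons <- function(st) {
  st$atoms <- st$atoms[st$atoms$name != "H", ]
  st$amides[, c("hx", "hy", "hz")] <- NA_real_
  st$amides$h_built <- FALSE
  st
}

test_that("amide protons are placed in the peptide plane at nh_length", {
  bare <- strip_protons(make_helix_protein(fixture_spec(n_residues = 10)))
  built <- build_amide_protons(bare, nh_length = 1.02)
  am <- built$amides
  expect_true(is.na(am$hx[1]))           # N-terminus stays bare
  expect_true(all(!is.na(am$hx[-1])))
  expect_true(all(am$h_built[-1]))
  # exact bond length and coplanarity with C(i-1), N, CA
  for (i in 2:10) {
    n <- as.numeric(am[i, c("nx", "ny", "nz")])
    h <- as.numeric(am[i, c("hx", "hy", "hz")])
    expect_equal(sqrt(sum((h - n)^2)), 1.02, tolerance = 1e-12)
    at <- built$atoms
    ca <- as.numeric(at[at$resno == i & at$name == "CA", c("x", "y", "z")])
    cp <- as.numeric(at[at$resno == i - 1 & at$name == "C", c("x", "y", "z")])
    nrm <- c((ca - n)[2] * (cp - n)[3] - (ca - n)[3] * (cp - n)[2],
             (ca - n)[3] * (cp - n)[1] - (ca - n)[1] * (cp - n)[3],
             (ca - n)[1] * (cp - n)[2] - (ca - n)[2] * (cp - n)[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    expect_lt(abs(sum((h - n) * nrm)), 1e-9)
  }
})

test_that("proton building skips prolines and existing protons (idempotent)", {
  st <- make_helix_protein(fixture_spec(n_residues = 8))
  bare <- strip_protons(st)
  bare$amides$resname[4] <- "PRO"
  bare$atoms$resname[bare$atoms$resno == 4] <- "PRO"
  built <- build_amide_protons(bare)
  expect_true(is.na(built$amides$hx[4]))
  again <- build_amide_protons(built)
  expect_identical(again$amides, built$amides)
  # pre-existing protons untouched, flag stays FALSE
  touched <- build_amide_protons(st)
  expect_identical(touched$amides[, c("hx", "hy", "hz")],
                   st$amides[, c("hx", "hy", "hz")])
})

test_that("pose ensembles round-trip with cluster and energy metadata", {
  spec <- fixture_spec(n_residues = 10, target_residue = 5, seed = 3)
  prot <- make_helix_protein(spec)
  poses <- make_pose_ensemble(spec, prot, n_poses = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ligand_poses(poses, f)
  back <- read_ligand_poses(f)
  expect_length(back, 5)
  expect_equal(vapply(back, function(p) p$pose_id, integer(1)), 1:5)
  expect_equal(vapply(back, function(p) p$cluster_id, integer(1)),
               vapply(poses, function(p) p$cluster_id, integer(1)))
  expect_equal(vapply(back, function(p) p$binding_energy, numeric(1)),
               vapply(poses, function(p) p$binding_energy, numeric(1)),
               tolerance = 1e-4)
  expect_lt(max(abs(back[[1]]$atoms$x - poses[[1]]$atoms$x)), 1e-3 + 1e-12)
  # single plain-PDB pose (no MODEL records): one pose, no metadata
  f2 <- withr::local_tempfile(fileext = ".pdb")
  a <- poses[[1]]$atoms
  writeLines(c(sprintf(
    "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), a$name, a$x, a$y, a$z, toupper(a$element)), "END"), f2)
  single <- read_ligand_poses(f2)
  expect_length(single, 1)
  expect_true(is.na(single[[1]]$cluster_id))
})

test_that("pdbqt poses carry AutoDock energies with sign preserved", {
  f <- withr::local_tempfile(fileext = ".pdbqt")
  writeLines(c(
    "MODEL        1",
    "USER    Estimated Free Energy of Binding    =   -5.70 kcal/mol",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.012 A ",
    "ATOM      2  N1  LIG A   1       1.400   0.000   0.000  0.00  0.00    -0.350 NA",
    "ATOM      3  H1  LIG A   1       2.000   1.000   0.000  0.00  0.00    +0.160 HD",
    "ENDMDL"), f)
  poses <- read_ligand_poses(f)
  expect_length(poses, 1)
  expect_equal(poses[[1]]$binding_energy, -5.70)
  expect_equal(poses[[1]]$atoms$element, c("C", "N", "H"))
})

test_that("malformed and empty pose files give structured errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL 1", "ATOM      1  C1  LIG A   1         bad-coords",
               "ENDMDL"), f)
  expect_error(read_ligand_poses(f), "line 2", class = "ringcsp_parse_error")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f2)
  expect_error(read_ligand_poses(f2), class = "ringcsp_parse_error")
})

test_that("ring perception finds the right rings", {
  spec <- fixture_spec(n_rings = 2)
  biphenyl <- make_ring_pose(spec)
  expect_length(biphenyl$rings, 2)
  expect_true(all(vapply(biphenyl$rings, function(r) nrow(r$coords), numeric(1)) == 6))
  expect_true(all(vapply(biphenyl$rings, function(r) r$intensity_factor, numeric(1)) == 1))

  ethane <- structure(list(
    pose_id = 1L,
    atoms = data.frame(name = c("C1", "C2"), element = "C",
                       x = c(0, 1.54), y = 0, z = 0),
    rings = list(), cluster_id = NA_integer_, binding_energy = NA_real_),
    class = "ligand_pose")
  expect_length(perceive_aromatic_rings(ethane)$rings, 0)
})

test_that("ring perception is invariant to rigid motion and atom order", {
  set.seed(11)
  pose <- make_ring_pose(fixture_spec(n_rings = 2))
  ring_sets <- function(p) {
    lapply(p$rings, function(r) {
      round(sort(r$coords %*% c(1, 10, 100)), 6)  # order-free fingerprint
    })
  }
  moved <- rigid_transform(pose, random_rotation(), rnorm(3, 0, 5))
  moved$rings <- list()
  moved <- perceive_aromatic_rings(moved)
  expect_length(moved$rings, 2)

  perm <- sample(nrow(pose$atoms))
  shuffled <- pose
  shuffled$atoms <- pose$atoms[perm, ]
  shuffled$rings <- list()
  shuffled <- perceive_aromatic_rings(shuffled)
  expect_length(shuffled$rings, 2)
  expect_setequal(unlist(ring_sets(shuffled)), unlist(ring_sets(pose)))
})

test_that("peak lists and RDC tables round-trip at full precision", {
  pl <- make_test_peaklist(c(2, 5, 9), c(8.1234567891234, 7.9, 8.5),
                           c(117.77, 120.2, 123.4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_peaklist(pl, f)
  back <- read_peaklist(f, state_label = "test")
  expect_equal(nrow(back$entries), 3)
  expect_identical(back$entries$delta_h, pl$entries$delta_h)
  expect_identical(back$entries$delta_n, pl$entries$delta_n)

  rd <- make_test_rdcset(c("A:1" = -33.0, "A:2" = 29.0, "A:3" = 0.123456789))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_rdc_table(rd, f2)
  back2 <- read_rdc_table(f2)
  expect_identical(back2$rdc_hz, rd$rdc_hz)
  expect_true(any(back2$rdc_hz < 0) && any(back2$rdc_hz > 0))
})

test_that("tabular readers reject bad input with structured errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_number,delta_h,delta_n", "5,8.1,117", "5,8.2,118"), f)
  expect_error(read_peaklist(f), class = "ringcsp_duplicate_key")
  writeLines(c("residue_number,delta_h", "5,8.1"), f)
  expect_error(read_peaklist(f), "delta_n", class = "ringcsp_parse_error")
  writeLines(c("residue_number,delta_h,delta_n", "5,abc,117"), f)
  expect_error(read_peaklist(f), class = "ringcsp_parse_error")
  writeLines("residue_number,rdc_hz", f)
  expect_error(read_rdc_table(f), "no RDC entries",
               class = "ringcsp_parse_error")
})
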