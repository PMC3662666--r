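# Alignment-tensor SVD fit, back-calculation, quality metrics, ranking.

test_that("N-H vectors are unit length and rotate with the structure", {
  prot <- make_helix_protein(fixture_spec(n_residues = 12))
  v <- nh_vectors(prot)
  expect_equal(unname(sqrt(rowSums(v^2))), rep(1, nrow(v)), tolerance = 1e-12)
  expect_false(residue_key("A", 1) %in% rownames(v))  # N-terminus bare

  set.seed(4)
  R <- random_rotation()
  vr <- nh_vectors(rigid_transform(prot, R, c(3, -2, 7)))
  expect_equal(unname(vr), unname(v %*% t(R)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("noise-free tensors are recovered exactly from spread vectors", {
  set.seed(9)
  v <- random_unit_vectors(20)
  S <- random_alignment_tensor(10, seed = 1)
  rd <- make_test_rdcset(back_calculate_rdc(S, v))
  fit <- fit_alignment_tensor(rd, v)
  expect_s3_class(fit, "rdcfit")
  expect_lt(max(abs(fit$saupe - S)) / max(abs(S)), 1e-8)
  expect_equal(fit$pearson_r, 1.0, tolerance = 1e-9)
  expect_lt(fit$q_factor, 1e-8)
  expect_lt(abs(sum(diag(fit$saupe))), 1e-12)
  expect_equal(fit$saupe, t(fit$saupe))
  # inverse consistency: refitted tensor reproduces the couplings
  expect_equal(unname(predict(fit, v)), unname(rd$rdc_hz), tolerance = 1e-8)
})

test_that("underdetermined and degenerate vector sets are rejected", {
  set.seed(10)
  v4 <- random_unit_vectors(4)
  rd4 <- make_test_rdcset(setNames(rnorm(4), rownames(v4)))
  expect_error(fit_alignment_tensor(rd4, v4), class = "ringcsp_underdetermined")

  par <- matrix(rep(c(1, 0, 0), each = 8), 8, 3)
  rownames(par) <- residue_key("A", 1:8)
  rdp <- make_test_rdcset(setNames(rnorm(8), rownames(par)))
  expect_error(fit_alignment_tensor(rdp, par), class = "ringcsp_rank_deficient")
})

test_that("back-calculation is linear in the tensor", {
  set.seed(12)
  v <- random_unit_vectors(10)
  S <- random_alignment_tensor(5, seed = 2)
  expect_true(all(back_calculate_rdc(matrix(0, 3, 3), v) == 0))
  expect_equal(back_calculate_rdc(2 * S, v), 2 * back_calculate_rdc(S, v),
               tolerance = 1e-12)
})

test_that("fit quality matches direct two-pass formulas", {
  d <- setNames(c(-10, -3, 2, 8, 12), residue_key("A", 1:5))
  expect_equal(unname(fit_quality(d, d)), c(1, 0))
  expect_equal(unname(fit_quality(d, -d)[1]), -1)
  off <- d + 2.5
  q <- fit_quality(d, off)
  expect_equal(unname(q["q_factor"]), 2.5 / sqrt(mean(d^2)))
  expect_equal(unname(q["pearson_r"]), 1)
  set.seed(13)
  e <- setNames(rnorm(30, 0, 8), residue_key("A", 1:30))
  cvals <- e + rnorm(30)
  q2 <- fit_quality(e, cvals)
  expect_equal(unname(q2["pearson_r"]),
               sum((e - mean(e)) * (cvals - mean(cvals))) /
                 sqrt(sum((e - mean(e))^2) * sum((cvals - mean(cvals))^2)),
               tolerance = 1e-12)
  expect_equal(unname(q2["q_factor"]),
               sqrt(sum((e - cvals)^2) / 30) / sqrt(sum(e^2) / 30),
               tolerance = 1e-12)
  expect_error(fit_quality(setNames(rep(1, 3), residue_key("A", 1:3)),
                           setNames(1:3, residue_key("A", 1:3))),
               class = "ringcsp_bad_input")
})

test_that("RDC outliers flagged above the deviation threshold", {
  d <- setNames(rep(0, 6), residue_key("A", 1:6))
  cvals <- d
  expect_length(flag_rdc_outliers(d, cvals), 0)
  cvals["A:4"] <- 10
  cvals["A:2"] <- -8
  ol <- flag_rdc_outliers(d, cvals)  # default 6.5 Hz
  expect_equal(as.character(ol), c("A:4", "A:2"))  # sorted by deviation
  expect_equal(attr(ol, "deviation"), c(10, 8))
  expect_length(flag_rdc_outliers(d, cvals, threshold = 11), 0)
})

test_that("rotation equivariance: tensor transforms, r and Q invariant", {
  prot <- make_helix_protein(fixture_spec(n_residues = 25))
  S <- random_alignment_tensor(8, seed = 3)
  rd <- make_synthetic_rdcs(prot, S, fixture_spec(noise_hz = 1, seed = 6))
  fit <- fit_alignment_tensor(rd, nh_vectors(prot))
  set.seed(14)
  R <- random_rotation()
  fit_rot <- fit_alignment_tensor(rd, nh_vectors(rigid_transform(prot, R, c(1, 2, 3))))
  expect_equal(fit_rot$saupe, R %*% fit$saupe %*% t(R), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit_rot$pearson_r, fit$pearson_r, tolerance = 1e-9)
  expect_equal(fit_rot$q_factor, fit$q_factor, tolerance = 1e-9)
})

test_that("noisy recovery improves with the number of couplings", {
  set.seed(15)
  med_err <- vapply(c(10, 40, 160), function(n) {
    errs <- replicate(30, {
      v <- random_unit_vectors(n)
      S <- random_alignment_tensor(10)
      d <- back_calculate_rdc(S, v) + rnorm(n, 0, 1)
      fit <- fit_alignment_tensor(make_test_rdcset(d), v)
      max(abs(fit$saupe - S))
    })
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

.cross_test <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

test_that("structure ranking puts the generating structure first", {
  spec <- fixture_spec(n_residues = 30)
  prot <- make_helix_protein(spec)
  S <- random_alignment_tensor(10, seed = 5)
  rd <- make_synthetic_rdcs(prot, S, spec)

  decoy <- prot
  sub <- decoy$amides$resno %in% 10:20
  for (i in which(sub)) {
    n <- as.numeric(decoy$amides[i, c("nx", "ny", "nz")])
    h <- as.numeric(decoy$amides[i, c("hx", "hy", "hz")])
    nh <- h - n
    perp <- .cross_test(nh, c(0, 0, 1))
    if (sqrt(sum(perp^2)) < 1e-6) perp <- .cross_test(nh, c(1, 0, 0))
    Rr <- rotation_matrix(perp, 30)
    decoy$amides[i, c("hx", "hy", "hz")] <- n + as.numeric(Rr %*% nh)
  }
  decoy$source_id <- "decoy"

  cmp <- compare_structures(rd, list(generator = prot, decoy = decoy))
  expect_equal(cmp$structure[1], "generator")
  expect_equal(cmp$pearson_r[1], 1.0, tolerance = 1e-9)
  expect_gt(cmp$pearson_r[1], cmp$pearson_r[2])

  # residue-subset bookkeeping
  keys <- residue_key("A", 5:15)
  cmp2 <- compare_structures(rd, list(prot), residue_subset = keys)
  expect_equal(cmp2$n_used, length(intersect(keys, rownames(rd))))

  # per-structure failures fill the error column, others still fit
  tiny <- prot
  tiny$amides <- tiny$amides[1:4, ]
  cmp3 <- compare_structures(rd, list(ok = prot, bad = tiny))
  expect_true(is.na(cmp3$pearson_r[cmp3$structure == "bad"]))
  expect_false(is.na(cmp3$pearson_r[cmp3$structure == "ok"]))
})

test_that("rdcfit behaves like a classic fitted model object", {
  prot <- make_helix_protein(fixture_spec(n_residues = 20))
  S <- random_alignment_tensor(10, seed = 8)
  rd <- make_synthetic_rdcs(prot, S, fixture_spec(noise_hz = 0.5, seed = 21))
  fit <- fit_alignment_tensor(rd, nh_vectors(prot))
  expect_named(coef(fit), c("Sxx", "Syy", "Sxy", "Sxz", "Syz"))
  expect_equal(fitted(fit) + residuals(fit), fit$d_exp, tolerance = 1e-12)
  expect_equal(predict(fit), fit$d_calc)
  expect_equal(unname(predict(fit, prot)[fit$residues_used]),
               unname(fit$d_calc), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("Pearson r", out)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
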