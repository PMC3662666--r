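# Alignment-tensor fitting of 1H-15N residual dipolar couplings.
#
# D_i = u_i' S u_i with S the 3x3 symmetric traceless Saupe order matrix
# scaled into Hz (the dipolar prefactor is absorbed into S; all comparisons
# are in Hz). Five independent elements, solved from >= 5 couplings by SVD
# least squares on the direction-cosine design matrix.

.saupe_design <- function(vectors) {
  x <- vectors[, 1L]; y <- vectors[, 2L]; z <- vectors[, 3L]
  cbind(Sxx = x * x - z * z, Syy = y * y - z * z,
        Sxy = 2 * x * y, Sxz = 2 * x * z, Syz = 2 * y * z)
}

.saupe_matrix <- function(coefs) {
  m <- matrix(c(coefs[["Sxx"]], coefs[["Sxy"]], coefs[["Sxz"]],
                coefs[["Sxy"]], coefs[["Syy"]], coefs[["Syz"]],
                coefs[["Sxz"]], coefs[["Syz"]],
                -coefs[["Sxx"]] - coefs[["Syy"]]), 3L, 3L)
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  m
}

.saupe_coefs <- function(S) {
  c(Sxx = S[1L, 1L], Syy = S[2L, 2L], Sxy = S[1L, 2L],
    Sxz = S[1L, 3L], Syz = S[2L, 3L])
}

.as_vector_matrix <- function(vectors) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  m <- as.matrix(vectors)
  if (ncol(m) != 3L) .ringcsp_error("N-H vectors must be 3-vectors",
                                    "ringcsp_bad_input")
  m
}

#' Backbone N-H bond unit vectors
#'
#' Unit vectors from the amide nitrogen to its proton for every residue with
#' an amide proton (built with [build_amide_protons] defaults if missing).
#' Prolines and the N-terminus are absent; any residue still lacking a
#' proton after building is listed in the `"missing"` attribute.
#'
#' @param structure A `protein_structure`.
#' @return Numeric matrix (residues x 3) with residue-key row names and a
#'   `missing` attribute.
#' @export
nh_vectors <- function(structure) {
  if (any(is.na(structure$amides$hx) & structure$amides$resname != "PRO")) {
    structure <- build_amide_protons(structure)
  }
  am <- structure$amides
  has <- !is.na(am$hx)
  v <- as.matrix(am[has, c("hx", "hy", "hz")]) -
    as.matrix(am[has, c("nx", "ny", "nz")])
  v <- v / sqrt(rowSums(v^2))
  dimnames(v) <- list(rownames(am)[has], c("x", "y", "z"))
  attr(v, "missing") <- rownames(am)[!has]
  v
}

#' Fit the molecular alignment tensor to RDCs by SVD
#'
#' Least-squares solution (via singular value decomposition) of the linear
#' system relating the five independent Saupe elements to the observed
#' couplings, over the residues shared between the RDC set and the N-H
#' vector set. Overlapped/missing residues are handled by key intersection.
#' Plain (unweighted) least squares: no per-residue uncertainties are
#' assumed.
#'
#' @param rdcs An `rdc_set` (or any data frame with residue-key row names
#'   and an `rdc_hz` column), in Hz.
#' @param vectors Unit N-H vectors with residue-key row names, from
#'   [nh_vectors].
#' @return An `rdcfit` object: the Saupe tensor (`saupe`, 3x3 symmetric
#'   traceless, Hz scale), its five coefficients, per-residue `d_exp` /
#'   `d_calc`, `pearson_r`, `q_factor`, `residues_used` and the design
#'   singular values. Errors (with classes `ringcsp_underdetermined`,
#'   `ringcsp_rank_deficient`) for < 5 shared residues or degenerate vector
#'   geometry (e.g. all vectors parallel).
#' @seealso [back_calculate_rdc], [fit_quality], [compare_structures]
#' @export
fit_alignment_tensor <- function(rdcs, vectors) {
  vectors <- .as_vector_matrix(vectors)
  shared <- intersect(rownames(rdcs), rownames(vectors))
  if (length(shared) < 5L) {
    .ringcsp_error(sprintf(
      "alignment tensor needs >= 5 shared residues, got %d", length(shared)),
      "ringcsp_underdetermined")
  }
  v <- vectors[shared, , drop = FALSE]
  d <- stats::setNames(rdcs[shared, "rdc_hz"], shared)
  A <- .saupe_design(v)
  sv <- svd(A)
  if (sv$d[5L] < max(sv$d) * 1e-8) {
    .ringcsp_error("degenerate N-H vector geometry: design matrix rank < 5",
                   "ringcsp_rank_deficient")
  }
  coefs <- stats::setNames(
    as.numeric(sv$v %*% ((t(sv$u) %*% d) / sv$d)), colnames(A))
  S <- .saupe_matrix(coefs)
  d_calc <- stats::setNames(as.numeric(A %*% coefs), shared)
  q <- fit_quality(d, d_calc)
  structure(list(saupe = S, coefs = coefs, d_exp = d, d_calc = d_calc,
                 pearson_r = q[["pearson_r"]], q_factor = q[["q_factor"]],
                 residues_used = shared, n = length(shared),
                 singular_values = sv$d),
            class = "rdcfit")
}

#' Back-calculate RDCs from an alignment tensor
#'
#' `D_i = u_i' S u_i`; linear in the tensor, so the zero tensor gives zero
#' couplings and scaling the tensor scales every coupling.
#'
#' @param tensor 3x3 symmetric traceless Saupe matrix (Hz scale), or an
#'   `rdcfit` object.
#' @param vectors Unit N-H vectors with residue-key row names.
#' @return Named numeric vector of couplings in Hz.
#' @export
back_calculate_rdc <- function(tensor, vectors) {
  if (inherits(tensor, "rdcfit")) tensor <- tensor$saupe
  if (abs(sum(diag(tensor))) > 1e-6 * (max(abs(tensor)) + 1e-300)) {
    .ringcsp_error("tensor is not traceless", "ringcsp_bad_input")
  }
  v <- .as_vector_matrix(vectors)
  stats::setNames(rowSums((v %*% tensor) * v), rownames(v))
}

#' Correlation and quality factor between observed and back-calculated RDCs
#'
#' Pearson sample correlation and `Q = rms(d_exp - d_calc) / rms(d_exp)`
#' over the residues shared by the two maps (the simpler of the cited
#' normalisations; a Da-based Q is out of scope).
#'
#' @param d_exp,d_calc Named numeric vectors of couplings in Hz.
#' @return Named numeric vector `c(pearson_r, q_factor)`.
#' @export
fit_quality <- function(d_exp, d_calc) {
  shared <- intersect(names(d_exp), names(d_calc))
  if (length(shared) < 2L) {
    .ringcsp_error("need >= 2 shared residues", "ringcsp_bad_input")
  }
  e <- d_exp[shared]
  c_ <- d_calc[shared]
  if (stats::var(e) == 0) {
    .ringcsp_error("zero variance in observed RDCs: correlation undefined",
                   "ringcsp_bad_input")
  }
  rms_e <- sqrt(mean(e^2))
  if (rms_e == 0) {
    .ringcsp_error("rms of observed RDCs is zero: Q undefined",
                   "ringcsp_bad_input")
  }
  c(pearson_r = stats::cor(e, c_),
    q_factor = sqrt(mean((e - c_)^2)) / rms_e)
}

#' Flag RDC outliers
#'
#' Residues whose observed and back-calculated couplings differ by more than
#' `threshold` (default 6.5 Hz), sorted by deviation descending. In the
#' conformational-change reading these are the N-H bonds whose orientation
#' changed between states.
#'
#' @param d_exp,d_calc Named numeric vectors of couplings in Hz.
#' @param threshold Deviation threshold in Hz (> 0, default 6.5).
#' @return Character vector of residue keys with a `deviation` attribute.
#' @export
flag_rdc_outliers <- function(d_exp, d_calc, threshold = 6.5) {
  if (threshold <= 0) .ringcsp_error("threshold must be > 0", "ringcsp_bad_input")
  shared <- intersect(names(d_exp), names(d_calc))
  dev <- abs(d_exp[shared] - d_calc[shared])
  out <- dev[dev > threshold]
  out <- sort(out, decreasing = TRUE)
  structure(names(out), deviation = unname(out))
}

#' Rank candidate structures by RDC agreement
#'
#' Fits the alignment tensor independently for each structure (the tensor is
#' refit per structure: each row is self-contained) over the optionally
#' restricted residue subset, and ranks by Pearson correlation. Useful to
#' ask which known conformer a measured RDC set most resembles.
#'
#' @param rdcs An `rdc_set` in Hz.
#' @param structures List of `protein_structure` objects, optionally named;
#'   unnamed entries are labelled by their `source_id`.
#' @param residue_subset Optional character vector of residue keys (e.g. the
#'   helices of interest) restricting the fit.
#' @param outlier_threshold Passed to [flag_rdc_outliers] (default 6.5 Hz).
#' @return An `rdc_comparison` data frame (structure, pearson_r, q_factor,
#'   n_used, outliers, error) sorted by pearson_r descending; per-structure
#'   fit failures fill the `error` column instead of aborting. The fitted
#'   `rdcfit` objects are attached as the `"fits"` attribute.
#' @export
compare_structures <- function(rdcs, structures, residue_subset = NULL,
                               outlier_threshold = 6.5) {
  if (length(structures) == 0L) {
    .ringcsp_error("need at least one structure", "ringcsp_bad_input")
  }
  ids <- names(structures)
  if (is.null(ids)) ids <- rep("", length(structures))
  blank <- !nzchar(ids)
  ids[blank] <- vapply(structures[blank], function(s) s$source_id, character(1L))
  rows <- vector("list", length(structures))
  fits <- stats::setNames(vector("list", length(structures)), ids)
  for (i in seq_along(structures)) {
    res <- tryCatch({
      v <- nh_vectors(structures[[i]])
      if (!is.null(residue_subset)) {
        v <- v[intersect(rownames(v), residue_subset), , drop = FALSE]
      }
      fit <- fit_alignment_tensor(rdcs, v)
      fits[[i]] <- fit
      ol <- flag_rdc_outliers(fit$d_exp, fit$d_calc, outlier_threshold)
      data.frame(structure = ids[i], pearson_r = fit$pearson_r,
                 q_factor = fit$q_factor, n_used = fit$n,
                 outliers = paste(ol, collapse = ","),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, ringcsp_error = function(e) {
      data.frame(structure = ids[i], pearson_r = NA_real_, q_factor = NA_real_,
                 n_used = NA_integer_, outliers = "",
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$pearson_r, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "outlier_threshold") <- outlier_threshold
  class(out) <- c("rdc_comparison", "data.frame")
  out
}

#' Write a structure-comparison table
#'
#' Tab-delimited with stable column order (structure, pearson_r, q_factor,
#' n_used, outliers) and the outlier threshold in a `#` header line.
#'
#' @param comparison An `rdc_comparison`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rdc_comparison <- function(comparison, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# outlier_threshold_hz: %g",
                     attr(comparison, "outlier_threshold")), con)
  utils::write.table(comparison[, c("structure", "pearson_r", "q_factor",
                                    "n_used", "outliers")],
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- rdcfit methods ---------------------------------------------------------

#' @export
print.rdcfit <- function(x, ...) {
  ev <- eigen(x$saupe, symmetric = TRUE)$values
  cat("Alignment tensor fit (SVD least squares)\n")
  cat(sprintf("  residues used: %d\n", x$n))
  cat(sprintf("  Pearson r: %.4f   Q factor: %.4f\n", x$pearson_r, x$q_factor))
  cat(sprintf("  Saupe eigenvalues (Hz): %s\n",
              paste(sprintf("%.3f", ev), collapse = ", ")))
  invisible(x)
}

#' @export
summary.rdcfit <- function(object, outlier_threshold = 6.5, ...) {
  ev <- sort(eigen(object$saupe, symmetric = TRUE)$values)
  # order by magnitude: |Szz| >= |Syy| >= |Sxx|
  o <- order(abs(ev))
  Sxx <- ev[o[1L]]; Syy <- ev[o[2L]]; Szz <- ev[o[3L]]
  out <- list(fit = object,
              eigenvalues = c(Sxx = Sxx, Syy = Syy, Szz = Szz),
              Da = Szz / 2,
              rhombicity = (Syy - Sxx) / Szz * (2 / 3),
              outliers = flag_rdc_outliers(object$d_exp, object$d_calc,
                                           outlier_threshold),
              residuals = object$d_exp - object$d_calc)
  class(out) <- "summary.rdcfit"
  out
}

#' @export
print.summary.rdcfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Da: %.3f Hz   rhombicity: %.3f\n", x$Da, x$rhombicity))
  if (length(x$outliers)) {
    cat(sprintf("  outliers (|dev| > threshold): %s\n",
                paste(x$outliers, collapse = ", ")))
  } else {
    cat("  no outliers\n")
  }
  cat(sprintf("  residual rms: %.3f Hz\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.rdcfit <- function(object, ...) object$coefs

#' @export
fitted.rdcfit <- function(object, ...) object$d_calc

#' @export
residuals.rdcfit <- function(object, ...) object$d_exp - object$d_calc

#' Predict couplings from a fitted alignment tensor
#'
#' @param object An `rdcfit`.
#' @param newdata Unit N-H vectors (matrix with residue-key row names) or a
#'   `protein_structure`; default the fitting vectors' couplings.
#' @param ... Unused.
#' @return Named numeric vector of back-calculated couplings in Hz.
#' @export
predict.rdcfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$d_calc)
  if (inherits(newdata, "protein_structure")) newdata <- nh_vectors(newdata)
  back_calculate_rdc(object$saupe, newdata)
}

#' Simulate RDC sets from a fitted tensor
#'
#' Draws `nsim` replicates of the back-calculated couplings with Gaussian
#' noise at the fit's residual standard deviation — a quick parametric
#' bootstrap for the fit.
#'
#' @param object An `rdcfit`.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame (residues x nsim) of couplings in Hz.
#' @export
simulate.rdcfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdres <- stats::sd(object$d_exp - object$d_calc)
  out <- as.data.frame(replicate(
    nsim, object$d_calc + stats::rnorm(object$n, 0, sdres)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$residues_used
  out
}

#' @rdname fit_alignment_tensor
#' @param x An `rdcfit`.
#' @param outlier_threshold Deviation (Hz) above which points are labelled.
#' @param ... Passed to [graphics::plot].
#' @details `plot()` draws observed vs back-calculated couplings with the
#'   identity line and labels outliers.
#' @export
plot.rdcfit <- function(x, outlier_threshold = 6.5, ...) {
  graphics::plot(x$d_calc, x$d_exp, pch = 16,
                 xlab = "back-calculated RDC (Hz)",
                 ylab = "observed RDC (Hz)",
                 main = sprintf("r = %.3f, Q = %.3f", x$pearson_r, x$q_factor),
                 ...)
  graphics::abline(0, 1, lty = 2)
  ol <- flag_rdc_outliers(x$d_exp, x$d_calc, outlier_threshold)
  if (length(ol)) {
    graphics::text(x$d_calc[ol], x$d_exp[ol], ol, pos = 3, cex = 0.7,
                   col = "red")
  }
  invisible(x)
}

#' Write per-residue fit results
#'
#' Tab-delimited residue, observed, back-calculated, residual (Hz).
#'
#' @param fit An `rdcfit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rdc_fit <- function(fit, path) {
  utils::write.table(
    data.frame(residue = fit$residues_used,
               d_exp_hz = unname(fit$d_exp),
               d_calc_hz = unname(fit$d_calc),
               residual_hz = unname(fit$d_exp - fit$d_calc)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
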