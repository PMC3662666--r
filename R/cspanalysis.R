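# Experimental CSPs, P-factor pose scoring, cluster aggregation, and
# disagreement flagging (the conformational-change readout).

#' Experimental chemical shift perturbations
#'
#' Per-residue CSPs between a free and a ligand-bound peak list:
#' `csp_h = |dH_bound - dH_free|`, `csp_n = |dN_bound - dN_free|`, and the
#' combined perturbation `sqrt(csp_h^2 + (n_weight * csp_n)^2)`. The 0.14
#' nitrogen weight is the standard amide scaling from the combined-CSP
#' literature; combined CSP is used for binding-site mapping only, never for
#' pose scoring. Residues present in only one list are reported as unmatched,
#' not scored.
#'
#' @param free,bound `peak_list` objects for the two states.
#' @param n_weight Nitrogen scaling weight (default 0.14).
#' @return A `csp_table`: data frame (chain, resno, csp_h, csp_n,
#'   csp_combined) with residue-key row names and attributes
#'   `unmatched_free`, `unmatched_bound`, `n_weight`.
#' @export
compute_experimental_csp <- function(free, bound, n_weight = 0.14) {
  kf <- rownames(free$entries)
  kb <- rownames(bound$entries)
  shared <- intersect(kf, kb)
  if (length(shared) == 0L) {
    .ringcsp_error("free and bound peak lists share no residues",
                   "ringcsp_no_overlap")
  }
  f <- free$entries[shared, ]
  b <- bound$entries[shared, ]
  csp_h <- abs(b$delta_h - f$delta_h)
  csp_n <- abs(b$delta_n - f$delta_n)
  out <- data.frame(chain = f$chain, resno = f$resno,
                    csp_h = csp_h, csp_n = csp_n,
                    csp_combined = sqrt(csp_h^2 + (n_weight * csp_n)^2),
                    stringsAsFactors = FALSE)
  rownames(out) <- shared
  attr(out, "unmatched_free") <- setdiff(kf, kb)
  attr(out, "unmatched_bound") <- setdiff(kb, kf)
  attr(out, "n_weight") <- n_weight
  class(out) <- c("csp_table", "data.frame")
  out
}

#' P factor: per-pose agreement between experimental and simulated CSPs
#'
#' For each pose k the agreement factor over residues carrying both an
#' experimental and a simulated proton CSP is, in `mad` mode,
#' `P_k = (1/N) * sum |csp_h_exp - csp_h_sim,k|`, and in `rmsd` mode
#' `P_k = sqrt((1/N) * sum (csp_h_exp - csp_h_sim,k)^2)`. N is the
#' caller-supplied total residue count of the protein (e.g. 196 for
#' Bcl-xL), not the number of observed residues: residues missing from
#' experiment contribute zero to the sum but still dilute the normalisation,
#' so P stays comparable across pose sets with different coverage. Low P
#' means good agreement.
#'
#' @param exp A `csp_table` from [compute_experimental_csp].
#' @param sim A `csp_matrix` from [simulate_ensemble].
#' @param n_residues Total residue count N (must be >= number of shared
#'   residues).
#' @param mode `"mad"` (mean absolute deviation, default) or `"rmsd"`.
#' @return A `pose_scores` data frame (pose_id, cluster_id, p_value,
#'   n_residues_used) with attributes `mode` and `n_residues`.
#' @export
p_factor <- function(exp, sim, n_residues, mode = c("mad", "rmsd")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_residues) || n_residues <= 0) {
    .ringcsp_error("n_residues must be a positive integer", "ringcsp_bad_input")
  }
  shared <- intersect(rownames(exp), rownames(sim))
  if (length(shared) == 0L) {
    .ringcsp_error("experimental and simulated CSPs share no residues",
                   "ringcsp_no_overlap")
  }
  if (n_residues < length(shared)) {
    .ringcsp_error("n_residues is smaller than the number of shared residues",
                   "ringcsp_bad_input")
  }
  e <- exp[shared, "csp_h"]
  s <- unclass(sim)[shared, , drop = FALSE]
  diffs <- sweep(s, 1L, e)
  p <- switch(mode,
              mad = colSums(abs(diffs)) / n_residues,
              rmsd = sqrt(colSums(diffs^2) / n_residues))
  cl <- attr(sim, "cluster_id") %||% rep(NA_integer_, ncol(s))
  out <- data.frame(pose_id = colnames(s), cluster_id = cl,
                    p_value = unname(p),
                    n_residues_used = length(shared),
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "n_residues") <- n_residues
  class(out) <- c("pose_scores", "data.frame")
  out
}

#' Aggregate pose scores by docking cluster
#'
#' Arithmetic mean, minimum, maximum and count of P per cluster; poses
#' without a cluster label are grouped under `"unclustered"`. The global P
#' range across all poses is attached as attributes.
#'
#' @param scores A `pose_scores` data frame from [p_factor].
#' @return A `cluster_summary` data frame (cluster_id, n_poses, mean_p,
#'   min_p, max_p) with attributes `global_min`, `global_max`.
#' @export
aggregate_clusters <- function(scores) {
  if (nrow(scores) == 0L) {
    .ringcsp_error("no pose scores to aggregate", "ringcsp_bad_input")
  }
  cl <- ifelse(is.na(scores$cluster_id), "unclustered",
               as.character(scores$cluster_id))
  sp <- split(scores$p_value, cl)
  out <- data.frame(
    cluster_id = names(sp),
    n_poses = vapply(sp, length, integer(1L)),
    mean_p = vapply(sp, mean, numeric(1L)),
    min_p = vapply(sp, min, numeric(1L)),
    max_p = vapply(sp, max, numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "global_min") <- min(scores$p_value)
  attr(out, "global_max") <- max(scores$p_value)
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("P factor over %d cluster(s); global range [%.4g, %.4g]\n",
              nrow(x), attr(x, "global_min"), attr(x, "global_max")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Flag residues whose experimental CSP no pose can explain
#'
#' For each residue observed in both experiment and simulation, computes
#' `delta = csp_h_exp - max(csp_h_sim)` over the in-scope poses and assigns
#' a tier: `strong` when delta exceeds `strong_threshold` (default 0.2 ppm),
#' `moderate` when it exceeds `moderate_threshold` (default 0.06 ppm),
#' `sim_exceeds_exp` when delta is negative, else `none`. Experimental CSP
#' larger than every simulated value is unexpected unless the protein itself
#' rearranges — those are the conformational-change candidates. The reverse
#' (simulation exceeding experiment) is tolerated: docking can place the
#' ligand unphysically close, and unsaturated binding caps experimental
#' CSPs.
#'
#' @param exp A `csp_table`.
#' @param sim A `csp_matrix`.
#' @param strong_threshold,moderate_threshold Tier cut-offs in ppm
#'   (defaults 0.2 and 0.06; must satisfy strong > moderate > 0).
#' @param scope `"all"` (default) or a vector of cluster ids restricting
#'   which poses the per-residue maximum runs over.
#' @return A `csp_disagreement` data frame (chain, resno, csp_h_exp,
#'   max_csp_h_sim, delta, tier) sorted by delta descending, with the
#'   thresholds and scope as attributes.
#' @export
flag_disagreement <- function(exp, sim, strong_threshold = 0.2,
                              moderate_threshold = 0.06, scope = "all") {
  if (!(strong_threshold > moderate_threshold && moderate_threshold > 0)) {
    .ringcsp_error("need strong_threshold > moderate_threshold > 0",
                   "ringcsp_bad_input")
  }
  s <- unclass(sim)
  if (!identical(scope, "all")) {
    cl <- attr(sim, "cluster_id")
    cols <- which(cl %in% scope)
    if (length(cols) == 0L) {
      .ringcsp_error("scope matches no poses", "ringcsp_bad_input")
    }
    s <- s[, cols, drop = FALSE]
  }
  shared <- intersect(rownames(exp), rownames(s))
  if (length(shared) == 0L) {
    .ringcsp_error("experimental and simulated CSPs share no residues",
                   "ringcsp_no_overlap")
  }
  max_sim <- apply(s[shared, , drop = FALSE], 1L, max)
  e <- exp[shared, ]
  delta <- e$csp_h - max_sim
  tier <- ifelse(delta > strong_threshold, "strong",
                 ifelse(delta > moderate_threshold, "moderate",
                        ifelse(delta < 0, "sim_exceeds_exp", "none")))
  out <- data.frame(chain = e$chain, resno = e$resno, csp_h_exp = e$csp_h,
                    max_csp_h_sim = unname(max_sim), delta = unname(delta),
                    tier = tier, stringsAsFactors = FALSE)
  rownames(out) <- shared
  out <- out[order(-out$delta), ]
  attr(out, "strong_threshold") <- strong_threshold
  attr(out, "moderate_threshold") <- moderate_threshold
  attr(out, "scope") <- scope
  class(out) <- c("csp_disagreement", "data.frame")
  out
}

#' @export
print.csp_disagreement <- function(x, ...) {
  ns <- sum(x$tier == "strong")
  nm <- sum(x$tier == "moderate")
  cat(sprintf("CSP disagreement over %d residues: %d strong (> %.2f ppm), %d moderate (> %.2f ppm)\n",
              nrow(x), ns, attr(x, "strong_threshold"),
              nm, attr(x, "moderate_threshold")))
  flagged <- x[x$tier %in% c("strong", "moderate"), , drop = FALSE]
  if (nrow(flagged)) print.data.frame(flagged, ...)
  invisible(x)
}

#' @rdname flag_disagreement
#' @param x A `csp_disagreement` report.
#' @param ... Passed to [graphics::plot].
#' @details `plot()` draws experimental CSPs against the per-residue maximum
#'   simulated CSP along the sequence, marking flagged residues.
#' @export
plot.csp_disagreement <- function(x, ...) {
  o <- order(x$resno)
  graphics::plot(x$resno[o], x$csp_h_exp[o], type = "h", col = "red",
                 xlab = "residue", ylab = "CSP_H (ppm)",
                 main = "experimental (red) vs max simulated (blue) CSP", ...)
  graphics::points(x$resno[o], x$max_csp_h_sim[o], col = "blue", pch = 16,
                   cex = 0.6)
  fl <- x$tier %in% c("strong", "moderate")
  if (any(fl)) {
    graphics::points(x$resno[fl], x$csp_h_exp[fl], col = "darkorange", pch = 8)
  }
  invisible(x)
}

#' Write a disagreement report / residue attribute file
#'
#' The report is tab-delimited with a `#`-prefixed header echoing the
#' thresholds and scope. The attribute file maps residue key to delta (ppm),
#' suitable for colouring a structure viewer.
#'
#' @param report A `csp_disagreement`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_disagreement <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# strong_threshold_ppm: %g", attr(report, "strong_threshold")),
               sprintf("# moderate_threshold_ppm: %g", attr(report, "moderate_threshold")),
               sprintf("# scope: %s", paste(attr(report, "scope"), collapse = ","))),
             con)
  utils::write.table(data.frame(residue = rownames(report), report),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_disagreement
#' @export
write_residue_attributes <- function(report, path) {
  utils::write.table(
    data.frame(residue = rownames(report), delta = report$delta),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
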