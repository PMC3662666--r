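# Independent brute-force Haigh-Mallion evaluator and small constructors
# used across the suite. The oracle shares no code with the package paths it
# checks: Newell polygon normal (not an SVD plane), explicit 2D in-plane
# coordinates, shoelace triangle areas.

hm_oracle <- function(proton, coords, intensity = 1, B = 1) {
  n <- nrow(coords)
  nxt <- c(2:n, 1L)
  nw <- c(sum((coords[, 2] - coords[nxt, 2]) * (coords[, 3] + coords[nxt, 3])),
          sum((coords[, 3] - coords[nxt, 3]) * (coords[, 1] + coords[nxt, 1])),
          sum((coords[, 1] - coords[nxt, 1]) * (coords[, 2] + coords[nxt, 2])))
  nv <- nw / sqrt(sum(nw^2))
  cen <- colMeans(coords)
  e1 <- coords[1, ] - cen
  e1 <- e1 - sum(e1 * nv) * nv
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
          nv[3] * e1[1] - nv[1] * e1[3],
          nv[1] * e1[2] - nv[2] * e1[1])
  to2d <- function(x) c(sum((x - cen) * e1), sum((x - cen) * e2))
  p2 <- to2d(proton)
  G <- 0
  for (k in seq_len(n)) {
    a <- coords[k, ]
    b <- coords[nxt[k], ]
    a2 <- to2d(a)
    b2 <- to2d(b)
    S <- 0.5 * ((a2[1] - p2[1]) * (b2[2] - p2[2]) -
                  (b2[1] - p2[1]) * (a2[2] - p2[2]))
    ra <- sqrt(sum((proton - a)^2))
    rb <- sqrt(sum((proton - b)^2))
    G <- G + S * (1 / ra^3 + 1 / rb^3)
  }
  -intensity * B * G
}

regular_polygon <- function(n = 6, radius = 1.39) {
  ang <- (seq_len(n) - 1) * 2 * pi / n
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# a random planar aromatic ring in general position + a proton nearby
random_ring_config <- function() {
  n <- sample(c(5L, 6L), 1L)
  coords <- regular_polygon(n, stats::runif(1, 1.2, 1.5))
  R <- random_rotation()
  t <- stats::rnorm(3, 0, 10)
  coords <- sweep(coords %*% t(R), 2, t, "+")
  repeat {
    p <- t + stats::rnorm(3, 0, 4)
    if (min(sqrt(rowSums(sweep(coords, 2, p)^2))) > 1.0) break
  }
  list(coords = coords, proton = p)
}

make_test_peaklist <- function(resno, delta_h, delta_n = rep(118, length(resno)),
                               chain = "A", state = "test") {
  e <- data.frame(chain = chain, resno = as.integer(resno),
                  resname = NA_character_, delta_h = delta_h,
                  delta_n = delta_n, stringsAsFactors = FALSE)
  rownames(e) <- residue_key(e$chain, e$resno)
  structure(list(state_label = state, entries = e,
                 ligand_concentration = NA_real_),
            class = "peak_list")
}

make_test_rdcset <- function(values, keys = names(values)) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, character(1), 1),
                    resno = as.integer(vapply(parts, `[`, character(1), 2)),
                    rdc_hz = unname(values), stringsAsFactors = FALSE)
  rownames(out) <- keys
  class(out) <- c("rdc_set", "data.frame")
  out
}

# random unit N-H vectors with residue keys
random_unit_vectors <- function(n, chain = "A") {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- residue_key(chain, seq_len(n))
  v
}
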