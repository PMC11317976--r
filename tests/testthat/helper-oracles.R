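# Independent oracles and small fixture builders. Everything here stays
# deliberately naive: the oracles must not share code paths with the package
# internals they check.

# Monte-Carlo union-of-spheres surface area: random points uniformly on each
# sphere, rejected when buried inside any other sphere. Independent of the
# deterministic golden-spiral quadrature in the package.
mc_union_area <- function(centers, radii, n_points = 1e6, seed = 42) {
  set.seed(seed)
  k <- nrow(centers)
  per <- ceiling(n_points / k)
  total <- 0
  for (i in seq_len(k)) {
    u <- matrix(stats::rnorm(per * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * radii[i], 2, centers[i, ], "+")
    exposed <- rep(TRUE, per)
    for (j in seq_len(k)) {
      if (j == i) next
      d2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
        (p[, 3] - centers[j, 3])^2
      exposed <- exposed & d2 >= radii[j]^2
    }
    total <- total + mean(exposed) * 4 * pi * radii[i]^2
  }
  total
}

# Random rotation matrix from a QR decomposition (seeded by caller).
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

write_temp_xyz <- function(lines) {
  f <- tempfile(fileext = ".xyz")
  writeLines(lines, f)
  f
}

# Generic (no symmetry) four-atom test molecule used across surface tests.
generic_geometry <- function() {
  geometry(c("C", "N", "O", "H"),
           rbind(c(0.00, 0.00, 0.00),
                 c(1.45, 0.10, -0.20),
                 c(-0.70, 1.15, 0.55),
                 c(0.35, -0.95, 0.85)))
}
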