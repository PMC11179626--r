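# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, pure bisection, and a frame-based
# dihedral so that agreement is a genuine cross-check.

# Positive root of K x^2 + (1 + K (m - xt)) x - xt = 0: the free ligand for
# a single class of n = 1 sites.
quad_free_ligand <- function(K, m, xt) {
  b <- 1 + K * (m - xt)
  # stable form: avoids the cancellation of (-b + sqrt(...)) for large b > 0
  ifelse(b >= 0,
         2 * xt / (b + sqrt(b^2 + 4 * K * xt)),
         (-b + sqrt(b^2 + 4 * K * xt)) / (2 * K))
}

# Pure bisection on [0, x_total], vectorised over draws; 80 halvings leave a
# bracket far below 1e-12 relative width.
bisect_free_ligand <- function(nmat, Kmat, m, xt, iters = 80L) {
  lo <- numeric(length(xt))
  hi <- xt
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    Kx <- Kmat * mid
    fx <- mid + m * rowSums(nmat * Kx / (1 + Kx)) - xt
    pos <- fx > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Dihedral via an explicit orthonormal frame around the central bond
# (project the outer bonds onto the plane normal to it, then atan2 in that
# frame) -- an implementation route distinct from the package's
# normal-vector formula.
dihedral_frame_oracle <- function(p1, p2, p3, p4) {
  ez <- p3 - p2
  ez <- ez / sqrt(sum(ez^2))
  u <- (p1 - p2)
  u <- u - sum(u * ez) * ez
  v <- (p4 - p3)
  v <- v - sum(v * ez) * ez
  ex <- u / sqrt(sum(u^2))
  ey <- cross3v(ez, ex)
  atan2(sum(v * ey), sum(v * ex)) * 180 / pi
}

planar_angle_oracle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  atan2(sqrt(sum(cross3v(u, v)^2)), sum(u * v)) * 180 / pi
}

rand_atom_group <- function(n = 5L) {
  atom_group(matrix(rnorm(3 * n), n, 3), runif(n, 0.5, 20))
}

# A minimal synthetic PDB file whose CA atoms land inside the residue
# ranges of the shipped example CV configuration.
write_tiny_pdb <- function(path) {
  resno <- c(50, 150, 250, 350)
  xyz <- c(0, 0, 0,  10, 0, 0,  10, 10, 0,  0, 10, 10)
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno,
                   chain = rep("A", 4), elety = rep("CA", 4),
                   resid = rep("ALA", 4), eleno = seq_len(4))
  path
}

# Reorder fitted (N, K, H) triplets by decreasing K: site classes are
# exchangeable in a fully free fit, so comparisons use the canonical
# reporting order.
canonical_class_params <- function(values, n_classes) {
  stopifnot(length(values) >= 3 * n_classes)
  trip <- matrix(values[seq_len(3 * n_classes)], nrow = 3)  # N, K, H per col
  trip <- trip[, order(-trip[2, ]), drop = FALSE]
  c(as.numeric(trip), values[-seq_len(3 * n_classes)])
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), .Machine$double.xmin)), tol)
}
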