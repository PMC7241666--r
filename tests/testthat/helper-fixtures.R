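# Shared fixtures and independent oracles for the test suite.
# Fixtures are built in code; oracles are deliberately naive implementations
# (grid search, closed forms, direct summation) independent of the package's
# computational path.

# A tiny tripeptide with waters, used by parsing/selection tests.
tiny_peptide <- function(n_waters = 2) {
  build_toy_topology(c("ALA", "SER", "GLY"), n_waters = n_waters)
}

# Euler-grid + local-refinement brute-force minimizer of superposition RMSD.
# Scans a dense rotation grid (vectorized through the trace identity
# |M R' - Rf|^2 = |M|^2 + |Rf|^2 - 2 tr(R M' Rf)), then polishes the best
# grid angles by Nelder-Mead. Deliberately independent of the SVD route.
euler_rot <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

euler_grid <- local({
  cache <- NULL
  function(step_deg = 10) {
    if (!is.null(cache) && attr(cache, "step") == step_deg) return(cache)
    angs <- seq(0, 2 * pi - 1e-9, by = step_deg * pi / 180)
    grid <- as.matrix(expand.grid(angs, angs, angs))
    rots <- t(apply(grid, 1, function(a) as.numeric(euler_rot(a))))
    out <- list(angles = grid, rot9 = rots)
    attr(out, "step") <- step_deg
    cache <<- out
    out
  }
})

grid_search_rmsd <- function(mobile, reference, step_deg = 10) {
  M <- sweep(mobile, 2, colMeans(mobile))
  Rf <- sweep(reference, 2, colMeans(reference))
  n <- nrow(M)
  const <- sum(M^2) + sum(Rf^2)
  A <- crossprod(M, Rf)                     # 3x3, tr(R A) = sum(R * t(A))
  g <- euler_grid(step_deg)
  scores <- const - 2 * as.numeric(g$rot9 %*% as.numeric(t(A)))
  best <- which.min(scores)
  obj <- function(ang) {
    R <- euler_rot(ang)
    sqrt(max(0, (const - 2 * sum(R * t(A))) / n))
  }
  opt <- stats::optim(g$angles[best, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  min(sqrt(max(0, scores[best] / n)), opt$value)
}

# Exposed area of sphere 1 when two probe-inflated spheres intersect
# (spherical-cap closed form).
two_sphere_exposed_area <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1
}

# Direct sums-of-squares one-way ANOVA (textbook decomposition).
anova_ss_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, df1 = df1, df2 = df2, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Random rigid motion applied to an n x 3 coordinate set.
random_rigid_motion <- function(coords) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
  sweep(coords %*% t(R), 2, stats::rnorm(3, sd = 5), "+")
}

# Minimal hand-placed H-bond fixture: one donor-H and one acceptor at a
# prescribed donor-acceptor distance and D-H-A angle.
hbond_geometry_traj <- function(da_dist, dha_angle_deg) {
  # donor N at origin with H along +x; acceptor placed so that the angle at
  # the hydrogen equals dha_angle_deg and |D-A| = da_dist.
  d <- c(0, 0, 0); h <- c(1, 0, 0)
  # position acceptor in the xy-plane: A = H + t * u with angle(HD, HA) given
  ang <- dha_angle_deg * pi / 180
  u <- c(cos(pi - ang), sin(pi - ang), 0)  # angle between u and (D-H)=( -x )
  # solve |D - (H + t u)| = da_dist for t > 0
  b <- 2 * sum((h - d) * u)
  cc <- sum((h - d)^2) - da_dist^2
  t <- (-b + sqrt(b^2 - 4 * cc)) / 2
  a <- h + t * u
  atoms <- data.frame(
    serial = 1:6,
    name = c("N", "CA", "C", "H", "OG", "CB"),
    resname = c("GLY", "GLY", "GLY", "GLY", "SER", "SER"),
    resseq = c(1, 1, 1, 1, 2, 2),
    chain = "A",
    stringsAsFactors = FALSE
  )
  coords <- rbind(d, c(-1.3, 0.8, 0), c(-2.5, 0, 0), h, a, a + c(0, 1.4, 0))
  topo <- build_topology(atoms, coords)
  trajectory(topo, array(coords, dim = c(6, 3, 1)))
}
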