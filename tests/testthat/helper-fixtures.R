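# Shared fixtures and independent oracles, built in code at test time.

# Synthetic backbone structure: n_res residues with N, CA, C, O atoms laid
# along a loose helix (geometry is irrelevant for selection tests).
make_backbone_structure <- function(n_res = 80, chain = "A", start = 1) {
  t <- seq_len(n_res)
  rows <- list()
  for (i in t) {
    base <- c(2.3 * cos(i * 1.745), 2.3 * sin(i * 1.745), 1.5 * i)
    offs <- list(N = c(-0.5, 0.4, -0.6), CA = c(0, 0, 0),
                 C = c(0.6, -0.3, 0.5), O = c(1.2, 0.2, 0.8))
    for (a in names(offs)) {
      p <- base + offs[[a]]
      rows[[length(rows) + 1]] <- data.frame(
        resno = start + i - 1, resid = "ALA", elety = a,
        x = p[1], y = p[2], z = p[3])
    }
  }
  chains <- list(do.call(rbind, rows))
  names(chains) <- chain
  structure_from_chains(chains)
}

random_points <- function(n, seed) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = 2), n, 3))
}

random_rotation <- function(seed) {
  withr::with_seed(seed,
    rotation_about(stats::rnorm(3), stats::runif(1, 0, 360)))
}

# Independent brute-force superposition oracle: exhaustive search over a
# ZYZ Euler-angle rotation grid, maximizing the alignment trace (the
# centered least-squares objective is linear in the rotation through
# tr(R M), M = t(P) Q -- an algebraic identity validated directly in the
# superposition tests).
oracle_grid_rmsd <- function(mobile, reference, step_deg = 6) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  M <- t(P) %*% Q
  n <- nrow(P)
  s2 <- sum(P^2) + sum(Q^2)
  a_grid <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  b_grid <- seq(0, 180, by = step_deg) * pi / 180
  c_grid <- a_grid
  bc <- expand.grid(b = b_grid, c = c_grid)
  cb <- cos(bc$b); sb <- sin(bc$b); cc <- cos(bc$c); sc <- sin(bc$c)
  best <- -Inf
  for (a in a_grid) {
    ca <- cos(a); sa <- sin(a)
    r11 <- ca * cb * cc - sa * sc; r12 <- -ca * cb * sc - sa * cc; r13 <- ca * sb
    r21 <- sa * cb * cc + ca * sc; r22 <- -sa * cb * sc + ca * cc; r23 <- sa * sb
    r31 <- -sb * cc;               r32 <- sb * sc;                 r33 <- cb
    tr <- r11 * M[1, 1] + r12 * M[2, 1] + r13 * M[3, 1] +
          r21 * M[1, 2] + r22 * M[2, 2] + r23 * M[3, 2] +
          r31 * M[1, 3] + r32 * M[2, 3] + r33 * M[3, 3]
    best <- max(best, max(tr))
  }
  sqrt(max(0, (s2 - 2 * best) / n))
}

# Literal evaluation of the superposition objective for one rotation,
# used to validate the trace shortcut above.
direct_rotation_rmsd <- function(mobile, reference, R) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}
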