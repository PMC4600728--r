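# Shared fixtures: small synthetic templates/lattices and oracles used across
# test files. All fixtures are built in code.

p2 <- function(x) (3 * x^2 - 1) / 2

small_template <- function(n_residues = 8) synthetic_chain_template(n_residues)

identity_lattice <- function(n_residues = 8, cell = c(30, 35, 40, 90, 90, 90)) {
  build_reference_lattice(
    lattice_spec(cell, n_chains_asu = 1,
                 chain_template = small_template(n_residues)))
}

orthorhombic_ops <- function() {
  list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(1, -1, -1)), t = c(0.5, 0.5, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0.5)),
    list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0.5))
  )
}

# the 24 proper signed-permutation matrices (octahedral rotation group),
# valid symmetry operators for a cubic cell
octahedral_ops <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  ops <- list()
  for (p in perms) {
    P <- diag(3)[p, ]
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      R <- diag(c(sx, sy, sz)) %*% P
      if (abs(det(R) - 1) < 1e-12) {
        ops[[length(ops) + 1]] <- list(R = R, t = c(0, 0, 0))
      }
    }
  }
  ops
}

# direct nested-loop P2 correlation oracle (all origins, all vectors)
nested_loop_corr <- function(mats, vectors, lags) {
  n <- dim(mats)[3]
  vapply(lags, function(lg) {
    tot <- 0; cnt <- 0
    for (t0 in seq_len(n - lg)) {
      for (k in seq_len(nrow(vectors))) {
        v1 <- mats[, , t0] %*% vectors[k, ]
        v2 <- mats[, , t0 + lg] %*% vectors[k, ]
        tot <- tot + p2(sum(v1 * v2))
        cnt <- cnt + 1
      }
    }
    tot / cnt
  }, numeric(1))
}

# analytic REDOR universal curve (Bessel closed form), lambda = D * t
redor_universal <- function(d_hz, times) {
  lam <- d_hz * times
  1 - (sqrt(2) * pi / 4) * besselJ(sqrt(2) * lam, 0.25) *
    besselJ(sqrt(2) * lam, -0.25)
}
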