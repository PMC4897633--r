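# Shared fixtures and independent brute-force oracles. Oracles are written
# against the raw definitions (no calls into the code paths they check).

aS <- alpha_syn_chain()

# --- brute-force superposition RMSD oracle -----------------------------------
# coarse Euler-angle grid search followed by Nelder-Mead refinement; entirely
# independent of the SVD-based Kabsch path.
euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

oracle_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  g <- seq(0, 2 * pi, length.out = 13)[-13]
  gb <- seq(0, pi, length.out = 7)
  best <- c(0, 0, 0); bv <- obj(best)
  for (a in g) for (b in gb) for (c in g) {
    v <- obj(c(a, b, c))
    if (v < bv) { bv <- v; best <- c(a, b, c) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# --- direct-summation dipole oracle ------------------------------------------
oracle_dipole <- function(conf, residues) {
  at <- conformation_atoms(conf)
  sel <- at[at$residue %in% residues, ]
  origin <- c(mean(sel$x), mean(sel$y), mean(sel$z))
  q <- ifelse(sel$atom == "SC" & sel$aa %in% c("K", "R"), 1,
              ifelse(sel$atom == "SC" & sel$aa %in% c("D", "E"), -1,
                     ifelse(sel$atom == "N" & sel$residue == 1, 1, 0)))
  mu <- c(sum(q * (sel$x - origin[1])), sum(q * (sel$y - origin[2])),
          sum(q * (sel$z - origin[3])))
  sqrt(sum(mu^2)) / 10
}

# --- misc --------------------------------------------------------------------
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rigid_copy <- function(conf, R = random_rotation(), t = rnorm(3, sd = 20)) {
  X <- conf$coords %*% t(R)
  X <- sweep(X, 2, t, "+")
  new_conformation(conf$chain, X, conf$phi, conf$psi)
}

# a deterministic "two-state" construction: n1 copies of one conformation and
# n2 of another, as a weighted ensemble
two_cluster_ensemble <- function(conf_a, conf_b, n_a, n_b) {
  ensemble_from_conformations(c(rep(list(conf_a), n_a),
                                rep(list(conf_b), n_b)))
}

# ensemble whose K6/D2 sidechain centroids sit within `near` Angstrom in an
# exact fraction of frames (coordinates edited directly)
planted_saltbridge_ensemble <- function(chain, frac, n = 200, near = 4,
                                        far = 20) {
  base <- build_ideal_helix(chain)
  n_near <- round(frac * n)
  confs <- lapply(seq_len(n), function(f) {
    X <- base$coords
    d2 <- X[memanchor:::atom_row(2L, "SC"), ]
    dir <- c(1, 0, 0)
    X[memanchor:::atom_row(6L, "SC"), ] <-
      d2 + dir * (if (f <= n_near) near else far)
    new_conformation(chain, X, base$phi, base$psi)
  })
  ensemble_from_conformations(confs)
}
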