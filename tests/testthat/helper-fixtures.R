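# Shared helpers: small synthetic inputs and independent oracles.

helix_chain <- function(n = 20) make_structure("ideal_helix", n)

# PDB text of a synthetic chain, optionally mutated line-by-line
chain_pdb_text <- function(chain) {
  f <- tempfile(fileext = ".pdb")
  write_chain(chain, f)
  on.exit(unlink(f))
  readLines(f)
}

# independent brute-force RMSD minimization over rotations (Euler angles +
# optimal translation), used as the oracle for the closed-form superposition
brute_force_rmsd <- function(mobile, target, n_starts = 8) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% rot(ang) - B)^2)))
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- runif(3, -pi, pi)
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# exhaustive medoid: member minimizing average pairwise RMSD to co-members,
# on the same common superposition the clustering used
exhaustive_medoid <- function(frames, members) {
  n <- nrow(frames[[1]])
  X <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  D <- as.matrix(dist(X[members, , drop = FALSE])) / sqrt(n)
  members[which.min(rowMeans(D))]
}

random_proper_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec) %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# independent R evaluation of the flat-bottom restraint sum
oracle_restraint_sum <- function(ca, restraints) {
  tot <- 0
  for (r in seq_len(nrow(restraints))) {
    d <- sqrt(sum((ca[restraints$i[r], ] - ca[restraints$j[r], ])^2))
    excess <- abs(d - restraints$d0[r]) - restraints$width[r]
    if (excess > 0) tot <- tot + restraints$k[r] * excess^2
  }
  tot
}

# independent R evaluation of the Calpha excluded-volume term
oracle_excluded_ca <- function(ca, radius = 3.0, k = 10, minsep = 2) {
  n <- nrow(ca)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < minsep) next
    d <- sqrt(sum((ca[i, ] - ca[j, ])^2))
    if (d < radius) tot <- tot + k * (radius - d)^2
  }
  tot
}

# dihedral angle with the standard sign convention
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2u <- b2 / sqrt(sum(b2^2))
  m <- c(n1[2] * b2u[3] - n1[3] * b2u[2], n1[3] * b2u[1] - n1[1] * b2u[3],
         n1[1] * b2u[2] - n1[2] * b2u[1])
  -atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
}
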