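# Synthetic structures and ensembles with known properties, so that every
# pipeline stage is testable without downloading real structures.

# internal-coordinate chain building (the NeRF construction): place atom D
# bonded to C with the given bond length, angle B-C-D and dihedral A-B-C-D
place_atom <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- unit2(C - B)
  n <- cross3(unit2(B - A), bc)
  n <- unit2(n)
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# build a full-backbone chain (N, CA, C, O and CB except Gly) from per-residue
# (phi, psi) with ideal bond lengths/angles and trans peptides
build_from_dihedrals <- function(phi, psi, sequence) {
  L <- length(phi)
  stopifnot(length(psi) == L, nchar(sequence) == L)
  aa <- strsplit(sequence, "")[[1]]

  N <- matrix(NA_real_, L, 3)
  CA <- matrix(NA_real_, L, 3)
  C <- matrix(NA_real_, L, 3)
  O <- matrix(NA_real_, L, 3)

  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111,
                             phi[i + 1])
    O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], 1.231, 120.8, 180)
  }
  O[L, ] <- place_atom(N[L, ], CA[L, ], C[L, ], 1.231, 120.8, 180)

  atoms <- list()
  for (i in seq_len(L)) {
    m <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O[i, ])
    if (aa[i] != "G")
      m <- rbind(m, CB = ideal_cb(N[i, ], CA[i, ], C[i, ]))
    atoms[[i]] <- data.frame(res = i, atom = rownames(m),
                             x = m[, 1], y = m[, 2], z = m[, 3],
                             stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  rownames(atoms) <- NULL
  structure(list(sequence = sequence, chain_id = "A",
                 numbering = seq_len(L), n_residues = L, atoms = atoms),
            class = "protein_chain")
}

#' Generate a synthetic test structure
#'
#' Builds a full-backbone single-chain structure from ideal internal
#' coordinates. Kinds: `ideal_helix` (alpha-helix dihedrals phi -57, psi -47:
#' rise about 1.5 Angstrom, about 100 degrees per residue), `extended`
#' (beta-strand dihedrals phi -139, psi 135), `helix_loop_helix` (two helices
#' joined by a polyproline-II-like coil linker), `poly_ala_n` (extended
#' poly-alanine of any length, e.g. 401 residues to probe the length rule),
#' and `beta_hairpin` (two antiparallel strands around a two-residue turn).
#'
#' @param kind One of the kinds above.
#' @param length Residue count (for `helix_loop_helix` a vector
#'   c(helix1, loop, helix2); for `beta_hairpin` the strand length).
#' @param sequence Optional one-letter sequence (defaults to poly-alanine of
#'   the right length).
#' @return A `protein_chain` (all non-boundary kinds pass
#'   [validate_chain()]).
#' @export
make_structure <- function(kind = c("ideal_helix", "extended",
                                    "helix_loop_helix", "poly_ala_n",
                                    "beta_hairpin"),
                           length = 20, sequence = NULL) {
  kind <- match.arg(kind)
  dihedrals <- switch(kind,
    ideal_helix = list(phi = rep(-57, length), psi = rep(-47, length)),
    extended = ,
    poly_ala_n = list(phi = rep(-139, length), psi = rep(135, length)),
    helix_loop_helix = {
      stopifnot(length(length) == 3)
      list(phi = c(rep(-57, length[1]), rep(-75, length[2]),
                   rep(-57, length[3])),
           psi = c(rep(-47, length[1]), rep(145, length[2]),
                   rep(-47, length[3])))
    },
    beta_hairpin = {
      n <- length[1]
      # two-residue type-II'-like turn between antiparallel strands
      list(phi = c(rep(-139, n), 60, -80, rep(-139, n)),
           psi = c(rep(135, n), -125, -10, rep(135, n)))
    })
  L <- length(dihedrals$phi)
  if (is.null(sequence)) sequence <- paste(rep("A", L), collapse = "")
  stopifnot(nchar(sequence) == L)
  build_from_dihedrals(dihedrals$phi, dihedrals$psi, sequence)
}

#' Generate a planted ensemble with known per-residue variance
#'
#' Frames are the base Calpha trace plus isotropic Gaussian noise with
#' per-residue standard deviation `sigmas`; each frame is then given a random
#' rigid transform (which superposition must remove). The ground-truth
#' mean-square fluctuation is msf_i = 3 * sigma_i^2.
#'
#' @param base A `protein_chain`, or an n x 3 Calpha matrix.
#' @param sigmas Per-residue noise standard deviation, Angstrom.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return List of n x 3 frames with attribute `truth_msf` = 3 * sigmas^2.
#' @export
make_planted_ensemble <- function(base, sigmas, n_frames = 2000, seed = 1) {
  ca <- if (inherits(base, "protein_chain")) chain_coords(base, "CA") else base
  n <- nrow(ca)
  stopifnot(length(sigmas) == n, all(sigmas >= 0))
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    noisy <- ca + matrix(rnorm(3 * n), n, 3) * sigmas
    R <- random_rotation()
    t0 <- runif(3, -10, 10)
    sweep(noisy %*% R, 2, t0, "+")
  })
  attr(frames, "truth_msf") <- 3 * sigmas^2
  frames
}

# uniform-ish random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  d <- diag(qr.R(qr_dec))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
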