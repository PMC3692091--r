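# Backbone reconstruction from a Calpha trace: peptide-plane atoms (C, O, N)
# placed analytically in local frames built from quadrilaterals of four
# consecutive Calpha, followed by ideal tetrahedral Cbeta. A deterministic,
# dependency-free stand-in for lookup-library reconstruction; fidelity is
# audited by the geometry invariants rather than learned from structures.

# offsets of the peptide atoms in the local (e1, e2) frame of an ideal trans
# peptide with Calpha-Calpha 3.804 A (e1 along Calpha_i -> Calpha_{i+1}, e2
# in the peptide plane); derived once from ideal internal coordinates
# (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A, CA-C-N 116.2, C-N-CA
# 121.7 degrees, omega 180)
PEPTIDE_N_OFFSET <- c(-1.408317, 0.3773686)   # N_{i+1} relative to Calpha_{i+1}
PEPTIDE_C_IDEAL <- c(1.428421, -0.5340768)    # C_i relative to Calpha_i
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_N_CA <- 1.458
BOND_C_O <- 1.231

#' Rebuild backbone atoms and Cbeta from a Calpha trace
#'
#' For each peptide between consecutive Calpha a local orthonormal frame is
#' built from the surrounding quadrilateral of four Calpha (extrapolated
#' frames at the termini). N is placed at its ideal offset from the following
#' Calpha; C is then placed in the peptide plane so that both the CA-C and
#' C-N bond lengths take their ideal values exactly (a two-circle
#' intersection in the plane), which keeps every bond inside its audit window
#' for any trace with pseudo-bonds in [3.2, 4.2] Angstrom; O is placed in the
#' peptide plane opposite N. Cbeta is built by ideal tetrahedral geometry
#' from N, CA, C. Input Calpha positions are preserved exactly.
#'
#' @param ca_trace Calpha coordinate matrix (n x 3, n >= 4) with consecutive
#'   distances in [3.2, 4.2] Angstrom.
#' @return An object of class `backbone_model`: matrices `n`, `ca`, `c`,
#'   `o`, `cb` (n x 3 each).
#' @export
rebuild_backbone <- function(ca_trace) {
  stopifnot(is.matrix(ca_trace), ncol(ca_trace) == 3)
  L <- nrow(ca_trace)
  if (L < 4) stop("backbone reconstruction needs at least 4 residues",
                  call. = FALSE)
  bonds <- sqrt(rowSums((ca_trace[-1, ] - ca_trace[-L, ])^2))
  if (any(bonds < 3.2 | bonds > 4.2))
    stop("Calpha pseudo-bond outside [3.2, 4.2] Angstrom in input trace",
         call. = FALSE)

  # extend by one virtual residue at each end so every real peptide and both
  # terminal N/C groups come out of the same placement rule
  ext <- rbind(2 * ca_trace[1, ] - ca_trace[2, ],
               ca_trace,
               2 * ca_trace[L, ] - ca_trace[L - 1, ])

  Nn <- matrix(NA_real_, L, 3)
  Cc <- matrix(NA_real_, L, 3)
  Oo <- matrix(NA_real_, L, 3)

  ne <- nrow(ext)
  for (p in seq_len(ne - 1)) {       # peptide ext[p] -> ext[p + 1]
    ca1 <- ext[p, ]; ca2 <- ext[p + 1, ]
    e1 <- ca2 - ca1
    d <- vnorm(e1)
    e1 <- e1 / d
    h <- ext[min(p + 2, ne), ] - ext[max(p - 1, 1), ]
    nrm <- cross3(e1, h)
    if (vnorm(nrm) < 1e-8) {
      # terminal quadrilaterals collapse onto the bond axis (the virtual
      # extension is collinear); widen to the next real neighbours first
      h <- ext[min(p + 3, ne), ] - ext[max(p - 2, 1), ]
      nrm <- cross3(e1, h)
    }
    if (vnorm(nrm) < 1e-8) {          # genuinely collinear trace
      ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      nrm <- cross3(e1, ref)
    }
    nrm <- nrm / vnorm(nrm)
    # in-plane axis oriented to match the handedness of real chains
    e2 <- cross3(e1, nrm)

    Npos <- ca2 + BOND_N_CA *
      unit2(PEPTIDE_N_OFFSET[1] * e1 + PEPTIDE_N_OFFSET[2] * e2)
    Cpos <- place_peptide_c(ca1, Npos, e1, e2)
    u1 <- unit2(Npos - Cpos)
    u2 <- unit2(ca1 - Cpos)
    Opos <- Cpos + BOND_C_O * unit2(-(u1 + u2))

    res_c <- p - 1L                   # real residue owning C_i, O_i
    res_n <- p                        # real residue owning N_{i+1}
    if (res_c >= 1 && res_c <= L) { Cc[res_c, ] <- Cpos; Oo[res_c, ] <- Opos }
    if (res_n >= 1 && res_n <= L) Nn[res_n, ] <- Npos
  }

  CB <- matrix(NA_real_, L, 3)
  for (i in seq_len(L))
    CB[i, ] <- ideal_cb(Nn[i, ], ca_trace[i, ], Cc[i, ])

  structure(list(n = Nn, ca = ca_trace, c = Cc, o = Oo, cb = CB),
            class = "backbone_model")
}

# in-plane two-circle intersection: |C - ca1| = BOND_CA_C and |C - N| =
# BOND_C_N; of the two roots, the one nearer the ideal C position is taken.
# If the circles do not intersect (outside the admissible pseudo-bond range)
# the closest feasible point on the ca1 circle is used.
place_peptide_c <- function(ca1, Npos, e1, e2) {
  p <- c(sum((Npos - ca1) * e1), sum((Npos - ca1) * e2))
  dd <- sqrt(sum(p^2))
  r1 <- BOND_CA_C
  r2 <- BOND_C_N
  if (dd > r1 + r2 || dd < abs(r1 - r2)) {
    sol <- p / dd * r1
  } else {
    a <- (r1^2 - r2^2 + dd^2) / (2 * dd)
    h2 <- r1^2 - a^2
    h <- sqrt(max(h2, 0))
    base <- p / dd * a
    perp <- c(-p[2], p[1]) / dd * h
    cand1 <- base + perp
    cand2 <- base - perp
    sol <- if (sum((cand1 - PEPTIDE_C_IDEAL)^2) <=
                 sum((cand2 - PEPTIDE_C_IDEAL)^2)) cand1 else cand2
  }
  ca1 + sol[1] * e1 + sol[2] * e2
}

unit2 <- function(v) v / vnorm(v)

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf("backbone model: %d residues (N, CA, C, O, CB)\n", nrow(x$ca)))
  invisible(x)
}

#' Backbone model coordinates as a per-atom frame
#'
#' Flattens a `backbone_model` into the atom order of
#' [backbone_atom_spec()] (N, CA, C, O, CB per residue; CB skipped for Gly),
#' ready for [write_models()].
#'
#' @param bb A `backbone_model`.
#' @param sequence One-letter sequence (controls Gly CB skipping).
#' @return n_atoms x 3 coordinate matrix.
#' @export
backbone_frame <- function(bb, sequence) {
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == nrow(bb$ca))
  rows <- lapply(seq_along(aa), function(i) {
    m <- rbind(bb$n[i, ], bb$ca[i, ], bb$c[i, ], bb$o[i, ])
    if (aa[i] != "G") m <- rbind(m, bb$cb[i, ])
    m
  })
  do.call(rbind, rows)
}
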