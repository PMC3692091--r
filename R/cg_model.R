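# Four-center coarse-grained chain representation and near-native restraints.

#' Build the coarse-grained chain representation
#'
#' Each residue is represented by up to four interaction centers: Calpha,
#' Cbeta, the side-chain center and the Calpha-Calpha pseudo-bond midpoint.
#' Calpha and Cbeta are copied from the input; a missing Cbeta is built by
#' ideal tetrahedral geometry from N, CA, C (glycine gets a virtual Cbeta used
#' for geometry only). The side-chain center is the centroid of side-chain
#' heavy atoms when present, otherwise a pseudo-center on the CA -> CB ray at
#' a residue-type-specific distance; glycine has no side-chain center.
#'
#' @param chain A validated `protein_chain`.
#' @param ss Secondary-structure string from [assign_ss()] (H/E/C).
#' @return An object of class `cg_chain`: n_residues, `ca`, `cb`, `sc`
#'   (NA row for Gly), `pep` ((L-1) x 3 midpoints), `sequence`, `ss`.
#' @export
build_cg <- function(chain, ss) {
  stopifnot(inherits(chain, "protein_chain"))
  n <- chain$n_residues
  if (nchar(ss) != n)
    stop("secondary structure length must equal chain length", call. = FALSE)
  aa <- strsplit(chain$sequence, "")[[1]]

  ca <- chain_coords(chain, "CA")
  Nc <- chain_coords(chain, "N")
  Cc <- chain_coords(chain, "C")
  cb <- chain_coords(chain, "CB")
  for (i in seq_len(n))
    if (anyNA(cb[i, ])) cb[i, ] <- ideal_cb(Nc[i, ], ca[i, ], Cc[i, ])

  bb <- c(BACKBONE_ATOMS, "OXT")
  sc <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (aa[i] == "G") next
    side <- chain$atoms[chain$atoms$res == i &
                          !(chain$atoms$atom %in% bb), , drop = FALSE]
    if (nrow(side) > 0) {
      sc[i, ] <- colMeans(as.matrix(side[, c("x", "y", "z")]))
    } else {
      dir <- cb[i, ] - ca[i, ]
      dir <- dir / vnorm(dir)
      sc[i, ] <- ca[i, ] + dir * (CA_CB_LENGTH + SC_EXTENSION[aa[i]])
    }
  }

  pep <- (ca[-n, , drop = FALSE] + ca[-1, , drop = FALSE]) / 2

  bonds <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(bonds < 3.2 | bonds > 4.2))
    warning("Calpha pseudo-bond length outside [3.2, 4.2] Angstrom in input")

  structure(list(n_residues = n, ca = ca, cb = cb, sc = sc, pep = pep,
                 sequence = chain$sequence, ss = ss),
            class = "cg_chain")
}

# ideal tetrahedral Cbeta from backbone N, CA, C (L-configuration)
ideal_cb <- function(N, CA, C, length = 1.521) {
  u <- (N - CA) / vnorm(N - CA)
  v <- (C - CA) / vnorm(C - CA)
  b <- u + v
  b <- b / vnorm(b)
  n <- cross3(u, v)
  n <- n / vnorm(n)
  CA + length * (-0.6165 * b + 0.7874 * n)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("coarse-grained chain: %d residues (ss: %s)\n",
              x$n_residues, x$ss))
  invisible(x)
}

#' Derive near-native distance restraints
#'
#' One flat-bottom harmonic restraint per residue pair (i, j) with
#' j - i >= `min_sep` whose native Calpha-Calpha distance is at most `cutoff`.
#' The restraint energy is zero inside |d - d0| <= width and quadratic
#' outside, k * (|d - d0| - width)^2. Pairs whose residues are both in
#' regular secondary structure (H or E) get their force constant multiplied
#' by `ss_factor`, so that loops fluctuate more than secondary-structure
#' elements while the chain stays near the input structure.
#'
#' @param cg A `cg_chain`.
#' @param cutoff Native-distance cutoff in Angstrom (default 8.0).
#' @param min_sep Minimum sequence separation j - i (default 3).
#' @param width Flat-bottom half-width in Angstrom (default 1.0).
#' @param k Force constant in energy units per square Angstrom (default 1.0).
#' @param ss_factor Stiffening factor for secondary-structure pairs
#'   (default 2).
#' @return A `restraint_set`: data frame with columns i, j, d0, width, k,
#'   sorted by (i, j).
#' @export
derive_restraints <- function(cg, cutoff = 8.0, min_sep = 3, width = 1.0,
                              k = 1.0, ss_factor = 2.0) {
  stopifnot(inherits(cg, "cg_chain"))
  n <- cg$n_residues
  lab <- strsplit(cg$ss, "")[[1]]
  rows <- list()
  for (i in seq_len(n)) {
    j <- seq_len(n)
    j <- j[j >= i + min_sep]
    if (!length(j)) next
    d <- sqrt(colSums((t(cg$ca[j, , drop = FALSE]) - cg$ca[i, ])^2))
    keep <- which(d <= cutoff)
    if (!length(keep)) next
    jj <- j[keep]
    kk <- ifelse(lab[i] %in% c("H", "E") & lab[jj] %in% c("H", "E"),
                 k * ss_factor, k)
    rows[[length(rows) + 1]] <-
      data.frame(i = i, j = jj, d0 = d[keep], width = width, k = kk)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(i = integer(), j = integer(), d0 = numeric(),
                         width = numeric(), k = numeric())
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Flat-bottom harmonic restraint energy at distance d
#'
#' @param d Observed distance (vectorized).
#' @param d0 Target distance.
#' @param width Flat-bottom half-width.
#' @param k Force constant.
#' @return Energy, zero within the window.
#' @export
restraint_energy <- function(d, d0, width, k) {
  excess <- pmax(0, abs(d - d0) - width)
  k * excess^2
}

#' Write a restraint set as plain text ("i j d0 width k" rows)
#'
#' @param restraints A `restraint_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  writeLines(sprintf("%d %d %.3f %.3f %.3f", restraints$i, restraints$j,
                     restraints$d0, restraints$width, restraints$k), path)
  invisible(path)
}

# deterministic CG frame from a bare Calpha trace: dependent centers derived
# from local geometry (used by the Monte Carlo sampler and energy model)
cg_frame <- function(ca, sequence) {
  centers <- cpp_rebuild_centers(ca, sc_pseudo_distance(sequence))
  list(ca = ca, cb = centers$cb, sc = centers$sc, pep = centers$pep)
}
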