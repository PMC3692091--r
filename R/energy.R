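# Coarse-grained force field: parameter set and energy evaluation.

#' Default coarse-grained energy parameters
#'
#' The force field sums five components: sequence- and secondary-structure-
#' dependent short-range terms (pseudo-bond, pseudo-angle, pseudo-dihedral
#' wells), a pairwise side-chain contact potential (well depths derived from
#' a hydrophobicity-sum approximation scaled to [-1, 0.2] energy units, so
#' that solvent is treated implicitly), a Calpha-model hydrogen-bond term,
#' flat-bottom harmonic near-native restraints and a steep excluded-volume
#' penalty. All values are in reduced energy units and Angstrom and may be
#' overridden.
#'
#' @param ... Named overrides of any default parameter, e.g.
#'   `default_energy_params(k_bond = 10)`. Component weights are in the
#'   `weights` element (short, pair, hbond, restraint, excluded).
#' @return An object of class `energy_params`.
#' @export
default_energy_params <- function(...) {
  p <- list(
    weights = c(short = 1, pair = 1, hbond = 1, restraint = 1, excluded = 1),
    # short range
    k_bond = 5.0, bond_ref = 3.8,
    k_angle = 2.0,                       # energy / rad^2, flat-bottom
    angle_lo = c(70, 80, 110),           # degrees, indexed C, H, E
    angle_hi = c(160, 105, 150),
    k_dih = 1.0,                         # energy / rad^2, flat-bottom
    dih_center = c(0, 50, 180),          # degrees, indexed C, H, E
    dih_halfwidth = c(-1, 25, 45),       # <0 disables (coil unconstrained)
    # side-chain contacts
    pair_eps = hydropathy_pair_wells(),
    contact_radius = 4.5,
    # Calpha-model hydrogen bonds
    hb_dmin = 4.4, hb_dmax = 5.6, hb_align = 0.75, hb_eps = 1.0,
    hb_minsep = 3L,
    # excluded volume
    excl_ca = 3.0, excl_sc = 2.5, k_excl = 10.0, excl_minsep = 2L)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(p))
      stop(sprintf("unknown energy parameter: %s", nm), call. = FALSE)
    p[[nm]] <- over[[nm]]
  }
  validate_energy_params(structure(p, class = "energy_params"))
}

# 20x20 symmetric side-chain pair well depths from Kyte-Doolittle
# hydropathy sums, scaled linearly to [-1, 0.2]: the most hydrophobic pair is
# the most attractive
hydropathy_pair_wells <- function() {
  h <- KD_HYDROPATHY[unname(AA3)]
  s <- outer(h, h, "+")
  rng <- range(s)
  eps <- -1 + (max(s) - s) / diff(rng) * 1.2
  dimnames(eps) <- list(unname(AA3), unname(AA3))
  eps
}

validate_energy_params <- function(p) {
  stopifnot(inherits(p, "energy_params"))
  if (!isTRUE(all.equal(p$pair_eps, t(p$pair_eps))))
    stop("pair_eps matrix must be symmetric", call. = FALSE)
  if (p$contact_radius <= 0 || p$excl_ca <= 0 || p$excl_sc <= 0)
    stop("radii must be positive", call. = FALSE)
  if (p$hb_dmin >= p$hb_dmax)
    stop("hb_dmin must be below hb_dmax", call. = FALSE)
  p
}

#' @export
print.energy_params <- function(x, ...) {
  cat("coarse-grained energy parameters\n")
  cat(sprintf("  weights: %s\n",
              paste(sprintf("%s=%.2g", names(x$weights), x$weights),
                    collapse = " ")))
  cat(sprintf("  contact radius %.1f A, hbond window [%.1f, %.1f] A, excluded CA %.1f / SC %.1f A\n",
              x$contact_radius, x$hb_dmin, x$hb_dmax, x$excl_ca, x$excl_sc))
  invisible(x)
}

#' Evaluate the coarse-grained energy of a conformation
#'
#' Computes the five force-field components and their weighted total for one
#' frame. The frame can be a `cg_chain`, a bare Calpha coordinate matrix
#' (dependent centers are then derived from local Calpha geometry; `sequence`
#' and `ss` must be given), or a list with elements `ca`, `sc`, `pep` for
#' fully explicit centers.
#'
#' @param frame Conformation as described above.
#' @param restraints A `restraint_set` (may have zero rows).
#' @param params An `energy_params` object.
#' @param sequence,ss Required when `frame` does not carry them.
#' @return An object of class `energy_breakdown`: named numeric vector with
#'   weighted components e_short, e_pair, e_hbond, e_restraint, e_excluded
#'   and their sum e_total.
#' @export
evaluate_energy <- function(frame, restraints, params = default_energy_params(),
                            sequence = NULL, ss = NULL) {
  params <- validate_energy_params(params)
  if (inherits(frame, "cg_chain")) {
    sequence <- frame$sequence
    ss <- frame$ss
    sc <- frame$sc
    # glycine has no physical side-chain center; use its virtual Cbeta
    gly <- which(is.na(sc[, 1]))
    if (length(gly)) sc[gly, ] <- frame$cb[gly, , drop = FALSE]
    frame <- list(ca = frame$ca, sc = sc, pep = frame$pep)
  }
  if (is.matrix(frame)) frame <- list(ca = frame)
  if (is.null(sequence) || is.null(ss))
    stop("sequence and ss are required for bare coordinate frames",
         call. = FALSE)
  if (!all(is.finite(frame$ca)))
    stop("frame contains non-finite coordinates", call. = FALSE)
  ssc <- ss_codes(ss)
  aa <- aa_index(sequence)
  rmat <- restraint_matrix(restraints)
  raw <- if (is.null(frame$sc) || is.null(frame$pep)) {
    cpp_energy_ca(frame$ca, sc_pseudo_distance(sequence), ssc, aa,
                  params$pair_eps, rmat, unclass(params))
  } else {
    cpp_energy_frame(frame$ca, frame$sc, frame$pep, ssc, aa,
                     params$pair_eps, rmat, unclass(params))
  }
  energy_breakdown(raw, params$weights)
}

restraint_matrix <- function(restraints) {
  if (is.null(restraints) || nrow(restraints) == 0)
    return(matrix(0, 0, 5))
  as.matrix(restraints[, c("i", "j", "d0", "width", "k")])
}

energy_breakdown <- function(raw, weights) {
  comp <- c(e_short = unname(weights["short"] * raw["short"]),
            e_pair = unname(weights["pair"] * raw["pair"]),
            e_hbond = unname(weights["hbond"] * raw["hbond"]),
            e_restraint = unname(weights["restraint"] * raw["restraint"]),
            e_excluded = unname(weights["excluded"] * raw["excluded"]))
  structure(c(comp, e_total = sum(comp)), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("E = %.4f (short %.3f, pair %.3f, hbond %.3f, restraint %.3f, excluded %.3f)\n",
              x["e_total"], x["e_short"], x["e_pair"], x["e_hbond"],
              x["e_restraint"], x["e_excluded"]))
  invisible(x)
}
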