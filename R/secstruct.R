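# Three-state secondary structure (H/E/C) from backbone hydrogen-bond
# geometry, in the spirit of the classic hydrogen-bond-pattern assignment:
# an electrostatic model energy identifies backbone N-H...O=C hydrogen bonds,
# 4-turn runs give helices and bridge ladders give strands. All other states
# are reported as coil, so the output alphabet is exactly {H, E, C}.

#' Assign 3-state secondary structure from backbone geometry
#'
#' Backbone hydrogen bonds are detected with the electrostatic energy model
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol, with a bond
#' assigned when E < -0.5 kcal/mol. The amide hydrogen is placed 1.0 Angstrom
#' from N along the bisector of the N-C(prev) and N-CA directions; the first
#' residue has no donor. Residues covered by two consecutive i -> i+4 turns
#' are labelled H; residues in parallel/antiparallel bridge ladders of length
#' at least 2 are labelled E; everything else (including 3-10/pi helices,
#' turns, bends and isolated bridges) is coil.
#'
#' @param chain A validated `protein_chain` with complete backbone.
#' @return A character scalar over the alphabet {H, E, C}, one letter per
#'   residue.
#' @export
assign_ss <- function(chain) {
  stopifnot(inherits(chain, "protein_chain"))
  n <- chain$n_residues
  if (n < 3) return(paste(rep("C", n), collapse = ""))

  N <- chain_coords(chain, "N")
  CA <- chain_coords(chain, "CA")
  C <- chain_coords(chain, "C")
  O <- chain_coords(chain, "O")

  # amide H for residues 2..n
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    d1 <- N[i, ] - C[i - 1, ]
    d2 <- N[i, ] - CA[i, ]
    dir <- d1 / vnorm(d1) + d2 / vnorm(d2)
    H[i, ] <- N[i, ] + dir / vnorm(dir)
  }

  # hbond[i, j]: N-H of residue i donates to C=O of residue j
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (i in 2:n) {
    for (j in 1:n) {
      if (abs(i - j) < 2) next
      r_on <- vnorm(O[j, ] - N[i, ])
      r_ch <- vnorm(C[j, ] - H[i, ])
      r_oh <- vnorm(O[j, ] - H[i, ])
      r_cn <- vnorm(C[j, ] - N[i, ])
      if (r_on < 0.5 || r_ch < 0.5 || r_oh < 0.5 || r_cn < 0.5) next
      e <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      if (e < -0.5) hb[i, j] <- TRUE
    }
  }

  labels <- rep("C", n)

  # strands: bridges between residues i, j (|i-j| >= 3, both interior)
  bridge <- matrix("", n, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[i, j] && hb[j, i]) || (hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par) bridge[i, j] <- "P"
      if (anti && !par) bridge[i, j] <- "A"
    }
  }
  # ladders: two or more consecutive bridges of the same type
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      ty <- bridge[i, j]
      if (ty == "") next
      nxt <- if (ty == "P") c(i + 1, j + 1) else c(i + 1, j - 1)
      prv <- if (ty == "P") c(i - 1, j - 1) else c(i - 1, j + 1)
      in_ladder <-
        (all(nxt >= 1 & nxt <= n) && bridge[nxt[1], nxt[2]] == ty) ||
        (all(prv >= 1 & prv <= n) && bridge[prv[1], prv[2]] == ty)
      if (in_ladder) labels[c(i, j)] <- "E"
    }
  }

  # helices: residues i..i+3 where 4-turns start at both i-1 and i
  # (turn4[i] means C=O of i accepts from N-H of i+4)
  turn4 <- rep(FALSE, n)
  for (i in 1:(n - 4)) turn4[i] <- hb[i + 4, i]
  for (i in 2:n) {
    if (i <= n - 4 && turn4[i - 1] && turn4[i])
      labels[i:(i + 3)] <- "H"
  }

  paste(labels, collapse = "")
}

vnorm <- function(v) sqrt(sum(v * v))

# ss string -> integer code used by the energy core (0 C, 1 H, 2 E)
ss_codes <- function(ss) {
  lab <- strsplit(ss, "")[[1]]
  if (!all(lab %in% c("H", "E", "C")))
    stop("secondary structure string may only contain H, E, C", call. = FALSE)
  unname(c(C = 0L, H = 1L, E = 2L)[lab])
}
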