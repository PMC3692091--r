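# Fixed-column PDB reading, chain validation, and multi-model writing.

#' Read a PDB-format structure
#'
#' Parses fixed-column PDB text into a raw structure: ATOM records grouped by
#' model, HETATM records (waters, ligands, ...) held separately and never used
#' downstream. When the file contains several models (e.g. an NMR ensemble),
#' the first model is flagged as the active one.
#'
#' @param source Path to a PDB file, or a character scalar containing PDB text
#'   (recognized by embedded newlines), or a character vector of lines.
#' @return An object of class `raw_structure`: a list with `atoms` (data frame
#'   of ATOM records: model, serial, name, altloc, resname, chain, resno,
#'   icode, x, y, z, occ, b, element, line), `het` (same layout for HETATM),
#'   `models` (model numbers present) and `active_model` (the first model).
#' @seealso [validate_chain()], [write_models()]
#' @export
read_structure <- function(source) {
  lines <- pdb_source_lines(source)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty PDB input", call. = FALSE)

  rec <- substr(lines, 1, 6)
  model_no <- integer(length(lines))
  cur <- 1L
  seen_model <- FALSE
  is_atom <- rec == "ATOM  "
  is_het <- rec == "HETATM"
  for (i in seq_along(lines)) {
    if (rec[i] == "MODEL ") {
      m <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      cur <- if (is.na(m)) cur + !seen_model else m
      seen_model <- TRUE
    } else if (rec[i] == "ENDMDL") {
      cur <- cur + 1L
    }
    model_no[i] <- cur
  }

  parse_records <- function(idx) {
    if (!length(idx)) {
      return(data.frame(model = integer(), serial = integer(),
                        name = character(), altloc = character(),
                        resname = character(), chain = character(),
                        resno = integer(), icode = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        occ = numeric(), b = numeric(),
                        element = character(), line = integer(),
                        stringsAsFactors = FALSE))
    }
    ln <- lines[idx]
    num <- function(a, b) suppressWarnings(as.numeric(substr(ln, a, b)))
    xyz <- cbind(num(31, 38), num(39, 46), num(47, 54))
    bad <- which(!is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) |
                   !is.finite(xyz[, 3]))
    if (length(bad))
      stop(sprintf("unparseable coordinate record at line %d: %s",
                   idx[bad[1]], trimws(ln[bad[1]])), call. = FALSE)
    occ <- num(55, 60); occ[is.na(occ)] <- 1
    bf <- num(61, 66); bf[is.na(bf)] <- 0
    data.frame(
      model = model_no[idx],
      serial = suppressWarnings(as.integer(substr(ln, 7, 11))),
      name = trimws(substr(ln, 13, 16)),
      altloc = trimws(substr(ln, 17, 17)),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resno = suppressWarnings(as.integer(substr(ln, 23, 26))),
      icode = trimws(substr(ln, 27, 27)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = occ, b = bf,
      element = trimws(substr(ln, 77, 78)),
      line = idx,
      stringsAsFactors = FALSE)
  }

  atoms <- parse_records(which(is_atom))
  het <- parse_records(which(is_het))
  if (nrow(atoms) == 0)
    stop("no ATOM records found in input", call. = FALSE)
  models <- sort(unique(atoms$model))
  structure(list(atoms = atoms, het = het, models = models,
                 active_model = models[1]),
            class = "raw_structure")
}

pdb_source_lines <- function(source) {
  if (!is.character(source))
    stop("source must be a path or PDB text", call. = FALSE)
  if (length(source) == 1 && !grepl("\n", source)) {
    if (!nzchar(trimws(source)))
      stop("empty PDB input", call. = FALSE)
    if (file.exists(source))
      return(readLines(source, warn = FALSE))
    # a single line of record-like text is treated as content, not a path
    if (grepl("^(ATOM|HETATM|MODEL|ENDMDL|TER|END|REMARK|HEADER|TITLE)",
              source))
      return(source)
    stop(sprintf("input file not found: %s", source), call. = FALSE)
  }
  if (length(source) == 1) return(strsplit(source, "\n", fixed = TRUE)[[1]])
  source
}

#' @export
print.raw_structure <- function(x, ...) {
  cat(sprintf("PDB raw structure: %d model(s), %d ATOM records, %d HETATM records\n",
              length(x$models), nrow(x$atoms), nrow(x$het)))
  invisible(x)
}

#' Validate a raw structure into a simulation-ready protein chain
#'
#' Enforces, in order: single chain; standard amino acids only; at most 400
#' residues; a complete backbone (N, CA, C, O) for every residue; geometric
#' chain continuity. Only the first model of a multi-model file is used. For
#' residues with alternate locations, only the first conformation is kept.
#' Hydrogens and terminal OXT atoms are dropped silently. Residues are
#' renumbered 1..L; original author numbering is retained in `numbering`.
#'
#' Continuity is geometric: residues i and i+1 are continuous when the
#' C(i)-N(i+1) distance is at most `break_cutoff` (2.0 Angstrom); numbering
#' gaps alone do not reject a chain.
#'
#' @param raw A `raw_structure` from [read_structure()].
#' @param max_length Maximum accepted chain length (default 400 residues).
#' @param break_cutoff Maximum peptide C-N distance counted as continuous, in
#'   Angstrom.
#' @return A list with `chain` (a `protein_chain`, or `NULL` when rejected)
#'   and `report` (a `validation_report` with `accepted` and a data frame of
#'   `violations`: rule, ref, message).
#' @export
validate_chain <- function(raw, max_length = 400, break_cutoff = 2.0) {
  stopifnot(inherits(raw, "raw_structure"))
  at <- raw$atoms[raw$atoms$model == raw$active_model, , drop = FALSE]
  violations <- data.frame(rule = character(), ref = character(),
                           message = character(), stringsAsFactors = FALSE)
  add <- function(rule, ref, message) {
    violations[nrow(violations) + 1L, ] <<- list(rule, ref, message)
  }

  chains <- unique(at$chain)
  if (length(chains) > 1) {
    add("single_chain", paste(chains, collapse = ","),
        sprintf("expected a single chain, found %d (%s)",
                length(chains), paste(chains, collapse = ", ")))
  }

  # keep the first alternate location per (residue, atom)
  if (any(nzchar(at$altloc))) {
    key <- paste(at$chain, at$resno, at$icode, at$name)
    at <- at[!duplicated(key), , drop = FALSE]
  }
  # hydrogens and OXT are ignored silently
  is_h <- at$element == "H" | grepl("^[0-9]*H", at$name)
  at <- at[!is_h & at$name != "OXT", , drop = FALSE]

  reskey <- paste(at$chain, at$resno, at$icode)
  res_ids <- unique(reskey)
  nres <- length(res_ids)

  first_of <- at[!duplicated(reskey), , drop = FALSE]
  nonstd <- which(!(first_of$resname %in% names(AA3)))
  for (i in nonstd)
    add("nonstandard_residue",
        sprintf("%s %s%d", first_of$resname[i], first_of$chain[i],
                first_of$resno[i]),
        sprintf("non-standard residue %s", first_of$resname[i]))

  if (nres > max_length)
    add("max_length", sprintf("%d residues", nres),
        sprintf("chain has %d residues, maximum accepted is %d",
                nres, max_length))

  # complete backbone per residue
  for (rid in res_ids) {
    names_here <- at$name[reskey == rid]
    missing <- setdiff(BACKBONE_ATOMS, names_here)
    if (length(missing))
      add("incomplete_backbone", rid,
          sprintf("residue %s is missing backbone atom(s): %s", rid,
                  paste(missing, collapse = ", ")))
  }

  # geometric continuity (only meaningful when backbones are complete)
  if (!any(violations$rule %in% c("incomplete_backbone", "single_chain"))) {
    get_atom <- function(rid, nm) {
      r <- at[reskey == rid & at$name == nm, , drop = FALSE]
      if (nrow(r) == 0) return(NULL)
      c(r$x[1], r$y[1], r$z[1])
    }
    if (nres >= 2) {
      for (i in seq_len(nres - 1)) {
        ci <- get_atom(res_ids[i], "C")
        ni <- get_atom(res_ids[i + 1], "N")
        d <- sqrt(sum((ci - ni)^2))
        if (d > break_cutoff)
          add("chain_break", sprintf("%s | %s", res_ids[i], res_ids[i + 1]),
              sprintf("C-N distance %.2f A exceeds %.1f A between residues %s and %s",
                      d, break_cutoff, res_ids[i], res_ids[i + 1]))
      }
    }
  }

  report <- structure(list(accepted = nrow(violations) == 0,
                           violations = violations),
                      class = "validation_report")
  chain <- NULL
  if (report$accepted) {
    res_index <- match(reskey, res_ids)
    atoms <- data.frame(res = res_index, atom = at$name,
                        x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
    sequence <- paste(AA3[first_of$resname], collapse = "")
    chain <- structure(list(sequence = sequence,
                            chain_id = first_of$chain[1],
                            numbering = first_of$resno,
                            n_residues = nres,
                            atoms = atoms),
                       class = "protein_chain")
  }
  list(chain = chain, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$accepted) {
    cat("chain accepted: no violations\n")
  } else {
    cat(sprintf("chain rejected: %d violation(s)\n", nrow(x$violations)))
    for (i in seq_len(nrow(x$violations)))
      cat(sprintf("  [%s] %s\n", x$violations$rule[i], x$violations$message[i]))
  }
  invisible(x)
}

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("protein chain %s: %d residues, %d atoms\n",
              x$chain_id, x$n_residues, nrow(x$atoms)))
  cat(sprintf("sequence: %s\n", x$sequence))
  invisible(x)
}

#' Per-residue coordinates of one atom type
#'
#' @param chain A `protein_chain`.
#' @param atom Atom name, e.g. "CA".
#' @return An L x 3 coordinate matrix (NA rows where the atom is absent).
#' @export
chain_coords <- function(chain, atom = "CA") {
  stopifnot(inherits(chain, "protein_chain"))
  out <- matrix(NA_real_, chain$n_residues, 3)
  sel <- chain$atoms[chain$atoms$atom == atom, , drop = FALSE]
  out[sel$res, ] <- as.matrix(sel[, c("x", "y", "z")])
  out
}

#' Write coordinate frames as a (multi-model) PDB file
#'
#' Writes one MODEL/ENDMDL block per frame (a single frame is written without
#' the MODEL wrapper). When `bfactors` is supplied, the per-residue values are
#' formatted into the temperature-factor field, columns 61-66, replacing it in
#' every model; this is how the fluctuation profile is carried in the output
#' ensembles.
#'
#' @param frames A coordinate matrix (n_atoms x 3) or a list of them, all with
#'   the same atom count.
#' @param atom_spec Data frame describing the atoms of one frame, in order:
#'   columns `res` (residue index), `resname` (three-letter code), `atom`
#'   (atom name). See [ca_atom_spec()] and [backbone_atom_spec()].
#' @param path Output file path.
#' @param bfactors Optional per-residue values for columns 61-66.
#' @param chain_id Single-character chain identifier.
#' @return The path, invisibly.
#' @export
write_models <- function(frames, atom_spec, path, bfactors = NULL,
                         chain_id = "A") {
  if (is.matrix(frames)) frames <- list(frames)
  n_atoms <- nrow(atom_spec)
  for (f in frames)
    if (nrow(f) != n_atoms)
      stop("all frames must have one row per atom_spec atom", call. = FALSE)
  res_ord <- match(atom_spec$res, unique(atom_spec$res))
  nres <- max(res_ord)
  if (!is.null(bfactors) && length(bfactors) != nres)
    stop(sprintf("bfactors has length %d but the frame has %d residues",
                 length(bfactors), nres), call. = FALSE)
  bcol <- if (is.null(bfactors)) rep(0, n_atoms) else bfactors[res_ord]

  element <- substr(gsub("[0-9]", "", atom_spec$atom), 1, 1)
  name_field <- ifelse(nchar(atom_spec$atom) < 4,
                       sprintf(" %-3s", atom_spec$atom),
                       atom_spec$atom)
  multi <- length(frames) > 1
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    xyz <- frames[[m]]
    lines <- sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(n_atoms), name_field,
                     seq1_to_3_checked(atom_spec$resname), chain_id,
                     atom_spec$res, xyz[, 1], xyz[, 2], xyz[, 3],
                     1.0, bcol, element)
    writeLines(lines, con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# atom_spec resname may already be three-letter; pass through in that case
seq1_to_3_checked <- function(resnames) {
  ifelse(nchar(resnames) == 3, resnames, unname(AA1[resnames]))
}

#' Atom specification for a Calpha-only trace
#'
#' @param sequence One-letter sequence string.
#' @return Data frame with columns res, resname, atom.
#' @export
ca_atom_spec <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  data.frame(res = seq_along(aa), resname = unname(AA1[aa]), atom = "CA",
             stringsAsFactors = FALSE)
}

#' Atom specification for a backbone + Cbeta model
#'
#' @param sequence One-letter sequence string.
#' @param cb Include Cbeta rows (skipped for glycine).
#' @return Data frame with columns res, resname, atom, one row per atom in
#'   N, CA, C, O, (CB) order per residue.
#' @export
backbone_atom_spec <- function(sequence, cb = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  rows <- do.call(rbind, lapply(seq_along(aa), function(i) {
    atoms <- c("N", "CA", "C", "O")
    if (cb && aa[i] != "G") atoms <- c(atoms, "CB")
    data.frame(res = i, resname = unname(AA1[aa[i]]), atom = atoms,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Serialize a protein chain to PDB text on disk
#'
#' @param chain A `protein_chain`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "protein_chain"))
  aa <- strsplit(chain$sequence, "")[[1]]
  spec <- data.frame(res = chain$numbering[chain$atoms$res],
                     resname = unname(AA1[aa[chain$atoms$res]]),
                     atom = chain$atoms$atom, stringsAsFactors = FALSE)
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  write_models(xyz, spec, path, chain_id = chain$chain_id)
}

#' Write a fluctuation profile as plain text
#'
#' Two whitespace-separated columns: residue index and mean-square
#' fluctuation in square Angstrom.
#'
#' @param profile A `fluct_profile` (or data frame with residue and msf).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fluctuations <- function(profile, path) {
  writeLines(sprintf("%d %.4f", profile$residue, profile$msf), path)
  invisible(path)
}
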