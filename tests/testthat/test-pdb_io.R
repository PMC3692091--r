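test_that("reading a toy single-model structure counts records correctly", {
  chain <- make_structure("extended", 5)
  # backbone-only text: drop CB lines to get exactly 4 atoms per residue
  txt <- chain_pdb_text(chain)
  txt <- txt[!(grepl("^ATOM", txt) & substr(txt, 13, 16) == " CB ")]
  raw <- read_structure(txt)
  expect_s3_class(raw, "raw_structure")
  expect_length(raw$models, 1)
  expect_equal(nrow(raw$atoms), 20)
  expect_equal(nrow(raw$het), 0)
})

test_that("only the first model of a multi-model file is flagged active", {
  chain <- helix_chain(5)
  ca <- chain_coords(chain, "CA")
  f <- tempfile(fileext = ".pdb")
  write_models(list(ca, ca + 1), ca_atom_spec(chain$sequence), f)
  raw <- read_structure(f)
  expect_equal(raw$models, c(1, 2))
  expect_equal(raw$active_model, 1)
  # validation uses the active (first) model only
  vc <- validate_chain(raw)
  at <- raw$atoms[raw$atoms$model == raw$active_model, ]
  expect_equal(at$x, ca[, 1], tolerance = 1e-3)
})

test_that("HETATM records are kept separately and never enter the models", {
  txt <- c(chain_pdb_text(helix_chain(5)),
           "HETATM  900  O   HOH A 201      10.000  10.000  10.000  1.00  0.00           O")
  txt <- txt[txt != "END"]
  raw <- read_structure(txt)
  expect_equal(nrow(raw$het), 1)
  expect_equal(raw$het$resname, "HOH")
  expect_false("HOH" %in% raw$atoms$resname)
})

test_that("parse errors carry the offending line number", {
  txt <- chain_pdb_text(helix_chain(3))
  bad <- sub("^(ATOM.{24}).{8}", "\\1   xyzzy", txt[5])
  txt[5] <- bad
  expect_error(read_structure(txt), "line 5")
  expect_error(read_structure(""), "empty")
  expect_error(read_structure(c("REMARK nothing here")), "empty|no ATOM")
})

test_that("validation enforces the acceptance rules with one fixture per rule", {
  # over-long chain
  long <- make_structure("poly_ala_n", 401)
  vc <- validate_chain(read_structure(chain_pdb_text(long)))
  expect_false(vc$report$accepted)
  expect_true("max_length" %in% vc$report$violations$rule)
  expect_null(vc$chain)

  # non-standard residue
  txt <- chain_pdb_text(helix_chain(5))
  txt <- sub("ALA A   3", "MSE A   3", txt)
  vc <- validate_chain(read_structure(txt))
  expect_false(vc$report$accepted)
  expect_true("nonstandard_residue" %in% vc$report$violations$rule)

  # two chains
  txt <- chain_pdb_text(helix_chain(6))
  txt <- sub("ALA A   5", "ALA B   5", txt)
  txt <- sub("ALA A   6", "ALA B   6", txt)
  vc <- validate_chain(read_structure(txt))
  expect_true("single_chain" %in% vc$report$violations$rule)

  # missing backbone atom
  txt <- chain_pdb_text(helix_chain(5))
  txt <- txt[!(grepl("^ATOM", txt) & substr(txt, 13, 16) == " O  " &
                 substr(txt, 23, 26) == "   2")]
  vc <- validate_chain(read_structure(txt))
  expect_true("incomplete_backbone" %in% vc$report$violations$rule)

  # geometric chain break: translate the second half far away
  chain <- helix_chain(8)
  chain$atoms[chain$atoms$res > 4, c("x", "y", "z")] <-
    chain$atoms[chain$atoms$res > 4, c("x", "y", "z")] + 20
  vc <- validate_chain(read_structure(chain_pdb_text(chain)))
  expect_true("chain_break" %in% vc$report$violations$rule)

  # a numbering gap with continuous geometry is not a break
  chain <- helix_chain(6)
  chain$numbering <- c(1, 2, 3, 10, 11, 12)
  txt <- chain_pdb_text(chain)
  vc <- validate_chain(read_structure(txt))
  expect_true(vc$report$accepted)
})

test_that("alternate locations keep the first conformation", {
  txt <- chain_pdb_text(helix_chain(4))
  i <- which(grepl("^ATOM", txt) & substr(txt, 13, 16) == " CA " &
               substr(txt, 23, 26) == "   2")
  lineA <- txt[i]
  substr(lineA, 17, 17) <- "A"
  lineB <- lineA
  substr(lineB, 17, 17) <- "B"
  substr(lineB, 31, 38) <- sprintf("%8.3f", 99.0)
  txt <- append(txt[-i], c(lineA, lineB), after = i - 1)
  vc <- validate_chain(read_structure(txt))
  expect_true(vc$report$accepted)
  ca2 <- chain_coords(vc$chain, "CA")[2, ]
  expect_false(isTRUE(all.equal(ca2[1], 99.0)))
})

test_that("write_models produces the expected block structure and B-factors", {
  chain <- helix_chain(5)
  ca <- chain_coords(chain, "CA")
  f <- tempfile(fileext = ".pdb")
  write_models(list(ca, ca, ca), ca_atom_spec(chain$sequence), f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  expect_equal(sum(grepl("^ATOM", txt)), 15)

  # zero bfactors read back as 0.00
  write_models(ca, ca_atom_spec(chain$sequence), f, bfactors = rep(0, 5))
  raw <- read_structure(f)
  expect_equal(raw$atoms$b, rep(0, 5))

  # fixed-point rounding of the temperature-factor column
  one <- matrix(c(0, 0, 0), 1, 3)
  write_models(one, data.frame(res = 1, resname = "ALA", atom = "CA"), f,
               bfactors = 12.345)
  field <- substr(grep("^ATOM", readLines(f), value = TRUE), 61, 66)
  expect_lte(abs(as.numeric(field) - 12.345), 0.005)

  expect_error(write_models(ca, ca_atom_spec(chain$sequence), f,
                            bfactors = c(1, 2)), "bfactors")
})

test_that("coordinates round-trip through write and read at PDB precision", {
  for (kind in c("ideal_helix", "extended", "helix_loop_helix")) {
    chain <- if (kind == "helix_loop_helix")
      make_structure(kind, c(6, 4, 6)) else make_structure(kind, 12)
    f <- tempfile(fileext = ".pdb")
    write_chain(chain, f)
    raw <- read_structure(f)
    back <- cbind(raw$atoms$x, raw$atoms$y, raw$atoms$z)
    orig <- as.matrix(chain$atoms[, c("x", "y", "z")])
    expect_lt(max(abs(back - orig)), 5.1e-4)
  }
})

test_that("validation is idempotent on an accepted, re-serialized chain", {
  chain <- make_structure("helix_loop_helix", c(6, 3, 6))
  vc1 <- validate_chain(read_structure(chain_pdb_text(chain)))
  expect_true(vc1$report$accepted)
  vc2 <- validate_chain(read_structure(chain_pdb_text(vc1$chain)))
  expect_true(vc2$report$accepted)
  expect_equal(nrow(vc2$report$violations), 0)
})

test_that("written PDB agrees with an independent reader", {
  skip_if_not_installed("bio3d")
  chain <- helix_chain(8)
  f <- tempfile(fileext = ".pdb")
  write_chain(chain, f)
  pdb <- bio3d::read.pdb(f)
  idx <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  xyz <- matrix(pdb$xyz[idx$xyz], ncol = 3, byrow = TRUE)
  expect_equal(xyz, chain_coords(chain, "CA"), tolerance = 1e-3,
               ignore_attr = TRUE)
})
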