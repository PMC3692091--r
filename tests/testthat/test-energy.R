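make_cg <- function(kind = "ideal_helix", n = 15) {
  chain <- if (kind == "helix_loop_helix") make_structure(kind, n)
           else make_structure(kind, n)
  build_cg(chain, assign_ss(chain))
}

test_that("isolated side-chain centers outside the contact radius give e_pair 0", {
  # two residues far apart laterally: construct an explicit frame
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  # place sc so that all pairwise sc distances exceed the radius
  sc <- ca + matrix(c(0, 50, 0), 4, 3, byrow = TRUE) * seq_len(4)
  pep <- (ca[-4, ] + ca[-1, ]) / 2
  e <- evaluate_energy(list(ca = ca, sc = sc, pep = pep),
                       restraints = NULL, sequence = "AAAA", ss = "CCCC")
  expect_equal(unname(e["e_pair"]), 0)
})

test_that("flat-bottom restraint algebra matches the closed form", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.3, 1, 0), c(5.5, 4.2, 0))
  rs <- data.frame(i = 1, j = 4, d0 = 5.0, width = 1.0, k = 1.0)
  d <- sqrt(sum(ca[4, ]^2))
  e <- evaluate_energy(ca, rs, sequence = "AAAA", ss = "CCCC")
  expect_equal(unname(e["e_restraint"]), restraint_energy(d, 5, 1, 1))
  # at d = 5.5 (inside window): zero; at 6.5: 0.25
  for (target in c(5.5, 6.5)) {
    ca2 <- ca
    ca2[4, ] <- ca[4, ] / d * target
    e2 <- evaluate_energy(ca2, rs, sequence = "AAAA", ss = "CCCC")
    expect_equal(unname(e2["e_restraint"]),
                 if (target <= 6) 0 else 0.25, tolerance = 1e-12)
  }
})

test_that("the total equals the independently summed components on random frames", {
  cg <- make_cg("ideal_helix", 12)
  rs <- derive_restraints(cg)
  set.seed(42)
  for (rep in 1:100) {
    ca <- cg$ca + matrix(rnorm(nrow(cg$ca) * 3, sd = 0.4), ncol = 3)
    e <- evaluate_energy(ca, rs, sequence = cg$sequence, ss = cg$ss)
    expect_equal(unname(e["e_total"]),
                 sum(e[c("e_short", "e_pair", "e_hbond", "e_restraint",
                         "e_excluded")]),
                 tolerance = 1e-9)
  }
})

test_that("the restraint component agrees with an independent R oracle", {
  cg <- make_cg("ideal_helix", 12)
  rs <- derive_restraints(cg)
  expect_gt(nrow(rs), 0)
  set.seed(9)
  for (rep in 1:10) {
    ca <- cg$ca + matrix(rnorm(36, sd = 0.8), ncol = 3)
    e <- evaluate_energy(ca, rs, sequence = cg$sequence, ss = cg$ss)
    expect_equal(unname(e["e_restraint"]), oracle_restraint_sum(ca, rs),
                 tolerance = 1e-9)
  }
})

test_that("energy is invariant under global rigid transforms", {
  cg <- make_cg("helix_loop_helix", c(6, 4, 6))
  rs <- derive_restraints(cg)
  e0 <- evaluate_energy(cg$ca, rs, sequence = cg$sequence, ss = cg$ss)
  set.seed(11)
  for (rep in 1:50) {
    R <- random_proper_rotation()
    shift <- runif(3, -50, 50)
    ca2 <- sweep(cg$ca %*% R, 2, shift, "+")
    e2 <- evaluate_energy(ca2, rs, sequence = cg$sequence, ss = cg$ss)
    expect_lt(max(abs(unclass(e2) - unclass(e0))), 1e-6)
  }
})

test_that("excluded volume is zero on native geometry and positive on forced overlap", {
  cg <- make_cg("ideal_helix", 15)
  e0 <- evaluate_energy(cg$ca, NULL, sequence = cg$sequence, ss = cg$ss)
  expect_equal(unname(e0["e_excluded"]), 0)

  clash <- cg$ca
  clash[8, ] <- cg$ca[10, ] + c(1.5, 0, 0)  # two Calpha within 2 A
  e1 <- evaluate_energy(clash, NULL, sequence = cg$sequence, ss = cg$ss)
  expect_gt(unname(e1["e_excluded"]), 0)
  # cross-check the Calpha part against the independent oracle
  expect_gte(unname(e1["e_excluded"]), oracle_excluded_ca(clash) - 1e-9)
})

test_that("moving a restrained pair off its well never decreases e_restraint", {
  rs <- data.frame(i = 1, j = 4, d0 = 5.0, width = 1.0, k = 1.5)
  dists <- seq(6.0, 12, by = 0.25)
  e_along <- vapply(dists, function(d) {
    ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(d, 0.01, 0))
    unname(evaluate_energy(ca, rs, sequence = "AAAA",
                           ss = "CCCC")["e_restraint"])
  }, numeric(1))
  expect_true(all(diff(e_along) >= 0))
})

test_that("component weights scale their component and the total", {
  cg <- make_cg("ideal_helix", 10)
  rs <- derive_restraints(cg)
  ca <- cg$ca * 1.05  # slightly inflated: nonzero short + restraint terms
  p1 <- default_energy_params()
  p2 <- default_energy_params(weights = c(short = 2, pair = 1, hbond = 1,
                                          restraint = 0.5, excluded = 1))
  e1 <- evaluate_energy(ca, rs, p1, sequence = cg$sequence, ss = cg$ss)
  e2 <- evaluate_energy(ca, rs, p2, sequence = cg$sequence, ss = cg$ss)
  expect_equal(unname(e2["e_short"]), 2 * unname(e1["e_short"]))
  expect_equal(unname(e2["e_restraint"]), 0.5 * unname(e1["e_restraint"]))
})

test_that("parameter validation rejects broken inputs", {
  expect_error(default_energy_params(nonsense = 1), "unknown")
  p <- default_energy_params()
  p$pair_eps[1, 2] <- p$pair_eps[1, 2] + 1
  expect_error(flexens:::validate_energy_params(p), "symmetric")
  cg <- make_cg("ideal_helix", 5)
  bad <- cg$ca; bad[2, 1] <- NaN
  expect_error(evaluate_energy(bad, NULL, sequence = cg$sequence, ss = cg$ss),
               "finite")
})
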