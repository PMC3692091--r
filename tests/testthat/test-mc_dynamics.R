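test_that("zero-amplitude proposals leave the frame unchanged", {
  ca <- chain_coords(helix_chain(8), "CA")
  set.seed(1)
  out <- propose_move(ca, amp_single = 0, amp_terminal = 0)
  expect_identical(out$ca, ca)
})

test_that("moves are local: untouched residues are bit-identical", {
  ca <- chain_coords(helix_chain(10), "CA")
  set.seed(2)
  for (rep in 1:50) {
    out <- propose_move(ca)
    moved <- out$move$residues
    expect_identical(out$ca[-moved, , drop = FALSE],
                     ca[-moved, , drop = FALSE])
    expect_false(isTRUE(all.equal(out$ca[moved, ], ca[moved, ])))
  }
})

test_that("the proposal stream replays identically under a fixed seed", {
  ca <- chain_coords(helix_chain(10), "CA")
  draw <- function(seed, n = 1e4) {
    set.seed(seed)
    vapply(seq_len(n), function(i) {
      m <- propose_move(ca)$move
      sum(m$delta) + m$residues[1] * 1000 +
        match(m$type, c("single", "pair", "terminal")) * 1e6
    }, numeric(1))
  }
  expect_identical(draw(123), draw(123))
  expect_false(identical(draw(123), draw(124)))
})

test_that("the Metropolis rule accepts downhill always and uphill by the Boltzmann factor", {
  set.seed(3)
  expect_true(metropolis_accept(10, 5, 1))
  expect_true(metropolis_accept(10, 10, 1))
  expect_false(metropolis_accept(0, 1e6, 1))
  expect_error(metropolis_accept(0, 1, 0), "temperature")
  expect_error(metropolis_accept(NaN, 1, 1), "finite")

  # empirical acceptance at dE = T ln 2 is 1/2
  temp <- 0.7
  de <- temp * log(2)
  set.seed(4)
  acc <- mean(vapply(seq_len(1e5), function(i)
    metropolis_accept(0, de, temp), logical(1)))
  expect_lt(abs(acc - 0.5), 0.01)
})

test_that("the Metropolis kernel reproduces two-state double-well occupancies", {
  # two wells separated by dE: analytic occupancy ratio is exp(-dE / T)
  de <- 0.8; temp <- 1.0
  energy <- c(0, de)
  set.seed(5)
  state <- 1L
  n_sweep <- 1e5
  occ <- integer(2)
  visits <- integer(n_sweep)
  for (s in seq_len(n_sweep)) {
    prop <- 3L - state
    if (metropolis_accept(energy[state], energy[prop], temp)) state <- prop
    occ[state] <- occ[state] + 1L
    visits[s] <- state
  }
  ratio <- occ[2] / occ[1]
  # standard error from batch means over 20 batches
  batches <- colMeans(matrix(visits == 2L, ncol = 20))
  p_hat <- mean(batches)
  se_p <- sd(batches) / sqrt(length(batches))
  p_true <- exp(-de / temp) / (1 + exp(-de / temp))
  expect_lt(abs(p_hat - p_true), 3 * se_p)
  expect_equal(ratio, exp(-de / temp), tolerance = 0.1)
})

test_that("simulations are reproducible and respect the pseudo-bond window", {
  hel <- helix_chain(15)
  cg <- build_cg(hel, assign_ss(hel))
  rs <- derive_restraints(cg)
  sp <- sim_params(n_snapshots = 60, seed = 31)
  t1 <- run_simulation(cg, rs, sparams = sp)
  t2 <- run_simulation(cg, rs, sparams = sp)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_simulation(cg, rs, sparams = sim_params(n_snapshots = 60,
                                                    seed = 32))
  expect_false(identical(t1$frames, t3$frames))

  expect_length(t1$frames, 60)
  for (f in t1$frames) {
    d <- sqrt(rowSums(diff(f)^2))
    expect_true(all(d >= 3.2 & d <= 4.2))
  }
  expect_gt(t1$acceptance_rate, 0.05)
  expect_lt(t1$acceptance_rate, 0.95)
})

test_that("recorded energies match a fresh evaluation of the recorded frames", {
  hel <- helix_chain(12)
  cg <- build_cg(hel, assign_ss(hel))
  rs <- derive_restraints(cg)
  traj <- run_simulation(cg, rs, sparams = sim_params(n_snapshots = 20,
                                                      seed = 8))
  for (f in c(1, 10, 20)) {
    e <- evaluate_energy(traj$frames[[f]], rs, sequence = cg$sequence,
                         ss = cg$ss)
    expect_equal(unname(e["e_total"]), traj$energies$e_total[f],
                 tolerance = 1e-9)
  }
})

test_that("a cold run stays close to the start structure", {
  hel <- helix_chain(20)
  cg <- build_cg(hel, assign_ss(hel))
  rs <- derive_restraints(cg)
  traj <- run_simulation(cg, rs,
                         sparams = sim_params(temperature = 0.01,
                                              n_snapshots = 100, seed = 17))
  disp <- vapply(traj$frames, function(f)
    mean(sqrt(rowSums((f - cg$ca)^2))), numeric(1))
  expect_lt(mean(disp), 1)
})
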