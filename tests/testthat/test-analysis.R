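test_that("identical frames give a zero fluctuation profile", {
  ca <- chain_coords(helix_chain(10), "CA")
  msf <- compute_msf(rep(list(ca), 8))
  expect_true(all(msf$msf < 1e-20))
  expect_warning(compute_msf(list(ca)), "single")
})

test_that("a two-frame displacement gives msf d^2 / 2 at the moved residue", {
  ca <- chain_coords(helix_chain(10), "CA")
  # two long arms differing by a pure displacement of residue 5; use many
  # identical anchor residues so superposition is pinned by the rest
  ca2 <- ca
  d <- 1.2
  ca2[5, ] <- ca[5, ] + c(0, 0, d)
  frames <- c(rep(list(ca), 50), rep(list(ca2), 50))
  msf <- compute_msf(frames)
  # mean position is halfway: each frame deviates d/2, and the trajectory
  # average of squared deviations is (d/2)^2 = d^2/4
  expect_equal(msf$msf[5], d^2 / 4, tolerance = 0.05)
  msf2 <- compute_msf(list(ca, ca2))
  expect_equal(msf2$msf[5], d^2 / 4, tolerance = 0.05)
})

test_that("planted per-residue variances are recovered within 10 percent", {
  hel <- helix_chain(30)
  sig <- rep(0.1, 30); sig[15] <- 1
  frames <- make_planted_ensemble(hel, sig, n_frames = 2000, seed = 5)
  msf <- compute_msf(frames)
  expect_equal(msf$msf[15], 3.0, tolerance = 0.1)
  expect_equal(mean(msf$msf[-15]), 0.03, tolerance = 0.1)
})

test_that("the profile is invariant to a common rigid transform of all frames", {
  hel <- helix_chain(12)
  frames <- make_planted_ensemble(hel, rep(0.4, 12), n_frames = 60, seed = 2)
  msf0 <- compute_msf(frames)
  R <- random_proper_rotation()
  moved <- lapply(frames, function(f) sweep(f %*% R, 2, c(9, -4, 2), "+"))
  expect_equal(compute_msf(moved)$msf, msf0$msf, tolerance = 1e-6)
})

test_that("summed msf equals the mean per-frame squared deviation (brute force)", {
  hel <- helix_chain(10)
  frames <- make_planted_ensemble(hel, rep(0.5, 10), n_frames = 40, seed = 3)
  msf <- compute_msf(frames)
  aligned <- ml_superpose(frames)$aligned
  mean_s <- Reduce(`+`, aligned) / length(aligned)
  per_frame <- vapply(aligned, function(a) sum((a - mean_s)^2), numeric(1))
  expect_equal(sum(msf$msf), mean(per_frame), tolerance = 1e-9)
})

test_that("clustering recovers a planted two-conformer partition", {
  hel <- helix_chain(20)
  ca <- chain_coords(hel, "CA")
  set.seed(2)
  bend <- outer(c(rep(0, 10), seq(0, 4.5, length.out = 10)), c(1, 0, 0))
  conf2 <- ca + bend
  frames <- c(make_planted_ensemble(ca, rep(0.15, 20), 100, seed = 11),
              make_planted_ensemble(conf2, rep(0.15, 20), 100, seed = 12))
  cr <- cluster_frames(frames, k = 2, seed = 3)
  truth <- rep(1:2, each = 100)
  tab <- table(cr$assignment, truth)
  expect_equal(sort(diag(tab[order(-tab[, 1]), ])), c(100, 100),
               ignore_attr = TRUE)
  expect_identical(cr$assignment,
                   cluster_frames(frames, k = 2, seed = 3)$assignment)
})

test_that("medoids equal the exhaustive argmin on every cluster", {
  hel <- helix_chain(12)
  frames <- make_planted_ensemble(hel, rep(0.5, 12), n_frames = 90, seed = 7)
  cr <- cluster_frames(frames, k = 4, seed = 2)
  aligned <- flexens:::superpose_to_mean(frames)
  for (c in seq_len(cr$k)) {
    members <- which(cr$assignment == c)
    expect_lte(length(members), 90)
    expect_equal(cr$medoid_frame_ids[c], exhaustive_medoid(aligned, members))
    expect_true(cr$medoid_frame_ids[c] %in% members)
  }
  # assignment covers every frame exactly once
  expect_equal(sort(unlist(lapply(seq_len(cr$k),
                                  function(c) which(cr$assignment == c)))),
               1:90)
})

test_that("k = 1 gives a single cluster with the global medoid", {
  hel <- helix_chain(10)
  frames <- make_planted_ensemble(hel, rep(0.4, 10), n_frames = 20, seed = 4)
  cr <- cluster_frames(frames, k = 1, seed = 1)
  expect_equal(unique(cr$assignment), 1L)
  aligned <- flexens:::superpose_to_mean(frames)
  expect_equal(cr$medoid_frame_ids, exhaustive_medoid(aligned, 1:20))
  expect_error(cluster_frames(frames, k = 21, seed = 1), "exceed")
})

test_that("density ranking puts the tighter of two equal-size clusters first", {
  hel <- helix_chain(15)
  ca <- chain_coords(hel, "CA")
  # same size, different internal shape (a bend superposition cannot remove),
  # one cluster twice as spread as the other
  bent <- ca + outer(c(rep(0, 7), seq(0, 4, length.out = 8)), c(1, 0, 0))
  tight <- make_planted_ensemble(ca, rep(0.1, 15), 50, seed = 21)
  loose <- make_planted_ensemble(bent, rep(0.8, 15), 50, seed = 22)
  frames <- c(tight, loose)
  cr <- cluster_frames(frames, k = 2, seed = 5)
  first <- cr$rank_order[1]
  # the top-ranked cluster must be the tight one (members 1..50)
  expect_true(all(which(cr$assignment == first) <= 50))
  expect_gt(cr$density[first], cr$density[cr$rank_order[2]])

  ens <- rank_and_extract(cr, frames)
  expect_equal(vapply(ens$models, `[[`, numeric(1), "rank"), 1:2)
  expect_equal(ens$models[[1]]$cluster, first)
  expect_equal(ens$models[[1]]$ca, frames[[ens$models[[1]]$frame_id]])
})

test_that("singleton clusters rank deterministically by the tie-break rule", {
  hel <- helix_chain(8)
  ca <- chain_coords(hel, "CA")
  # four singletons, pairwise equidistant-ish: density ties broken by id
  frames <- lapply(c(0, 20, 40, 60), function(s) ca + s)
  cr1 <- cluster_frames(frames, k = 4, seed = 9)
  cr2 <- cluster_frames(frames, k = 4, seed = 9)
  expect_identical(cr1$rank_order, cr2$rank_order)
  expect_equal(sort(cr1$rank_order), 1:4)
  expect_true(all(cr1$sizes == 1))
  expect_true(all(cr1$density == 1))  # size 1 / (1 + 0)
  expect_equal(cr1$rank_order, 1:4)   # equal densities -> lower id first
})
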