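test_that("parameter validation rejects invalid settings before simulating", {
  expect_error(sim_params(mu = -0.1), "\\[0, 1\\]")
  expect_error(sim_params(mu = 1.5), "\\[0, 1\\]")
  expect_error(sim_params(generations = 0), "generations")
  expect_error(sim_params(dup_len = c(2, 10)), "L_min")
  expect_error(sim_params(kappa = 0), "kappa")
})

test_that("with all rates zero the sequence never changes", {
  p <- sim_params(mu = 0, sigma = 0, delta = 0, generations = 25,
                  n_replicates = 3, seed = 5)
  traj <- evolve(strrep("CAG", 12), p)
  for (r in traj$replicates) {
    expect_identical(r$final_seq, strrep("CAG", 12))
    expect_equal(nrow(r$events), 0)
  }
})

test_that("a forced slippage insertion adds one unit and preserves purity", {
  p <- sim_params(mu = 0, sigma = 1, delta = 0, generations = 1,
                  n_replicates = 1, seed = 2, ins_prob = 1)
  traj <- evolve(strrep("CAG", 10), p)
  fin <- traj$replicates[[1]]$final_seq
  expect_equal(nchar(fin), 33)
  tr <- find_repeat_tracts(fin, "CAG", min_units = 2, max_divergence = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$purity, 1.0)
})

test_that("trajectories are reproducible from the seed", {
  p <- sim_params(mu = 0.001, sigma = 0.01, delta = 0.005, generations = 100,
                  n_replicates = 2, seed = 7)
  t1 <- evolve(strrep("CAG", 20), p)
  t2 <- evolve(strrep("CAG", 20), p)
  for (r in 1:2) {
    expect_identical(t1$replicates[[r]]$final_seq, t2$replicates[[r]]$final_seq)
    expect_identical(t1$replicates[[r]]$events, t2$replicates[[r]]$events)
  }
})

test_that("replaying the event log reproduces final sequences exactly", {
  init <- paste0(rand_dna(30), strrep("CAG", 25), rand_dna(30))
  p <- sim_params(mu = 0.005, sigma = 0.1, delta = 0.05, generations = 60,
                  n_replicates = 5, seed = 13, dup_len = c(12, 40))
  set.seed(999)  # replay must not depend on ambient RNG state
  traj <- evolve(init, p)
  for (r in traj$replicates) {
    expect_gt(nrow(r$events), 0)
    expect_identical(replay_events(init, r$events), r$final_seq)
  }
})

test_that("snapshots are consistent with the event log", {
  init <- strrep("CAG", 30)
  p <- sim_params(mu = 0.01, sigma = 0.2, delta = 0.02, generations = 30,
                  n_replicates = 2, seed = 17, snapshot_every = 10)
  traj <- evolve(init, p)
  for (r in traj$replicates) {
    for (g in names(r$snapshots)) {
      ev <- r$events[r$events$generation <= as.integer(g), , drop = FALSE]
      expect_identical(replay_events(init, ev), r$snapshots[[g]])
    }
  }
})

test_that("sequence length is constant without slippage or duplication", {
  p <- sim_params(mu = 0.05, sigma = 0, delta = 0, generations = 50,
                  n_replicates = 4, seed = 3)
  traj <- evolve(strrep("CAG", 15), p)
  for (r in traj$replicates) expect_equal(nchar(r$final_seq), 45)
})

test_that("symmetric slippage conserves expected repeat length (martingale)", {
  n_rep <- 200
  p <- sim_params(mu = 0, sigma = 0.5, delta = 0, generations = 40,
                  n_replicates = n_rep, seed = 29, ins_prob = 0.5)
  traj <- evolve(strrep("CAG", 30), p)
  lens <- vapply(traj$replicates, function(r) nchar(r$final_seq), numeric(1))
  se <- sd(lens) / sqrt(n_rep)
  expect_lte(abs(mean(lens) - 90), 3 * se)
})

test_that("closed-form stop-gain hazard matches codon-space minima", {
  mu <- 0.001
  expect_equal(stop_gain_hazard("CAG", "polyQ", mu), mu / 3)
  expect_equal(stop_gain_hazard("CAG", "polyS", mu), 0)
  expect_equal(stop_gain_hazard("CAG", "polyA", mu), 0)
  # kappa reweighting: the C->T route to TAG is a transition
  kappa <- 4
  expect_equal(stop_gain_hazard("CAG", "polyQ", mu, kappa),
               mu * kappa / (kappa + 2))
  expect_error(stop_gain_hazard("CAG", "polyX", mu), "unknown frame")
})

test_that("survival is 1 everywhere without mutation and monotone in general", {
  p0 <- sim_params(mu = 0, sigma = 0, delta = 0, generations = 20,
                   n_replicates = 10, seed = 11)
  t0 <- evolve(strrep("CAG", 20), p0)
  for (f in c("polyQ", "polyS", "polyA")) {
    s <- frame_survival(t0, f)
    expect_true(all(s$surviving_fraction == 1))
  }
  p1 <- sim_params(mu = 0.01, sigma = 0, delta = 0, generations = 50,
                   n_replicates = 100, seed = 19)
  t1 <- evolve(strrep("CAG", 20), p1)
  for (f in c("polyQ", "polyS", "polyA")) {
    s <- frame_survival(t1, f)$surviving_fraction
    expect_true(all(diff(s) <= 0))
  }
  expect_error(frame_survival(t1, "polyX"), "unknown frame")
})

test_that("simulated polyQ survival matches the exact codon Markov chain", {
  # independent oracle: 64-state per-codon chain with absorbing stops;
  # codons evolve independently so locus survival is the codon survival
  # raised to the number of codons
  mu <- 0.002; G <- 50; n_units <- 30; n_rep <- 400
  p <- sim_params(mu = mu, sigma = 0, delta = 0, generations = G,
                  n_replicates = n_rep, seed = 37)
  traj <- evolve(strrep("CAG", n_units), p)
  sim <- frame_survival(traj, "polyQ")$surviving_fraction[-1]
  exact <- oracle_codon_survival("CAG", mu, G)^n_units
  se <- sqrt(pmax(exact * (1 - exact), 1e-12) / n_rep)
  expect_true(all(abs(sim - exact) <= 3 * se))
})
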