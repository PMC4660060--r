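# single bead pinned to the origin by a degenerate box: E = |x|^2, the
# 3D harmonic oscillator (each coordinate Boltzmann-distributed with
# variance T/2)
harmonic_system <- function() {
  eps <- 1e-9
  topo <- assembly_topology(
    sequences = c(A = "AAAAAAAAAA"), copy_count = 1,
    boxes = list(A = list(min = rep(-eps, 3), max = rep(eps, 3)))
  )
  list(topology = topo, restraints = restraint_set(topo))
}

test_that("sampler configuration validates its invariants", {
  expect_error(sampler_config(t_min = 3, t_max = 1), "t_min")
  expect_error(sampler_config(n_replicas = 0), "n_replicas")
  expect_error(sampler_config(max_move = 0), "max_move")
  cfg <- sampler_config(n_replicas = 5, t_min = 1, t_max = 3)
  tl <- temperature_ladder(cfg)
  expect_equal(tl[1], 1)
  expect_equal(tl[5], 3)
  expect_equal(diff(log(tl)), rep(log(3) / 4, 4))  # geometric spacing
})

test_that("initialization respects boxes and the union rule", {
  topo <- assembly_topology(
    sequences = c(A = seq_of(30), B = seq_of(20)), copy_count = 1,
    boxes = list(A = list(min = c(0, 0, 0), max = c(10, 10, 10)))
  )
  rs <- restraint_set(topo)
  st <- initialize_state(topo, rs, seed = 3)
  rows_a <- st$beads$component == "A"
  expect_true(all(st$xyz[rows_a, ] >= 0 & st$xyz[rows_a, ] <= 10))
  # same seed, same coordinates; different seed, different
  expect_identical(st$xyz, initialize_state(topo, rs, seed = 3)$xyz)
  expect_false(identical(st$xyz, initialize_state(topo, rs, seed = 4)$xyz))
  # unboxed components fall inside the union of boxes (two disjoint boxes)
  topo2 <- assembly_topology(
    sequences = c(A = seq_of(10), B = seq_of(10), C = seq_of(10)), copy_count = 1,
    boxes = list(A = list(min = c(0, 0, 0), max = c(10, 10, 10)),
                 B = list(min = c(40, 40, 40), max = c(50, 50, 50)))
  )
  rs2 <- restraint_set(topo2)
  in_union <- function(x) {
    all(x >= 0 & x <= 10) || all(x >= 40 & x <= 50)
  }
  for (seed in 1:200) {
    st2 <- initialize_state(topo2, rs2, seed = seed)
    expect_true(in_union(st2$xyz[st2$beads$component == "C", ]))
  }
  # no boxes anywhere: no initialization volume
  topo3 <- assembly_topology(c(A = seq_of(10)), copy_count = 1)
  expect_error(initialize_state(topo3, restraint_set(topo3), seed = 1), "box")
})

test_that("Metropolis acceptance frequency matches exp(-dE/T)", {
  hs <- harmonic_system()
  st <- initialize_state(hs$topology, hs$restraints, seed = 1)
  cfg <- sampler_config(n_replicas = 1, t_min = 1, t_max = 1, n_steps = 1e5,
                        exchange_interval = 1000, seed = 2, top_n_keep = 1,
                        max_move = 1)
  sys <- xlbeads:::build_system(st, hs$restraints)
  res <- xlbeads:::pt_engine(st, hs$restraints, cfg, sys, diag = TRUE)
  dE <- res$diag_dE
  acc <- res$diag_accepted
  expect_true(all(acc[dE <= 0] == 1))  # downhill always accepted
  # binned uphill acceptance within 3 standard errors of the closed form
  for (centre in c(0.5, 1, 2)) {
    sel <- dE > centre - 0.1 & dE < centre + 0.1
    expect_gt(sum(sel), 500)
    p_obs <- mean(acc[sel])
    p_exp <- mean(exp(-dE[sel]))
    se <- sqrt(p_exp * (1 - p_exp) / sum(sel))
    expect_lt(abs(p_obs - p_exp), 3 * se + 1e-12)
  }
})

test_that("a rejected move leaves the state bitwise unchanged", {
  topo <- toy_topology()
  rs <- restraint_set(topo)
  st <- initialize_state(topo, rs, seed = 5)
  # freezing cold: any uphill proposal is rejected
  n_rej <- 0
  for (seed in 1:40) {
    out <- mc_step(st, rs, temperature = 1e-9, seed = seed)
    if (!attr(out, "accepted")) {
      n_rej <- n_rej + 1
      expect_identical(out$xyz, st$xyz)
    } else {
      expect_lte(attr(out, "delta_e"), 0)
    }
  }
  expect_gt(n_rej, 0)
})

test_that("symmetry is exactly maintained along a trajectory", {
  topo <- toy_topology()
  rs <- restraint_set(topo, data.frame(protein_a = "A", position_a = 5,
                                       protein_b = "B", position_b = 9,
                                       q_value = 1e-3))
  cfg <- sampler_config(n_replicas = 2, n_steps = 2000, exchange_interval = 100,
                        seed = 8, top_n_keep = 10)
  ens <- run_sampling(topo, rs, cfg)
  n0 <- sum(ens$assembly$beads$copy == 0)
  for (m in ens$models) {
    expect_equal(m[(n0 + 1):(2 * n0), ],
                 apply_symmetry(m[1:n0, , drop = FALSE], topo$symmetry),
                 tolerance = 1e-12)
  }
})

test_that("sampling is reproducible and returns a sorted ensemble", {
  topo <- toy_topology()
  rs <- restraint_set(topo)
  cfg <- sampler_config(n_replicas = 3, n_steps = 3000, exchange_interval = 50,
                        seed = 21, top_n_keep = 15)
  e1 <- run_sampling(topo, rs, cfg)
  e2 <- run_sampling(topo, rs, cfg)
  expect_identical(e1$models, e2$models)  # bit-for-bit
  expect_identical(e1$scores, e2$scores)
  expect_false(is.unsorted(e1$scores))
  expect_lte(length(e1$models), cfg$top_n_keep)
  # n_steps = 0 returns just the initial state
  cfg0 <- sampler_config(n_replicas = 2, n_steps = 0, seed = 21, top_n_keep = 5)
  e0 <- run_sampling(topo, rs, cfg0)
  expect_equal(length(e0$models), 1)
  init <- initialize_state(topo, rs, seed = 21)
  expect_equal(e0$models[[1]], init$xyz, ignore_attr = TRUE)
})

test_that("a feasible cross-link toy relaxes to (near) zero score", {
  # 3-bead chain, one cross-link between the chain ends, no boxes
  topo <- assembly_topology(c(A = seq_of(30)), copy_count = 1,
                            boxes = list(A = list(min = rep(-30, 3),
                                                  max = rep(30, 3))))
  xl <- data.frame(protein_a = "A", position_a = 1,
                   protein_b = "A", position_b = 30, q_value = 1e-3)
  rs <- restraint_set(topo, xl, box_k = 0)  # box only used for initialization
  cfg <- sampler_config(n_replicas = 4, n_steps = 1e5, exchange_interval = 100,
                        seed = 13, top_n_keep = 10)
  ens <- run_sampling(topo, rs, cfg)
  expect_lt(ens$scores[1], 1e-3)
})

test_that("per-replica Boltzmann statistics on the harmonic toy", {
  hs <- harmonic_system()
  st <- initialize_state(hs$topology, hs$restraints, seed = 1)
  cfg <- sampler_config(n_replicas = 4, t_min = 1, t_max = 3, n_steps = 1e6,
                        exchange_interval = 10, seed = 5, top_n_keep = 1,
                        max_move = 1.5)
  sys <- xlbeads:::build_system(st, hs$restraints)
  res <- xlbeads:::pt_engine(st, hs$restraints, cfg, sys, trace = TRUE)
  temps <- temperature_ladder(cfg)
  burn <- 5000
  for (r in seq_along(temps)) {
    v <- mean(c(var(res$trace_x[-(1:burn), r]),
                var(res$trace_y[-(1:burn), r]),
                var(res$trace_z[-(1:burn), r])))
    expect_lt(abs(v / (temps[r] / 2) - 1), 0.05)
  }
})

test_that("replica exchange accepts equal-energy and equal-temperature swaps", {
  # two replicas at the same temperature swap with probability 1: the
  # exchange rate over a trajectory must be exactly 1
  hs <- harmonic_system()
  st <- initialize_state(hs$topology, hs$restraints, seed = 2)
  cfg <- sampler_config(n_replicas = 2, t_min = 2, t_max = 2, n_steps = 5000,
                        exchange_interval = 10, seed = 6, top_n_keep = 1)
  sys <- xlbeads:::build_system(st, hs$restraints)
  res <- xlbeads:::pt_engine(st, hs$restraints, cfg, sys)
  expect_equal(res$exchange_rate, 1)
})

test_that("two-state Metropolis chain reaches the Boltzmann distribution", {
  # states {0, 1} with energies {0, dE}; flips proposed every step and
  # accepted by the same min(1, exp(-dE/T)) rule the sampler uses
  dE <- 1.3
  temp <- 0.9
  n <- 1e6
  set.seed(31)
  u <- runif(n)
  state <- integer(n)
  s <- 0L
  p_up <- exp(-dE / temp)
  for (i in seq_len(n)) {
    s <- if (s == 0L) { if (u[i] < p_up) 1L else 0L } else 0L
    state[i] <- s
  }
  pi1_obs <- mean(state)
  pi1_exp <- p_up / (1 + p_up)
  se <- sqrt(pi1_exp * (1 - pi1_exp) / n) * 3  # 3 SE, ignoring autocorrelation
  expect_lt(abs(pi1_obs - pi1_exp), 10 * se)   # conservative for correlated draws
})

test_that("well-tempered bias obeys its defining properties", {
  b <- wte_bias(gamma = 16, sigma = 2, height = 1, temperature = 1)
  expect_equal(wte_bias_value(b, c(-5, 0, 5)), c(0, 0, 0))  # no deposits
  b1 <- wte_bias_update(b, 10)
  expect_equal(wte_bias_value(b1, 10), 1)  # first Gaussian at full height
  # heights at a revisited energy decrease strictly
  heights <- numeric(6)
  bb <- b
  for (i in 1:6) {
    bb <- wte_bias_update(bb, 10)
    heights[i] <- bb$heights[i]
  }
  expect_true(all(diff(heights) < 0))
  expect_error(wte_bias(gamma = 1), "gamma")
  # the engine runs with the bias enabled and stays reproducible
  topo <- toy_topology()
  rs <- restraint_set(topo)
  cfg <- sampler_config(n_replicas = 3, n_steps = 2000, exchange_interval = 50,
                        seed = 17, top_n_keep = 5, wte_enabled = TRUE)
  e1 <- run_sampling(topo, rs, cfg)
  e2 <- run_sampling(topo, rs, cfg)
  expect_identical(e1$models, e2$models)
})
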