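two_bead_assembly <- function(gap, radius = 5) {
  # two beads of one chain at a prescribed surface separation
  topo <- assembly_topology(c(A = seq_of(20)), copy_count = 1)
  asm <- build_assembly(topo)
  asm$beads$radius <- rep(radius, 2)
  asm$xyz <- rbind(c(0, 0, 0), c(2 * radius + gap, 0, 0))
  asm
}

test_that("connectivity penalizes gaps only", {
  expect_equal(connectivity_score(two_bead_assembly(0)), 0)
  expect_equal(connectivity_score(two_bead_assembly(2)), 4)
  expect_equal(connectivity_score(two_bead_assembly(-3)), 0)  # overlap is EV's job
  single <- build_assembly(assembly_topology(c(A = seq_of(8)), copy_count = 1))
  single$xyz <- matrix(0, 1, 3)
  expect_equal(connectivity_score(single), 0)
})

test_that("excluded volume penalizes overlap of non-adjacent pairs", {
  topo <- assembly_topology(c(A = seq_of(10), B = seq_of(10)), copy_count = 1)
  asm <- build_assembly(topo)
  asm$beads$radius <- c(5, 5)
  asm$xyz <- rbind(c(0, 0, 0), c(11, 0, 0))   # gap +1
  expect_equal(excluded_volume_score(asm), 0)
  asm$xyz[2, 1] <- 8                          # s = -2
  expect_equal(excluded_volume_score(asm), 4)
  # sequence-adjacent overlap is exempt
  adj <- two_bead_assembly(-2)
  expect_equal(excluded_volume_score(adj), 0)
  # concentric identical beads match the enumeration oracle
  conc <- asm
  conc$xyz <- rbind(c(0, 0, 0), c(0, 0, 0))
  rs <- restraint_set(topo)
  expect_equal(excluded_volume_score(conc), oracle_total_score(conc, rs))
  expect_equal(excluded_volume_score(conc), (2 * 5)^2)
})

test_that("cross-link restraints act on the minimum ambiguous distance", {
  topo <- toy_topology(boxes = list())
  asm <- random_assembly(topo, seed = 3)
  udr <- list(protein_a = "A", position_a = 5, protein_b = "B", position_b = 9)
  ra0 <- which(asm$beads$component == "A" & asm$beads$copy == 0 & asm$beads$bead == 0)
  rb0 <- which(asm$beads$component == "B" & asm$beads$copy == 0 & asm$beads$bead == 0)
  rb1 <- which(asm$beads$component == "B" & asm$beads$copy == 1 & asm$beads$bead == 0)
  place <- function(asm, s_intra, s_inter) {
    r <- asm$beads$radius
    asm$xyz[ra0, ] <- c(0, 0, 0)
    asm$xyz[rb0, ] <- c(r[ra0] + r[rb0] + s_intra, 0, 0)
    asm$xyz[rb1, ] <- c(0, r[ra0] + r[rb1] + s_inter, 0)
    asm
  }
  # exactly at the bound: no penalty
  expect_equal(crosslink_score(udr, place(asm, 5, 50), bound = 5), 0)
  # 2 A beyond: quadratic
  expect_equal(crosslink_score(udr, place(asm, 7, 50), bound = 5), 4)
  # ambiguity rule: a close inter-copy pairing silences a far intra-copy one
  expect_equal(crosslink_score(udr, place(asm, 12, 3), bound = 5), 0)
})

test_that("localization boxes penalize the Euclidean exit distance", {
  box <- list(min = c(0, 0, 0), max = c(10, 10, 10))
  expect_equal(localization_score(c(5, 5, 5), box), 0)
  expect_equal(localization_score(c(13, 5, 5), box), 9)
  expect_equal(localization_score(c(13, 14, 5), box), 25)  # (3,4,0) corner
  expect_error(localization_score(c(0, 0, 0), list(min = c(1, 0, 0), max = c(0, 1, 1))),
               "box")
})

test_that("subcomplex connectivity scores isolated members", {
  topo <- assembly_topology(
    sequences = c(A = seq_of(10), B = seq_of(10), C = seq_of(10)),
    copy_count = 1, subcomplex_groups = list(c("A", "B", "C"))
  )
  asm <- build_assembly(topo)
  r <- asm$beads$radius[1]
  # all three mutually touching
  asm$xyz <- rbind(c(0, 0, 0), c(2 * r, 0, 0), c(r, r * sqrt(3), 0))
  expect_equal(subcomplex_score(c("A", "B", "C"), asm), 0, tolerance = 1e-9)
  # C isolated 2 A from its nearest partner contributes 4
  asm$xyz[3, ] <- c(2 * r + (2 * r + 2), 0, 0)
  expect_equal(subcomplex_score(c("A", "B", "C"), asm), 4, tolerance = 1e-9)
  # two members in contact: nothing
  expect_equal(subcomplex_score(c("A", "B"), asm), 0)
  expect_error(subcomplex_score("A", asm), ">= 2")
})

test_that("symmetry application is an exact isometry", {
  sym <- list(R = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
              t = c(0, 0, 0))
  expect_equal(apply_symmetry(matrix(c(1, 0, 0), 1, 3), sym),
               matrix(c(-1, 0, 0), 1, 3))
  id <- list(R = diag(3), t = c(0, 0, 0))
  x <- matrix(rnorm(30), 10, 3)
  expect_identical(apply_symmetry(x, id), x)
  set.seed(2)
  tr <- random_rigid()
  y <- apply_symmetry(x, tr)
  expect_equal(as.matrix(dist(y)), as.matrix(dist(x)), tolerance = 1e-12)
  expect_error(apply_symmetry(x, list(R = diag(3) * 1.1, t = c(0, 0, 0))), "rigid")
})

test_that("total score equals the brute-force oracle on random assemblies", {
  # 50-bead dimer assemblies with full restraint sets, 1e-9 relative
  topo <- assembly_topology(
    sequences = c(P1 = seq_of(100), P2 = seq_of(80), P3 = seq_of(70)),
    copy_count = 2,
    symmetry = list(R = matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
                    t = c(30, 10, -5)),
    subcomplex_groups = list(c("P1", "P3")),
    boxes = list(P1 = list(min = c(-15, -15, -15), max = c(15, 15, 15)),
                 P2 = list(min = c(-30, 0, -10), max = c(5, 25, 20)))
  )
  set.seed(9)
  xl <- data.frame(
    protein_a = sample(c("P1", "P2", "P3"), 12, TRUE),
    position_a = sample(70, 12, TRUE),
    protein_b = sample(c("P1", "P2", "P3"), 12, TRUE),
    position_b = sample(70, 12, TRUE),
    q_value = 0.001
  )
  rs <- restraint_set(topo, xl)
  for (seed in 1:5) {
    asm <- random_assembly(topo, seed = seed, spread = 20)
    got <- total_score(asm, rs)
    want <- oracle_total_score(asm, rs)
    expect_equal(got$total, want, tolerance = 1e-9)
    # the C++ engine evaluates the identical function
    sys <- xlbeads:::build_system(asm, rs)
    cpp <- xlbeads:::.cg_energy_cpp(sys, asm$xyz)
    expect_equal(unname(cpp["total"]), want, tolerance = 1e-9)
    expect_equal(got$total,
                 got$connectivity + got$excluded_volume + got$crosslink +
                   got$box + got$subcomplex)
  }
})

test_that("score is invariant under global rigid motion without boxes", {
  topo <- toy_topology(boxes = list())
  rs <- restraint_set(topo, data.frame(protein_a = "A", position_a = 5,
                                       protein_b = "B", position_b = 9,
                                       q_value = 0.001))
  asm <- random_assembly(topo, seed = 4)
  base <- total_score(asm, rs)$total
  set.seed(7)
  for (i in 1:3) {
    tr <- random_rigid()
    moved <- asm
    moved$xyz <- sweep(asm$xyz %*% t(tr$R), 2, tr$t, `+`)
    expect_equal(total_score(moved, rs)$total, base, tolerance = 1e-9)
  }
})

test_that("all terms are non-negative and the breakdown sums", {
  topo <- toy_topology()
  rs <- restraint_set(topo, data.frame(protein_a = "A", position_a = 1,
                                       protein_b = "B", position_b = 20,
                                       q_value = 1e-3))
  for (seed in 1:4) {
    asm <- random_assembly(topo, seed = seed, spread = 40)
    sc <- total_score(asm, rs)
    expect_true(all(unlist(sc) >= 0))
  }
})
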