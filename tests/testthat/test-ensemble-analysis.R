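test_that("pairwise RMSD is a superposition-invariant metric", {
  set.seed(5)
  a <- matrix(rnorm(36), 12, 3)
  b <- a + matrix(rnorm(36, sd = 0.5), 12, 3)
  D <- pairwise_rmsd(list(a, b))
  expect_equal(D[1, 1], 0)
  expect_equal(D[1, 2], D[2, 1])
  # agreement with the independent bio3d implementation
  expect_equal(D[1, 2],
               bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE),
               tolerance = 1e-3)
  # invariant to rigid motion of either structure
  tr <- random_rigid()
  b_mov <- sweep(b %*% t(tr$R), 2, tr$t, `+`)
  D2 <- pairwise_rmsd(list(a, b_mov))
  expect_equal(D2[1, 2], D[1, 2], tolerance = 1e-6)
})

test_that("greedy clustering handles the canonical small cases", {
  m <- matrix(rnorm(9), 3, 3)
  # pairwise RMSDs {0-1: 1, 0-2: 30, 1-2: 30} at cutoff 17 -> {0,1}, {2}
  D <- matrix(c(0, 1, 30, 1, 0, 30, 30, 30, 0), 3, 3)
  cl <- daura_cluster(list(m, m, m), cutoff = 17, rmsd = D)
  expect_equal(cl$membership, c(1, 1, 2))
  expect_equal(cl$centres[2], 3)
  # identical structures collapse into one cluster
  cl2 <- daura_cluster(list(m, m, m, m), cutoff = 5)
  expect_equal(cl2$membership, rep(1, 4))
  # cutoff 0 with generic structures: all singletons
  set.seed(8)
  ms <- lapply(1:4, function(i) matrix(rnorm(9), 3, 3))
  cl3 <- daura_cluster(ms, cutoff = 0)
  expect_equal(length(cl3$centres), 4)
})

test_that("greedy clustering agrees with the exhaustive oracle", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0, 30)
    D <- D + t(D)
    scores <- runif(n)
    cutoff <- runif(1, 5, 20)
    got <- daura_cluster(replicate(n, matrix(0, 2, 3), simplify = FALSE),
                         cutoff = cutoff, rmsd = D, scores = scores)
    want <- oracle_daura(D, cutoff, scores)
    expect_identical(got$membership, want$membership)
    expect_identical(got$centres, want$centres)
  }
})

test_that("per-bead densities are normalized probability histograms", {
  # identical models: all mass in one voxel per bead
  m <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  dm <- compute_density(replicate(50, m, simplify = FALSE), bin = 2,
                        reference = m, align = FALSE)
  expect_equal(nrow(dm$voxels), 2)
  expect_equal(dm$voxels$p, c(1, 1))
  v <- bead_variability(dm)
  expect_equal(v$extent, c(0, 0))
  expect_equal(v$fraction_within, 1)
})

test_that("density sums to one per bead on scattered ensembles", {
  set.seed(12)
  models <- lapply(1:200, function(i) matrix(rnorm(15, sd = 6), 5, 3))
  dm <- compute_density(models, bin = 2, reference = models[[1]], align = FALSE)
  sums <- tapply(dm$voxels$p, dm$voxels$bead, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, 5), tolerance = 1e-12)
})

test_that("two equal half-max voxels 2 A apart give extent 2", {
  models <- c(replicate(10, matrix(c(0.5, 0.5, 0.5), 1, 3), simplify = FALSE),
              replicate(10, matrix(c(2.5, 0.5, 0.5), 1, 3), simplify = FALSE))
  dm <- compute_density(models, bin = 2, reference = models[[1]], align = FALSE)
  v <- bead_variability(dm)
  expect_equal(v$extent, 2)
})

test_that("Gaussian scatter recovers the closed-form FWHM", {
  set.seed(3)
  sigma <- 4
  n <- 10000
  pts <- matrix(rnorm(3 * n, sd = sigma), n, 3)
  models <- lapply(seq_len(n), function(i) matrix(pts[i, ], 1, 3))
  dm <- compute_density(models, bin = 2, reference = models[[1]], align = FALSE)
  v <- bead_variability(dm)
  fwhm <- 2 * sigma * sqrt(2 * log(2))
  expect_lt(abs(v$extent - fwhm), 2)  # within one 2 A bin
})

test_that("satisfaction counts minimum ambiguous distances against the cutoff", {
  topo <- toy_topology(boxes = list())
  asm <- build_assembly(topo)
  n0 <- sum(asm$beads$copy == 0)
  r <- asm$beads$radius
  place_first_pair <- function(s) {
    xyz <- matrix(rep(c(500, 500, 500), nrow(asm$beads)), ncol = 3, byrow = TRUE)
    xyz <- xyz + matrix(seq_len(nrow(asm$beads)) * 40, nrow(asm$beads), 3)
    xyz[1, ] <- c(0, 0, 0)
    rowB <- which(asm$beads$component == "B" & asm$beads$copy == 0)[1]
    xyz[rowB, ] <- c(r[1] + r[rowB] + s, 0, 0)
    asm$xyz <- xyz
    asm
  }
  udr <- data.frame(protein_a = "A", position_a = 1,
                    protein_b = "B", position_b = 1, q_value = 1e-3)
  expect_true(satisfaction_fraction(place_first_pair(9.9), udr)$satisfied)
  expect_false(satisfaction_fraction(place_first_pair(10.1), udr)$satisfied)
  expect_error(satisfaction_fraction(place_first_pair(1), udr[0, ]), "undefined")
  # restraints generated from a model at <= 5 A are all satisfied by it
  truth <- cached_truth()
  xl <- simulate_crosslinks(truth, d_true = 5, p_det = 1, f_decoy = 0, seed = 2)
  rep <- satisfaction_fraction(truth$assembly, xl, cutoff = 10)
  expect_equal(rep$fraction, 1)
  # monotone non-decreasing in the cutoff
  fr <- vapply(c(2, 5, 10, 20),
               function(ct) satisfaction_fraction(truth$assembly, xl, ct)$fraction, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("macro-regions partition each sequence into ~100-residue blocks", {
  lens <- c(Ask1 = 292, Dad1 = 94, Dam1 = 343)
  mr <- macro_regions(lens)
  ask1 <- mr[mr$component == "Ask1", ]
  expect_equal(ask1$label, c("Ask1N", "Ask1M", "Ask1C"))
  expect_equal(ask1$last_res - ask1$first_res + 1, c(97, 97, 98))
  expect_equal(mr$label[mr$component == "Dad1"], "Dad1")
  # partition property: contiguous cover of [1, len]
  for (nm in names(lens)) {
    sub <- mr[mr$component == nm, ]
    expect_equal(sub$first_res[1], 1)
    expect_equal(sub$last_res[nrow(sub)], unname(lens[nm]))
    if (nrow(sub) > 1) {
      expect_equal(sub$first_res[-1], sub$last_res[-nrow(sub)] + 1)
    }
  }
})

test_that("contact maps equal an all-pairs oracle and split intra/inter", {
  truth <- cached_truth()
  asm <- truth$assembly
  cutoff <- 5
  cm <- contact_map(asm, cutoff = cutoff)
  # oracle: enumerate every pair
  beads <- asm$beads
  n <- nrow(beads)
  want <- 0
  want_inter <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (beads$chain[i] == beads$chain[j] &&
        abs(beads$bead[i] - beads$bead[j]) == 1) next
    s <- oracle_surface(asm$xyz[i, ], asm$xyz[j, ], beads$radius[i], beads$radius[j])
    if (s <= cutoff) {
      want <- want + 1
      if (beads$copy[i] != beads$copy[j]) want_inter <- want_inter + 1
    }
  }
  expect_equal(nrow(cm$bead_pairs), want)
  expect_equal(sum(cm$bead_pairs$inter), want_inter)
  expect_equal(sum(cm$protein_pairs$intra + cm$protein_pairs$inter), want)
  # two touching beads of different proteins -> one protein-pair contact
  topo2 <- assembly_topology(c(A = seq_of(10), B = seq_of(10)), copy_count = 1)
  a2 <- build_assembly(topo2)
  a2$xyz <- rbind(c(0, 0, 0), c(2 * a2$beads$radius[1], 0, 0))
  cm2 <- contact_map(a2)
  expect_equal(nrow(cm2$protein_pairs), 1)
  # fully dispersed model: empty map
  a2$xyz <- rbind(c(0, 0, 0), c(500, 0, 0))
  expect_equal(nrow(contact_map(a2)$bead_pairs), 0)
})

test_that("macro-region comparison classifies gains and losses consistently", {
  truth <- cached_truth()
  cmA <- contact_map(truth$assembly)
  expect_true(all(macro_region_compare(cmA, cmA)$status == "shared"))
  # perturb: push one protein far away in B
  asmB <- truth$assembly
  rows <- asmB$beads$component == "P3"
  asmB$xyz[rows, ] <- asmB$xyz[rows, ] + 500
  cmB <- contact_map(asmB)
  cmp <- macro_region_compare(cmA, cmB)
  expect_true(any(cmp$status == "lost"))
  # set identity: statuses partition the union of observed pairs
  expect_equal(sum(cmp$status %in% c("shared", "lost", "gained")), nrow(cmp))
  expect_true(all((cmp$count_a > 0) | (cmp$count_b > 0)))
  lostB <- cmp[cmp$status == "lost", ]
  expect_true(all(lostB$count_b == 0))
  # mismatched topologies are refused
  topo2 <- assembly_topology(c(Z = seq_of(30)), copy_count = 1)
  a2 <- build_assembly(topo2)
  a2$xyz <- matrix(rnorm(9), 3, 3)
  expect_error(macro_region_compare(cmA, contact_map(a2)), "topolog")
})
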