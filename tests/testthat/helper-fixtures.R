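# Shared fixtures, built in code.

seq_of <- function(len) paste(rep("A", len), collapse = "")

# small two-protein dimer topology with a box on A and a subcomplex group
toy_topology <- function(lenA = 35, lenB = 22, copy_count = 2,
                         boxes = list(A = list(min = c(-20, -20, -20),
                                               max = c(20, 20, 20)))) {
  assembly_topology(
    sequences = c(A = seq_of(lenA), B = seq_of(lenB)),
    copy_count = copy_count,
    symmetry = list(R = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
                    t = c(40, 0, 0)),
    subcomplex_groups = list(c("A", "B")),
    boxes = boxes
  )
}

# assembly with random (symmetry-respecting) coordinates
random_assembly <- function(topology, seed = 1, spread = 25) {
  asm <- build_assembly(topology)
  rows0 <- which(asm$beads$copy == 0L)
  set.seed(seed)
  asm$xyz[rows0, ] <- matrix(runif(3 * length(rows0), -spread, spread),
                             ncol = 3)
  if (topology$copy_count == 2L) {
    asm$xyz[-rows0, ] <- apply_symmetry(asm$xyz[rows0, , drop = FALSE],
                                        topology$symmetry)
  }
  asm
}

# deterministic synthetic ground truth shared by several files
cached_truth <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      spec <- toy_assembly_spec(lengths = c(P1 = 160, P2 = 140, P3 = 100),
                                rg_target = 25, seed = 5,
                                subcomplex_groups = list(c("P2", "P3")))
      val <<- generate_toy_assembly(spec)
    }
    val
  }
})

# docking study: a slightly looser dimer resting on the lattice face,
# with planted tubulin cross-links and tight boxes in the planted frame.
# Stage sampling uses enlarged rigid lattice moves (6 A / 10 deg) so the
# long-range approach and re-registration converge at desk scale.
cached_docking_toy <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      spec <- toy_assembly_spec(lengths = c(P1 = 160, P2 = 140, P3 = 100),
                                rg_target = 35, seed = 5,
                                subcomplex_groups = list(c("P2", "P3")))
      truth <- generate_toy_assembly(spec)
      lat <- build_lattice(alpha_seq = 80, beta_seq = 80)
      plant <- simulate_tubulin_xls(truth, lat, d_true = 10, p_det = 1,
                                    seed = 3, gap = 0)
      xl <- simulate_crosslinks(truth, d_true = 5, p_det = 0.7, f_decoy = 0,
                                seed = 2)
      boxes <- derive_bounding_boxes(plant, pad = 10)
      rs <- restraint_set(truth$topology,
                          xl[, setdiff(names(xl), "is_decoy")], boxes = boxes)
      val <<- list(truth = truth, lattice = lat, plant = plant,
                   restraints = rs)
    }
    val
  }
})

dock_toy_once <- function(seed, n_steps = 2e5, n_replicas = 4) {
  toy <- cached_docking_toy()
  cfg <- sampler_config(n_replicas = n_replicas, n_steps = n_steps,
                        exchange_interval = 200, top_n_keep = 50, seed = seed)
  dock_flexible(toy$plant$assembly, toy$lattice, toy$plant$xls,
                toy$restraints, cfg, init_dist = 1000,
                lat_move_prob = 0.1, lat_max_trans = 6, lat_max_rot = 10)
}

# tiny PDB text fixture: two chains, Calpha-only, with lysines
write_toy_pdb <- function(path, coords, chains, resnos, resids) {
  lines <- vapply(seq_along(chains), function(i) {
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, resids[i], chains[i], resnos[i],
            coords[i, 1], coords[i, 2], coords[i, 3])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}
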