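#' Specification of a synthetic toy assembly
#'
#' Defines a ground-truth assembly with known coordinates from which
#' cross-link observations can be simulated, so every pipeline stage can
#' be exercised against a known answer.
#'
#' @param lengths named integer vector: component name -> sequence length
#'   (residues).  Synthetic sequences are generated with lysine-like
#'   sites at a fixed spacing (see [crosslink_sites()]).
#' @param granularity residues per bead (default 10).
#' @param rg_target compactness target: maximum radius of gyration per
#'   monomer, A (default 25).
#' @param copy_count 1 or 2.
#' @param symmetry rigid transform for copy 1; default: 180-degree
#'   rotation about z plus a translation of `2.4 * rg_target` along x,
#'   which puts the two monomers side by side in contact.
#' @param subcomplex_groups list of component-name groups (default: none).
#' @param seed RNG seed.
#' @return object of class `toy_assembly_spec`.
#' @export
toy_assembly_spec <- function(lengths, granularity = 10, rg_target = 25,
                              copy_count = 2, symmetry = NULL,
                              subcomplex_groups = list(), seed = 1) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("lengths must be a named vector")
  }
  if (all(lengths < granularity)) {
    stop("at least one component must span a full bead")
  }
  if (is.null(symmetry)) {
    symmetry <- list(
      R = matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
      t = c(2.4 * rg_target, 0, 0)
    )
  }
  if (copy_count == 2) check_rigid_transform(symmetry)
  structure(list(lengths = lengths, granularity = as.integer(granularity),
                 rg_target = rg_target, copy_count = as.integer(copy_count),
                 symmetry = symmetry, subcomplex_groups = subcomplex_groups,
                 seed = as.integer(seed)),
            class = "toy_assembly_spec")
}

# synthetic sequence with lysine-like sites every `spacing` residues
# (roughly the lysine frequency of real proteins) and alanine elsewhere
synthetic_sequence <- function(len, spacing = 8) {
  aa <- rep("A", len)
  aa[seq(1, len, by = spacing)] <- "K"
  paste(aa, collapse = "")
}

#' Lysine-like cross-linkable sites of a topology
#'
#' @param topology an [assembly_topology()].
#' @return data.frame `protein`, `position` of every lysine in the
#'   sequences.
#' @export
crosslink_sites <- function(topology) {
  out <- lapply(names(topology$sequences), function(nm) {
    pos <- which(strsplit(topology$sequences[[nm]], "")[[1]] == "K")
    if (length(pos) == 0) return(NULL)
    data.frame(protein = nm, position = pos)
  })
  do.call(rbind, out)
}

radius_of_gyration <- function(xyz) {
  c0 <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
}

# n x m matrix of pairwise Euclidean distances between two point sets
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# force-based relaxation: connectivity springs + excluded-volume pushes
# (including against the symmetric image) + a centring pull that acts only
# while the monomer radius of gyration exceeds the target
relax_truth <- function(xyz, beads, topology, rg_target, max_iter = 4000,
                        tol = 1e-3, step = 0.25) {
  n <- nrow(xyz)
  ap <- adjacent_pairs(beads[beads$copy == 0L, ])
  rad <- beads$radius[beads$copy == 0L]
  sym <- topology$symmetry
  two <- topology$copy_count == 2L
  adj <- matrix(FALSE, n, n)
  adj[ap] <- TRUE
  adj[ap[, 2:1, drop = FALSE]] <- TRUE
  rsum <- outer(rad, rad, `+`)
  for (iter in seq_len(max_iter)) {
    f <- matrix(0, n, 3)
    d <- as.matrix(dist(xyz))
    s <- d - rsum
    for (k in seq_len(nrow(ap))) {
      i <- ap[k, 1]; j <- ap[k, 2]
      if (s[i, j] > 0) {
        u <- (xyz[i, ] - xyz[j, ]) / d[i, j]
        f[i, ] <- f[i, ] - 2 * s[i, j] * u
        f[j, ] <- f[j, ] + 2 * s[i, j] * u
      }
    }
    ov <- which(s < 0 & !adj & upper.tri(s), arr.ind = TRUE)
    for (k in seq_len(nrow(ov))) {
      i <- ov[k, 1]; j <- ov[k, 2]
      u <- if (d[i, j] > 1e-9) (xyz[i, ] - xyz[j, ]) / d[i, j] else c(1, 0, 0)
      f[i, ] <- f[i, ] - 2 * s[i, j] * u
      f[j, ] <- f[j, ] + 2 * s[i, j] * u
    }
    # overlaps against the symmetric image
    simg <- NULL
    if (two) {
      img <- apply_symmetry(xyz, sym)
      dimg <- cross_dist(xyz, img)
      simg <- dimg - rsum
      hits <- which(simg < 0, arr.ind = TRUE)
      for (k in seq_len(nrow(hits))) {
        i <- hits[k, 1]; j <- hits[k, 2]
        dd <- dimg[i, j]
        u <- if (dd > 1e-9) (xyz[i, ] - img[j, ]) / dd else c(1, 0, 0)
        f[i, ] <- f[i, ] - 2 * simg[i, j] * u
        # reaction on the image maps back through the rotation transpose
        f[j, ] <- f[j, ] + 2 * simg[i, j] * as.numeric(t(sym$R) %*% u)
      }
    }
    rg <- radius_of_gyration(xyz)
    if (rg > rg_target) {
      c0 <- colMeans(xyz)
      f <- f - 0.4 * sweep(xyz, 2, c0)
    }
    # converged when the assembly-level construction scores (doubled for
    # the two copies, plus cross-copy overlaps) stay under the tolerance
    conn_tot <- if (nrow(ap)) sum(pmax(s[ap], 0)^2) else 0
    ev_tot <- if (nrow(ov)) sum(pmin(s[ov], 0)^2) else 0
    img_tot <- if (two) sum(pmin(simg, 0)^2) else 0
    if (rg <= rg_target && 2 * (conn_tot + ev_tot) + img_tot < 0.5 * tol) {
      return(xyz)
    }
    f_norm <- sqrt(rowSums(f^2))
    cap <- pmin(1, 1.5 / pmax(f_norm, 1e-9))   # bound per-iteration motion
    xyz <- xyz + step * f * cap
  }
  NULL
}

#' Generate a ground-truth toy assembly
#'
#' Builds each component as a self-avoiding chain of touching beads by a
#' random walk, then relaxes the monomer under connectivity + excluded
#' volume (including against the symmetric copy) with a centring pull
#' until the radius-of-gyration target is met.  Deterministic given the
#' spec seed.  Errors if the compactness target cannot be reached after
#' bounded attempts.
#'
#' @param spec a [toy_assembly_spec()].
#' @return list with `assembly` (positioned ground-truth `bead_assembly`)
#'   and `topology`.
#' @export
generate_toy_assembly <- function(spec) {
  stopifnot(inherits(spec, "toy_assembly_spec"))
  seqs <- vapply(spec$lengths, synthetic_sequence, "")
  topology <- assembly_topology(
    sequences = seqs, copy_count = spec$copy_count,
    granularity = spec$granularity, symmetry = spec$symmetry,
    subcomplex_groups = spec$subcomplex_groups
  )
  assembly <- build_assembly(topology)
  beads0 <- which(assembly$beads$copy == 0L)
  rad <- assembly$beads$radius[beads0]
  chain <- assembly$beads$chain[beads0]
  n <- length(beads0)
  # packing feasibility: beads of total volume V cannot compact below the
  # radius of gyration of a dense ball holding V (Rg of a uniform ball of
  # radius R is R * sqrt(3/5); random packings stay under ~64% density)
  v_total <- sum(4 / 3 * pi * rad^3)
  r_ball <- spec$rg_target * sqrt(5 / 3)
  if (v_total > 0.64 * 4 / 3 * pi * r_ball^3) {
    stop("could not build a self-avoiding assembly at the requested compactness",
         " (bead volume exceeds the packing limit)")
  }
  for (attempt in 1:20) {
    xyz <- with_seed(spec$seed + 1000 * (attempt - 1), {
      x <- matrix(0, n, 3)
      ok <- TRUE
      for (i in seq_len(n)) {
        if (i == 1 || chain[i] != chain[i - 1]) {
          x[i, ] <- runif(3, -spec$rg_target / 2, spec$rg_target / 2)
        } else {
          placed <- FALSE
          for (try in 1:200) {
            u <- stats::rnorm(3)
            u <- u / sqrt(sum(u^2))
            cand <- x[i - 1, ] + (rad[i] + rad[i - 1]) * u
            prev <- seq_len(i - 1)
            sd_min <- min(sqrt(rowSums(sweep(x[prev, , drop = FALSE], 2, cand)^2)) -
                          rad[prev] - rad[i])
            if (sd_min > -0.05 || (length(prev) == 1)) {
              x[i, ] <- cand
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) x else NULL
    })
    if (is.null(xyz)) next
    relaxed <- relax_truth(xyz, assembly$beads, topology, spec$rg_target)
    if (!is.null(relaxed)) {
      assembly$xyz[beads0, ] <- relaxed
      if (spec$copy_count == 2L) {
        assembly$xyz[-beads0, ] <- apply_symmetry(relaxed, spec$symmetry)
      }
      return(list(assembly = assembly, topology = topology))
    }
  }
  stop("could not build a self-avoiding assembly at the requested compactness")
}

#' Simulate cross-link observations from a ground truth
#'
#' Emulates cross-linker chemistry and MS detection at the bead level:
#' every pair of lysine-like sites whose ground-truth minimum ambiguous
#' surface distance is at most `d_true` is observed with probability
#' `p_det`; then `ceiling(f_decoy * n_true)` uniformly random site pairs
#' are appended as false positives (mimicking the residual contamination
#' of a 1% FDR dataset).  All records get q-value 0.001 and are
#' order-normalized and deduplicated.  The decoy flag is internal
#' book-keeping for evaluation; [write_crosslink_table()] drops it.
#'
#' @param truth result of [generate_toy_assembly()] (or a list with
#'   `assembly`).
#' @param sites data.frame `protein`, `position`; default
#'   [crosslink_sites()] of the topology.
#' @param d_true maximum observable bead surface distance, A (default 5,
#'   the bead-level analogue of the ~30 A Calpha-Calpha reach of a
#'   DSS-class cross-linker).
#' @param p_det detection probability per eligible pair (default 0.7).
#' @param f_decoy decoy fraction relative to the true records (default 0.01).
#' @param seed RNG seed.
#' @param condition condition tag stored on the records.
#' @return `crosslink_table` data.frame with internal `is_decoy` column.
#' @export
simulate_crosslinks <- function(truth, sites = NULL, d_true = 5, p_det = 0.7,
                                f_decoy = 0.01, seed = 1,
                                condition = "synthetic") {
  assembly <- truth$assembly %||% truth
  if (p_det < 0 || p_det > 1 || f_decoy < 0) stop("invalid simulation parameters")
  sites <- sites %||% crosslink_sites(assembly$topology)
  pr <- combn(nrow(sites), 2)
  d <- vapply(seq_len(ncol(pr)), function(k) {
    min_ambiguous_surface(assembly,
                          sites$protein[pr[1, k]], sites$position[pr[1, k]],
                          sites$protein[pr[2, k]], sites$position[pr[2, k]])
  }, 0)
  eligible <- which(d <= d_true)
  if (length(eligible) == 0) stop("no site pair within d_true: nothing to observe")
  with_seed(seed, {
    keep <- eligible[runif(length(eligible)) < p_det]
    rec <- data.frame(
      protein_a = sites$protein[pr[1, keep]],
      position_a = sites$position[pr[1, keep]],
      protein_b = sites$protein[pr[2, keep]],
      position_b = sites$position[pr[2, keep]],
      q_value = 0.001, condition = condition, is_decoy = FALSE
    )
    n_decoy <- ceiling(f_decoy * nrow(rec))
    if (n_decoy > 0 && nrow(rec) > 0) {
      pool <- setdiff(seq_len(ncol(pr)), keep)
      pick <- pool[ceiling(runif(n_decoy) * length(pool))]
      dec <- data.frame(
        protein_a = sites$protein[pr[1, pick]],
        position_a = sites$position[pr[1, pick]],
        protein_b = sites$protein[pr[2, pick]],
        position_b = sites$position[pr[2, pick]],
        q_value = 0.001, condition = condition, is_decoy = TRUE
      )
      rec <- rbind(rec, dec)
    }
    dedupe_udrs(rec)
  })
}

#' Simulate mono-link observations
#'
#' Each lysine-like site is reported as a mono-link with probability
#' `p_det` (reagent accessibility at the surface is not modelled: the
#' toy beads have no buried/exposed distinction).
#'
#' @inheritParams simulate_crosslinks
#' @export
simulate_monolinks <- function(truth, sites = NULL, p_det = 0.8, seed = 1) {
  assembly <- truth$assembly %||% truth
  sites <- sites %||% crosslink_sites(assembly$topology)
  with_seed(seed, {
    keep <- runif(nrow(sites)) < p_det
    out <- data.frame(protein = sites$protein[keep],
                      position = sites$position[keep], q_value = 0.001)
    rownames(out) <- NULL
    out
  })
}

#' Derive padded bounding boxes from a ground truth
#'
#' Axis-aligned box of each listed component's true copy-0 bead centres,
#' expanded by `pad` on every face — purposefully larger than the truth,
#' like localization boxes drawn generously around EM data.
#'
#' @param truth result of [generate_toy_assembly()].
#' @param pad padding per face, A (>= 0).
#' @param subset component names to box (default: all).
#' @return named list of `list(min =, max =)` boxes.
#' @export
derive_bounding_boxes <- function(truth, pad = 20, subset = NULL) {
  if (pad < 0) stop("pad must be >= 0")
  assembly <- truth$assembly %||% truth
  comps <- subset %||% names(assembly$topology$sequences)
  out <- lapply(comps, function(nm) {
    rows <- assembly$beads$component == nm & assembly$beads$copy == 0L
    xyz <- assembly$xyz[rows, , drop = FALSE]
    list(min = apply(xyz, 2, min) - pad, max = apply(xyz, 2, max) + pad)
  })
  names(out) <- comps
  out
}

#' Plant a docked pose and simulate tubulin cross-links
#'
#' Translates the ground-truth complex so that it rests on top of the
#' lattice patch (above the interior subunits), then records a tubulin
#' cross-link for every complex-side site within `d_true` of an interior
#' tubulin bead, each observed with probability `p_det`.  The planted
#' pose is returned so recovery can be scored.
#'
#' @param truth result of [generate_toy_assembly()].
#' @param lattice a [build_lattice()] result.
#' @param d_true maximum observable surface distance, A (default 5).
#' @param p_det detection probability (default 1).
#' @param seed RNG seed.
#' @param gap resting gap between complex and lattice surface, A.
#' @return list with `assembly` (complex in the planted pose), `xls`
#'   (tubulin cross-link table), `orientation` (planted orientation
#'   report, lattice at identity pose).
#' @export
simulate_tubulin_xls <- function(truth, lattice, d_true = 5, p_det = 1,
                                 seed = 1, gap = 1) {
  assembly <- truth$assembly %||% truth
  # rest the complex on the lattice face (the patch spans x laterally and
  # z axially; its outward normal is +y), centred over the interior subunits
  interior <- lattice$subunits$interior
  int_beads <- lattice$beads$subunit %in% lattice$subunits$subunit[interior]
  top_y <- max(lattice$xyz[int_beads, 2] + lattice$beads$radius[int_beads])
  planted <- assembly
  lo_y <- min(assembly$xyz[, 2] - assembly$beads$radius)
  shift <- c(mean(range(lattice$xyz[int_beads, 1])) - mean(range(assembly$xyz[, 1])),
             top_y + gap - lo_y,
             mean(range(lattice$xyz[int_beads, 3])) - mean(range(assembly$xyz[, 3])))
  planted$xyz <- sweep(assembly$xyz, 2, shift, `+`)
  # lower until the closest complex/interior-bead surface gap equals `gap`
  int_xyz <- lattice$xyz[int_beads, , drop = FALSE]
  int_rad <- lattice$beads$radius[int_beads]
  min_s <- function(xyz) {
    min(cross_dist(xyz, int_xyz) -
        outer(planted$beads$radius, int_rad, `+`))
  }
  for (it in 1:60) {
    s0 <- min_s(planted$xyz)
    if (s0 <= gap + 0.1) break
    dy <- min(0.8 * (s0 - gap), 10)
    planted$xyz[, 2] <- planted$xyz[, 2] - dy
    shift[2] <- shift[2] - dy
  }
  # conjugate the symmetry transform into the planted frame so that
  # copy 1 is still the exact symmetric image of copy 0
  if (planted$topology$copy_count == 2L) {
    sym <- planted$topology$symmetry
    planted$topology$symmetry$t <-
      as.numeric(sym$t + shift - sym$R %*% shift)
  }
  sites <- crosslink_sites(planted$topology)
  recs <- list()
  for (i in seq_len(nrow(sites))) {
    for (cp in seq_len(planted$topology$copy_count) - 1L) {
      r <- bead_row(planted, sites$protein[i], sites$position[i], cp)
      dv <- sweep(lattice$xyz[int_beads, , drop = FALSE], 2, planted$xyz[r, ])
      sdists <- sqrt(rowSums(dv^2)) - planted$beads$radius[r] -
        lattice$beads$radius[int_beads]
      # a reactive site cross-links to every tubulin bead it can reach,
      # like a lysine reporting against several tubulin residues
      for (j in which(sdists <= d_true)) {
        lb <- lattice$beads[int_beads, ][j, ]
        recs[[length(recs) + 1]] <- data.frame(
          protein = sites$protein[i], position = sites$position[i],
          tubulin = lb$isoform,
          tubulin_position = (lb$first_res + lb$last_res) %/% 2
        )
      }
    }
  }
  if (length(recs) == 0) stop("planted pose yields no tubulin cross-links")
  xls <- unique(do.call(rbind, recs))
  xls <- with_seed(seed, xls[runif(nrow(xls)) < p_det, , drop = FALSE])
  if (nrow(xls) == 0) stop("no tubulin cross-link survived detection")
  rownames(xls) <- NULL
  orient <- classify_orientation(planted, lattice,
                                 pose = list(R = diag(3), t = c(0, 0, 0)))
  list(assembly = planted, xls = xls, orientation = orient)
}

#' Write a simulation bundle
#'
#' Emits FASTA sequences, the cross-link and mono-link TSVs and a YAML
#' topology config into a directory, consumable unchanged by the
#' modelling and analysis functions.
#'
#' @param truth result of [generate_toy_assembly()].
#' @param crosslinks,monolinks simulated tables (monolinks optional).
#' @param dir output directory (created if needed).
#' @export
write_simulation_bundle <- function(truth, crosslinks, monolinks = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  topo <- truth$topology %||% truth$assembly$topology
  write_sequences(topo$sequences, file.path(dir, "sequences.fasta"))
  write_crosslink_table(crosslinks, file.path(dir, "crosslinks.tsv"))
  if (!is.null(monolinks)) {
    write.table(monolinks, file.path(dir, "monolinks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_assembly_config(topo, file.path(dir, "config.yaml"))
  invisible(dir)
}
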