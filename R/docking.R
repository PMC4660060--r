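#' Build a coarse-grained tubulin lattice
#'
#' A flat patch of `n_pf` protofilaments by `n_per_pf` monomers, with
#' alpha- and beta-tubulin alternating along each protofilament (alpha at
#' the minus end).  Protofilaments run along +z (the plus-end direction);
#' lateral neighbours are spaced along x.  Each monomer is a bead chain
#' built by [build_beads()] from the supplied sequences, laid out on a
#' compact helix inside the subunit footprint.  Edge subunits are flagged
#' and excluded from restraint ambiguity; a 6 x 6 patch has 36 subunits,
#' 20 edge and 16 interior.  The lattice is rigid: its internal geometry
#' never changes, only its pose.
#'
#' @param alpha_seq,beta_seq tubulin sequences (one-letter) or lengths.
#' @param n_pf protofilaments (default 6).
#' @param n_per_pf monomers per protofilament (default 6).
#' @param lateral_spacing protofilament spacing, A (default 52).
#' @param axial_spacing monomer rise along the protofilament, A (default 40).
#' @param granularity residues per bead (default 10).
#' @return object of class `tubulin_lattice`: `beads` (data.frame with
#'   `subunit`, `pf`, `pos`, `isoform`, `bead`, `first_res`, `last_res`,
#'   `radius`), `xyz` (base coordinates), `subunits` (per-subunit table
#'   with `interior` flag), `axis` (plus-end unit vector) and spacings.
#' @export
build_lattice <- function(alpha_seq, beta_seq, n_pf = 6, n_per_pf = 6,
                          lateral_spacing = 52, axial_spacing = 40,
                          granularity = 10) {
  if (lateral_spacing <= 0 || axial_spacing <= 0) stop("spacings must be positive")
  chains <- list(alpha = build_beads(alpha_seq, granularity),
                 beta = build_beads(beta_seq, granularity))
  subunits <- expand.grid(pf = seq_len(n_pf) - 1L, pos = seq_len(n_per_pf) - 1L)
  subunits <- subunits[order(subunits$pf, subunits$pos), ]
  subunits$subunit <- seq_len(nrow(subunits))
  subunits$isoform <- ifelse(subunits$pos %% 2 == 0, "alpha", "beta")
  subunits$interior <- subunits$pf > 0 & subunits$pf < n_pf - 1 &
    subunits$pos > 0 & subunits$pos < n_per_pf - 1
  rownames(subunits) <- NULL
  bead_list <- list()
  xyz_list <- list()
  for (s in seq_len(nrow(subunits))) {
    iso <- subunits$isoform[s]
    ch <- chains[[iso]]
    nb <- nrow(ch)
    centre <- c(subunits$pf[s] * lateral_spacing, 0,
                subunits$pos[s] * axial_spacing)
    # compact deterministic helix filling the subunit footprint
    r_sub <- bead_radius(sum(ch$n_res)) * 0.55
    ang <- 2.4 * (seq_len(nb) - 1)             # golden-angle-like winding
    zz <- if (nb > 1) seq(-0.35, 0.35, length.out = nb) * axial_spacing else 0
    local <- cbind(r_sub * cos(ang), r_sub * sin(ang), zz)
    b <- ch
    b$subunit <- subunits$subunit[s]
    b$pf <- subunits$pf[s]
    b$pos <- subunits$pos[s]
    b$isoform <- iso
    b$bead <- seq_len(nb) - 1L
    bead_list[[s]] <- b
    xyz_list[[s]] <- sweep(local, 2, centre, `+`)
  }
  beads <- do.call(rbind, bead_list)
  rownames(beads) <- NULL
  structure(
    list(beads = beads[, c("subunit", "pf", "pos", "isoform", "bead",
                           "first_res", "last_res", "n_res", "radius")],
         xyz = do.call(rbind, xyz_list), subunits = subunits,
         axis = c(0, 0, 1), lateral_spacing = lateral_spacing,
         axial_spacing = axial_spacing, granularity = granularity),
    class = "tubulin_lattice"
  )
}

#' @export
print.tubulin_lattice <- function(x, ...) {
  cat("tubulin_lattice:", nrow(x$subunits), "subunits (",
      sum(x$subunits$interior), "interior ),", nrow(x$beads), "beads\n")
  invisible(x)
}

# lattice bead rows (1-based) a tubulin-side residue can map to: the bead
# holding that residue in every *interior* subunit of the matching isoform
# (or of both isoforms when ambiguity is not isoform-restricted)
tubulin_candidate_beads <- function(lattice, isoform, position,
                                    isoform_restricted = TRUE) {
  subs <- lattice$subunits
  ok <- subs$interior & (if (isoform_restricted) subs$isoform == isoform else TRUE)
  if (!any(ok)) {
    stop("no interior ", isoform, "-tubulin subunit available for restraint")
  }
  rows <- integer(0)
  for (s in subs$subunit[ok]) {
    iso_s <- subs$isoform[subs$subunit == s]
    hit <- which(lattice$beads$subunit == s &
                 lattice$beads$first_res <= position &
                 lattice$beads$last_res >= position)
    if (length(hit) == 0) {
      stop("tubulin position ", position, " does not map to a bead of the ",
           iso_s, " chain")
    }
    rows <- c(rows, hit)
  }
  rows
}

lattice_world <- function(lattice, pose) {
  sweep(lattice$xyz %*% t(pose$R), 2, pose$t, `+`)
}

#' Complex-to-tubulin cross-link restraint score
#'
#' Ambiguous upper-bound harmonic between a complex-side bead (either
#' monomer copy) and the bead holding the tubulin-side residue in every
#' interior lattice subunit of the matching isoform; edge subunits are
#' excluded from the ambiguity.  The restraint acts on the smallest of
#' all these surface distances.
#'
#' @param record list/row with `protein`, `position` (complex side) and
#'   `tubulin` ("alpha"/"beta"), `tubulin_position`.
#' @param assembly positioned complex.
#' @param lattice a [build_lattice()] result.
#' @param pose lattice pose, list(R =, t =) (identity by default).
#' @param bound upper bound, A (default 5).
#' @param k spring constant (default 1).
#' @param isoform_restricted restrict ambiguity to subunits of the
#'   record's isoform (default TRUE); FALSE spreads it over both.
#' @export
tubulin_xl_score <- function(record, assembly, lattice,
                             pose = list(R = diag(3), t = c(0, 0, 0)),
                             bound = 5, k = 1, isoform_restricted = TRUE) {
  latW <- lattice_world(lattice, pose)
  cand <- tubulin_candidate_beads(lattice, record$tubulin, record$tubulin_position,
                                  isoform_restricted = isoform_restricted)
  s <- min_tubulin_surface(record, assembly, lattice, latW, cand)
  if (s > bound) k * (s - bound)^2 else 0
}

min_tubulin_surface <- function(record, assembly, lattice, latW, cand) {
  best <- Inf
  for (cp in seq_len(assembly$topology$copy_count) - 1L) {
    r <- bead_row(assembly, record$protein, record$position, cp)
    for (j in cand) {
      best <- min(best, surface_dist(assembly$xyz[r, ], latW[j, ],
                                     assembly$beads$radius[r],
                                     lattice$beads$radius[j]))
    }
  }
  best
}

#' Tubulin cross-link satisfaction of a docked model
#'
#' @param assembly docked complex.
#' @param lattice lattice.
#' @param pose lattice pose.
#' @param tubulin_xls data.frame of tubulin cross-link records.
#' @param cutoff satisfaction cutoff, A (default 10).
#' @param isoform_restricted see [tubulin_xl_score()].
#' @return list with `distance` per record and `fraction`.
#' @export
tubulin_xl_satisfaction <- function(assembly, lattice, pose, tubulin_xls,
                                    cutoff = 10, isoform_restricted = TRUE) {
  latW <- lattice_world(lattice, pose)
  d <- vapply(seq_len(nrow(tubulin_xls)), function(i) {
    rec <- tubulin_xls[i, ]
    cand <- tubulin_candidate_beads(lattice, rec$tubulin, rec$tubulin_position,
                                    isoform_restricted = isoform_restricted)
    min_tubulin_surface(rec, assembly, lattice, latW, cand)
  }, 0)
  list(distance = d, fraction = mean(d <= cutoff), cutoff = cutoff)
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w * w + x * x - y * y - z * z, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w * w - x * x + y * y - z * z, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w * w - x * x - y * y + z * z
  ), 3, 3, byrow = TRUE)
}

#' Flexible docking onto the tubulin lattice
#'
#' Two-stage restraint-guided docking.  Stage 1 keeps the dimer symmetry
#' constraint and treats the lattice as one rigid body, initialized in a
#' random orientation at `init_dist` from the complex centre (1000 A, i.e.
#' 100 nm, by default); per-bead complex moves and rigid lattice moves
#' (translation up to `lat_max_trans`, rotation up to `lat_max_rot`) are
#' sampled under the combined score: all free-complex restraints plus the
#' ambiguous tubulin cross-links and complex-lattice excluded volume.
#' Stage 2 continues from the best stage-1 state with the symmetry
#' constraint released, so the relative orientation of the two monomers
#' can relax.
#'
#' @param model positioned `bead_assembly` (e.g. the cluster-centre model
#'   from free-complex sampling).
#' @param lattice a [build_lattice()] result.
#' @param tubulin_xls data.frame with columns `protein`, `position`,
#'   `tubulin`, `tubulin_position`.
#' @param restraints the free-complex [restraint_set()].
#' @param config a [sampler_config()]; `n_steps` applies per stage.
#' @param stage2 run the symmetry-released second stage (default TRUE).
#' @param init_dist initial lattice distance from the complex centre, A.
#' @param tubulin_bound,tubulin_k tubulin restraint parameters (5 A, 1.0).
#' @param isoform_restricted see [tubulin_xl_score()].
#' @param lat_max_trans,lat_max_rot lattice move sizes (2 A, 2 degrees).
#' @param lat_move_prob probability of proposing a rigid lattice move
#'   instead of a bead move (default: one lattice move per sweep over the
#'   movable beads, i.e. `1 / (n_beads + 1)`).  Larger values speed up the
#'   long-range approach and re-registration of the lattice.
#' @param satisfaction_cutoff fit cutoff for reporting, A (default 10).
#' @return object of class `docking_result`: best docked `assembly`,
#'   lattice `pose`, per-stage ensembles, tubulin-XL `satisfaction`, and
#'   the [classify_orientation()] report.
#' @export
dock_flexible <- function(model, lattice, tubulin_xls, restraints, config,
                          stage2 = TRUE, init_dist = 1000,
                          tubulin_bound = 5, tubulin_k = 1,
                          isoform_restricted = TRUE,
                          lat_max_trans = 2, lat_max_rot = 2,
                          lat_move_prob = NULL,
                          satisfaction_cutoff = 10) {
  stopifnot(inherits(model, "bead_assembly"))
  if (anyNA(model$xyz)) stop("model must be positioned before docking")
  pose0 <- with_seed(config$seed, {
    R0 <- random_rotation()
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    centre <- colMeans(model$xyz)
    list(R = R0, t = centre + init_dist * u -
           as.numeric(R0 %*% colMeans(lattice$xyz)))
  })
  sys1 <- build_system(model, restraints, sym_on = model$topology$copy_count == 2L,
                       lattice = lattice, tubulin_xls = tubulin_xls,
                       tubulin_bound = tubulin_bound, tubulin_k = tubulin_k,
                       isoform_restricted = isoform_restricted,
                       lat_max_trans = lat_max_trans, lat_max_rot = lat_max_rot)
  res1 <- pt_engine(model, restraints, config, sys1, lat_mobile = TRUE,
                    latR = pose0$R, latT = pose0$t,
                    lat_move_prob = lat_move_prob)
  stage1 <- list(scores = as.numeric(res1$scores), snapshots = res1$snapshots,
                 poses = res1$poses)
  best <- model
  best$xyz <- res1$snapshots[[1]]
  dimnames(best$xyz) <- dimnames(model$xyz)
  pose <- res1$poses[[1]]
  stage2_out <- NULL
  if (stage2 && model$topology$copy_count == 2L) {
    cfg2 <- config
    cfg2$seed <- config$seed + 1L
    sys2 <- build_system(model, restraints, sym_on = FALSE,
                         lattice = lattice, tubulin_xls = tubulin_xls,
                         tubulin_bound = tubulin_bound, tubulin_k = tubulin_k,
                         isoform_restricted = isoform_restricted,
                         lat_max_trans = lat_max_trans, lat_max_rot = lat_max_rot)
    res2 <- pt_engine(best, restraints, cfg2, sys2, lat_mobile = TRUE,
                      latR = pose$R, latT = pose$t,
                      lat_move_prob = lat_move_prob)
    stage2_out <- list(scores = as.numeric(res2$scores),
                       snapshots = res2$snapshots, poses = res2$poses)
    best$xyz <- res2$snapshots[[1]]
    dimnames(best$xyz) <- dimnames(model$xyz)
    pose <- res2$poses[[1]]
  }
  sat <- tubulin_xl_satisfaction(best, lattice, pose, tubulin_xls,
                                 cutoff = satisfaction_cutoff,
                                 isoform_restricted = isoform_restricted)
  orient <- classify_orientation(best, lattice, pose)
  structure(
    list(assembly = best, pose = pose, stage1 = stage1, stage2 = stage2_out,
         satisfaction = sat, orientation = orient),
    class = "docking_result"
  )
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("docking_result: tubulin-XL satisfaction %.0f%%, axis angle %.1f deg (%s)\n",
              100 * x$satisfaction$fraction, x$orientation$angle,
              x$orientation$class))
  invisible(x)
}

#' Classify the orientation of a docked complex
#'
#' Angle between the complex's principal axis (largest-variance direction
#' of its bead centres) and the protofilament axis, folded into
#' `[0, 90]` degrees; class "parallel" below 45 degrees, "perpendicular"
#' at or above (perpendicular is the ring-compatible arrangement).  Each
#' labelled terminus bead is classified plus- or minus-end facing by the
#' sign of its axial coordinate relative to the complex centroid.
#'
#' @param assembly docked complex.
#' @param lattice the lattice (supplies the protofilament axis).
#' @param pose lattice pose.
#' @param termini data.frame with `component`, `residue` naming the
#'   labelled beads; default: the C-terminal residue of every component.
#' @return list with `angle` (degrees, NA when the bead cloud is
#'   isotropic), `class`, and `termini` (data.frame with signed `axial`
#'   offset and `facing`).
#' @export
classify_orientation <- function(assembly, lattice, pose,
                                 termini = NULL) {
  axis <- as.numeric(pose$R %*% lattice$axis)
  axis <- axis / sqrt(sum(axis^2))
  pc <- prcomp(assembly$xyz, center = TRUE)
  ev <- pc$sdev^2
  angle <- if (ev[1] < 1e-12 || (ev[2] / ev[1]) > 0.99) NA_real_ else {
    v <- pc$rotation[, 1]
    acos(min(1, abs(sum(v * axis)))) * 180 / pi
  }
  cls <- if (is.na(angle)) "undefined" else if (angle < 45) "parallel" else "perpendicular"
  if (is.null(termini)) {
    termini <- data.frame(
      component = names(assembly$topology$sequences),
      residue = nchar(assembly$topology$sequences)
    )
  }
  centroid <- colMeans(assembly$xyz)
  rows <- do.call(rbind, lapply(seq_len(nrow(termini)), function(i) {
    comp <- termini$component[i]
    res <- termini$residue[i]
    do.call(rbind, lapply(seq_len(assembly$topology$copy_count) - 1L, function(cp) {
      r <- bead_row(assembly, comp, res, cp)
      ax <- sum((assembly$xyz[r, ] - centroid) * axis)
      data.frame(component = comp, residue = res, copy = cp, axial = ax,
                 facing = ifelse(ax > 0, "plus", "minus"))
    }))
  }))
  rownames(rows) <- NULL
  list(angle = angle, class = cls, axis = axis, termini = rows)
}

#' Read a tubulin cross-link table
#'
#' TSV with columns `protein`, `position`, `tubulin` ("alpha"/"beta"),
#' `tubulin_position`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_tubulin_xl_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "position", "tubulin", "tubulin_position")
  if (!all(need %in% names(df))) {
    stop("tubulin cross-link table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$tubulin %in% c("alpha", "beta"))) {
    stop("tubulin column must be 'alpha' or 'beta'")
  }
  df
}
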