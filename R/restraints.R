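#' Restraint terms and the total scoring function
#'
#' All terms act on bead *surface* distances
#' `s(i, j) = ||c_i - c_j|| - r_i - r_j` (negative when beads overlap) and
#' are non-negative harmonic penalties in kT units:
#'
#' * connectivity: `k * s^2` for sequence-adjacent beads when `s > 0`
#'   (gap-only; overlap between neighbours is handled by excluded volume);
#' * excluded volume: `k * s^2` for non-adjacent pairs when `s < 0`;
#' * cross-link: `k * (s* - bound)^2` when the minimum ambiguous surface
#'   distance `s*` (over intra- and inter-copy endpoint assignments)
#'   exceeds `bound`;
#' * localization: `k * d^2` where `d` is the Euclidean distance from the
#'   bead centre to its component's bounding box (0 inside);
#' * subcomplex connectivity: for each group member, `k * g^2` where `g`
#'   is its smallest surface distance to any other group member (0 when
#'   touching).
#'
#' @name restraint-terms
NULL

surface_dist <- function(xa, xb, ra, rb) {
  sqrt(sum((xa - xb)^2)) - ra - rb
}

# sequence adjacency matrix helper: TRUE for rows in the same chain instance
# with consecutive bead offsets
adjacent_pairs <- function(beads) {
  ord <- order(beads$chain, beads$bead)
  rows <- ord[-length(ord)]
  nxt <- ord[-1]
  keep <- beads$chain[rows] == beads$chain[nxt] &
    beads$bead[nxt] == beads$bead[rows] + 1L
  cbind(rows[keep], nxt[keep])
}

#' Chain connectivity score
#'
#' Sum over sequence-adjacent bead pairs (within every chain instance of
#' the assembly) of `k * s^2` for positive surface gaps `s`.
#'
#' @param assembly a positioned [build_assembly()] object.
#' @param k spring constant (default 1).
#' @return non-negative energy.
#' @export
connectivity_score <- function(assembly, k = 1) {
  ap <- adjacent_pairs(assembly$beads)
  if (nrow(ap) == 0) return(0)
  d <- sqrt(rowSums((assembly$xyz[ap[, 1], , drop = FALSE] -
                     assembly$xyz[ap[, 2], , drop = FALSE])^2))
  s <- d - assembly$beads$radius[ap[, 1]] - assembly$beads$radius[ap[, 2]]
  sum(k * pmax(s, 0)^2)
}

#' Excluded volume score
#'
#' Soft steric penalty `k * s^2` over every non-sequence-adjacent bead
#' pair with overlapping surfaces (`s < 0`).  Sequence-adjacent pairs are
#' governed by connectivity and skipped.
#'
#' @inheritParams connectivity_score
#' @param k intensity (default 1).
#' @export
excluded_volume_score <- function(assembly, k = 1) {
  n <- nrow(assembly$beads)
  if (n < 2) return(0)
  d <- as.matrix(dist(assembly$xyz))
  s <- d - outer(assembly$beads$radius, assembly$beads$radius, `+`)
  ap <- adjacent_pairs(assembly$beads)
  skip <- matrix(FALSE, n, n)
  skip[ap] <- TRUE
  skip[ap[, 2:1, drop = FALSE]] <- TRUE
  pen <- (s < 0 & !skip & upper.tri(s)) * pmin(s, 0)^2
  k * sum(pen)
}

# minimum ambiguous surface distance for one residue pair: over intra-copy
# and inter-copy assignments of the two endpoints
min_ambiguous_surface <- function(assembly, protein_a, position_a,
                                  protein_b, position_b) {
  ncopy <- assembly$topology$copy_count
  ra <- vapply(seq_len(ncopy) - 1L, function(cp) bead_row(assembly, protein_a, position_a, cp), 0L)
  rb <- vapply(seq_len(ncopy) - 1L, function(cp) bead_row(assembly, protein_b, position_b, cp), 0L)
  combos <- expand.grid(a = ra, b = rb)
  combos <- combos[combos$a != combos$b, , drop = FALSE]
  if (nrow(combos) == 0) return(-2 * assembly$beads$radius[ra[1]])
  min(vapply(seq_len(nrow(combos)), function(i) {
    surface_dist(assembly$xyz[combos$a[i], ], assembly$xyz[combos$b[i], ],
                 assembly$beads$radius[combos$a[i]], assembly$beads$radius[combos$b[i]])
  }, 0))
}

#' Ambiguous cross-link restraint score
#'
#' Upper-bound harmonic on the minimum surface distance `s*` over all
#' endpoint-to-copy assignments (intra-copy and inter-copy): the restraint
#' never chooses an assignment a priori, it is always applied to the
#' smallest distance.
#'
#' @param udr one cross-link record: list/row with `protein_a`,
#'   `position_a`, `protein_b`, `position_b`.
#' @param assembly positioned assembly.
#' @param bound upper bound in Angstrom (default 5).
#' @param k spring constant (default 1).
#' @export
crosslink_score <- function(udr, assembly, bound = 5, k = 1) {
  s <- min_ambiguous_surface(assembly, udr$protein_a, udr$position_a,
                             udr$protein_b, udr$position_b)
  if (s > bound) k * (s - bound)^2 else 0
}

# distance from a point to an axis-aligned box (0 inside)
point_box_distance <- function(x, box) {
  dv <- pmax(box$min - x, 0, x - box$max)
  sqrt(sum(dv^2))
}

#' Localization (bounding-box) score
#'
#' Harmonic penalty on the distance between a bead centre and the wall of
#' its bounding box, acting only when the bead has exited the box.  A bead
#' may leave its box by any amount provided the violation is paid for in
#' score.
#'
#' @param centre length-3 bead centre.
#' @param box list(min =, max =) corners.
#' @param k spring constant.
#' @export
localization_score <- function(centre, box, k = 1) {
  if (any(box$min >= box$max)) stop("malformed box (min must be < max)")
  k * point_box_distance(centre, box)^2
}

# total localization energy of an assembly: copy-0 beads against their
# component's box directly, copy-1 beads through the inverse symmetry
# transform (distance to the copy-0 box evaluated in the copy-0 frame)
localization_total <- function(assembly, boxes, k = 1) {
  if (length(boxes) == 0) return(0)
  sym <- assembly$topology$symmetry
  total <- 0
  for (i in seq_len(nrow(assembly$beads))) {
    nm <- assembly$beads$component[i]
    if (!nm %in% names(boxes)) next
    x <- assembly$xyz[i, ]
    if (assembly$beads$copy[i] == 1L) x <- drop(t(sym$R) %*% (x - sym$t))
    total <- total + k * point_box_distance(x, boxes[[nm]])^2
  }
  total
}

#' Subcomplex connectivity score
#'
#' Encodes the biochemical requirement that each member of a group be in
#' contact with at least one other member: per member, the smallest bead
#' surface distance `g` to any other member contributes `k * g^2` when
#' positive.  Evaluated per copy.
#'
#' @param group character vector of component names (>= 2).
#' @param assembly positioned assembly.
#' @param k spring constant.
#' @export
subcomplex_score <- function(group, assembly, k = 1) {
  if (length(group) < 2) stop("subcomplex group needs >= 2 members")
  total <- 0
  for (cp in seq_len(assembly$topology$copy_count) - 1L) {
    for (a in group) {
      rows_a <- which(assembly$beads$component == a & assembly$beads$copy == cp)
      g <- Inf
      for (b in setdiff(group, a)) {
        rows_b <- which(assembly$beads$component == b & assembly$beads$copy == cp)
        for (i in rows_a) for (j in rows_b) {
          g <- min(g, surface_dist(assembly$xyz[i, ], assembly$xyz[j, ],
                                   assembly$beads$radius[i], assembly$beads$radius[j]))
        }
      }
      if (is.finite(g) && g > 0) total <- total + k * g^2
    }
  }
  total
}

#' Apply the dimer symmetry constraint
#'
#' Maps copy-0 coordinates onto copy 1 through the topology's rigid
#' transform.  Copy 1 carries no independent degrees of freedom while the
#' constraint is enabled.
#'
#' @param xyz0 n x 3 matrix of copy-0 centres.
#' @param symmetry list(R =, t =) proper rigid transform.
#' @return n x 3 matrix of copy-1 centres.
#' @export
apply_symmetry <- function(xyz0, symmetry) {
  check_rigid_transform(symmetry)
  sweep(xyz0 %*% t(symmetry$R), 2, symmetry$t, `+`)
}

#' Restraint set
#'
#' The full scoring function: parameters of every term plus the attached
#' cross-link table, boxes (taken from the topology unless overridden) and
#' subcomplex groups.
#'
#' @param topology an [assembly_topology()].
#' @param crosslinks data.frame of unique distance restraints (UDRs) with
#'   columns `protein_a`, `position_a`, `protein_b`, `position_b`
#'   (e.g. from [read_crosslink_table()] or [simulate_crosslinks()]).
#' @param connectivity_k,excluded_volume_k,box_k,subcomplex_k,xl_k spring
#'   constants / intensity, all defaulting to 1.0.
#' @param xl_upper_bound cross-link surface-distance bound, default 5 A.
#' @param boxes optional override of the topology's bounding boxes.
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(topology, crosslinks = NULL,
                          connectivity_k = 1, excluded_volume_k = 1,
                          xl_upper_bound = 5, xl_k = 1,
                          box_k = 1, subcomplex_k = 1, boxes = NULL) {
  stopifnot(inherits(topology, "assembly_topology"))
  ks <- c(connectivity_k, excluded_volume_k, xl_k, box_k, subcomplex_k)
  if (any(ks < 0)) stop("spring constants must be >= 0")
  if (xl_upper_bound <= 0) stop("xl_upper_bound must be > 0")
  if (!is.null(crosslinks) && nrow(crosslinks) > 0) {
    for (p in unique(c(crosslinks$protein_a, crosslinks$protein_b))) {
      if (!p %in% names(topology$sequences)) {
        stop("cross-link references unknown protein '", p, "'")
      }
    }
  }
  structure(
    list(
      topology = topology, crosslinks = crosslinks,
      connectivity_k = connectivity_k, excluded_volume_k = excluded_volume_k,
      xl_upper_bound = xl_upper_bound, xl_k = xl_k,
      box_k = box_k, subcomplex_k = subcomplex_k,
      boxes = boxes %||% topology$boxes,
      subcomplex_groups = topology$subcomplex_groups
    ),
    class = "restraint_set"
  )
}

#' Total score with per-term breakdown
#'
#' Pure function of the coordinates: sums connectivity, excluded volume,
#' cross-link, localization and subcomplex terms.  Distances only, so the
#' total is invariant under global rigid motion whenever no bounding boxes
#' are active.
#'
#' @param assembly positioned assembly (symmetry already applied).
#' @param restraints a [restraint_set()].
#' @return object of class `score_breakdown`: named list of per-term
#'   totals plus `total`.
#' @export
total_score <- function(assembly, restraints) {
  stopifnot(inherits(restraints, "restraint_set"))
  xl <- 0
  if (!is.null(restraints$crosslinks) && nrow(restraints$crosslinks) > 0) {
    for (i in seq_len(nrow(restraints$crosslinks))) {
      xl <- xl + crosslink_score(restraints$crosslinks[i, ], assembly,
                                 bound = restraints$xl_upper_bound,
                                 k = restraints$xl_k)
    }
  }
  sub <- 0
  for (g in restraints$subcomplex_groups) {
    sub <- sub + subcomplex_score(g, assembly, k = restraints$subcomplex_k)
  }
  out <- list(
    connectivity = connectivity_score(assembly, restraints$connectivity_k),
    excluded_volume = excluded_volume_score(assembly, restraints$excluded_volume_k),
    crosslink = xl,
    box = localization_total(assembly, restraints$boxes, restraints$box_k),
    subcomplex = sub
  )
  out$total <- sum(unlist(out))
  structure(out, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("score breakdown (kT):\n")
  for (nm in setdiff(names(x), "total")) {
    cat(sprintf("  %-16s %12.6f\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-16s %12.6f\n", "total", x$total))
  invisible(x)
}
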