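#' Pairwise RMSD matrix over an ensemble
#'
#' Bead-centre RMSD after optimal least-squares rigid superposition over
#' all beads (no chain relabelling: the symmetric copy is a constraint,
#' not a free permutation).  Invariant to global rigid motion of either
#' structure.
#'
#' @param ensemble an `xl_ensemble` or a list of coordinate matrices.
#' @return symmetric matrix of RMSDs in Angstrom.
#' @export
pairwise_rmsd <- function(ensemble) {
  models <- if (inherits(ensemble, "xl_ensemble")) ensemble$models else ensemble
  .pairwise_rmsd_cpp(models)
}

#' Greedy neighbour-count (Daura) clustering
#'
#' Iteratively selects the structure with the most neighbours within
#' `cutoff` RMSD, forms a cluster from it and its neighbours, removes
#' them, and repeats until all structures are assigned.  Ties are broken
#' by lowest score, then lowest index.  The cluster centre is the
#' selected (most-neighboured) member.
#'
#' @param ensemble an `xl_ensemble`, or a list of coordinate matrices.
#' @param cutoff neighbour cutoff in Angstrom (default 17, i.e. 1.7 nm).
#' @param rmsd optional precomputed RMSD matrix.
#' @param scores optional score vector for tie-breaking (taken from the
#'   ensemble when available; defaults to zero).
#' @return object of class `cluster_result`: `membership` (integer vector,
#'   1 = largest-neighbourhood cluster found first), `centres` (index of
#'   each cluster's centre model), `cutoff`.
#' @export
daura_cluster <- function(ensemble, cutoff = 17, rmsd = NULL, scores = NULL) {
  models <- if (inherits(ensemble, "xl_ensemble")) ensemble$models else ensemble
  if (length(models) == 0) stop("ensemble is empty")
  if (is.null(scores)) {
    scores <- if (inherits(ensemble, "xl_ensemble")) ensemble$scores else rep(0, length(models))
  }
  D <- rmsd %||% .pairwise_rmsd_cpp(models)
  n <- length(models)
  membership <- rep(NA_integer_, n)
  centres <- integer(0)
  remaining <- rep(TRUE, n)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    counts <- vapply(idx, function(i) sum(D[i, idx] <= cutoff), 0L) # self included
    best <- idx[order(-counts, scores[idx], idx)][1]
    members <- idx[D[best, idx] <= cutoff]
    membership[members] <- cl
    centres <- c(centres, best)
    remaining[members] <- FALSE
  }
  structure(list(membership = membership, centres = centres, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- table(x$membership)
  cat("cluster_result:", length(x$centres), "clusters at cutoff",
      x$cutoff, "A; sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Per-bead localization probability density
#'
#' Superposes every model of the ensemble onto a reference (by default
#' the centre of the top cluster), then histograms each bead's centre on
#' a common 3D grid.  Each bead's voxel values are normalized to sum to 1,
#' expressing the probability that a region of space is occupied by that
#' bead across the ensemble.
#'
#' @param ensemble an `xl_ensemble` or list of coordinate matrices.
#' @param bin grid spacing in Angstrom (default 2).
#' @param reference reference coordinate matrix for superposition; by
#'   default the top-cluster centre from [daura_cluster()].
#' @param align superpose models onto the reference first (default TRUE).
#' @return object of class `density_map`: sparse data.frame `voxels`
#'   (`bead`, `ix`, `iy`, `iz`, `p`), plus `origin`, `bin`, `dim`,
#'   `n_beads`, `n_models`.
#' @export
compute_density <- function(ensemble, bin = 2, reference = NULL, align = TRUE) {
  models <- if (inherits(ensemble, "xl_ensemble")) ensemble$models else ensemble
  if (length(models) == 0) stop("ensemble is empty")
  if (is.null(reference)) {
    cl <- daura_cluster(ensemble)
    reference <- models[[cl$centres[1]]]
  }
  if (align) models <- lapply(models, function(m) .superpose_cpp(reference, m))
  all_xyz <- do.call(rbind, models)
  origin <- floor(apply(all_xyz, 2, min) / bin) * bin
  n_beads <- nrow(models[[1]])
  n_models <- length(models)
  ix <- matrix(0L, n_models * n_beads, 3)
  for (k in 1:3) ix[, k] <- as.integer(floor((all_xyz[, k] - origin[k]) / bin))
  bead <- rep(seq_len(n_beads), times = n_models)
  key <- paste(bead, ix[, 1], ix[, 2], ix[, 3], sep = ":")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  voxels <- data.frame(
    bead = as.integer(parts[, 1]),
    ix = as.integer(parts[, 2]), iy = as.integer(parts[, 3]),
    iz = as.integer(parts[, 4]),
    p = as.numeric(tab) / n_models
  )
  voxels <- voxels[order(voxels$bead, voxels$ix, voxels$iy, voxels$iz), ]
  rownames(voxels) <- NULL
  structure(
    list(voxels = voxels, origin = origin, bin = bin,
         dim = apply(ix, 2, max) + 1L, n_beads = n_beads, n_models = n_models),
    class = "density_map"
  )
}

# centre of a voxel in Angstrom
voxel_centres <- function(map, vox) {
  cbind(map$origin[1] + (vox$ix + 0.5) * map$bin,
        map$origin[2] + (vox$iy + 0.5) * map$bin,
        map$origin[3] + (vox$iz + 0.5) * map$bin)
}

#' Bead variability at half-maximum
#'
#' For each bead, the extent of its density at half-maximal height: the
#' maximum distance between centres of voxels whose probability is at
#' least half that bead's maximum (a diameter; 0 for a single voxel).
#' Reports the per-bead extents and the fraction of beads whose extent is
#' at or below `threshold` (3 A by default).
#'
#' @param map a [compute_density()] result.
#' @param threshold tight-localization threshold in Angstrom (default 3).
#' @return list with `extent` (numeric vector per bead), `fraction_within`
#'   (share of beads with extent <= threshold) and `threshold`.
#' @export
bead_variability <- function(map, threshold = 3) {
  stopifnot(inherits(map, "density_map"))
  extent <- vapply(seq_len(map$n_beads), function(b) {
    vox <- map$voxels[map$voxels$bead == b, ]
    vox <- vox[vox$p >= max(vox$p) / 2, ]
    if (nrow(vox) <= 1) return(0)
    xyz <- voxel_centres(map, vox)
    max(dist(xyz))
  }, 0)
  list(extent = extent, fraction_within = mean(extent <= threshold),
       threshold = threshold)
}

#' Cross-link satisfaction of a model
#'
#' A restraint counts as a fit when the minimum ambiguous surface
#' distance between the beads holding its two residues is within
#' `cutoff` (10 A by default).
#'
#' @param assembly positioned `bead_assembly`.
#' @param udrs data.frame of unique distance restraints.
#' @param cutoff satisfaction cutoff in Angstrom (default 10).
#' @return object of class `satisfaction_report`: `satisfied` (logical per
#'   UDR), `distance` (minimum ambiguous surface distance), `fraction`,
#'   `cutoff`.
#' @export
satisfaction_fraction <- function(assembly, udrs, cutoff = 10) {
  if (is.null(udrs) || nrow(udrs) == 0) {
    stop("empty UDR set: satisfaction fraction is undefined")
  }
  dists <- vapply(seq_len(nrow(udrs)), function(i) {
    min_ambiguous_surface(assembly, udrs$protein_a[i], udrs$position_a[i],
                          udrs$protein_b[i], udrs$position_b[i])
  }, 0)
  satisfied <- dists <= cutoff
  structure(list(satisfied = satisfied, distance = dists,
                 fraction = mean(satisfied), cutoff = cutoff),
            class = "satisfaction_report")
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat(sprintf("satisfaction: %d/%d UDRs (%.1f%%) within %g A\n",
              sum(x$satisfied), length(x$satisfied), 100 * x$fraction, x$cutoff))
  invisible(x)
}

#' Macro-region partition of sequences
#'
#' Divides each protein into consecutive regions of roughly
#' `target_size` residues for coarse interaction accounting.  A protein
#' of length L gets `max(1, round(L / target_size))` regions of near-equal
#' size (a 292-residue protein gives 97 + 97 + 98).  Labels are N/M/C
#' (N, M1..Mk, C for more than three); proteins that fit in one region
#' keep the bare protein name.
#'
#' @param sequences named character vector of sequences (or named integer
#'   lengths).
#' @param target_size target residues per macro-region (default 100).
#' @return data.frame: `component`, `label`, `first_res`, `last_res`.
#' @export
macro_regions <- function(sequences, target_size = 100) {
  lens <- if (is.character(sequences)) nchar(sequences) else sequences
  out <- lapply(names(lens), function(nm) {
    len <- lens[[nm]]
    k <- max(1L, as.integer(round(len / target_size)))
    bounds <- floor(seq(0, len, length.out = k + 1))  # remainder to the C region
    labels <- if (k == 1) nm else if (k == 2) paste0(nm, c("N", "C"))
      else paste0(nm, c("N", if (k > 3) paste0("M", seq_len(k - 2)) else "M", "C"))
    data.frame(component = nm, label = labels,
               first_res = bounds[-(k + 1)] + 1L, last_res = bounds[-1])
  })
  do.call(rbind, out)
}

region_of <- function(regions, component, residue) {
  hit <- regions$component == component &
    regions$first_res <= residue & regions$last_res >= residue
  regions$label[which(hit)[1]]
}

#' Bead-level contact map
#'
#' Two beads are in contact when their surface distance is at or below
#' `cutoff` (default 5 A, the cross-link restraint bound).  Sequence
#' adjacent bead pairs are excluded (they touch by construction).
#' Contacts are reported at bead level and aggregated per protein pair
#' and per macro-region pair, split intra-monomer vs inter-monomer.
#'
#' @param assembly positioned `bead_assembly`.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @param regions macro-region table from [macro_regions()]; computed from
#'   the topology by default.
#' @return object of class `contact_map` with data.frames `bead_pairs`,
#'   `protein_pairs` and `region_pairs` (columns `intra`, `inter` hold
#'   counts) plus the region table.
#' @export
contact_map <- function(assembly, cutoff = 5, regions = NULL) {
  beads <- assembly$beads
  n <- nrow(beads)
  regions <- regions %||% macro_regions(assembly$topology$sequences)
  d <- as.matrix(dist(assembly$xyz))
  s <- d - outer(beads$radius, beads$radius, `+`)
  ap <- adjacent_pairs(beads)
  skip <- matrix(FALSE, n, n)
  skip[ap] <- TRUE
  skip[ap[, 2:1, drop = FALSE]] <- TRUE
  hit <- which(s <= cutoff & !skip & upper.tri(s), arr.ind = TRUE)
  if (nrow(hit) == 0) {
    bead_pairs <- data.frame(i = integer(0), j = integer(0),
                             surface_distance = numeric(0), inter = logical(0))
  } else {
    bead_pairs <- data.frame(
      i = hit[, 1], j = hit[, 2],
      surface_distance = s[hit],
      inter = beads$copy[hit[, 1]] != beads$copy[hit[, 2]]
    )
  }
  mid_res <- function(r) (beads$first_res[r] + beads$last_res[r]) %/% 2
  lab <- vapply(seq_len(n), function(r) {
    region_of(regions, beads$component[r], mid_res(r))
  }, "")
  agg <- function(keys_i, keys_j) {
    a <- pmin(keys_i, keys_j)
    b <- pmax(keys_i, keys_j)
    df <- data.frame(a = a, b = b, inter = bead_pairs$inter)
    if (nrow(df) == 0) {
      return(data.frame(a = character(0), b = character(0),
                        intra = integer(0), inter = integer(0)))
    }
    tab <- stats::aggregate(cbind(intra = !df$inter, inter = df$inter),
                            by = list(a = df$a, b = df$b), FUN = sum)
    tab$intra <- as.integer(tab$intra)
    tab$inter <- as.integer(tab$inter)
    tab
  }
  protein_pairs <- agg(beads$component[bead_pairs$i], beads$component[bead_pairs$j])
  names(protein_pairs)[1:2] <- c("protein_a", "protein_b")
  region_pairs <- agg(lab[bead_pairs$i], lab[bead_pairs$j])
  names(region_pairs)[1:2] <- c("region_a", "region_b")
  structure(
    list(bead_pairs = bead_pairs, protein_pairs = protein_pairs,
         region_pairs = region_pairs, regions = regions, cutoff = cutoff,
         topology_signature = topology_signature(assembly$topology)),
    class = "contact_map"
  )
}

topology_signature <- function(topology) {
  paste(names(topology$sequences), nchar(topology$sequences),
        topology$granularity, topology$copy_count, collapse = ";")
}

#' Compare macro-region interactions between two conditions
#'
#' Classifies every macro-region pair as shared, gained or lost between
#' contact maps A (reference) and B, using presence (count > 0) of any
#' bead contact.  Both maps must come from the same topology and region
#' partition.
#'
#' @param mapA,mapB [contact_map()] results on identical topologies.
#' @return data.frame: `region_a`, `region_b`, `count_a`, `count_b`,
#'   `status` in {"shared", "lost", "gained"} (relative to A -> B).
#' @export
macro_region_compare <- function(mapA, mapB) {
  stopifnot(inherits(mapA, "contact_map"), inherits(mapB, "contact_map"))
  if (!identical(mapA$topology_signature, mapB$topology_signature)) {
    stop("contact maps were built on different topologies")
  }
  key <- function(m) paste(m$region_pairs$region_a, m$region_pairs$region_b, sep = "|")
  tot <- function(m) m$region_pairs$intra + m$region_pairs$inter
  all_keys <- union(key(mapA), key(mapB))
  ca <- setNames(tot(mapA), key(mapA))[all_keys]
  cb <- setNames(tot(mapB), key(mapB))[all_keys]
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L
  parts <- do.call(rbind, strsplit(all_keys, "|", fixed = TRUE))
  status <- ifelse(ca > 0 & cb > 0, "shared", ifelse(ca > 0, "lost", "gained"))
  out <- data.frame(region_a = parts[, 1], region_b = parts[, 2],
                    count_a = as.integer(ca), count_b = as.integer(cb),
                    status = status)
  rownames(out) <- NULL
  out
}

# bead-pair contact identity set of a model (for jackknife conservation)
contact_keys <- function(assembly, cutoff = 5) {
  cm <- contact_map(assembly, cutoff = cutoff)
  bp <- cm$bead_pairs
  paste(bp$i, bp$j, sep = "-")
}

#' Jackknife validation by restraint subsampling
#'
#' Remodels the assembly with random subsets of the cross-link data
#' (`fraction` of the UDRs, drawn without replacement) and measures how
#' many of the full-data model's bead-pair contacts each subset model
#' conserves.  Subset runs reuse the full run's sampling seed, so
#' `fraction = 1` reproduces the full model exactly (conservation 1).
#'
#' @param topology an [assembly_topology()].
#' @param restraints full-data [restraint_set()].
#' @param config a [sampler_config()] (its seed drives the sampling; the
#'   subset draws use `seed + subset index` on a separate stream).
#' @param fraction fraction of UDRs per subset, in (0, 1] (default 0.95).
#' @param n_subsets number of subsets (default 3).
#' @param seed RNG seed for the subset draws (default: config seed).
#' @param contact_cutoff contact definition, A (default 5).
#' @param cluster_cutoff Daura cutoff for picking centre models (default 17).
#' @return object of class `jackknife_report`: `conserved` (fraction per
#'   subset), `subset_sizes`, `fraction`, `n_subsets`.
#' @export
jackknife_validate <- function(topology, restraints, config, fraction = 0.95,
                               n_subsets = 3, seed = NULL,
                               contact_cutoff = 5, cluster_cutoff = 17) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  seed <- seed %||% config$seed
  udrs <- restraints$crosslinks
  if (is.null(udrs) || nrow(udrs) == 0) stop("restraint set has no cross-links")
  centre_model <- function(rs) {
    ens <- run_sampling(topology, rs, config)
    cl <- daura_cluster(ens, cutoff = cluster_cutoff)
    asm <- ens$assembly
    asm$xyz <- ens$models[[cl$centres[1]]]
    asm
  }
  full <- centre_model(restraints)
  full_keys <- contact_keys(full, cutoff = contact_cutoff)
  n_pick <- round(fraction * nrow(udrs))
  conserved <- numeric(n_subsets)
  sizes <- integer(n_subsets)
  for (s in seq_len(n_subsets)) {
    pick <- if (n_pick >= nrow(udrs)) seq_len(nrow(udrs)) else {
      with_seed(seed + s, sort(sample.int(nrow(udrs), n_pick)))
    }
    sizes[s] <- length(pick)
    rs <- restraints
    rs$crosslinks <- udrs[pick, , drop = FALSE]
    sub_keys <- contact_keys(centre_model(rs), cutoff = contact_cutoff)
    conserved[s] <- if (length(full_keys) == 0) NA_real_ else
      length(intersect(sub_keys, full_keys)) / length(full_keys)
  }
  structure(list(conserved = conserved, subset_sizes = sizes,
                 fraction = fraction, n_subsets = n_subsets, seed = seed),
            class = "jackknife_report")
}

#' @export
print.jackknife_report <- function(x, ...) {
  cat(sprintf("jackknife (%d subsets of %.0f%%): conserved %s\n",
              x$n_subsets, 100 * x$fraction,
              paste(sprintf("%.0f%%", 100 * x$conserved), collapse = ", ")))
  invisible(x)
}
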