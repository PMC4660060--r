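# Independent brute-force oracles, written as plain double loops straight
# from the scoring definitions.  They deliberately share no code with the
# package implementation (no vectorization, no dist(), no C++).

oracle_surface <- function(xi, xj, ri, rj) {
  sqrt(sum((xi - xj)^2)) - ri - rj
}

oracle_box_dist <- function(x, lo, hi) {
  d2 <- 0
  for (k in 1:3) {
    d <- 0
    if (x[k] < lo[k]) d <- lo[k] - x[k]
    if (x[k] > hi[k]) d <- x[k] - hi[k]
    d2 <- d2 + d * d
  }
  sqrt(d2)
}

# every term re-derived by exhaustive enumeration over all bead pairs
oracle_total_score <- function(assembly, restraints) {
  beads <- assembly$beads
  xyz <- assembly$xyz
  n <- nrow(beads)
  is_adj <- function(i, j) {
    beads$chain[i] == beads$chain[j] && abs(beads$bead[i] - beads$bead[j]) == 1
  }
  conn <- 0
  ev <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- oracle_surface(xyz[i, ], xyz[j, ], beads$radius[i], beads$radius[j])
    if (is_adj(i, j)) {
      if (s > 0) conn <- conn + restraints$connectivity_k * s^2
    } else {
      if (s < 0) ev <- ev + restraints$excluded_volume_k * s^2
    }
  }
  xl <- 0
  udrs <- restraints$crosslinks
  ncopy <- assembly$topology$copy_count
  if (!is.null(udrs) && nrow(udrs) > 0) {
    for (r in seq_len(nrow(udrs))) {
      rows_a <- which(beads$component == udrs$protein_a[r] &
                        beads$bead == floor((udrs$position_a[r] - 1) /
                                              assembly$topology$granularity))
      rows_b <- which(beads$component == udrs$protein_b[r] &
                        beads$bead == floor((udrs$position_b[r] - 1) /
                                              assembly$topology$granularity))
      best <- Inf
      for (i in rows_a) for (j in rows_b) {
        if (i == j) next
        best <- min(best, oracle_surface(xyz[i, ], xyz[j, ],
                                         beads$radius[i], beads$radius[j]))
      }
      if (is.finite(best) && best > restraints$xl_upper_bound) {
        xl <- xl + restraints$xl_k * (best - restraints$xl_upper_bound)^2
      }
    }
  }
  box <- 0
  sym <- assembly$topology$symmetry
  for (i in 1:n) {
    nm <- beads$component[i]
    if (!nm %in% names(restraints$boxes)) next
    b <- restraints$boxes[[nm]]
    x <- xyz[i, ]
    if (beads$copy[i] == 1) x <- as.numeric(t(sym$R) %*% (x - sym$t))
    box <- box + restraints$box_k * oracle_box_dist(x, b$min, b$max)^2
  }
  sub <- 0
  for (grp in restraints$subcomplex_groups) {
    for (cp in seq_len(ncopy) - 1) {
      for (a in grp) {
        g <- Inf
        ra <- which(beads$component == a & beads$copy == cp)
        for (b in setdiff(grp, a)) {
          rb <- which(beads$component == b & beads$copy == cp)
          for (i in ra) for (j in rb) {
            g <- min(g, oracle_surface(xyz[i, ], xyz[j, ],
                                       beads$radius[i], beads$radius[j]))
          }
        }
        if (is.finite(g) && g > 0) sub <- sub + restraints$subcomplex_k * g^2
      }
    }
  }
  unname(conn + ev + xl + box + sub)
}

# greedy largest-neighbourhood clustering, re-derived with explicit
# neighbour recounts at every round
oracle_daura <- function(D, cutoff, scores = NULL) {
  n <- nrow(D)
  if (is.null(scores)) scores <- rep(0, n)
  membership <- rep(NA_integer_, n)
  centres <- integer(0)
  left <- seq_len(n)
  cl <- 0L
  while (length(left) > 0) {
    cl <- cl + 1L
    counts <- integer(length(left))
    for (ii in seq_along(left)) {
      for (jj in seq_along(left)) {
        if (D[left[ii], left[jj]] <= cutoff) counts[ii] <- counts[ii] + 1
      }
    }
    best_ii <- order(-counts, scores[left], left)[1]
    centre <- left[best_ii]
    members <- left[D[centre, left] <= cutoff]
    membership[members] <- cl
    centres <- c(centres, centre)
    left <- setdiff(left, members)
  }
  list(membership = membership, centres = centres)
}

random_rigid <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 20))
}
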