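#' Bead radius for a run of residues
#'
#' Radius of the sphere whose volume equals the average volume occupied by
#' `n_res` amino-acid residues, using a standard protein partial specific
#' volume.  With the defaults a ten-residue bead has V = 1331 A^3 and
#' radius ~6.82 A.
#'
#' @param n_res number of residues represented by the bead (>= 1).
#' @param c_vol volume per unit mass, A^3/Da.  Default 1.21 A^3/Da, the
#'   conventional protein value.
#' @param m_res mean residue mass in Da.  Default 110 Da.
#' @return bead radius in Angstrom; vectorized over `n_res`.
#' @examples
#' bead_radius(10)  # ~6.82
#' bead_radius(1)   # ~3.17
#' @export
bead_radius <- function(n_res, c_vol = 1.21, m_res = 110) {
  if (any(n_res < 1)) stop("n_res must be >= 1")
  v <- c_vol * m_res * n_res
  (3 * v / (4 * pi))^(1 / 3)
}

#' Partition a sequence into coarse-grained beads
#'
#' Splits a protein sequence into consecutive, non-overlapping residue
#' ranges of `granularity` residues each; the final bead holds the
#' remainder (it is smaller, never redistributed, so that residue-to-bead
#' addressing stays a pure function of the residue index).
#'
#' @param sequence amino-acid string (one-letter codes) or an integer
#'   sequence length.
#' @param granularity residues per bead (default 10).
#' @param c_vol,m_res volume constants passed to [bead_radius()].
#' @return data.frame with columns `first_res`, `last_res`, `n_res`,
#'   `radius` (one row per bead, chain order).
#' @export
build_beads <- function(sequence, granularity = 10, c_vol = 1.21, m_res = 110) {
  len <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  if (length(len) != 1L || is.na(len) || len < 1L) {
    stop("sequence must be a non-empty amino-acid string or a positive length")
  }
  if (granularity < 1) stop("granularity must be >= 1")
  first <- seq.int(1L, len, by = granularity)
  last <- pmin(first + granularity - 1L, len)
  n <- last - first + 1L
  data.frame(
    first_res = first, last_res = last, n_res = n,
    radius = bead_radius(n, c_vol = c_vol, m_res = m_res)
  )
}

#' Map a residue to its bead
#'
#' Bead offsets are 0-based within a chain: residue 1 maps to bead 0,
#' residue `granularity` still to bead 0, residue `granularity + 1` to
#' bead 1, i.e. `floor((residue - 1) / granularity)`.
#'
#' @param component component name (used for error messages and, when
#'   `topology` is given, to look up the sequence length).
#' @param residue 1-based residue index.
#' @param topology an [assembly_topology()]; optional if `len` is given.
#' @param len sequence length (alternative to `topology`).
#' @param granularity residues per bead; taken from `topology` when given.
#' @return 0-based bead index within the component's chain.
#' @export
residue_to_bead <- function(component, residue, topology = NULL, len = NULL,
                            granularity = 10) {
  if (!is.null(topology)) {
    if (!component %in% names(topology$sequences)) {
      stop("unknown component '", component, "'")
    }
    len <- nchar(topology$sequences[[component]])
    granularity <- topology$granularity
  }
  if (is.null(len)) stop("either topology or len must be supplied")
  bad <- residue < 1 | residue > len
  if (any(bad)) {
    stop(
      "residue out of range for component '", component, "': position ",
      paste(residue[bad], collapse = ", "), " (length ", len, ")"
    )
  }
  as.integer(floor((residue - 1) / granularity))
}

check_rigid_transform <- function(sym, tol = 1e-8) {
  R <- sym$R
  t <- sym$t
  if (!is.matrix(R) || any(dim(R) != c(3, 3)) || length(t) != 3) {
    stop("symmetry transform must be a 3x3 rotation plus length-3 translation")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("symmetry transform is not a proper rigid transform (orthonormal, det = +1)")
  }
  invisible(sym)
}

#' Assembly topology
#'
#' Bundles everything needed to turn sequences into a positioned
#' coarse-grained assembly: the sequences, the copy count (2 for the
#' symmetric dimer), the bead granularity, the rigid transform mapping
#' copy 0 onto copy 1, subcomplex connectivity groups and per-component
#' localization bounding boxes.
#'
#' @param sequences named character vector or list, component name ->
#'   amino-acid sequence.
#' @param copy_count 1 or 2 (default 2, a symmetric dimer).
#' @param granularity residues per bead (default 10).
#' @param symmetry list with `R` (3x3 proper rotation) and `t` (length-3
#'   translation, Angstrom); copy 1 centres are `R %*% x + t`.
#' @param subcomplex_groups list of character vectors; every group must
#'   have at least two member components.
#' @param boxes named list, component name -> list(min =, max =) axis
#'   aligned corners in Angstrom.
#' @param c_vol,m_res bead volume constants (see [bead_radius()]).
#' @return object of class `assembly_topology`.
#' @export
assembly_topology <- function(sequences, copy_count = 2, granularity = 10,
                              symmetry = list(R = diag(3), t = c(0, 0, 0)),
                              subcomplex_groups = list(), boxes = list(),
                              c_vol = 1.21, m_res = 110) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("sequences must be uniquely named")
  }
  if (any(!nzchar(sequences))) stop("sequences must be non-empty")
  if (!copy_count %in% c(1, 2)) stop("copy_count must be 1 or 2")
  if (copy_count == 2) check_rigid_transform(symmetry)
  for (g in subcomplex_groups) {
    if (length(g) < 2) stop("every subcomplex group needs >= 2 members")
    if (!all(g %in% names(sequences))) {
      stop("subcomplex group names unknown: ", paste(setdiff(g, names(sequences)), collapse = ", "))
    }
  }
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    if (!nm %in% names(sequences)) stop("box for unknown component '", nm, "'")
    if (any(b$min >= b$max)) stop("malformed box for '", nm, "' (min must be < max)")
  }
  structure(
    list(
      sequences = sequences, copy_count = as.integer(copy_count),
      granularity = as.integer(granularity),
      symmetry = list(R = symmetry$R, t = as.numeric(symmetry$t)),
      subcomplex_groups = subcomplex_groups, boxes = boxes,
      c_vol = c_vol, m_res = m_res
    ),
    class = "assembly_topology"
  )
}

#' Build the bead assembly for a topology
#'
#' Expands every component of the topology into its bead chain and, for a
#' dimer, duplicates the full set for copy 1 (rows `n + 1 .. 2n` mirror
#' rows `1 .. n`).  Centres are `NA` until set by [initialize_state()] or
#' a sampler.
#'
#' @param topology an [assembly_topology()].
#' @return object of class `bead_assembly`: list with `beads` (data.frame:
#'   `component`, `copy`, `bead`, `first_res`, `last_res`, `n_res`,
#'   `radius`, `chain`), `xyz` (matrix, one row per bead) and `topology`.
#' @export
build_assembly <- function(topology) {
  stopifnot(inherits(topology, "assembly_topology"))
  per_comp <- lapply(names(topology$sequences), function(nm) {
    b <- build_beads(topology$sequences[[nm]], topology$granularity,
                     c_vol = topology$c_vol, m_res = topology$m_res)
    b$component <- nm
    b$bead <- seq_len(nrow(b)) - 1L
    b
  })
  one_copy <- do.call(rbind, per_comp)
  chain0 <- match(one_copy$component, names(topology$sequences))
  copies <- lapply(seq_len(topology$copy_count) - 1L, function(cp) {
    out <- one_copy
    out$copy <- cp
    out$chain <- chain0 + cp * length(topology$sequences)
    out
  })
  beads <- do.call(rbind, copies)
  rownames(beads) <- NULL
  beads <- beads[, c("component", "copy", "bead", "first_res", "last_res",
                     "n_res", "radius", "chain")]
  structure(
    list(beads = beads,
         xyz = matrix(NA_real_, nrow(beads), 3,
                      dimnames = list(NULL, c("x", "y", "z"))),
         topology = topology),
    class = "bead_assembly"
  )
}

n_beads_per_copy <- function(assembly) {
  sum(assembly$beads$copy == 0L)
}

#' @export
print.bead_assembly <- function(x, ...) {
  n0 <- n_beads_per_copy(x)
  cat("bead_assembly:", length(x$topology$sequences), "components,",
      x$topology$copy_count, "copies,", n0, "beads/copy",
      sprintf("(granularity %d)\n", x$topology$granularity))
  if (anyNA(x$xyz)) cat("  centres: unset\n") else cat("  centres: set\n")
  invisible(x)
}

# Row indices (1-based) of the copy-0 bead holding `residue` of `component`,
# for each copy.  Used to attach cross-link restraints to beads.
bead_row <- function(assembly, component, residue, copy = 0L) {
  idx <- residue_to_bead(component, residue, topology = assembly$topology)
  hit <- which(assembly$beads$component == component &
               assembly$beads$copy == copy &
               assembly$beads$bead == idx)
  if (length(hit) != 1L) {
    stop("cannot map ", component, " residue ", residue, " to a bead")
  }
  hit
}
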