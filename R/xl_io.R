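#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector (component name -> one-letter sequence).
#' @export
read_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(out))) stop("duplicate sequence names in ", path)
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

# order-normalize endpoint pairs: a <= b lexicographically, then by position
normalize_crosslinks <- function(df) {
  swap <- df$protein_a > df$protein_b |
    (df$protein_a == df$protein_b & df$position_a > df$position_b)
  if (any(swap)) {
    tmp_p <- df$protein_a[swap]
    tmp_i <- df$position_a[swap]
    df$protein_a[swap] <- df$protein_b[swap]
    df$position_a[swap] <- df$position_b[swap]
    df$protein_b[swap] <- tmp_p
    df$position_b[swap] <- tmp_i
  }
  df
}

udr_key <- function(df) {
  paste(df$protein_a, df$position_a, df$protein_b, df$position_b, sep = "|")
}

#' Read a cross-link table
#'
#' Reads a proxl-style TSV export with columns `protein_a`, `position_a`,
#' `protein_b`, `position_b`, `q_value` (optional `condition`), keeps
#' records with `q_value <= q_max`, order-normalizes the endpoints and
#' collapses duplicates to unique distance restraints (UDRs, keeping the
#' best q-value per pair).
#'
#' @param path TSV file.
#' @param q_max confidence threshold in `[0, 1]` (default 0.01, i.e. 1% FDR).
#' @param sequences optional named sequence set; when given, protein names
#'   and residue positions are validated against it.
#' @return data.frame of UDRs, class `crosslink_table`.
#' @export
read_crosslink_table <- function(path, q_max = 0.01, sequences = NULL) {
  if (q_max < 0 || q_max > 1) stop("q_max must be in [0, 1]")
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_a", "position_a", "protein_b", "position_b", "q_value")
  if (!all(need %in% names(df))) {
    stop("cross-link table must have columns: ", paste(need, collapse = ", "))
  }
  validate_positions(df, sequences, path)
  df <- df[df$q_value <= q_max, , drop = FALSE]
  dedupe_udrs(df)
}

validate_positions <- function(df, sequences, path = "table") {
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    for (side in c("a", "b")) {
      p <- df[[paste0("protein_", side)]]
      pos <- df[[paste0("position_", side)]]
      if (is.null(p)) next
      if (is.na(pos[i]) || !is.numeric(pos[i]) || pos[i] < 1 || pos[i] != round(pos[i])) {
        stop("malformed row at line ", line, " of ", path,
             ": position_", side, " = ", pos[i])
      }
      if (!is.null(sequences)) {
        if (!p[i] %in% names(sequences)) {
          stop("unknown protein '", p[i], "' in record at line ", line, " of ", path)
        }
        if (pos[i] > nchar(sequences[[p[i]]])) {
          stop("record at line ", line, " of ", path, ": position ", pos[i],
               " exceeds length of '", p[i], "'")
        }
      }
    }
    if (!is.null(df$q_value) && (is.na(df$q_value[i]) || df$q_value[i] < 0 || df$q_value[i] > 1)) {
      stop("malformed row at line ", line, " of ", path, ": q_value = ", df$q_value[i])
    }
  }
  invisible(df)
}

dedupe_udrs <- function(df) {
  df <- normalize_crosslinks(df)
  if (nrow(df) > 0) {
    df <- df[order(udr_key(df), df$q_value), , drop = FALSE]
    df <- df[!duplicated(udr_key(df)), , drop = FALSE]
    df <- df[order(df$protein_a, df$position_a, df$protein_b, df$position_b), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("crosslink_table", "data.frame")
  df
}

#' Write a cross-link table
#'
#' Emits the proxl-style TSV consumed by [read_crosslink_table()].  The
#' internal decoy flag of simulated tables is dropped: downstream code
#' never sees which records are decoys.
#'
#' @param df cross-link data.frame.
#' @param path output TSV.
#' @export
write_crosslink_table <- function(df, path) {
  df <- as.data.frame(df)
  df$is_decoy <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mono-link table
#'
#' TSV with columns `protein`, `position`, `q_value`: lysines modified by
#' a hydrolysed cross-linker on one end only.
#'
#' @inheritParams read_crosslink_table
#' @return data.frame of mono-links at `q_value <= q_max`, deduplicated.
#' @export
read_monolink_table <- function(path, q_max = 0.01, sequences = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "position", "q_value")
  if (!all(need %in% names(df))) {
    stop("mono-link table must have columns: ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    if (is.na(df$position[i]) || df$position[i] < 1) {
      stop("malformed row at line ", line, " of ", path)
    }
    if (!is.null(sequences) && !df$protein[i] %in% names(sequences)) {
      stop("unknown protein '", df$protein[i], "' at line ", line, " of ", path)
    }
  }
  df <- df[df$q_value <= q_max, , drop = FALSE]
  df <- df[order(df$protein, df$position, df$q_value), , drop = FALSE]
  df <- df[!duplicated(df[, c("protein", "position")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

pdb_chain_ids <- c(LETTERS, letters, 0:9)

#' Write a bead model as PDB pseudo-atoms
#'
#' One HETATM pseudo-atom per bead, one chain ID per component copy
#' (A-Z, a-z, 0-9; more than 62 chains is an error).  Residue number is
#' the first residue covered by the bead, occupancy the fraction of a
#' full bead it represents (residues / granularity), and the B-factor
#' column carries the bead radius in Angstrom.
#'
#' @param assembly positioned `bead_assembly`.
#' @param path output PDB.
#' @export
write_bead_model <- function(assembly, path) {
  if (anyNA(assembly$xyz) || any(!is.finite(assembly$xyz))) {
    stop("assembly has non-finite bead coordinates")
  }
  beads <- assembly$beads
  chain_key <- paste(beads$component, beads$copy)
  chain_idx <- match(chain_key, unique(chain_key))
  if (max(chain_idx) > length(pdb_chain_ids)) {
    stop("too many chains for PDB output (", max(chain_idx), " > 62)")
  }
  g <- assembly$topology$granularity
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(assembly$xyz)),
    type = rep("HETATM", nrow(beads)),
    resno = beads$first_res,
    resid = rep("BEA", nrow(beads)),
    chain = pdb_chain_ids[chain_idx],
    elety = rep("CA", nrow(beads)),
    o = beads$n_res / g,
    b = beads$radius
  )
  invisible(path)
}

#' Read a bead model PDB
#'
#' @param path PDB written by [write_bead_model()].
#' @return list with `xyz` (n x 3), `chain`, `resno`, `occupancy`,
#'   `radius` (from the B-factor column).
#' @export
read_bead_model <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  list(xyz = cbind(at$x, at$y, at$z), chain = at$chain, resno = at$resno,
       occupancy = at$o, radius = at$b)
}

#' Write a density map as an MRC/CCP4 volume
#'
#' Collapses the per-bead densities of a [compute_density()] map onto one
#' grid (sum over beads) and writes a standard little-endian MRC2014
#' mode-2 (float32) volume with correct voxel size and origin metadata.
#'
#' @param map a `density_map`, or a plain 3D array (then `bin` and
#'   `origin` must be supplied).
#' @param path output file.
#' @param bin,origin voxel size and origin for plain-array input.
#' @export
write_density_map <- function(map, path, bin = NULL, origin = NULL) {
  if (inherits(map, "density_map")) {
    if (nrow(map$voxels) == 0) stop("empty density map")
    vol <- array(0, dim = map$dim)
    v <- map$voxels
    vol[cbind(v$ix + 1L, v$iy + 1L, v$iz + 1L)] <-
      vol[cbind(v$ix + 1L, v$iy + 1L, v$iz + 1L)] + v$p
    bin <- map$bin
    origin <- map$origin
  } else {
    vol <- map
    if (is.null(bin) || is.null(origin)) stop("bin and origin required for array input")
    if (length(vol) == 0) stop("empty density map")
  }
  dm <- dim(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dm)                      # nx ny nz
  wi(2)                       # mode 2: float32
  wi(c(0, 0, 0))              # nxstart
  wi(dm)                      # mx my mz
  wf(dm * bin)                # cell dimensions
  wf(c(90, 90, 90))           # cell angles
  wi(c(1, 2, 3))              # axis order
  wf(c(min(vol), max(vol), mean(vol)))
  wi(1)                       # space group (volume)
  wi(0)                       # nsymbt
  wi(rep(0, 25))              # extra
  wf(origin)                  # origin (MRC2014 words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(vol)))
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  wf(as.numeric(vol))         # x fastest
  invisible(path)
}

#' Read an MRC/CCP4 volume
#'
#' @param path MRC file written by [write_density_map()].
#' @return list with `data` (3D array), `voxel` (length-3 voxel size),
#'   `origin`, `dmin`, `dmax`, `dmean`.
#' @export
read_density_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) MRC supported")
  ri(3)                       # nxstart
  mx <- ri(3)
  cell <- rf(3)
  rf(3)                       # angles
  ri(3)                       # axis order
  stats3 <- rf(3)
  ri(2)                       # ispg, nsymbt
  ri(25)                      # extra
  origin <- rf(3)
  readBin(con, "raw", 8)      # MAP + machine stamp
  rf(1)                       # rms
  ri(1)                       # nlabl
  readBin(con, "raw", 800)
  vals <- rf(prod(dm))
  list(data = array(vals, dim = dm), voxel = cell / mx, origin = origin,
       dmin = stats3[1], dmax = stats3[2], dmean = stats3[3])
}

#' Write an analysis report as JSON
#'
#' @param x named list of results.
#' @param path output file.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read an assembly configuration
#'
#' YAML bundle holding the topology (sequence file reference, copy count,
#' granularity, symmetry transform, subcomplex groups, bounding boxes)
#' and restraint parameters, so a simulation bundle can be consumed
#' unchanged by the modelling and analysis steps.
#'
#' @param topology an [assembly_topology()].
#' @param path YAML file.
#' @param sequence_file FASTA path stored in the config (read back
#'   relative to the config's directory).
#' @param restraint_params named list of restraint-set overrides.
#' @export
write_assembly_config <- function(topology, path, sequence_file = "sequences.fasta",
                                  restraint_params = list()) {
  cfg <- list(
    sequences = sequence_file,
    copy_count = topology$copy_count,
    granularity = topology$granularity,
    symmetry = list(R = as.numeric(topology$symmetry$R), t = topology$symmetry$t),
    subcomplex_groups = topology$subcomplex_groups,
    boxes = lapply(topology$boxes, function(b) list(min = b$min, max = b$max)),
    restraints = restraint_params
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_assembly_config
#' @return `read_assembly_config`: list with `topology` and `restraint_params`.
#' @export
read_assembly_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seqs <- read_sequences(file.path(dirname(path), cfg$sequences))
  topo <- assembly_topology(
    sequences = seqs,
    copy_count = cfg$copy_count,
    granularity = cfg$granularity,
    symmetry = list(R = matrix(cfg$symmetry$R, 3, 3), t = cfg$symmetry$t),
    subcomplex_groups = lapply(cfg$subcomplex_groups, unlist),
    boxes = lapply(cfg$boxes, function(b) list(min = unlist(b$min), max = unlist(b$max)))
  )
  list(topology = topo, restraint_params = cfg$restraints)
}
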