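#' Reference structure for cross-link benchmarking
#'
#' Loads the Calpha trace of an atomic structure and attaches the
#' explicit register mapping between dataset protein names and structure
#' chains.  Multi-model PDB files use model 1.  When a protein maps to
#' several equivalent chains (homo-oligomer), distances later take the
#' minimum over chain assignments, mirroring the ambiguity rule of the
#' modelling restraints.
#'
#' @param path PDB file.
#' @param mapping data.frame with columns `protein`, `chain` and optional
#'   `offset` (structure residue number = dataset position + offset,
#'   default 0).
#' @return object of class `reference_structure`: `ca` (data.frame
#'   `chain`, `resno`, `resid`, `x`, `y`, `z`) and `mapping`.
#' @export
reference_structure <- function(path, mapping) {
  if (!all(c("protein", "chain") %in% names(mapping))) {
    stop("mapping needs columns protein, chain")
  }
  if (is.null(mapping$offset)) mapping$offset <- 0L
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  at <- at[!duplicated(paste(at$chain, at$resno)), ]  # alt-locs: first CA wins
  ca <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                   x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  structure(list(ca = ca, mapping = mapping), class = "reference_structure")
}

ca_lookup <- function(ref, chain, resno) {
  hit <- which(ref$ca$chain == chain & ref$ca$resno == resno)
  if (length(hit) == 0) return(NULL)
  as.numeric(ref$ca[hit[1], c("x", "y", "z")])
}

#' Map cross-links onto reference Calpha-Calpha distances
#'
#' For every UDR, the Euclidean Calpha-Calpha distance in the reference
#' structure, minimized over the equivalent chains each protein maps to.
#' UDRs whose endpoints are absent from the structure are flagged
#' unmapped, never dropped silently.
#'
#' @param udrs cross-link data.frame.
#' @param ref a [reference_structure()].
#' @return data.frame: the UDR columns plus `distance` (A, NA when
#'   unmapped) and `mapped`.
#' @export
map_distances <- function(udrs, ref) {
  dist_one <- function(pa, ia, pb, ib) {
    ma <- ref$mapping[ref$mapping$protein == pa, , drop = FALSE]
    mb <- ref$mapping[ref$mapping$protein == pb, , drop = FALSE]
    best <- Inf
    for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(mb))) {
      xa <- ca_lookup(ref, ma$chain[i], ia + ma$offset[i])
      xb <- ca_lookup(ref, mb$chain[j], ib + mb$offset[j])
      if (is.null(xa) || is.null(xb)) next
      if (ma$chain[i] == mb$chain[j] && ia + ma$offset[i] == ib + mb$offset[j]) next
      best <- min(best, sqrt(sum((xa - xb)^2)))
    }
    if (is.finite(best)) best else NA_real_
  }
  d <- vapply(seq_len(nrow(udrs)), function(i) {
    dist_one(udrs$protein_a[i], udrs$position_a[i],
             udrs$protein_b[i], udrs$position_b[i])
  }, 0)
  if (all(is.na(d)) && nrow(udrs) > 0) {
    stop("structure maps no endpoint pair of any UDR")
  }
  out <- cbind(as.data.frame(udrs), distance = d, mapped = !is.na(d))
  rownames(out) <- NULL
  out
}

#' Fraction of mapped distances within a span
#'
#' @param distances numeric vector (NA = unmapped) or a [map_distances()]
#'   result.
#' @param span maximum cross-linkable Calpha-Calpha distance, A
#'   (30 A for a DSS-class reagent).
#' @return fraction of mapped distances `<= span`.
#' @export
fraction_within <- function(distances, span = 30) {
  if (is.data.frame(distances)) distances <- distances$distance
  d <- distances[!is.na(distances)]
  if (length(d) == 0) stop("no mapped distances")
  mean(d <= span)
}

#' Observed vs all-lysine-pair distance enrichment
#'
#' Compares the distribution of observed cross-linked Calpha-Calpha
#' distances with the background of *all* lysine-pair distances in the
#' reference structure, as normalized histograms on a common grid, and
#' reports the enrichment ratio of the two cumulative fractions at
#' `cutoff` (20 A): a ratio above 1 means short distances are enriched
#' among observations, i.e. the cross-links report on native structure.
#'
#' @param distances observed distances (vector or [map_distances()] result).
#' @param ref a [reference_structure()].
#' @param cutoff enrichment cutoff, A (default 20).
#' @param breaks histogram bin width, A (default 4).
#' @return list: `observed` and `background` (data.frames `mid`,
#'   `density`, each summing to 1), `ratio`, `cutoff`.
#' @export
enrichment_profile <- function(distances, ref, cutoff = 20, breaks = 4) {
  if (is.data.frame(distances)) distances <- distances$distance
  obs <- distances[!is.na(distances)]
  if (length(obs) == 0) stop("no mapped observed distances")
  lys <- ref$ca[ref$ca$resid == "LYS", , drop = FALSE]
  if (nrow(lys) < 2) stop("reference structure has fewer than two lysines")
  pr <- combn(nrow(lys), 2)
  bg <- sqrt((lys$x[pr[1, ]] - lys$x[pr[2, ]])^2 +
             (lys$y[pr[1, ]] - lys$y[pr[2, ]])^2 +
             (lys$z[pr[1, ]] - lys$z[pr[2, ]])^2)
  edges <- seq(0, max(obs, bg) + breaks, by = breaks)
  h <- function(x) {
    counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                       nbins = length(edges) - 1)
    data.frame(mid = edges[-length(edges)] + breaks / 2,
               density = counts / sum(counts))
  }
  list(observed = h(obs), background = h(bg),
       ratio = mean(obs <= cutoff) / mean(bg <= cutoff), cutoff = cutoff)
}

#' Lysine modification coverage
#'
#' Fraction of the sequences' lysines observed modified by the
#' cross-linker at least once, counting a lysine as observed when it
#' appears in a mono-link record or as a cross-link endpoint.
#'
#' @param monolinks data.frame with `protein`, `position` (may be empty).
#' @param sequences named character vector of sequences.
#' @param crosslinks optional cross-link data.frame whose endpoints also
#'   count as observed.
#' @return fraction in `[0, 1]`.
#' @export
monolink_coverage <- function(monolinks, sequences, crosslinks = NULL) {
  lys <- do.call(rbind, lapply(names(sequences), function(nm) {
    pos <- which(strsplit(sequences[[nm]], "")[[1]] == "K")
    if (length(pos) == 0) return(NULL)
    data.frame(protein = nm, position = pos)
  }))
  if (is.null(lys) || nrow(lys) == 0) return(NA_real_)
  seen <- character(0)
  if (!is.null(monolinks) && nrow(monolinks) > 0) {
    seen <- c(seen, paste(monolinks$protein, monolinks$position))
  }
  if (!is.null(crosslinks) && nrow(crosslinks) > 0) {
    seen <- c(seen, paste(crosslinks$protein_a, crosslinks$position_a),
              paste(crosslinks$protein_b, crosslinks$position_b))
  }
  mean(paste(lys$protein, lys$position) %in% seen)
}
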