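#' Sampler configuration
#'
#' Parameters of the parallel-tempering Monte Carlo protocol.  The
#' defaults are the production protocol (34 replicas between 1.0 and
#' 3.0 kT, 1 A bead moves, 1e8 steps, top 1000 models kept); analyses at
#' desk scale reduce `n_steps`/`n_replicas`.  Temperatures are spaced
#' geometrically between `t_min` and `t_max`.
#'
#' @param n_replicas number of replicas (default 34).
#' @param t_min,t_max temperature range, kT units (defaults 1.0 and 3.0).
#' @param max_move maximum bead translation per move, A (default 1.0).
#' @param n_steps Monte Carlo steps per replica (default 1e8).
#' @param exchange_interval steps between replica-exchange sweeps
#'   (default 100).  Snapshots of the lowest-temperature replica are
#'   collected at the same cadence.
#' @param seed RNG seed (integer).
#' @param wte_enabled enable the well-tempered-ensemble bias on the
#'   potential energy (off by default).
#' @param wte_gamma,wte_sigma,wte_height bias factor (> 1), Gaussian width
#'   (energy units) and initial Gaussian height.
#' @param top_n_keep number of best-scoring snapshots retained (default 1000).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_replicas = 34, t_min = 1.0, t_max = 3.0,
                           max_move = 1.0, n_steps = 1e8,
                           exchange_interval = 100, seed = 1,
                           wte_enabled = FALSE, wte_gamma = 16,
                           wte_sigma = 2, wte_height = 1,
                           top_n_keep = 1000) {
  if (t_min > t_max) stop("t_min must be <= t_max")
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  if (max_move <= 0) stop("max_move must be > 0")
  if (wte_enabled && wte_gamma <= 1) stop("wte_gamma must be > 1")
  structure(
    list(n_replicas = as.integer(n_replicas), t_min = t_min, t_max = t_max,
         max_move = max_move, n_steps = n_steps,
         exchange_interval = as.integer(exchange_interval),
         seed = as.integer(seed), wte_enabled = wte_enabled,
         wte_gamma = wte_gamma, wte_sigma = wte_sigma,
         wte_height = wte_height, top_n_keep = as.integer(top_n_keep)),
    class = "sampler_config"
  )
}

#' Geometric temperature ladder
#'
#' @param config a [sampler_config()].
#' @return vector of `n_replicas` temperatures from `t_min` to `t_max`,
#'   geometrically spaced.
#' @export
temperature_ladder <- function(config) {
  n <- config$n_replicas
  if (n == 1) return(config$t_min)
  config$t_min * (config$t_max / config$t_min)^((seq_len(n) - 1) / (n - 1))
}

# Assemble the list consumed by the C++ engine.  Bead/component indices
# are 0-based on the C++ side.
build_system <- function(assembly, restraints, sym_on = NULL,
                         lattice = NULL, tubulin_xls = NULL,
                         tubulin_bound = 5, tubulin_k = 1,
                         isoform_restricted = TRUE,
                         lat_max_trans = 2, lat_max_rot = 2) {
  topo <- assembly$topology
  beads0 <- assembly$beads[assembly$beads$copy == 0L, ]
  n <- nrow(beads0)
  comp_names <- names(topo$sequences)
  comp_id <- match(beads0$component, comp_names) - 1L
  has_box <- beads0$component %in% names(restraints$boxes)
  box_lo <- matrix(0, n, 3)
  box_hi <- matrix(0, n, 3)
  for (i in which(has_box)) {
    b <- restraints$boxes[[beads0$component[i]]]
    box_lo[i, ] <- b$min
    box_hi[i, ] <- b$max
  }
  xl <- restraints$crosslinks
  if (is.null(xl) || nrow(xl) == 0) {
    xa <- xb <- integer(0)
  } else {
    xa <- vapply(seq_len(nrow(xl)), function(i) {
      bead_row(assembly, xl$protein_a[i], xl$position_a[i], 0L)
    }, 0L) - 1L
    xb <- vapply(seq_len(nrow(xl)), function(i) {
      bead_row(assembly, xl$protein_b[i], xl$position_b[i], 0L)
    }, 0L) - 1L
  }
  groups <- lapply(restraints$subcomplex_groups, function(g) {
    match(g, comp_names) - 1L
  })
  comp_beads <- lapply(seq_along(comp_names), function(c) {
    which(comp_id == c - 1L) - 1L
  })
  sys <- list(
    n = n, ncopy = topo$copy_count,
    sym_on = if (is.null(sym_on)) topo$copy_count == 2L else isTRUE(sym_on),
    rad = beads0$radius, chain = as.integer(beads0$chain),
    comp = as.integer(comp_id),
    symR = topo$symmetry$R, symT = topo$symmetry$t,
    has_box = has_box, box_lo = box_lo, box_hi = box_hi,
    k_conn = restraints$connectivity_k, k_ev = restraints$excluded_volume_k,
    k_box = restraints$box_k, k_sub = restraints$subcomplex_k,
    xa = as.integer(xa), xb = as.integer(xb),
    xbound = rep(restraints$xl_upper_bound, length(xa)),
    xk = rep(restraints$xl_k, length(xa)),
    groups = groups, comp_beads = comp_beads,
    lattice = NULL
  )
  if (!is.null(lattice)) {
    if (is.null(tubulin_xls) || nrow(tubulin_xls) == 0) {
      tc <- integer(0); tcand <- list(); tbound <- tk <- numeric(0)
    } else {
      tc <- vapply(seq_len(nrow(tubulin_xls)), function(i) {
        bead_row(assembly, tubulin_xls$protein[i], tubulin_xls$position[i], 0L)
      }, 0L) - 1L
      tcand <- lapply(seq_len(nrow(tubulin_xls)), function(i) {
        tubulin_candidate_beads(lattice, tubulin_xls$tubulin[i],
                                tubulin_xls$tubulin_position[i],
                                isoform_restricted = isoform_restricted) - 1L
      })
      tbound <- rep(tubulin_bound, length(tc))
      tk <- rep(tubulin_k, length(tc))
    }
    sys$lattice <- list(
      L0 = lattice$xyz, lrad = lattice$beads$radius,
      lsub = as.integer(lattice$beads$subunit - 1L),
      nsub = nrow(lattice$subunits), ev_k = restraints$excluded_volume_k,
      tc = as.integer(tc), tcand = tcand, tbound = tbound, tk = tk,
      max_trans = lat_max_trans, max_rot = lat_max_rot
    )
  }
  sys
}

#' Randomized initial state
#'
#' Places the beads of box-restrained components uniformly at random
#' inside their bounding box and the beads of all other components
#' uniformly inside the union of all boxes, then applies the symmetry
#' constraint to generate copy 1.
#'
#' @param topology an [assembly_topology()].
#' @param restraints a [restraint_set()] (source of the boxes).
#' @param seed RNG seed; same seed, same coordinates.
#' @return a positioned `bead_assembly`.
#' @export
initialize_state <- function(topology, restraints, seed = 1) {
  assembly <- build_assembly(topology)
  boxes <- restraints$boxes
  if (length(boxes) == 0) {
    stop("no bounding boxes defined: cannot choose an initialization volume")
  }
  lo <- do.call(rbind, lapply(boxes, function(b) b$min))
  hi <- do.call(rbind, lapply(boxes, function(b) b$max))
  env_lo <- apply(lo, 2, min)
  env_hi <- apply(hi, 2, max)
  in_union <- function(x) {
    any(vapply(boxes, function(b) all(x >= b$min & x <= b$max), TRUE))
  }
  beads0 <- which(assembly$beads$copy == 0L)
  with_seed(seed, {
    for (i in beads0) {
      nm <- assembly$beads$component[i]
      if (nm %in% names(boxes)) {
        b <- boxes[[nm]]
        assembly$xyz[i, ] <- runif(3, b$min, b$max)
      } else {
        repeat {
          x <- runif(3, env_lo, env_hi)
          if (in_union(x)) break
        }
        assembly$xyz[i, ] <- x
      }
    }
  })
  if (topology$copy_count == 2L) {
    assembly$xyz[-beads0, ] <- apply_symmetry(assembly$xyz[beads0, , drop = FALSE],
                                              topology$symmetry)
  }
  assembly
}

# shared driver for run_sampling / mc_step / dock stages
pt_engine <- function(assembly, restraints, config, sys, trace = FALSE,
                      diag = FALSE, lat_mobile = FALSE,
                      latR = NULL, latT = NULL, lat_move_prob = NULL) {
  cfg <- list(
    temps = temperature_ladder(config),
    n_steps = config$n_steps,
    exchange_interval = config$exchange_interval,
    max_move = config$max_move,
    seed = config$seed,
    top_n = config$top_n_keep,
    trace = trace, diag = diag, lat_mobile = lat_mobile,
    wte_enabled = config$wte_enabled, wte_gamma = config$wte_gamma,
    wte_sigma = config$wte_sigma, wte_height = config$wte_height,
    latR = latR, latT = latT, lat_move_prob = lat_move_prob
  )
  .pt_run_cpp(sys, assembly$xyz, cfg)
}

#' Run parallel-tempering Monte Carlo sampling
#'
#' Samples assembly conformations under the restraint set with Metropolis
#' Monte Carlo coupled to parallel tempering.  One randomly chosen copy-0
#' bead is displaced per step (uniformly within a ball of `max_move`);
#' copy 1 follows through the symmetry constraint; moves are accepted
#' with probability `min(1, exp(-dE/T))`.  Neighbouring temperature pairs
#' are proposed for exchange every `exchange_interval` steps with
#' alternating even/odd pairing.  The best-scoring snapshots of the
#' lowest-temperature replica are returned.
#'
#' @param topology an [assembly_topology()].
#' @param restraints a [restraint_set()].
#' @param config a [sampler_config()].
#' @param init optional positioned `bead_assembly` to start from; by
#'   default [initialize_state()] with the config seed.
#' @return object of class `xl_ensemble`: `models` (list of coordinate
#'   matrices, score-ascending), `scores`, `steps`, `assembly` (template),
#'   plus acceptance diagnostics.
#' @export
run_sampling <- function(topology, restraints, config, init = NULL) {
  stopifnot(inherits(config, "sampler_config"))
  assembly <- init %||% initialize_state(topology, restraints, seed = config$seed)
  sys <- build_system(assembly, restraints)
  res <- pt_engine(assembly, restraints, config, sys)
  structure(
    list(models = res$snapshots, scores = as.numeric(res$scores),
         steps = as.numeric(res$steps), assembly = assembly,
         acceptance = as.numeric(res$acceptance),
         exchange_rate = res$exchange_rate),
    class = "xl_ensemble"
  )
}

#' @export
print.xl_ensemble <- function(x, ...) {
  cat("xl_ensemble:", length(x$models), "models, best score",
      sprintf("%.4f", min(x$scores)), "\n")
  invisible(x)
}

#' Single Monte Carlo step
#'
#' Executes one Metropolis step at a fixed temperature: displace one
#' randomly chosen copy-0 bead, update copy 1 by symmetry, accept with
#' probability `min(1, exp(-dE/T))`.  A rejected move leaves the
#' coordinates bitwise unchanged.
#'
#' @param state positioned `bead_assembly`.
#' @param restraints a [restraint_set()].
#' @param temperature temperature in kT units (> 0).
#' @param seed RNG seed for the proposal.
#' @param max_move maximum displacement, A.
#' @return the updated assembly, with attributes `accepted` (logical) and
#'   `delta_e` (proposal energy change).
#' @export
mc_step <- function(state, restraints, temperature, seed = 1, max_move = 1.0) {
  if (temperature <= 0) stop("temperature must be > 0")
  cfg <- sampler_config(n_replicas = 1, t_min = temperature, t_max = temperature,
                        max_move = max_move, n_steps = 1, exchange_interval = 1,
                        seed = seed, top_n_keep = 1)
  sys <- build_system(state, restraints)
  res <- pt_engine(state, restraints, cfg, sys, diag = TRUE)
  out <- state
  out$xyz <- res$finals[[1]]$X
  dimnames(out$xyz) <- dimnames(state$xyz)
  attr(out, "accepted") <- res$diag_accepted[1] == 1L
  attr(out, "delta_e") <- res$diag_dE[1]
  out
}

#' Well-tempered-ensemble bias
#'
#' History-dependent Gaussian bias on the total potential energy used to
#' broaden energy fluctuations and boost replica-exchange acceptance.
#' Each deposited Gaussian has width `sigma`; its height decays with the
#' bias already present at the deposition energy,
#' `h = height * exp(-V(E) / ((gamma - 1) * temperature))`, so heights at
#' a revisited energy form a decreasing sequence.
#'
#' @param gamma bias factor, must be > 1.
#' @param sigma Gaussian width in energy units.
#' @param height initial Gaussian height.
#' @param temperature replica temperature the bias is attached to.
#' @return object of class `wte_bias` with zero deposits (bias identically 0).
#' @export
wte_bias <- function(gamma = 16, sigma = 2, height = 1, temperature = 1) {
  if (gamma <= 1) stop("gamma must be > 1")
  structure(list(gamma = gamma, sigma = sigma, height = height,
                 temperature = temperature,
                 centres = numeric(0), heights = numeric(0)),
            class = "wte_bias")
}

#' @rdname wte_bias
#' @param bias a `wte_bias` object.
#' @param energy energy at which to deposit / evaluate.
#' @export
wte_bias_update <- function(bias, energy) {
  stopifnot(inherits(bias, "wte_bias"))
  v <- wte_bias_value(bias, energy)
  h <- bias$height * exp(-v / ((bias$gamma - 1) * bias$temperature))
  bias$centres <- c(bias$centres, energy)
  bias$heights <- c(bias$heights, h)
  bias
}

#' @rdname wte_bias
#' @export
wte_bias_value <- function(bias, energy) {
  stopifnot(inherits(bias, "wte_bias"))
  if (length(bias$centres) == 0) return(rep(0, length(energy)))
  vapply(energy, function(e) {
    sum(bias$heights * exp(-0.5 * ((e - bias$centres) / bias$sigma)^2))
  }, 0)
}
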