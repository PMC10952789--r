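#' Configuration of the diffusion random walk
#'
#' Defaults follow the simulation protocol: `Np = 1e5` walkers, `Nt = 1e4`
#' timesteps, extracellular diffusivity 2.5 um^2/ms, intracellular 1 um^2/ms,
#' sarcolemma permeability between 0 (impermeable) and 0.05 um/ms, and a
#' reduced intercalated-disk permeability of 0.005 um/ms when ICDs are
#' modelled explicitly.
#'
#' @param Np Number of walkers.
#' @param Nt Number of timesteps (`dt = T / Nt`).
#' @param D_ics,D_ecs Intra-/extracellular diffusivities (um^2/ms).
#' @param kappa_sarco Sarcolemma permeability (um/ms).
#' @param kappa_icd Intercalated-disk permeability (um/ms); `NULL` means
#'   equal to `kappa_sarco` (homogeneous membranes).
#' @param pd_exponent Exponent `p` in the diffusivity-step transit factor
#'   `p_d = (D_ICS / D_ECS)^p` applied to extracellular-to-intracellular
#'   transits.  Default 1 (plain ratio), the value under which the transit
#'   model conserves compartment occupancy at equilibrium given this `p_b`;
#'   0.5 reproduces square-root interface conventions.
#' @param seed Integer seed; every walker derives its own counter-based
#'   stream from `(seed, walker id)`.
#' @param max_substeps Membrane-interaction budget per step.
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(Np = 1e5, Nt = 1e4, D_ics = 1, D_ecs = 2.5,
                        kappa_sarco = 0, kappa_icd = NULL,
                        pd_exponent = 1, seed = 1L, max_substeps = 100L) {
  stopifnot(Np >= 1, Nt >= 1, D_ics > 0, D_ecs > 0,
            kappa_sarco >= 0, pd_exponent >= 0)
  if (is.null(kappa_icd)) kappa_icd <- kappa_sarco
  structure(list(Np = as.integer(Np), Nt = as.integer(Nt),
                 D_ics = D_ics, D_ecs = D_ecs,
                 kappa_sarco = kappa_sarco, kappa_icd = kappa_icd,
                 pd_exponent = pd_exponent, seed = as.integer(seed),
                 max_substeps = as.integer(max_substeps)),
            class = "walk_config")
}

#' Membrane transit probability of the hybrid model
#'
#' The permeability barrier gives `p_b = 2 kappa dx / (D_ICS + 2 kappa dx)`
#' where `dx` is the walker's distance from the membrane at the start of the
#' step, projected on the membrane normal.  Crossing from extracellular to
#' intracellular space additionally pays the diffusivity-step factor
#' `p_d = (D_ICS / D_ECS)^p`, treating membrane and diffusivity change as
#' successive barriers.  With this form of `p_b` (intracellular diffusivity
#' in the denominator on both sides), particle conservation at equal
#' concentration requires the plain ratio `p = 1`, the default; `p = 0.5`
#' is available for comparison with square-root interface conventions.
#'
#' @param kappa Membrane permeability (um/ms); select the sarcolemma or ICD
#'   value according to the membrane kind.
#' @param dx Projected start distance (um), clamped below at 1e-6.
#' @param D_ics,D_ecs Diffusivities (um^2/ms).
#' @param direction `"ICS->ECS"` or `"ECS->ICS"`.
#' @param pd_exponent Exponent of the diffusivity-step factor.
#' @return Transit probability in [0, 1].
#' @export
transit_probability <- function(kappa, dx, D_ics = 1, D_ecs = 2.5,
                                direction = c("ICS->ECS", "ECS->ICS"),
                                pd_exponent = 1) {
  direction <- match.arg(direction)
  stopifnot(kappa >= 0, dx > 0)
  dx <- pmax(dx, 1e-6)
  pb <- 2 * kappa * dx / (D_ics + 2 * kappa * dx)
  if (direction == "ECS->ICS") pb * (D_ics / D_ecs)^pd_exponent else pb
}

#' Propose one random-walk displacement per walker
#'
#' Each Cartesian component is `+/- sqrt(2 D dt)` with independent fair
#' coin flips, the fixed-step-length random walk whose per-component mean
#' square displacement is `2 D dt`.
#'
#' @param n Number of displacements.
#' @param D Local diffusivity (um^2/ms).
#' @param dt Timestep (ms).
#' @return An `n x 3` matrix of displacements (um).
#' @export
propose_step <- function(n, D, dt) {
  stopifnot(D > 0, dt > 0)
  len <- sqrt(2 * D * dt)
  matrix(len * sign(stats::runif(3 * n) - 0.5), ncol = 3)
}

# Voxel box (centred at the origin) and seeding box (voxel plus buffer).
walk_boxes <- function(s, buffer) {
  half <- s$voxel / 2
  list(vox_lo = -half, vox_hi = half,
       seed_lo = -half - buffer, seed_hi = half + buffer)
}

default_buffer <- function(s, cfg, T_enc) {
  if (!is.null(s$buffer)) return(s$buffer)
  4 * sqrt(2 * cfg$D_ecs * T_enc)
}

#' Seed walkers uniformly over the voxel and buffer zone
#'
#' The voxel is centred at the origin; the buffer width defaults to
#' `4 * sqrt(2 * D_ECS * T)`, wide enough that walkers diffusing into or out
#' of the voxel during the encoding are represented.  Positions reproduce
#' exactly the seeding used by [run_diffusion()] for the same seed.
#'
#' @param s A `substrate`.
#' @param cfg A [walk_config()].
#' @param T_enc Sequence duration in ms (sets the default buffer width).
#' @param buffer Buffer width in um (overrides the default).
#' @return A tibble with walker positions and initial compartments.
#' @export
seed_walkers <- function(s, cfg = walk_config(), T_enc = 52, buffer = NULL) {
  if (is.null(buffer)) buffer <- default_buffer(s, cfg, T_enc)
  bx <- walk_boxes(s, buffer)
  res <- mw_seed_walkers(substrate_cdata(s), cfg$Np, bx$seed_lo, bx$seed_hi,
                         cfg$seed)
  tibble::tibble(x = res$pos[, 1], y = res$pos[, 2], z = res$pos[, 3],
                 compartment = ifelse(res$comp >= 0, "ICS", "ECS"),
                 cell_id = ifelse(res$comp >= 0, res$comp + 1L, NA_integer_))
}

# One full random walk under a unit-amplitude waveform; returns the
# per-walker phase integrals psi (rad per mT/m when dotted with a direction
# and multiplied by Gmax), voxel membership and compartment bookkeeping.
run_walk <- function(s, wf, cfg, buffer = NULL) {
  if (is.null(buffer)) buffer <- default_buffer(s, cfg, wf$T)
  bx <- walk_boxes(s, buffer)
  dt <- wf$T / cfg$Nt
  amp <- waveform_step_amps(wf, cfg$Nt)
  pd <- (cfg$D_ics / cfg$D_ecs)^cfg$pd_exponent
  res <- mw_run_walk(substrate_cdata(s), cfg$Np, cfg$Nt, dt,
                     cfg$D_ics, cfg$D_ecs,
                     cfg$kappa_sarco, cfg$kappa_icd, pd,
                     cfg$seed, cfg$max_substeps,
                     bx$seed_lo, bx$seed_hi, bx$vox_lo, bx$vox_hi, amp)
  res$dt <- dt
  res
}

#' Run diffusion simulations and compute normalized signals
#'
#' Performs the Monte Carlo random walk in the substrate once per sequence
#' and evaluates the normalized diffusion signal
#' `S/S0 = |sum_i exp(-j phi_i)| / N` for every (direction, b-value)
#' measurement of the encoding scheme, restricted to walkers inside the
#' voxel at echo time.  The per-walker phase integral is accumulated with
#' the exact per-step mean gradient, so the gradient direction and amplitude
#' factor out and all measurements share one walk.
#'
#' @param s A `substrate`.
#' @param spec A [sequence_spec()] or a (possibly named) list of them.
#' @param cfg A [walk_config()].
#' @param scheme An [encoding_scheme()].
#' @param buffer Seeding buffer width in um (`NULL` = derived per sequence).
#' @return A tibble with columns `sequence`, `b`, `gx`, `gy`, `gz`,
#'   `S_over_S0` and `n_walkers`, one row per measurement.  Walker
#'   bookkeeping (initial/final intracellular fractions, substep overflow
#'   count) is attached as attribute `"walk_stats"`.
#' @export
run_diffusion <- function(s, spec, cfg = walk_config(),
                          scheme = encoding_scheme(), buffer = NULL) {
  specs <- if (inherits(spec, "sequence_spec")) list(spec) else spec
  nm <- names(specs)
  if (is.null(nm)) nm <- vapply(specs, function(x) x$kind, character(1))
  out <- vector("list", length(specs))
  stats_ <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    wf <- make_waveform(sp, Gmax = 1)
    b_unit <- b_value(wf)
    res <- run_walk(s, wf, cfg, buffer)
    keep <- res$in_voxel
    psi <- res$psi[keep, , drop = FALSE]
    nin <- nrow(psi)
    meas <- scheme$measurements
    Gm <- sqrt(meas$b / b_unit)
    Svals <- numeric(nrow(meas))
    for (m in seq_len(nrow(meas))) {
      if (meas$b[m] == 0) { Svals[m] <- 1; next }
      phi <- Gm[m] * (psi %*% c(meas$gx[m], meas$gy[m], meas$gz[m]))
      Svals[m] <- Mod(sum(exp(-1i * phi))) / nin
    }
    out[[i]] <- tibble::tibble(sequence = nm[i], b = meas$b,
                               gx = meas$gx, gy = meas$gy, gz = meas$gz,
                               S_over_S0 = Svals, n_walkers = nin)
    stats_[[i]] <- tibble::tibble(
      sequence = nm[i],
      ics_frac_init = mean(res$comp_init >= 0),
      ics_frac_final = mean(res$comp_final >= 0),
      overflow = res$overflow)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "walk_stats") <- dplyr::bind_rows(stats_)
  res
}
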