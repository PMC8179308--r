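# Constrained double-well model of hinge transport and its Langevin dynamics.
# The reduced coordinate z is the transport direction across the interface;
# the two minima are the Layer-1 and Layer-2 bound states of the water-
# carrying octanol cluster and the barrier sits at z = 0. The piecewise
# quartic below is the unique-shape choice satisfying every stated constraint
# (well positions, barrier location, two barrier heights, C1 smoothness)
# with no free shape parameters; beyond each minimum it continues
# harmonically with matched curvature.

KCAL_TO_AMU_NM2_PS2 <- 4.184  # 1 kcal/mol in amu nm^2 / ps^2

#' Constrained double-well specification
#'
#' @param z_left,z_right well minima, nm (`z_left < 0 < z_right`); defaults
#'   are the mean Layer-1 / Layer-2 octanol molecular lengths (-0.868,
#'   +0.854 nm).
#' @param Ea_fwd left-to-right barrier height (depth of the left well below
#'   the barrier), kcal/mol.
#' @param Ea_rev right-to-left barrier height, kcal/mol.
#' @return object of class `"double_well_spec"`.
#' @export
double_well_spec <- function(z_left = -0.868, z_right = 0.854,
                             Ea_fwd = 6.00, Ea_rev = 5.60) {
  if (!(z_left < 0 && z_right > 0)) stop("need z_left < 0 < z_right")
  if (Ea_fwd <= 0 || Ea_rev <= 0) stop("barrier heights must be positive")
  structure(list(z_left = z_left, z_right = z_right, barrier_z = 0,
                 Ea_fwd = Ea_fwd, Ea_rev = Ea_rev), class = "double_well_spec")
}

#' Build the double-well potential and force
#'
#' Piecewise C1 potential with `U(0) = 0`: on `[z_left, 0]`,
#' `U = Ea_fwd (-1 + 2 s^2 - s^4)` with `s = (z - z_left)/(-z_left)`; mirrored
#' with `Ea_rev` on `[0, z_right]`; harmonic continuation with matched
#' curvature beyond each minimum. Forces are analytic.
#'
#' @param spec a [double_well_spec()].
#' @return object of class `"double_well"`: functions `U(z)` and `force(z)`
#'   (kcal/mol, kcal/mol/nm; vectorised) plus the spec.
#' @export
build_double_well <- function(spec) {
  stopifnot(inherits(spec, "double_well_spec"))
  U <- function(z) .ld_potential_cpp(as.numeric(z), spec$z_left, spec$z_right,
                                     spec$Ea_fwd, spec$Ea_rev)$U
  force <- function(z) .ld_potential_cpp(as.numeric(z), spec$z_left, spec$z_right,
                                         spec$Ea_fwd, spec$Ea_rev)$F
  # constraint check (1e-9): minima depths, barrier value, stationary points
  chk <- c(U(0), U(spec$z_left) + spec$Ea_fwd, U(spec$z_right) + spec$Ea_rev,
           force(spec$z_left), force(spec$z_right), force(0))
  if (max(abs(chk)) > 1e-9)
    stop("double-well constraints violated (internal error): max dev ",
         max(abs(chk)))
  structure(list(U = U, force = force, spec = spec), class = "double_well")
}

#' @export
print.double_well <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<double_well: minima %.3f / %.3f nm, barriers %.2f / %.2f kcal/mol>\n",
              s$z_left, s$z_right, s$Ea_fwd, s$Ea_rev))
  invisible(x)
}

#' Langevin dynamics configuration
#'
#' @param T temperature, K (default 300).
#' @param mass particle mass, amu (default 18.015, one water).
#' @param friction Langevin friction gamma, ps^-1.
#' @param dt inner integration step, ps (default 0.01).
#' @param sample_interval position sampling interval, ps (default 1, the
#'   production-sampling value).
#' @param n_samples sampled positions per replicate (default 100000).
#' @param n_replicates independent replicates (default 1000).
#' @param seed integer RNG seed.
#' @return object of class `"ld_config"`.
#' @export
ld_config <- function(T = 300, mass = 18.015, friction = 1.0, dt = 0.01,
                      sample_interval = 1, n_samples = 100000,
                      n_replicates = 1000, seed = 1) {
  if (any(c(T, mass, friction, dt, sample_interval, n_samples,
            n_replicates) <= 0)) stop("all ld_config parameters must be positive")
  if (dt > sample_interval) stop("dt must not exceed sample_interval")
  structure(list(T = T, mass = mass, friction = friction, dt = dt,
                 sample_interval = sample_interval,
                 n_samples = as.integer(n_samples),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)), class = "ld_config")
}

#' Run Langevin dynamics on the double well
#'
#' BAOAB discretisation at inner step `dt`; positions recorded every
#' `sample_interval` for `n_samples` records per replicate; every replicate
#' starts at the left minimum with a Maxwell-Boltzmann velocity. A well
#' transition is counted when the particle, last assigned to one minimum,
#' reaches the other minimum's z (hysteresis at the minima, not at the
#' barrier), so per-replicate |forward - backward| <= 1.
#'
#' @param spec a [double_well_spec()] (or [build_double_well()] object).
#' @param config an [ld_config()].
#' @param store_replicates store the full sampled trajectory for this many
#'   leading replicates (default 0; memory scales with
#'   `n_samples * store_replicates`).
#' @param velocity_stride keep every n-th sampled velocity for diagnostics
#'   (default: thinned to ~2e5 pooled samples).
#' @return object of class `"ld_result"`: per-replicate `forward`/`backward`
#'   counts, pooled crossing `ratio` with 3-block `sem`, per-replicate left-
#'   basin occupancies, a pooled position histogram, pooled velocity
#'   subsample, optional `trajectories` (nm), and the inputs.
#' @export
ld_simulate <- function(spec, config = ld_config(), store_replicates = 0,
                        velocity_stride = NULL) {
  if (inherits(spec, "double_well")) spec <- spec$spec
  stopifnot(inherits(spec, "double_well_spec"), inherits(config, "ld_config"))
  n_inner <- as.integer(round(config$sample_interval / config$dt))
  if (abs(n_inner * config$dt - config$sample_interval) > 1e-9)
    stop("sample_interval must be an integer multiple of dt")
  kT <- GAS_CONSTANT_KCAL * config$T * KCAL_TO_AMU_NM2_PS2
  if (is.null(velocity_stride)) {
    tot <- as.numeric(config$n_samples) * config$n_replicates
    velocity_stride <- max(1, floor(tot / 2e5))
  }
  lo <- 2.5 * spec$z_left; hi <- 2.5 * spec$z_right
  res <- .ld_simulate_cpp(spec$z_left, spec$z_right,
                          spec$Ea_fwd * KCAL_TO_AMU_NM2_PS2,
                          spec$Ea_rev * KCAL_TO_AMU_NM2_PS2,
                          config$mass, kT, config$friction, config$dt,
                          n_inner, config$n_samples, config$n_replicates,
                          as.numeric(config$seed), as.integer(velocity_stride),
                          as.integer(store_replicates),
                          400L, lo, hi)
  ratio <- sum(res$forward) / max(1L, sum(res$backward))
  # 3-block SEM over replicate blocks
  blocks <- cut(seq_len(config$n_replicates), 3, labels = FALSE)
  br <- vapply(1:3, function(b) {
    f <- sum(res$forward[blocks == b]); bk <- sum(res$backward[blocks == b])
    if (bk > 0) f / bk else NA_real_
  }, 0)
  sem <- stats::sd(br, na.rm = TRUE) / sqrt(sum(is.finite(br)))
  structure(list(forward = res$forward, backward = res$backward,
                 ratio = ratio, sem = sem, block_ratios = br,
                 left_fraction = res$left_fraction,
                 z_hist = data.frame(
                   z = seq(lo + (hi - lo) / 800, hi, by = (hi - lo) / 400),
                   count = res$z_hist),
                 velocities = res$velocities,
                 trajectories = if (store_replicates > 0) res$traj else NULL,
                 spec = spec, config = config,
                 metadata = list(friction_ps = config$friction,
                                 integrator = "BAOAB", dt_ps = config$dt)),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf(paste0("<ld_result: %d replicates x %d samples; crossings ",
                     "%d fwd / %d bwd; ratio %.3f +/- %.3f (gamma = %.2g ps^-1)>\n"),
              x$config$n_replicates, x$config$n_samples,
              sum(x$forward), sum(x$backward), x$ratio, x$sem,
              x$config$friction))
  invisible(x)
}

#' @export
plot.ld_result <- function(x, ...) {
  graphics::plot(x$z_hist$z, x$z_hist$count / sum(x$z_hist$count),
                 type = "h", xlab = "z (nm)", ylab = "relative occupancy",
                 main = "Double-well occupancy", ...)
  invisible(x)
}

#' Compare basin occupancies with Boltzmann weights
#'
#' Time fractions in each basin (split at the barrier, z = 0) against the
#' numerically integrated Boltzmann weights `int exp(-U/kT) dz` per basin.
#'
#' @param result an [ld_simulate()] result.
#' @return list with `occupancy_left` (+ 3-block `sem`), `boltzmann_left`,
#'   `visited` flags, and `consistent` (within 3 SEM) or `flagged` when a well
#'   was never visited.
#' @export
occupancy_check <- function(result) {
  stopifnot(inherits(result, "ld_result"))
  spec <- result$spec
  dw <- build_double_well(spec)
  kT <- GAS_CONSTANT_KCAL * result$config$T
  zz <- seq(2.5 * spec$z_left, 2.5 * spec$z_right, length.out = 4001)
  w <- exp(-dw$U(zz) / kT)
  wl <- sum(w[zz < 0]); wr <- sum(w[zz >= 0])
  p_left <- wl / (wl + wr)
  occ <- mean(result$left_fraction)
  sem <- block_sem(result$left_fraction, 3)
  visited_left <- any(result$z_hist$count[result$z_hist$z < 0] > 0)
  visited_right <- any(result$z_hist$count[result$z_hist$z >= 0] > 0)
  if (!visited_left || !visited_right)
    return(list(occupancy_left = occ, sem = sem, boltzmann_left = p_left,
                visited = c(left = visited_left, right = visited_right),
                flagged = TRUE, consistent = NA))
  list(occupancy_left = occ, sem = sem, boltzmann_left = p_left,
       visited = c(left = TRUE, right = TRUE), flagged = FALSE,
       consistent = abs(occ - p_left) <= 3 * max(sem, 1e-12))
}
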