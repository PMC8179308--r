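# Interfacial tension from the planar Kirkwood-Buff pressure-tensor route and
# mole-fraction solubility of water in the organic phase.

# exact unit chain: 1 bar * 1 Angstrom = 1e5 Pa * 1e-10 m = 1e-5 N/m = 1e-2 mN/m
BAR_ANGSTROM_TO_MN_PER_M <- 1e-2

#' Pressure-tensor time series
#'
#' @param times ps.
#' @param Pxx,Pyy,Pzz diagonal pressure-tensor components, bar.
#' @param Lz box height, Angstrom.
#' @param n_interfaces interfaces in the periodic cell (default 2).
#' @return object of class `"pressure_series"`.
#' @export
pressure_series <- function(times, Pxx, Pyy, Pzz, Lz, n_interfaces = 2) {
  n <- length(times)
  if (length(Pxx) != n || length(Pyy) != n || length(Pzz) != n)
    stop("pressure series length mismatch")
  if (Lz <= 0 || n_interfaces < 1) stop("invalid Lz or interface count")
  structure(list(times = times, Pxx = Pxx, Pyy = Pyy, Pzz = Pzz,
                 Lz = Lz, n_interfaces = n_interfaces),
            class = "pressure_series")
}

#' Interfacial tension (Kirkwood-Buff pressure-tensor route)
#'
#' `gamma = (L_z / (2 N_int)) < P_zz - (P_xx + P_yy)/2 >`, converted from
#' bar Angstrom to mN/m, with a block-averaged SEM.
#'
#' @param series a [pressure_series()].
#' @param n_blocks blocks for the SEM (default 3).
#' @return list with `gamma` (mN/m), `sem`, `n`.
#' @export
interfacial_tension <- function(series, n_blocks = 3) {
  stopifnot(inherits(series, "pressure_series"))
  if (length(series$times) < n_blocks)
    stop("need at least ", n_blocks, " samples for a ", n_blocks, "-block error")
  anis <- series$Pzz - (series$Pxx + series$Pyy) / 2
  pref <- series$Lz / (2 * series$n_interfaces)
  g <- pref * anis * BAR_ANGSTROM_TO_MN_PER_M
  list(gamma = mean(g), sem = block_sem(g, n_blocks), n = length(g))
}

#' Phase composition (mean number densities in a region)
#' @param rho_water,rho_octanol mean number densities, molecules / A^3.
#' @return object of class `"phase_composition"`.
#' @export
phase_composition <- function(rho_water, rho_octanol) {
  if (rho_water < 0 || rho_octanol < 0) stop("densities must be non-negative")
  structure(list(rho_water = rho_water, rho_octanol = rho_octanol),
            class = "phase_composition")
}

#' Mole-fraction solubility of water in the organic phase
#'
#' `x_w = rho_w / (rho_w + rho_oct)` from the mean densities in the
#' octanol-rich region.
#'
#' @param composition a [phase_composition()], or the water density if
#'   `rho_octanol` is given.
#' @param rho_octanol optional octanol density when passing raw numbers.
#' @return dimensionless mole fraction.
#' @export
mole_fraction_solubility <- function(composition, rho_octanol = NULL) {
  if (!inherits(composition, "phase_composition"))
    composition <- phase_composition(composition, rho_octanol)
  s <- composition$rho_water + composition$rho_octanol
  if (s <= 0) stop("both phase densities are zero")
  composition$rho_water / s
}

#' Phase composition of the octanol-rich region of a trajectory
#'
#' Counts water and octanol molecules whose O sits beyond `z_boundary`
#' (on the `side` given) and divides by the region volume.
#'
#' @param trajectory an [md_trajectory()] or single frame.
#' @param z_boundary start of the octanol-rich region, Angstrom.
#' @param side `"above"` or `"below"` the boundary.
#' @return a [phase_composition()].
#' @export
octanol_phase_composition <- function(trajectory, z_boundary,
                                      side = c("above", "below")) {
  side <- match.arg(side)
  frames <- if (inherits(trajectory, "md_trajectory")) trajectory$frames
            else list(trajectory)
  L <- frames[[1]]$box$L
  depth <- if (side == "above") L[3] - z_boundary else z_boundary
  vol <- L[1] * L[2] * depth
  nw <- no <- 0
  for (fr in frames) {
    ox <- .oxygen_table(fr)
    sel <- if (side == "above") ox$z >= z_boundary else ox$z <= z_boundary
    nw <- nw + sum(sel & ox$role == "water_O")
    no <- no + sum(sel & ox$role == "hydroxyl_O")
  }
  phase_composition(nw / (length(frames) * vol), no / (length(frames) * vol))
}
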