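# Core geometric types: periodic boxes, frames of typed molecules, trajectories,
# and minimum-image arithmetic. Internal units throughout the package are
# Angstrom, ps, kcal/mol, Kelvin, amu.

#' Orthorhombic periodic box
#'
#' @param Lx,Ly,Lz box edge lengths in Angstrom (all > 0).
#' @param periodic logical 3-vector; which axes are periodic.
#' @return An object of class `"box"`.
#' @export
box3 <- function(Lx, Ly, Lz, periodic = c(TRUE, TRUE, TRUE)) {
  L <- c(Lx, Ly, Lz)
  if (!all(is.finite(L)) || any(L <= 0))
    stop("box lengths must be finite and positive")
  periodic <- rep_len(as.logical(periodic), 3L)
  structure(list(L = as.numeric(L), periodic = periodic), class = "box")
}

#' @export
print.box <- function(x, ...) {
  cat(sprintf("<box %.3f x %.3f x %.3f A, periodic [%s]>\n",
              x$L[1], x$L[2], x$L[3],
              paste(ifelse(x$periodic, "x", "-"), collapse = "")))
  invisible(x)
}

VALID_ROLES <- c("water_O", "water_H", "hydroxyl_O", "hydroxyl_H",
                 "chain_C", "terminal_C", "other")

#' Single configuration of typed molecules in a periodic box
#'
#' `atoms` is a data frame with one row per atom and columns
#' `atom` (integer id), `mol` (integer molecule id), `species`
#' (`"water"` or `"octanol"`), `role` (see Details), `element`,
#' and Cartesian positions `x`, `y`, `z` in Angstrom.
#'
#' @details Roles drive every analysis: hydrogen-bond detection uses
#' `water_O`/`hydroxyl_O` as donors/acceptors with their covalent
#' `water_H`/`hydroxyl_H`; orientation analysis uses the hydroxyl H and
#' `terminal_C` chain end. A water must carry exactly one `water_O`;
#' an octanol exactly one `hydroxyl_O`, one `hydroxyl_H`, one `terminal_C`.
#'
#' @param atoms atom table (see above).
#' @param box a [box3()] object.
#' @param time frame time in ps.
#' @param validate check molecular-role invariants (default TRUE).
#' @return An object of class `"md_frame"`.
#' @export
md_frame <- function(atoms, box, time = 0, validate = TRUE) {
  stopifnot(inherits(box, "box"))
  need <- c("atom", "mol", "species", "role", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom positions")
  fr <- structure(list(atoms = as.data.frame(atoms), box = box,
                       time = as.numeric(time)), class = "md_frame")
  if (validate) validate_frame(fr)
  fr
}

#' @export
print.md_frame <- function(x, ...) {
  ns <- table(mol_species(x))
  cat(sprintf("<md_frame t=%.2f ps, %d atoms, %d molecules (%s)>\n",
              x$time, nrow(x$atoms), length(unique(x$atoms$mol)),
              paste(sprintf("%s: %d", names(ns), ns), collapse = ", ")))
  invisible(x)
}

validate_frame <- function(frame) {
  at <- frame$atoms
  bad <- setdiff(unique(at$role), VALID_ROLES)
  if (length(bad)) stop("unknown atom roles: ", paste(bad, collapse = ", "))
  sp <- tapply(at$species, at$mol, function(s) s[1])
  for (m in names(sp)) {
    rr <- at$role[at$mol == as.integer(m)]
    if (sp[[m]] == "water") {
      if (sum(rr == "water_O") != 1L)
        stop("water molecule ", m, " must have exactly one water_O")
    } else if (sp[[m]] == "octanol") {
      if (sum(rr == "hydroxyl_O") != 1L || sum(rr == "hydroxyl_H") != 1L ||
          sum(rr == "terminal_C") != 1L)
        stop("octanol molecule ", m,
             " must have one hydroxyl_O, one hydroxyl_H, one terminal_C")
    }
  }
  invisible(frame)
}

#' Species of every molecule in a frame
#' @param frame an [md_frame()].
#' @return named character vector, names = molecule ids.
#' @export
mol_species <- function(frame) {
  at <- frame$atoms
  idx <- !duplicated(at$mol)
  stats::setNames(at$species[idx], at$mol[idx])
}

#' Positions (matrix) of atoms with a given role
#' @param frame an [md_frame()].
#' @param role atom role, e.g. `"water_O"`.
#' @return matrix with columns x, y, z and rownames = molecule ids.
#' @keywords internal
role_positions <- function(frame, role) {
  at <- frame$atoms[frame$atoms$role %in% role, , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$mol
  m
}

#' Minimum-image displacement between points in a periodic box
#'
#' Returns `b - a` mapped into the primary image: each component lies in
#' `[-L/2, L/2)` on periodic axes.
#'
#' @param a,b numeric 3-vectors or n x 3 matrices (Angstrom).
#' @param box a [box3()].
#' @return displacement(s), same shape as inputs.
#' @export
minimum_image <- function(a, b, box) {
  stopifnot(inherits(box, "box"))
  a <- rbind2mat(a); b <- rbind2mat(b)
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite input positions")
  d <- b - a
  for (k in 1:3) if (box$periodic[k]) {
    L <- box$L[k]
    d[, k] <- d[, k] - L * floor(d[, k] / L + 0.5)
  }
  if (nrow(d) == 1L) drop(d) else d
}

rbind2mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 3)
}

#' Wrap all atom positions into the primary cell
#'
#' Idempotent; minimum-image pair distances are unchanged.
#'
#' @param frame an [md_frame()].
#' @return the frame with positions in `[0, L)` on periodic axes.
#' @export
wrap_frame <- function(frame) {
  at <- frame$atoms
  for (k in 1:3) if (frame$box$periodic[k]) {
    L <- frame$box$L[k]
    col <- c("x", "y", "z")[k]
    at[[col]] <- at[[col]] - L * floor(at[[col]] / L)
  }
  frame$atoms <- at
  frame
}

#' Time-ordered trajectory of frames
#'
#' @param frames list of [md_frame()]s with strictly increasing times and a
#'   constant molecule roster.
#' @param sampling_interval frame spacing in ps; inferred from times if `NULL`.
#' @return object of class `"md_trajectory"`.
#' @export
md_trajectory <- function(frames, sampling_interval = NULL) {
  stopifnot(length(frames) >= 1L, all(vapply(frames, inherits, TRUE, "md_frame")))
  tt <- vapply(frames, function(f) f$time, 0)
  if (length(tt) > 1 && any(diff(tt) <= 0)) stop("frame times must strictly increase")
  m0 <- frames[[1]]$atoms$mol
  for (f in frames[-1])
    if (!identical(f$atoms$mol, m0)) stop("molecule roster differs across frames")
  if (is.null(sampling_interval))
    sampling_interval <- if (length(tt) > 1) tt[2] - tt[1] else 1
  structure(list(frames = frames, sampling_interval = sampling_interval),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory %d frames, dt=%.4g ps, t=[%.4g, %.4g] ps>\n",
              length(x$frames), x$sampling_interval,
              x$frames[[1]]$time, x$frames[[length(x$frames)]]$time))
  invisible(x)
}

#' @export
length.md_trajectory <- function(x) length(x$frames)

frame_times <- function(traj) vapply(traj$frames, function(f) f$time, 0)
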