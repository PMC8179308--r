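# Intrinsic-surface detection. ITIM: probe spheres descend along an xy grid
# of test lines; the molecules whose atoms are touched first are "truly
# interfacial". A density-based cluster correction removes waters that have
# penetrated the organic phase before ITIM sees them. The Willard-Chandler
# surface is the isosurface of a Gaussian coarse-grained density field at a
# fraction of the bulk water density; for the quasi-planar slabs in scope it
# is extracted column-wise as a periodic height field (no marching-cubes
# library exists in this R stack; equivalent for single-valued surfaces).

#' ITIM parameters
#'
#' @param probe_radius probe sphere radius, Angstrom (default 1.5).
#' @param grid_spacing test-line grid spacing, Angstrom (default 0.2).
#' @param atomic_radii named vector of van der Waals radii per role prefix
#'   (`O`, `H`, `C`); Bondi-type defaults O 1.52, H 1.10, C 1.70 A.
#' @param direction `"down"` (probes descend along -z onto the upper surface)
#'   or `"up"` (ascend along +z onto the lower surface).
#' @return object of class `"itim_params"`.
#' @export
itim_params <- function(probe_radius = 1.5, grid_spacing = 0.2,
                        atomic_radii = c(O = 1.52, H = 1.10, C = 1.70),
                        direction = c("down", "up")) {
  if (probe_radius <= 0 || grid_spacing <= 0)
    stop("probe radius and grid spacing must be positive")
  direction <- match.arg(direction)
  structure(list(probe_radius = probe_radius, grid_spacing = grid_spacing,
                 atomic_radii = atomic_radii, direction = direction),
            class = "itim_params")
}

.role_radius <- function(roles, radii) {
  el <- ifelse(grepl("_O$|^water_O$", roles), "O",
               ifelse(grepl("_H$", roles), "H",
                      ifelse(grepl("_C$|chain_C", roles), "C", "O")))
  unname(radii[el])
}

#' Identify truly interfacial molecules of one phase (ITIM)
#'
#' Probe spheres of radius `probe_radius` descend along test lines on an xy
#' grid (periodic in x, y). A molecule is interfacial iff at least one probe
#' first touches one of its atoms, where touching means the line passes within
#' `atomic radius + probe radius` of the atom centre and the contact height is
#' the highest (direction `"down"`) among all atoms on that line.
#'
#' @param frame a wrapped [md_frame()].
#' @param phase_member_ids molecule ids making up the phase to be probed.
#' @param params an [itim_params()].
#' @return object of class `"surface_set"`: `frame_time`, sorted interfacial
#'   `molecules`, `side` (`"upper"` for direction down), and the params.
#' @export
itim_layer <- function(frame, phase_member_ids, params = itim_params()) {
  phase_member_ids <- as.integer(phase_member_ids)
  if (!length(phase_member_ids)) stop("empty phase membership")
  at <- frame$atoms[frame$atoms$mol %in% phase_member_ids, , drop = FALSE]
  if (!nrow(at)) stop("phase members have no atoms in frame")
  Lx <- frame$box$L[1]; Ly <- frame$box$L[2]
  nx <- max(1L, as.integer(round(Lx / params$grid_spacing)))
  ny <- max(1L, as.integer(round(Ly / params$grid_spacing)))
  sx <- Lx / nx; sy <- Ly / ny
  down <- params$direction == "down"
  bestz <- matrix(if (down) -Inf else Inf, nx, ny)
  bestmol <- matrix(NA_integer_, nx, ny)
  R <- .role_radius(at$role, params$atomic_radii) + params$probe_radius
  xs <- at$x - Lx * floor(at$x / Lx)
  ys <- at$y - Ly * floor(at$y / Ly)
  for (i in seq_len(nrow(at))) {
    Ri <- R[i]
    xlo <- ceiling((xs[i] - Ri) / sx); xhi <- floor((xs[i] + Ri) / sx)
    ylo <- ceiling((ys[i] - Ri) / sy); yhi <- floor((ys[i] + Ri) / sy)
    if (xlo > xhi || ylo > yhi) next
    ix <- seq(xlo, xhi); iy <- seq(ylo, yhi)
    dx <- ix * sx - xs[i]; dy <- iy * sy - ys[i]
    d2 <- outer(dx^2, dy^2, `+`)
    hit <- d2 <= Ri^2
    if (!any(hit)) next
    dz <- sqrt(pmax(0, Ri^2 - d2[hit]))
    zc <- if (down) at$z[i] + dz else at$z[i] - dz
    gx <- (as.integer(ix) %% nx) + 1L   # line ix sits at x = ix * sx
    gy <- (as.integer(iy) %% ny) + 1L
    idx <- cbind(rep(gx, length(gy)), rep(gy, each = length(gx)))[hit, , drop = FALSE]
    better <- if (down) zc > bestz[idx] else zc < bestz[idx]
    if (any(better)) {
      upd <- idx[better, , drop = FALSE]
      bestz[upd] <- zc[better]
      bestmol[upd] <- at$mol[i]
    }
  }
  mols <- sort(unique(bestmol[!is.na(bestmol)]))
  structure(list(frame_time = frame$time, molecules = as.integer(mols),
                 side = if (down) "upper" else "lower", params = params),
            class = "surface_set")
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set t=%.2f ps, side=%s, %d interfacial molecules>\n",
              x$frame_time, x$side, length(x$molecules)))
  invisible(x)
}

# plain DBSCAN on a position matrix under periodic minimum image.
# Returns integer cluster labels (0 = noise). Neighbourhoods use d <= eps and
# counts include the point itself (scikit-learn convention).
.dbscan_labels <- function(pos, box, eps, min_samples) {
  n <- nrow(pos)
  prs <- neighbor_pairs(pos, box, eps * (1 + 1e-12))  # strict < just above eps ~ <= eps
  deg <- tabulate(c(prs$i, prs$j), nbins = n)
  core <- (deg + 1L) >= min_samples
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  cc <- prs[core[prs$i] & core[prs$j], , drop = FALSE]
  if (nrow(cc)) g <- igraph::add_edges(g, rbind(cc$i, cc$j))
  memb <- igraph::components(g)$membership
  labels <- integer(n)
  labels[core] <- memb[core]
  # border points: attach to the lowest-labelled adjacent core cluster
  if (nrow(prs)) {
    for (r in seq_len(nrow(prs))) {
      i <- prs$i[r]; j <- prs$j[r]
      if (!core[i] && core[j] && (labels[i] == 0L || labels[i] > labels[j]))
        labels[i] <- labels[j]
      if (!core[j] && core[i] && (labels[j] == 0L || labels[j] > labels[i]))
        labels[j] <- labels[i]
    }
  }
  # renumber clusters consecutively in order of appearance
  u <- unique(labels[labels > 0L])
  labels[labels > 0L] <- match(labels[labels > 0L], u)
  labels
}

#' Separate aqueous-connected from penetrated waters
#'
#' Density-based clustering (DBSCAN, `eps`/`min_samples`) of water oxygen
#' positions. The largest cluster is the aqueous phase; any other cluster
#' hydrogen-bond-connected to it (via `hbgraph`) is merged in. Remaining
#' waters have penetrated the organic phase. ITIM input should be restricted
#' to the aqueous set.
#'
#' @param frame an [md_frame()].
#' @param hbgraph a [detect_hbonds()] graph for the same frame.
#' @param eps DBSCAN radius, Angstrom (default 3.5, the HB O...O scale).
#' @param min_samples DBSCAN core-point threshold (default 3, self included).
#' @return list with `aqueous` and `penetrated` (sorted molecule ids).
#' @export
split_penetrated_waters <- function(frame, hbgraph, eps = 3.5, min_samples = 3) {
  sp <- mol_species(frame)
  waters <- as.integer(names(sp)[sp == "water"])
  if (!length(waters)) stop("frame contains no waters")
  ox <- .oxygen_table(frame, waters)
  ox <- ox[order(ox$mol), , drop = FALSE]
  labels <- .dbscan_labels(as.matrix(ox[, c("x", "y", "z")]), frame$box,
                           eps, min_samples)
  if (!any(labels > 0L)) stop("no dense aqueous cluster found")
  sizes <- tabulate(labels[labels > 0L])
  main <- which.max(sizes)
  aq_cl <- main
  # merge clusters HB-connected to the aqueous component (water-water edges)
  if (nrow(hbgraph$edges)) {
    e <- hbgraph$edges
    lab_of <- stats::setNames(labels, ox$mol)
    ld <- lab_of[as.character(e$donor)]; la <- lab_of[as.character(e$acceptor)]
    ok <- !is.na(ld) & !is.na(la) & ld > 0L & la > 0L & ld != la
    cg <- igraph::make_empty_graph(n = length(sizes), directed = FALSE)
    if (any(ok)) cg <- igraph::add_edges(cg, rbind(ld[ok], la[ok]))
    aq_cl <- which(igraph::components(cg)$membership ==
                     igraph::components(cg)$membership[main])
  }
  aq <- ox$mol[labels %in% aq_cl]
  list(aqueous = sort(as.integer(aq)),
       penetrated = sort(setdiff(waters, aq)))
}

#' Truly interfacial octanols
#'
#' An octanol is truly interfacial iff its hydroxyl is hydrogen bonded (as
#' donor or acceptor) to at least one truly interfacial water.
#'
#' @param frame an [md_frame()].
#' @param surface_waters a [itim_layer()] `surface_set` of corrected waters,
#'   or a plain vector of water molecule ids.
#' @param hbgraph a [detect_hbonds()] graph for the frame.
#' @return sorted integer vector of octanol molecule ids.
#' @export
interfacial_octanols <- function(frame, surface_waters, hbgraph) {
  sw <- if (inherits(surface_waters, "surface_set")) surface_waters$molecules
        else as.integer(surface_waters)
  sp <- mol_species(frame)
  octs <- as.integer(names(sp)[sp == "octanol"])
  e <- hbgraph$edges
  if (!nrow(e)) return(integer(0))
  touching <- unique(c(e$donor[e$acceptor %in% sw], e$acceptor[e$donor %in% sw]))
  sort(intersect(as.integer(touching), octs))
}

#' Willard-Chandler parameters
#' @param coarse_len Gaussian coarse-graining length xi, Angstrom (default 2.5).
#' @param level isosurface level as a fraction of bulk density (default 0.90).
#' @param voxel voxel grid spacing, Angstrom (default 1.0).
#' @param truncate kernel truncation radius in units of xi (default 4).
#' @return object of class `"wc_params"`.
#' @export
wc_params <- function(coarse_len = 2.5, level = 0.90, voxel = 1.0, truncate = 4) {
  structure(list(coarse_len = coarse_len, level = level, voxel = voxel,
                 truncate = truncate), class = "wc_params")
}

# Gaussian coarse-grained number density of points on a periodic voxel grid.
# Returns list(grid = 3d array, xs, ys, zs voxel centres).
.wc_density_grid <- function(pos, box, params) {
  L <- box$L
  nv <- pmax(4L, as.integer(round(L / params$voxel)))
  vx <- L / nv
  xi <- params$coarse_len
  rad <- params$truncate * xi
  norm <- (2 * pi * xi^2)^(-1.5)
  grid <- array(0, dim = nv)
  centers <- lapply(1:3, function(k) (seq_len(nv[k]) - 0.5) * vx[k])
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ] - L * floor(pos[i, ] / L)
    idx <- lapply(1:3, function(k) {
      seq(floor((p[k] - rad) / vx[k] - 0.5), ceiling((p[k] + rad) / vx[k] - 0.5))
    })
    g1 <- lapply(1:3, function(k) {
      d <- (idx[[k]] + 0.5) * vx[k] - p[k]
      exp(-d^2 / (2 * xi^2))
    })
    w <- ((idx[[1]]) %% nv[1]) + 1L
    u <- ((idx[[2]]) %% nv[2]) + 1L
    v <- ((idx[[3]]) %% nv[3]) + 1L
    kern <- norm * outer(outer(g1[[1]], g1[[2]]), g1[[3]])
    grid[w, u, v] <- grid[w, u, v] + kern
  }
  list(grid = grid, centers = centers, nv = nv, vx = vx)
}

# area of a periodic height field h[ix, iy] over a box (two triangles/cell)
surface_mesh_area <- function(h, Lx, Ly) {
  nx <- nrow(h); ny <- ncol(h)
  sx <- Lx / nx; sy <- Ly / ny
  ip <- c(2:nx, 1L); jp <- c(2:ny, 1L)
  h00 <- h; h10 <- h[ip, , drop = FALSE]
  h01 <- h[, jp, drop = FALSE]; h11 <- h[ip, jp, drop = FALSE]
  # triangle (00,10,01): cross((sx,0,h10-h00),(0,sy,h01-h00))
  a1 <- 0.5 * sqrt((sy * (h10 - h00))^2 + (sx * (h01 - h00))^2 + (sx * sy)^2)
  # triangle (10,11,01): edges (0,sy,h11-h10) and (-sx,0,h01-h11)
  a2 <- 0.5 * sqrt((sy * (h11 - h01))^2 + (sx * (h11 - h10))^2 + (sx * sy)^2)
  sum(a1) + sum(a2)
}

#' Willard-Chandler instantaneous surface of the water phase
#'
#' Builds the Gaussian coarse-grained density field of the water oxygens on a
#' periodic voxel grid, estimates the bulk density from the central 20% of
#' the aqueous slab, and extracts the isosurface at `level` x bulk density as
#' a periodic height field (first crossing moving outward from the slab
#' centre), triangulated to give the instantaneous interfacial area.
#'
#' @param frame an [md_frame()].
#' @param water_ids molecule ids of (aqueous) waters.
#' @param params a [wc_params()].
#' @param side `"upper"` (crossing above the slab centre) or `"lower"`.
#' @return object of class `"wc_surface"`: `area` (A^2), `heights` matrix,
#'   `bulk_density`, `level_density`, grid axes, `side`, `frame_time`.
#' @export
willard_chandler <- function(frame, water_ids, params = wc_params(),
                             side = c("upper", "lower")) {
  side <- match.arg(side)
  ox <- .oxygen_table(frame, as.integer(water_ids))
  if (nrow(ox) < 4) stop("too few waters for a density field")
  pos <- as.matrix(ox[, c("x", "y", "z")])
  dg <- .wc_density_grid(pos, frame$box, params)
  zs <- dg$centers[[3]]
  # bulk density over the central 20% (z between the 40% and 60% quantiles
  # of the water oxygens)
  qz <- stats::quantile(pos[, 3], c(0.4, 0.6), names = FALSE)
  zc_idx <- which(zs >= qz[1] & zs <= qz[2])
  if (!length(zc_idx)) zc_idx <- which.min(abs(zs - stats::median(pos[, 3])))
  bulk <- mean(dg$grid[, , zc_idx])
  lev <- params$level * bulk
  kc <- zc_idx[ceiling(length(zc_idx) / 2)]
  nz <- dg$nv[3]
  h <- matrix(NA_real_, dg$nv[1], dg$nv[2])
  for (i in seq_len(dg$nv[1])) for (j in seq_len(dg$nv[2])) {
    prof <- dg$grid[i, j, ]
    # start from the slab centre; if this column is locally dilute there,
    # start from its densest voxel instead
    kc_eff <- if (prof[kc] >= lev) kc else which.max(prof)
    ks <- if (side == "upper") kc_eff:(nz - 1L) else kc_eff:2L
    found <- FALSE
    for (k in ks) {
      k2 <- if (side == "upper") k + 1L else k - 1L
      if (prof[k] >= lev && prof[k2] < lev) {
        f <- (prof[k] - lev) / (prof[k] - prof[k2])
        h[i, j] <- zs[k] + f * (zs[k2] - zs[k])
        found <- TRUE; break
      }
    }
    if (!found)
      stop(sprintf(
        "no isosurface at level %.4g (column density range [%.4g, %.4g]); bulk = %.4g",
        lev, min(prof), max(prof), bulk))
  }
  area <- surface_mesh_area(h, frame$box$L[1], frame$box$L[2])
  structure(list(frame_time = frame$time, side = side, area = area,
                 heights = h, xs = dg$centers[[1]], ys = dg$centers[[2]],
                 bulk_density = bulk, level_density = lev, params = params),
            class = "wc_surface")
}

#' @export
print.wc_surface <- function(x, ...) {
  cat(sprintf("<wc_surface t=%.2f ps, side=%s, area=%.2f A^2, mean z=%.2f A>\n",
              x$frame_time, x$side, x$area, mean(x$heights)))
  invisible(x)
}

#' Export a surface height field as an OBJ-style triangle mesh
#' @param surf a [willard_chandler()] surface.
#' @param path output path.
#' @export
write_surface_obj <- function(surf, path) {
  h <- surf$heights; nx <- nrow(h); ny <- ncol(h)
  con <- file(path, "w"); on.exit(close(con))
  for (j in seq_len(ny)) for (i in seq_len(nx))
    writeLines(sprintf("v %.4f %.4f %.4f", surf$xs[i], surf$ys[j], h[i, j]), con)
  vid <- function(i, j) (j - 1L) * nx + i
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    ip <- if (i == nx) 1L else i + 1L
    jp <- if (j == ny) 1L else j + 1L
    writeLines(sprintf("f %d %d %d", vid(i, j), vid(ip, j), vid(i, jp)), con)
    writeLines(sprintf("f %d %d %d", vid(ip, j), vid(ip, jp), vid(i, jp)), con)
  }
  invisible(path)
}
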