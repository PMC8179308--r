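# Five-region layer assignment and in-plane structure. Regions: bulk_water,
# water_surface (truly interfacial waters), layer1 (octanols HB'd to surface
# waters, heads toward water), layer2 (second intrinsic octanol layer, heads
# toward the organic phase) and bulk_octanol. Waters hydrogen bonded to
# layer1/layer2 octanols inherit the layer label.

REGIONS <- c("bulk_water", "water_surface", "layer1", "layer2", "bulk_octanol")

#' End-to-end orientation cosines of octanols
#'
#' cos(theta) of the molecular end-to-end vector (hydroxyl H -> terminal C,
#' minimum image) against the +z surface normal.
#'
#' @param frame an [md_frame()].
#' @return data frame with `mol`, `cos_theta`, `z` (hydroxyl O height).
#' @export
octanol_orientations <- function(frame) {
  at <- frame$atoms
  oh <- at[at$role == "hydroxyl_H", , drop = FALSE]
  tc <- at[at$role == "terminal_C", , drop = FALSE]
  oo <- at[at$role == "hydroxyl_O", , drop = FALSE]
  oh <- oh[order(oh$mol), ]; tc <- tc[order(tc$mol), ]; oo <- oo[order(oo$mol), ]
  if (!nrow(oh)) return(data.frame(mol = integer(), cos_theta = numeric(),
                                   z = numeric()))
  v <- minimum_image(as.matrix(oh[, c("x", "y", "z")]),
                     as.matrix(tc[, c("x", "y", "z")]), frame$box)
  v <- if (is.null(dim(v))) matrix(v, ncol = 3) else v
  len <- sqrt(rowSums(v^2))
  ok <- len > 1e-12
  if (any(!ok)) warning("skipping octanol(s) with zero-length end-to-end vector")
  data.frame(mol = oh$mol[ok], cos_theta = v[ok, 3] / len[ok], z = oo$z[ok])
}

#' Assign every molecule to one of the five interfacial regions
#'
#' Given the corrected truly-interfacial waters of one interface and the
#' frame's hydrogen-bond graph: surface waters keep the `water_surface`
#' label; octanols hydrogen bonded to them are `layer1`; a second ITIM pass
#' over the remaining octanols, intersected with the orientation criterion
#' (hydroxyl toward the organic phase) and a depth bound, yields `layer2`;
#' non-surface waters HB-attached to layer octanols inherit that layer
#' (majority of HB partners, ties to layer1); everything else is bulk by
#' species (`penetrated` waters count as `bulk_octanol`).
#'
#' @param frame a wrapped [md_frame()].
#' @param surface_waters corrected truly-interfacial water ids (vector or
#'   `surface_set`).
#' @param hbgraph a [detect_hbonds()] graph for the frame.
#' @param penetrated water ids deep in the organic phase (from
#'   [split_penetrated_waters()]).
#' @param water_side `"below"` if the aqueous slab sits at lower z than the
#'   organic phase across this interface, else `"above"`.
#' @param itim [itim_params()] for the octanol-phase pass (direction is set
#'   from `water_side`).
#' @param interface_z reference interface height, Angstrom; default = mean z
#'   of the surface-water oxygens.
#' @param layer2_zmax depth bound for layer2 hydroxyl O beyond `interface_z`,
#'   Angstrom (default 25; roughly the second density-oscillation minimum,
#'   two molecular lengths).
#' @return object of class `"layer_assignment"`: data frame `mol`, `region`
#'   with attributes `frame_time`, `interface_z`.
#' @export
assign_layers <- function(frame, surface_waters, hbgraph,
                          penetrated = integer(),
                          water_side = c("below", "above"),
                          itim = itim_params(grid_spacing = 0.5),
                          interface_z = NULL, layer2_zmax = 25) {
  if (is.null(surface_waters) || is.null(hbgraph))
    stop("assign_layers needs surface waters and an HB graph")
  water_side <- match.arg(water_side)
  sw <- if (inherits(surface_waters, "surface_set")) surface_waters$molecules
        else as.integer(surface_waters)
  sp <- mol_species(frame)
  mols <- as.integer(names(sp))
  octs <- mols[sp == "octanol"]
  waters <- mols[sp == "water"]
  region <- stats::setNames(rep(NA_character_, length(mols)), mols)
  region[as.character(intersect(sw, waters))] <- "water_surface"

  layer1 <- interfacial_octanols(frame, sw, hbgraph)
  region[as.character(layer1)] <- "layer1"

  ooz <- role_positions(frame, "hydroxyl_O")[, 3]
  names(ooz) <- rownames(role_positions(frame, "hydroxyl_O"))
  if (is.null(interface_z)) {
    swO <- role_positions(frame, "water_O")
    interface_z <- mean(swO[rownames(swO) %in% as.character(sw), 3])
  }
  # second intrinsic octanol layer, probing from the water side
  rest <- setdiff(octs, layer1)
  layer2 <- integer(0)
  if (length(rest)) {
    itim$direction <- if (water_side == "below") "up" else "down"
    cand <- itim_layer(frame, rest, itim)$molecules
    ori <- octanol_orientations(frame)
    cosd <- stats::setNames(ori$cos_theta, ori$mol)
    toward_organic <- if (water_side == "below") cosd < 0 else cosd > 0
    depth_ok <- if (water_side == "below")
      ooz >= interface_z - 2 & ooz <= interface_z + layer2_zmax
    else
      ooz <= interface_z + 2 & ooz >= interface_z - layer2_zmax
    keep <- cand[toward_organic[as.character(cand)] &
                   depth_ok[as.character(cand)]]
    layer2 <- sort(keep[!is.na(keep)])
    region[as.character(layer2)] <- "layer2"
  }

  # waters attached to layer octanols inherit the label
  e <- hbgraph$edges
  if (nrow(e)) {
    partner <- rbind(data.frame(w = e$donor, o = e$acceptor),
                     data.frame(w = e$acceptor, o = e$donor))
    partner <- partner[partner$w %in% waters & partner$o %in% c(layer1, layer2), ]
    partner <- partner[is.na(region[as.character(partner$w)]), ]
    if (nrow(partner)) {
      partner$lab <- ifelse(partner$o %in% layer1, "layer1", "layer2")
      for (w in unique(partner$w)) {
        labs <- partner$lab[partner$w == w]
        n1 <- sum(labs == "layer1"); n2 <- sum(labs == "layer2")
        region[as.character(w)] <- if (n2 > n1) "layer2" else "layer1"
      }
    }
  }

  # remaining molecules: bulk by species; penetrated waters sit in octanol
  restw <- waters[is.na(region[as.character(waters)])]
  region[as.character(restw)] <-
    ifelse(restw %in% penetrated, "bulk_octanol", "bulk_water")
  resto <- octs[is.na(region[as.character(octs)])]
  region[as.character(resto)] <- "bulk_octanol"
  region[is.na(region)] <- "bulk_octanol"  # species "other", if any

  structure(data.frame(mol = mols, region = unname(region[as.character(mols)]),
                       stringsAsFactors = FALSE),
            class = c("layer_assignment", "data.frame"),
            frame_time = frame$time, interface_z = interface_z,
            species = stats::setNames(unname(sp[as.character(mols)]), mols))
}

#' Mean orientation cosine vs z
#'
#' Per-bin mean of the octanol end-to-end cos(theta) (hydroxyl H -> terminal
#' C against +z), binned on the hydroxyl O height.
#'
#' @param trajectory an [md_trajectory()] (or single frame).
#' @param bin_width z bin width, Angstrom.
#' @param reference_z optional origin subtracted from z before binning.
#' @return data frame `z` (bin centre), `mean_cos`, `n`.
#' @export
orientation_profile <- function(trajectory, bin_width = 1, reference_z = 0) {
  frames <- if (inherits(trajectory, "md_trajectory")) trajectory$frames
            else list(trajectory)
  rec <- do.call(rbind, lapply(frames, octanol_orientations))
  if (!nrow(rec)) return(data.frame(z = numeric(), mean_cos = numeric(),
                                    n = integer()))
  zb <- floor((rec$z - reference_z) / bin_width)
  agg <- tapply(rec$cos_theta, zb, mean)
  cnt <- tapply(rec$cos_theta, zb, length)
  data.frame(z = (as.numeric(names(agg)) + 0.5) * bin_width,
             mean_cos = as.numeric(agg), n = as.integer(cnt))
}

#' Number-density profile along z
#'
#' @param trajectory an [md_trajectory()] or single frame.
#' @param roles atom roles to count (e.g. `"hydroxyl_O"`), or `NULL` for all
#'   atoms.
#' @param bin_width bin width, Angstrom.
#' @return data frame `z` (bin centre), `density` (atoms / A^3) averaged over
#'   frames. `sum(density) * bin_width * Lx * Ly` equals the mean selected
#'   atom count.
#' @export
density_profile <- function(trajectory, roles = NULL, bin_width = 1) {
  frames <- if (inherits(trajectory, "md_trajectory")) trajectory$frames
            else list(trajectory)
  L <- frames[[1]]$box$L
  nb <- max(1L, as.integer(ceiling(L[3] / bin_width)))
  counts <- numeric(nb)
  for (fr in frames) {
    at <- fr$atoms
    if (!is.null(roles)) at <- at[at$role %in% roles, , drop = FALSE]
    z <- at$z - L[3] * floor(at$z / L[3])
    k <- pmin(floor(z / bin_width), nb - 1L) + 1L
    counts <- counts + tabulate(k, nbins = nb)
  }
  data.frame(z = (seq_len(nb) - 0.5) * bin_width,
             density = counts / (length(frames) * L[1] * L[2] * bin_width))
}

#' Two-dimensional radial distribution function of a layer
#'
#' Histogram of xy-projected minimum-image pair distances between the member
#' molecules' oxygens, normalised by `2 pi r dr rho N` per frame (ordered
#' pairs), periodic in x and y.
#'
#' @param frames list of [md_frame()]s (or an [md_trajectory()], or one frame).
#' @param members molecule ids (vector applied to all frames, or list with one
#'   vector per frame).
#' @param dr bin width, Angstrom (default 0.1).
#' @param r_max histogram range; default `min(Lx, Ly) / 2`.
#' @return object of class `"rdf2d"`: data frame `r`, `g` with attributes
#'   `rho` (mean areal density, A^-2) and `n_mean`.
#' @export
rdf2d <- function(frames, members, dr = 0.1, r_max = NULL) {
  if (inherits(frames, "md_trajectory")) frames <- frames$frames
  if (inherits(frames, "md_frame")) frames <- list(frames)
  if (!is.list(members)) members <- rep(list(members), length(frames))
  L <- frames[[1]]$box$L
  if (is.null(r_max)) r_max <- min(L[1], L[2]) / 2
  nb <- as.integer(ceiling(r_max / dr))
  hist_tot <- numeric(nb); norm_tot <- 0; rho_sum <- 0; n_sum <- 0
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    ox <- .oxygen_table(fr, as.integer(members[[fi]]))
    n <- nrow(ox)
    if (n < 2) stop("rdf2d needs at least two member molecules per frame")
    pos <- as.matrix(ox[, c("x", "y", "z")])
    rho <- n / (L[1] * L[2])
    # all unordered pairs, xy minimum image
    idx <- utils::combn(n, 2L)
    dxy <- minimum_image(pos[idx[1, ], , drop = FALSE],
                         pos[idx[2, ], , drop = FALSE], fr$box)
    dxy <- if (is.null(dim(dxy))) matrix(dxy, ncol = 3) else dxy
    r <- sqrt(dxy[, 1]^2 + dxy[, 2]^2)
    k <- floor(r / dr) + 1L
    k <- k[r < r_max]
    hist_tot <- hist_tot + 2 * tabulate(k, nbins = nb)  # ordered pairs
    norm_tot <- norm_tot + n
    rho_sum <- rho_sum + rho; n_sum <- n_sum + n
  }
  rc <- (seq_len(nb) - 0.5) * dr
  rho_bar <- rho_sum / length(frames)
  shell <- 2 * pi * rc * dr
  g <- hist_tot / (norm_tot * rho_bar * shell)
  structure(data.frame(r = rc, g = g), class = c("rdf2d", "data.frame"),
            rho = rho_bar, n_mean = n_sum / length(frames), dr = dr)
}

#' Excess coordination number from a 2D RDF
#'
#' `N_excess(r) = rho * integral_0^r (g - 1) 2 pi r' dr'` by trapezoidal
#' quadrature (two-dimensional specialisation of the Kirkwood-Buff excess
#' count). Negative values indicate depletion relative to a uniform layer.
#'
#' @param rdf an [rdf2d()] result.
#' @return object of class `"ecn_curve"`: data frame `r`, `n_excess`, starting
#'   at `n_excess(0) = 0`.
#' @export
ecn <- function(rdf) {
  stopifnot(inherits(rdf, "rdf2d"))
  rho <- attr(rdf, "rho")
  r <- c(0, rdf$r)
  f <- c(0, (rdf$g - 1) * 2 * pi * rdf$r)  # integrand -> 0 at r = 0
  cumint <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(r)))
  structure(data.frame(r = r, n_excess = rho * cumint),
            class = c("ecn_curve", "data.frame"))
}

#' Surface packing density
#'
#' Per-frame molecule count divided by instantaneous surface area, averaged
#' over frames and reported per nm^2.
#'
#' @param counts per-frame molecule counts (e.g. layer1 octanols).
#' @param areas per-frame surface areas, Angstrom^2 (e.g. Willard-Chandler).
#' @return list with `mean` (molecules / nm^2), `per_frame`, and `sem`
#'   (3-block standard error when >= 3 frames).
#' @export
packing_density <- function(counts, areas) {
  stopifnot(length(counts) == length(areas))
  if (any(areas <= 0)) stop("zero or negative surface area")
  pf <- counts / areas * 100  # A^-2 -> nm^-2
  list(mean = mean(pf), per_frame = pf,
       sem = if (length(pf) >= 3) block_sem(pf, 3) else NA_real_)
}

#' Bilayer islands in Layer-2
#'
#' O-O cutoff clusters restricted to layer2 members (octanols plus their
#' HB-attached waters as labelled by [assign_layers()]); an island requires
#' at least two octanols.
#'
#' @param assignment a [assign_layers()] result.
#' @param frame the corresponding [md_frame()].
#' @param cutoff O-O clustering cutoff, Angstrom.
#' @return list of islands, each with `members`, `octanol_count`,
#'   `water_count`, `frame_time`.
#' @export
find_bilayer_islands <- function(assignment, frame, cutoff = 3.5) {
  mem <- assignment$mol[assignment$region == "layer2"]
  if (!length(mem)) return(list())
  cls <- find_clusters(frame, mem, cutoff = cutoff)
  isl <- Filter(function(cl) cl$n_octanol >= 2, cls)
  lapply(isl, function(cl)
    structure(list(members = cl$members, octanol_count = cl$n_octanol,
                   water_count = cl$n_water, frame_time = cl$frame_time),
              class = "bilayer_island"))
}

#' Construct a layer assignment directly
#'
#' Used by the synthetic generator (ground-truth labels) and in tests.
#'
#' @param mol molecule ids.
#' @param region region labels (one of the five regions) per molecule.
#' @param time frame time, ps.
#' @param species optional species per molecule (named by `mol` if given).
#' @return a `layer_assignment` like [assign_layers()] produces.
#' @export
layer_assignment <- function(mol, region, time = 0, species = NULL) {
  stopifnot(length(mol) == length(region), all(region %in% REGIONS))
  if (!is.null(species)) species <- stats::setNames(unname(species), mol)
  structure(data.frame(mol = as.integer(mol), region = as.character(region),
                       stringsAsFactors = FALSE),
            class = c("layer_assignment", "data.frame"),
            frame_time = time, interface_z = NA_real_, species = species)
}

# 3-block standard error of the mean of a series
block_sem <- function(x, n_blocks = 3) {
  n <- length(x)
  if (n < n_blocks) return(NA_real_)
  cuts <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  bm <- tapply(x, cuts, mean)
  stats::sd(bm) / sqrt(n_blocks)
}
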