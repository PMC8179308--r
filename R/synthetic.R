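# Synthetic biphasic slabs, scripted transport-event trajectories with ground
# truth, and pressure-tensor series. The generator states a world matching the
# analysed system: a water slab under an octanol phase with a corrugated
# boundary, Layer-1 octanols hydrogen bonded to surface waters at ~45 deg
# mean tilt, Layer-2 "bilayer islands" (rings of 2.8 A O-O spaced octanols
# with attached waters, heads toward the organic phase), sparse bulk octanol
# and optional deeply penetrated waters. All generators are deterministic
# under a fixed seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# geometry constants (Angstrom)
.OH_BOND <- 0.9572      # water O-H
.HOH_DEG <- 104.52
.OCT_OH <- 0.97         # octanol O-H
.OCT_CC <- 1.5          # C-C spacing along the elongated chain
.HB_OO <- 2.8           # planted donor-acceptor O...O distance

# water atom rows; h1dir = unit vector of the first O-H bond
.water_atoms <- function(mol, opos, h1dir, atom0) {
  u <- .perp_unit(h1dir)
  a <- .HOH_DEG * pi / 180
  h2dir <- cos(a) * h1dir + sin(a) * u
  data.frame(atom = atom0 + 0:2, mol = mol, species = "water",
             role = c("water_O", "water_H", "water_H"),
             element = c("O", "H", "H"),
             x = opos[1] + c(0, .OH_BOND * h1dir[1], .OH_BOND * h2dir[1]),
             y = opos[2] + c(0, .OH_BOND * h1dir[2], .OH_BOND * h2dir[2]),
             z = opos[3] + c(0, .OH_BOND * h1dir[3], .OH_BOND * h2dir[3]),
             stringsAsFactors = FALSE)
}

# octanol as a 10-site elongated chain along unit axis m (hydroxyl H -> C8
# direction); hydroxyl H sits at O - 0.97 m so the end-to-end cos(theta)
# equals m's z component exactly.
.octanol_atoms <- function(mol, opos, m, atom0) {
  k <- 1:8
  px <- c(opos[1], opos[1] - .OCT_OH * m[1], opos[1] + .OCT_CC * k * m[1])
  py <- c(opos[2], opos[2] - .OCT_OH * m[2], opos[2] + .OCT_CC * k * m[2])
  pz <- c(opos[3], opos[3] - .OCT_OH * m[3], opos[3] + .OCT_CC * k * m[3])
  data.frame(atom = atom0 + 0:9, mol = mol, species = "octanol",
             role = c("hydroxyl_O", "hydroxyl_H", rep("chain_C", 7), "terminal_C"),
             element = c("O", "H", rep("C", 8)),
             x = px, y = py, z = pz, stringsAsFactors = FALSE)
}

.perp_unit <- function(v) {
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- u - sum(u * v) * v
  w / sqrt(sum(w^2))
}

.rand_unit <- function(n = 1) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# unit axis with given polar angle (cos = cz) and random azimuth
.tilted_axis <- function(cz) {
  s <- sqrt(max(0, 1 - cz^2))
  phi <- stats::runif(1, 0, 2 * pi)
  c(s * cos(phi), s * sin(phi), cz)
}

#' Generate a biphasic slab with planted interfacial structure
#'
#' Water fills `z` below a (possibly corrugated) boundary
#' `zb(x) = boundary_z + amplitude * sin(2 pi x / wavelength)`; octanol sits
#' above. Planted: Layer-1 octanols hydrogen bonded to surface waters at the
#' given mean tilt, Layer-2 bilayer islands (octanol rings with attached
#' waters, heads toward the organic phase), sparse randomly oriented bulk
#' octanol, and isolated penetrated waters >= 15 A past the boundary.
#'
#' @param box a [box3()] (default 40 x 40 x 120 A).
#' @param boundary_z mean boundary height, Angstrom.
#' @param amplitude,wavelength boundary corrugation, Angstrom.
#' @param water_spacing aqueous lattice constant (default 3.1 A, liquid
#'   water's number density).
#' @param n_layer1 Layer-1 octanol count; default targets the observed
#'   2.80 molecules/nm^2 surface packing.
#' @param island_sizes octanol count per planted Layer-2 island.
#' @param island_loading_slope waters per island = `round(slope * size)`
#'   (linear loading rule; default 0.4 gives the observed 1-3 waters on
#'   4-5 octanol islands).
#' @param tilt_mean_deg,tilt_sd_deg Layer-1 axis tilt from the normal
#'   (default 45 +/- 5 deg, i.e. mean cos(theta) ~ 0.707).
#' @param n_penetrated isolated waters planted deep in the octanol phase.
#' @param bulk_octanol_spacing lattice constant of the bulk octanol region
#'   (`NULL` for none).
#' @param jitter uniform positional jitter on lattice waters, Angstrom.
#' @param seed RNG seed.
#' @return list with `frame` (an [md_frame()]), and `truth`: a
#'   [layer_assignment()] of ground-truth regions, `surface_waters`,
#'   `layer1`, `layer2`, `islands` (list of member vectors), `penetrated`,
#'   `interface_z`, and counts.
#' @export
gen_slab <- function(box = box3(40, 40, 120), boundary_z = 60,
                     amplitude = 0, wavelength = 40,
                     water_spacing = 3.1, n_layer1 = NULL,
                     island_sizes = c(4, 4, 5), island_loading_slope = 0.4,
                     tilt_mean_deg = 45, tilt_sd_deg = 5,
                     n_penetrated = 0, bulk_octanol_spacing = 6.5,
                     jitter = 0.25, seed = 1) .with_seed(seed, {
  L <- box$L
  if (amplitude >= boundary_z / 2) stop("roughness amplitude too large for slab")
  zb <- function(x) boundary_z + amplitude * sin(2 * pi * x / wavelength)
  a <- water_spacing
  # commensurate xy lattice: no vacuum channel at the periodic boundary
  nxw <- max(1L, round(L[1] / a)); nyw <- max(1L, round(L[2] / a))
  xs <- (seq_len(nxw) - 0.5) * L[1] / nxw
  ys <- (seq_len(nyw) - 0.5) * L[2] / nyw
  rows <- list(); mol <- 0L; atom0 <- 1L
  region <- character(0); species <- character(0)
  surface_waters <- integer(0)
  add <- function(df, reg) {
    rows[[length(rows) + 1L]] <<- df
    region <<- c(region, reg); species <<- c(species, df$species[1])
    atom0 <<- atom0 + nrow(df)
  }
  # aqueous slab: jittered lattice columns up to the boundary
  top_water <- list()
  for (x in xs) for (y in ys) {
    ztop <- zb(x) - 1.2
    zs <- seq(1.6, ztop, by = a)
    for (zi in seq_along(zs)) {
      mol <- mol + 1L
      p <- c(x, y, zs[zi]) + stats::runif(3, -jitter, jitter)
      is_top <- zi == length(zs)
      hdir <- if (is_top) c(0, 0, 1) else .rand_unit()
      add(.water_atoms(mol, p, drop(hdir), atom0),
          if (is_top) "water_surface" else "bulk_water")
      if (is_top) {
        surface_waters <- c(surface_waters, mol)
        top_water[[length(top_water) + 1L]] <- c(mol, p)
      }
    }
  }
  tw <- do.call(rbind, top_water)
  # Layer-1 octanols: heads HB'd to chosen surface waters (the water's first
  # H already points straight up at the incoming hydroxyl O)
  if (is.null(n_layer1)) n_layer1 <- round(2.80 * L[1] * L[2] / 100)
  n_layer1 <- min(n_layer1, nrow(tw))
  pick <- sample(nrow(tw), n_layer1)
  layer1 <- integer(0)
  for (i in pick) {
    mol <- mol + 1L
    opos <- tw[i, 2:4] + c(0, 0, .HB_OO)
    cz <- cos(pi / 180 * stats::rnorm(1, tilt_mean_deg, tilt_sd_deg))
    add(.octanol_atoms(mol, opos, .tilted_axis(cz), atom0), "layer1")
    layer1 <- c(layer1, mol)
  }
  # Layer-2 bilayer islands: rings of octanols (O-O chord 2.8 A), heads up
  # (toward the organic phase), planted waters on an inner ring
  islands <- list(); layer2 <- integer(0)
  if (length(island_sizes)) {
    k <- length(island_sizes)
    gx <- seq(L[1] / (k + 1), by = L[1] / (k + 1), length.out = k)
    gy <- rep(L[2] / 2, k)
    for (ii in seq_len(k)) {
      n <- island_sizes[ii]
      cx <- gx[ii]; cy <- gy[ii]; czl <- zb(cx) + 14
      rring <- if (n > 1) (.HB_OO / 2) / sin(pi / n) else 0
      mem <- integer(0)
      ophi <- stats::runif(1, 0, 2 * pi)
      opos_list <- lapply(seq_len(n), function(j) {
        th <- ophi + 2 * pi * j / n
        c(cx + rring * cos(th), cy + rring * sin(th), czl)
      })
      for (j in seq_len(n)) {
        mol <- mol + 1L
        cz <- cos(pi / 180 * stats::rnorm(1, 180 - tilt_mean_deg, tilt_sd_deg))
        add(.octanol_atoms(mol, opos_list[[j]], .tilted_axis(cz), atom0), "layer2")
        mem <- c(mem, mol)
      }
      m_wat <- max(1L, as.integer(round(island_loading_slope * n)))
      # waters sit 2 A below the head-group ring at HB range from the Os
      rwat <- if (m_wat > 1) max(1.0, rring - 2.2) else max(0, rring - 2.2)
      for (j in seq_len(m_wat)) {
        mol <- mol + 1L
        th <- 2 * pi * j / m_wat
        wp <- c(cx + rwat * cos(th), cy + rwat * sin(th), czl - 2)
        # donate toward the nearest island octanol O
        d <- t(vapply(opos_list, function(p) p - wp, numeric(3)))
        nn <- which.min(rowSums(d^2))
        add(.water_atoms(mol, wp, d[nn, ] / sqrt(sum(d[nn, ]^2)), atom0), "layer2")
        mem <- c(mem, mol)
      }
      islands[[ii]] <- mem
      layer2 <- c(layer2, mem)
    }
  }
  # penetrated waters: isolated, >= 15 A past the boundary, away from islands
  penetrated <- integer(0)
  if (n_penetrated > 0) {
    px <- seq(a, L[1] - a, length.out = n_penetrated + 2)[-c(1, n_penetrated + 2)]
    for (i in seq_len(n_penetrated)) {
      mol <- mol + 1L
      p <- c(px[i], L[2] / 8, zb(px[i]) + 15 + 2 * i)
      add(.water_atoms(mol, p, drop(.rand_unit()), atom0), "bulk_octanol")
      penetrated <- c(penetrated, mol)
    }
  }
  # sparse bulk octanol, random orientation, below the box top
  if (!is.null(bulk_octanol_spacing)) {
    s <- bulk_octanol_spacing
    bx <- seq(s / 2, L[1] - s / 4, by = s)
    by <- seq(s / 2, L[2] - s / 4, by = s)
    bz <- seq(boundary_z + amplitude + 26, L[3] - 12, by = s)
    if (length(bz)) for (x in bx) for (y in by) for (z in bz) {
      mol <- mol + 1L
      p <- c(x, y, z) + stats::runif(3, -jitter, jitter)
      add(.octanol_atoms(mol, p, drop(.rand_unit()), atom0), "bulk_octanol")
    }
  }
  at <- do.call(rbind, rows)
  frame <- wrap_frame(md_frame(at, box, time = 0))
  mols <- unique(at$mol)
  truth <- layer_assignment(mols, region, time = 0, species = species)
  list(frame = frame,
       truth = list(assignment = truth, surface_waters = surface_waters,
                    layer1 = layer1, layer2 = layer2, islands = islands,
                    penetrated = penetrated, interface_z = boundary_z,
                    n_water = sum(species == "water"),
                    n_octanol = sum(species == "octanol")))
})

#' Scripted transport-event specification
#'
#' @param mechanism per event: `"diffusion"`, `"flip"` or `"hinge"`.
#' @param direction per event: `"L1->L2"`, `"L2->L1"`, `"L2->bulk"`,
#'   `"bulk->L2"` or `"bulkW->surface"` (the latter three diffusion only).
#' @param t_start event start times, ps.
#' @param duration event durations, ps.
#' @param n_oct carrier octanols (0 for diffusion, 1 for flip, >= 2 hinge).
#' @param m_water carrier waters (>= 1 except flips may carry 0).
#' @return validated `event_script` data frame.
#' @export
event_script <- function(mechanism, direction, t_start, duration,
                         n_oct, m_water) {
  d <- data.frame(mechanism = mechanism, direction = direction,
                  t_start = t_start, duration = duration,
                  n_oct = as.integer(n_oct), m_water = as.integer(m_water),
                  stringsAsFactors = FALSE)
  ok_dir <- d$direction %in% c("L1->L2", "L2->L1", "L2->bulk", "bulk->L2",
                               "bulkW->surface")
  if (!all(ok_dir)) stop("unknown direction(s)")
  bad <- (d$mechanism == "diffusion" & d$n_oct != 0L) |
    (d$mechanism == "flip" & (d$n_oct != 1L | d$m_water > 1L)) |
    (d$mechanism == "hinge" & d$n_oct < 2L) |
    (d$mechanism != "flip" & d$m_water < 1L) |
    (d$mechanism != "diffusion" & !d$direction %in% c("L1->L2", "L2->L1"))
  if (any(bad)) stop("carrier composition inconsistent with mechanism for event(s) ",
                     paste(which(bad), collapse = ", "))
  structure(d, class = c("event_script", "data.frame"))
}

# rotation of row-vectors about the y axis by angle phi (radians)
.rot_y <- function(p, phi) {
  c_ <- cos(phi); s_ <- sin(phi)
  cbind(c_ * p[, 1] + s_ * p[, 3], p[, 2], -s_ * p[, 1] + c_ * p[, 3])
}

#' Generate a trajectory with scripted, ground-truth-labelled transport events
#'
#' Each event gets its own xy site (30 A grid) and its own molecules. Hinge
#' carriers move as rigid hydrogen-bond-intact clusters rotating about a
#' pivot in the Layer-1 plane; flips reorient a single octanol in place;
#' diffusing waters traverse without approaching any octanol. Region labels
#' (the ground truth) switch at the frame where the moving group crosses the
#' half-height between the Layer-1 and Layer-2 stations.
#'
#' @param script an [event_script()].
#' @param n_frames frames in the trajectory.
#' @param sampling frame spacing, ps (default 10, the production sampling).
#' @param boundary_z interface height, Angstrom.
#' @param seed RNG seed (used only for tiny background jitter).
#' @param n_background_waters optional block of inert aqueous waters.
#' @return list with `trajectory` ([md_trajectory()]), `assignments` (ground
#'   truth, one [layer_assignment()] per frame) and `events` (ground-truth
#'   table with molecule ids).
#' @export
gen_event_trajectory <- function(script, n_frames = 12, sampling = 10,
                                 boundary_z = 30, seed = 1,
                                 n_background_waters = 0) .with_seed(seed, {
  stopifnot(inherits(script, "event_script"))
  ne <- nrow(script)
  t_end <- script$t_start + script$duration
  if (any(script$t_start < sampling) ||
      any(t_end > (n_frames - 2) * sampling))
    stop("events must start after the first frame and end before the last")
  nx <- ceiling(sqrt(ne + (n_background_waters > 0)))
  spacing <- 30
  Lxy <- max(60, nx * spacing)
  box <- box3(Lxy, Lxy, 2 * boundary_z + 60)
  sites <- as.matrix(expand.grid(x = seq(spacing / 2, Lxy, by = spacing),
                                 y = seq(spacing / 2, Lxy, by = spacing)))
  h1 <- 2.8; h2 <- 14  # Layer-1 / Layer-2 head heights above the boundary
  hmid <- (h1 + h2) / 2
  times <- (seq_len(n_frames) - 1) * sampling

  # per-event static template + motion functions. Each event is built inside
  # its own function call so the place() closures capture private state.
  build_event <- function(sc, site, mol, atom0) {
    sc <- as.list(sc); site <- as.numeric(site)  # force promises eagerly
    fwd <- sc$direction %in% c("L1->L2", "bulk->L2")  # toward organic
    mech <- sc$mechanism
    t0 <- sc$t_start; t1 <- sc$t_start + sc$duration
    e <- list(mols = integer(0), water_ids = integer(0), oct_ids = integer(0),
              mech = mech, dir = sc$direction, t0 = t0, t1 = t1)
    if (mech == "hinge") {
      n <- sc$n_oct; m <- sc$m_water
      rring <- (.HB_OO / 2) / sin(pi / n)
      local <- list()
      for (j in seq_len(n)) {
        th <- 2 * pi * j / n
        op <- c(rring * cos(th), rring * sin(th), 0)
        mol <- mol + 1L
        local[[length(local) + 1L]] <-
          list(df = .octanol_atoms(mol, op, c(0, 0, 1), atom0), mol = mol,
               water = FALSE)
        atom0 <- atom0 + 10L
        e$oct_ids <- c(e$oct_ids, mol); e$mols <- c(e$mols, mol)
      }
      rwat <- if (m > 1) max(1.0, rring - 2.2) else max(0, rring - 2.2)
      for (j in seq_len(m)) {
        th <- 2 * pi * j / m + pi / m
        wp <- c(rwat * cos(th), rwat * sin(th), -2)
        # donor H toward the first octanol O
        op1 <- c(rring * cos(2 * pi / n), rring * sin(2 * pi / n), 0)
        hdir <- (op1 - wp); hdir <- hdir / sqrt(sum(hdir^2))
        mol <- mol + 1L
        local[[length(local) + 1L]] <-
          list(df = .water_atoms(mol, wp, hdir, atom0), mol = mol, water = TRUE)
        atom0 <- atom0 + 3L
        e$water_ids <- c(e$water_ids, mol); e$mols <- c(e$mols, mol)
      }
      tmpl <- do.call(rbind, lapply(local, `[[`, "df"))
      d <- 14.5
      phi_of_h <- function(h) acos(pmin(1, h / d))
      ph_a <- phi_of_h(h1); ph_b <- phi_of_h(h2)
      phis <- if (fwd) c(ph_a, ph_b) else c(ph_b, ph_a)
      e$place <- function(t) {
        f <- min(1, max(0, (t - t0) / (t1 - t0)))
        phi <- phis[1] + f * (phis[2] - phis[1])
        p <- as.matrix(tmpl[, c("x", "y", "z")])
        # template centred at origin; lift to pivot frame then rotate
        p[, 3] <- p[, 3] + d
        p <- .rot_y(p, phi)
        p[, 1] <- p[, 1] + site[1]; p[, 2] <- p[, 2] + site[2]
        p[, 3] <- p[, 3] + boundary_z
        out <- tmpl; out$x <- p[, 1]; out$y <- p[, 2]; out$z <- p[, 3]
        height <- d * cos(phi)
        lab <- if (height < hmid) "layer1" else "layer2"
        list(atoms = out, labels = stats::setNames(rep(lab, length(e$mols)),
                                                   e$mols))
      }
    } else if (mech == "flip") {
      mol <- mol + 1L; oct_id <- mol
      e$oct_ids <- oct_id; e$mols <- oct_id
      opos <- c(site[1], site[2], boundary_z + 6)
      wdf <- NULL
      if (sc$m_water == 1L) {
        mol <- mol + 1L
        wpos <- opos + c(0, .HB_OO, 0)
        hdir <- c(0, -1, 0)
        wdf <- .water_atoms(mol, wpos, hdir, atom0 + 10L)
        e$water_ids <- mol; e$mols <- c(e$mols, mol)
      }
      a0 <- atom0
      atom0 <- atom0 + 10L + if (is.null(wdf)) 0L else 3L
      cz0 <- if (fwd) cos(pi / 4) else -cos(pi / 4)
      e$place <- function(t) {
        f <- min(1, max(0, (t - t0) / (t1 - t0)))
        cz <- cz0 * (1 - 2 * f)  # linear cos interpolation through 0
        s <- sqrt(max(0, 1 - cz^2))
        df <- .octanol_atoms(oct_id, opos, c(s, 0, cz), a0)
        lab1 <- if (cz > 0) "layer1" else "layer2"
        labs <- stats::setNames(lab1, oct_id)
        if (!is.null(wdf)) {
          df <- rbind(df, wdf)
          labs <- c(labs, stats::setNames(lab1, e$water_ids))
        }
        list(atoms = df, labels = labs)
      }
    } else {  # diffusion
      mol <- mol + 1L; wid <- mol
      e$water_ids <- wid; e$mols <- wid
      stations <- switch(sc$direction,
        "L1->L2" = c(h1, h2, "layer1", "layer2"),
        "L2->L1" = c(h2, h1, "layer2", "layer1"),
        "L2->bulk" = c(h2, 28, "layer2", "bulk_octanol"),
        "bulk->L2" = c(28, h2, "bulk_octanol", "layer2"),
        "bulkW->surface" = c(-10, -1.2, "bulk_water", "water_surface"))
      za <- as.numeric(stations[1]); zbnd <- as.numeric(stations[2])
      a0 <- atom0; atom0 <- atom0 + 3L
      e$place <- function(t) {
        f <- min(1, max(0, (t - t0) / (t1 - t0)))
        z <- boundary_z + za + f * (zbnd - za)
        df <- .water_atoms(wid, c(site[1], site[2], z), c(0, 0, 1), a0)
        lab <- if (f < 0.5) stations[3] else stations[4]
        list(atoms = df, labels = stats::setNames(lab, wid))
      }
    }
    list(e = e, mol = mol, atom0 = atom0)
  }
  ev <- vector("list", ne)
  mol <- 0L; atom0 <- 1L
  for (i in seq_len(ne)) {
    built <- build_event(script[i, ], sites[i, ], mol, atom0)
    ev[[i]] <- built$e; mol <- built$mol; atom0 <- built$atom0
  }
  # optional inert background water block on the last site
  bg <- NULL
  if (n_background_waters > 0) {
    site <- sites[ne + 1, ]
    bgl <- list()
    for (j in seq_len(n_background_waters)) {
      mol <- mol + 1L
      p <- c(site[1] + 3.1 * ((j - 1) %% 3), site[2] + 3.1 * ((j - 1) %/% 3),
             boundary_z - 5)
      bgl[[j]] <- .water_atoms(mol, p, drop(.rand_unit()), atom0)
      atom0 <- atom0 + 3L
    }
    bg <- do.call(rbind, bgl)
  }

  frames <- vector("list", n_frames)
  assignments <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    t <- times[fi]
    placed <- lapply(ev, function(e) e$place(t))
    at <- do.call(rbind, c(lapply(placed, `[[`, "atoms"), list(bg)))
    at <- at[order(at$mol), ]
    labs <- do.call(c, lapply(placed, `[[`, "labels"))
    if (!is.null(bg)) {
      bglab <- stats::setNames(rep("bulk_water", length(unique(bg$mol))),
                               unique(bg$mol))
      labs <- c(labs, bglab)
    }
    labs <- labs[order(as.integer(names(labs)))]
    frames[[fi]] <- wrap_frame(md_frame(at, box, time = t))
    sp <- at$species[!duplicated(at$mol)][order(unique(at$mol))]
    assignments[[fi]] <- layer_assignment(as.integer(names(labs)),
                                          unname(labs), time = t,
                                          species = sp)
  }
  events <- do.call(rbind, lapply(seq_len(ne), function(i) {
    e <- ev[[i]]
    data.frame(event_id = i, mechanism = e$mech, direction = e$dir,
               t_start = e$t0, t_end = e$t1,
               n_octanol = length(e$oct_ids),
               m_water = length(e$water_ids),
               water_ids = paste(e$water_ids, collapse = ";"),
               octanol_ids = paste(e$oct_ids, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  list(trajectory = md_trajectory(frames, sampling),
       assignments = assignments, events = events, box = box)
})

#' Generate a stationary pressure-tensor series with planted anisotropy
#'
#' Tangential components are held at `P0`; the normal component is
#' `P0 + mean_anisotropy + N(0, noise_sd)`.
#'
#' @param mean_anisotropy planted mean of `Pzz - (Pxx + Pyy)/2`, bar.
#' @param noise_sd Gaussian noise on `Pzz`, bar.
#' @param n samples (>= 3).
#' @param Lz box height, Angstrom.
#' @param seed RNG seed.
#' @param P0 baseline pressure, bar.
#' @param dt sample spacing, ps.
#' @return a [pressure_series()].
#' @export
gen_pressure_series <- function(mean_anisotropy, noise_sd, n, Lz,
                                seed = 1, P0 = 1.0, dt = 10) .with_seed(seed, {
  if (n < 3) stop("need n >= 3")
  pressure_series(times = (seq_len(n) - 1) * dt,
                  Pxx = rep(P0, n), Pyy = rep(P0, n),
                  Pzz = P0 + mean_anisotropy + stats::rnorm(n, 0, noise_sd),
                  Lz = Lz)
})
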