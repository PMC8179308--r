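# Region-transition tracking and mechanism classification. Each water
# transfer between interfacial regions is classified by the composition of
# the hydrogen-bonded carrier cluster around the crossing: no octanol =>
# plain diffusion; exactly one octanol that itself changes layer =>
# stochastic flip; two or more octanols => collective hinge transport.

GAS_CONSTANT_KCAL <- 1.98720425864083e-3  # kcal / (mol K)

# assignments: list of layer_assignment -> list(mat[mol, frame], mols, times)
.assign_matrix <- function(assignments) {
  mols <- assignments[[1]]$mol
  mat <- vapply(assignments, function(a) {
    if (!identical(a$mol, mols)) stop("assignment rosters differ across frames")
    a$region
  }, character(length(mols)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(mols))
  times <- vapply(assignments, function(a) attr(a, "frame_time"), 0)
  list(mat = mat, mols = mols, times = times)
}

#' Detect persistent region transitions
#'
#' A transition is recorded when a molecule's region differs between
#' consecutive frames and the new region persists for at least `persistence`
#' frames; shorter excursions (flicker) are debounced away. The transition is
#' timestamped at the first frame of the new region.
#'
#' @param assignments list of [assign_layers()] results, time ordered.
#' @param persistence minimum run length, frames (default 1 = no debounce).
#' @return data frame `mol`, `from`, `to`, `frame` (index of the first frame
#'   in the new region), `time` (ps).
#' @export
detect_transitions <- function(assignments, persistence = 1) {
  if (length(assignments) < 2L) stop("need at least two assigned frames")
  am <- .assign_matrix(assignments)
  out <- vector("list", length(am$mols))
  for (mi in seq_along(am$mols)) {
    labs <- am$mat[mi, ]
    r <- rle(labs)
    keep <- r$lengths >= persistence
    if (sum(keep) < 2L) next
    vals <- r$values[keep]
    starts <- (cumsum(r$lengths) - r$lengths + 1L)[keep]
    # merge adjacent kept runs with the same label
    dup <- c(FALSE, vals[-1] == vals[-length(vals)])
    vals <- vals[!dup]; starts <- starts[!dup]
    if (length(vals) < 2L) next
    out[[mi]] <- data.frame(mol = am$mols[mi],
                            from = vals[-length(vals)], to = vals[-1],
                            frame = starts[-1], time = am$times[starts[-1]])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(mol = integer(), from = character(),
                                      to = character(), frame = integer(),
                                      time = numeric())
  res[order(res$frame, res$mol), , drop = FALSE]
}

.DIRECTIONS <- c("layer1->layer2" = "L1->L2", "layer2->layer1" = "L2->L1",
                 "layer2->bulk_octanol" = "L2->bulk",
                 "bulk_octanol->layer2" = "bulk->L2",
                 "bulk_water->water_surface" = "bulkW->surface")

# carrier cluster of `water` at one frame: connected O-O component among the
# interfacial members (layer1/layer2 octanols, layer/surface waters)
.carrier_at <- function(water, frame, assignment) {
  lay <- assignment$mol[assignment$region %in% c("layer1", "layer2")]
  swf <- assignment$mol[assignment$region == "water_surface"]
  sp <- mol_species(frame)
  members <- unique(c(lay, intersect(swf, as.integer(names(sp)[sp == "water"])),
                      water))
  cls <- find_clusters(frame, members)
  for (cl in cls) if (water %in% cl$members) return(cl)
  structure(list(members = water, n_octanol = 0L, n_water = 1L,
                 frame_time = frame$time), class = "molecule_cluster")
}

#' Classify water transfer events by mechanism
#'
#' For every water region transition among the transport directions, the
#' hydrogen-bonded carrier cluster containing the water is inspected over a
#' window around the crossing; the maximal composition (most octanols, then
#' most waters) is recorded. Mechanism: `>= 2` carrier octanols => `hinge`;
#' exactly one octanol that itself changes layer in the window => `flip`;
#' otherwise `diffusion`. Waters sharing a carrier octanol, direction and an
#' overlapping window are merged into a single event.
#'
#' @param transitions output of [detect_transitions()].
#' @param frames list of [md_frame()]s (or an [md_trajectory()]).
#' @param assignments list of [assign_layers()] results, one per frame.
#' @param window frames inspected on either side of the crossing (default 1).
#' @return list of `transport_event` objects: `water_ids`, `direction`,
#'   `t_start`, `t_end`, `n_octanol`, `n_water` (carrier composition),
#'   `carrier` members, `mechanism`.
#' @export
classify_transfers <- function(transitions, frames, assignments, window = 1) {
  if (inherits(frames, "md_trajectory")) frames <- frames$frames
  nf <- length(frames)
  if (length(assignments) != nf) stop("need one assignment per frame")
  am <- .assign_matrix(assignments)
  sp <- mol_species(frames[[1]])
  key <- paste(transitions$from, transitions$to, sep = "->")
  tr <- transitions[key %in% names(.DIRECTIONS) &
                      sp[as.character(transitions$mol)] == "water", , drop = FALSE]
  raw <- list()
  for (r in seq_len(nrow(tr))) {
    f0 <- tr$frame[r]
    idx <- max(1L, f0 - 1L - window):min(nf, f0 + window)
    best <- NULL
    oct_layers <- NULL
    for (fi in idx) {
      cl <- .carrier_at(tr$mol[r], frames[[fi]], assignments[[fi]])
      if (is.null(best) || cl$n_octanol > best$n_octanol ||
          (cl$n_octanol == best$n_octanol && cl$n_water > best$n_water))
        best <- cl
    }
    octs <- best$members[sp[as.character(best$members)] == "octanol"]
    mech <- if (best$n_octanol >= 2) "hinge"
    else if (best$n_octanol == 1) {
      mrow <- match(octs[1], am$mols)
      labs <- am$mat[mrow, idx]
      labs <- labs[labs %in% c("layer1", "layer2")]
      if (length(unique(labs)) > 1) "flip" else "diffusion"
    } else "diffusion"
    raw[[r]] <- list(water = tr$mol[r], frame = f0,
                     direction = unname(.DIRECTIONS[paste(tr$from[r], tr$to[r],
                                                          sep = "->")]),
                     idx = idx, carrier = best, octs = octs, mechanism = mech)
  }
  # merge co-transferred waters: same direction + shared carrier octanol +
  # overlapping windows
  merged <- list()
  used <- rep(FALSE, length(raw))
  for (i in seq_along(raw)) {
    if (used[i]) next
    grp <- i
    if (length(raw[[i]]$octs)) {
      for (j in seq_along(raw)) {
        if (j == i || used[j] || raw[[j]]$direction != raw[[i]]$direction) next
        if (length(intersect(raw[[j]]$octs, raw[[i]]$octs)) &&
            length(intersect(raw[[j]]$idx, raw[[i]]$idx)))
          grp <- c(grp, j)
      }
    }
    used[grp] <- TRUE
    members <- raw[grp]
    carrier <- members[[which.max(vapply(members, function(m)
      m$carrier$n_octanol * 1e6 + m$carrier$n_water, 0))]]$carrier
    fr_span <- range(unlist(lapply(members, function(m) m$idx)))
    merged[[length(merged) + 1L]] <- structure(list(
      water_ids = sort(unique(vapply(members, function(m) m$water, 0L))),
      direction = raw[[i]]$direction,
      t_start = am$times[fr_span[1]], t_end = am$times[fr_span[2]],
      crossing_time = am$times[raw[[i]]$frame],
      n_octanol = carrier$n_octanol, n_water = carrier$n_water,
      carrier = carrier$members,
      mechanism = raw[[i]]$mechanism), class = "transport_event")
  }
  merged
}

#' @export
print.transport_event <- function(x, ...) {
  cat(sprintf("<transport_event %s %s: %d water(s), carrier (oct)%d(H2O)%d, t=%.1f ps>\n",
              x$mechanism, x$direction, length(x$water_ids),
              x$n_octanol, x$n_water, x$crossing_time))
  invisible(x)
}

#' Flatten transport events to a table
#' @param events list of `transport_event`s from [classify_transfers()].
#' @return data frame, one row per event.
#' @export
event_table <- function(events) {
  if (!length(events))
    return(data.frame(direction = character(), mechanism = character(),
                      n_waters = integer(), n_octanol = integer(),
                      n_water_carrier = integer(), t_start = numeric(),
                      t_end = numeric()))
  do.call(rbind, lapply(events, function(e)
    data.frame(direction = e$direction, mechanism = e$mechanism,
               n_waters = length(e$water_ids), n_octanol = e$n_octanol,
               n_water_carrier = e$n_water, t_start = e$t_start,
               t_end = e$t_end)))
}

#' Census of stochastic octanol flips
#'
#' Octanol layer1 <-> layer2 transitions with the concurrent water-HB count
#' of the flipping octanol, and per-direction rates per 10 ps.
#'
#' @param assignments list of [assign_layers()] results.
#' @param hbgraphs list of [detect_hbonds()] graphs, one per frame.
#' @param persistence debounce for [detect_transitions()].
#' @return list with `events` (data frame mol, direction, time,
#'   water_hb_count), `rate_fwd`, `rate_rev` (flips per 10 ps), counts.
#' @export
flip_census <- function(assignments, hbgraphs, persistence = 1) {
  am <- .assign_matrix(assignments)
  sp_mols <- am$mols
  tr <- detect_transitions(assignments, persistence)
  key <- paste(tr$from, tr$to, sep = "->")
  fl <- tr[key %in% c("layer1->layer2", "layer2->layer1"), , drop = FALSE]
  species <- attr(assignments[[1]], "species")
  if (!is.null(species))  # flips are an octanol phenomenon
    fl <- fl[species[as.character(fl$mol)] == "octanol", , drop = FALSE]
  if (nrow(fl)) {
    whb <- integer(nrow(fl))
    for (r in seq_len(nrow(fl))) {
      e <- hbgraphs[[fl$frame[r]]]$edges
      m <- fl$mol[r]
      partners <- unique(c(e$acceptor[e$donor == m], e$donor[e$acceptor == m]))
      whb[r] <- if (is.null(species)) length(partners)
                else sum(species[as.character(partners)] == "water")
    }
    fl$water_hb_count <- whb
  } else fl$water_hb_count <- integer(0)
  elapsed <- am$times[length(am$times)] - am$times[1]
  fwd <- sum(fl$from == "layer1")
  rev <- sum(fl$from == "layer2")
  list(events = data.frame(mol = fl$mol,
                           direction = ifelse(fl$from == "layer1",
                                              "L1->L2", "L2->L1"),
                           time = fl$time,
                           water_hb_count = fl$water_hb_count),
       n_fwd = fwd, n_rev = rev,
       rate_fwd = fwd / elapsed * 10, rate_rev = rev / elapsed * 10)
}

#' Aggregate transfer statistics
#'
#' Per-direction event counts, waters transferred, mean carrier composition,
#' mechanism fractions both by events and by transferred waters (with the
#' all-mechanism and the HB-mediated-only denominators), per-water
#' stoichiometry (mean octanols per event / mean waters per event) and
#' 3-block uncertainties.
#'
#' @param events list of `transport_event`s, or an [event_table()]-shaped
#'   data frame.
#' @param n_blocks blocks for the block-averaged SEMs (default 3).
#' @return object of class `"transfer_stats"`: named list of per-direction
#'   summaries plus a `pooled` entry.
#' @export
transfer_statistics <- function(events, n_blocks = 3) {
  tab <- if (is.data.frame(events)) events else event_table(events)
  summarise_dir <- function(d) {
    if (!nrow(d))
      return(list(n_events = 0L, waters_transferred = 0L,
                  mean_octanols = NA_real_, mean_waters = NA_real_,
                  stoichiometry = NA_real_, fraction_events = c(),
                  fraction_waters = c(), sem_mean_octanols = NA_real_,
                  sem_mean_waters = NA_real_))
    mech <- factor(d$mechanism, levels = c("diffusion", "flip", "hinge"))
    wt <- tapply(d$n_waters, mech, sum, default = 0)
    ev <- table(mech)
    hb <- d$mechanism != "diffusion"
    mean_oct <- mean(d$n_octanol[hb])
    mean_wat <- mean(d$n_waters[hb])
    ord <- order(d$t_start)
    blk <- function(x) if (length(x) >= n_blocks) block_sem(x, n_blocks) else NA_real_
    list(n_events = nrow(d),
         waters_transferred = sum(d$n_waters),
         mean_octanols = mean_oct,
         mean_waters = mean_wat,
         stoichiometry = mean_oct / mean_wat,
         fraction_events = as.numeric(ev) / nrow(d),
         fraction_waters = as.numeric(wt) / sum(d$n_waters),
         fraction_waters_hb_denominator =
           as.numeric(wt) / max(1, sum(d$n_waters[hb])),
         mechanism_levels = levels(mech),
         sem_mean_octanols = blk(d$n_octanol[hb][order(d$t_start[hb])]),
         sem_mean_waters = blk(d$n_waters[hb][order(d$t_start[hb])]))
  }
  dirs <- unique(tab$direction)
  out <- lapply(dirs, function(dd) summarise_dir(tab[tab$direction == dd, ]))
  names(out) <- dirs
  out$pooled <- summarise_dir(tab)
  structure(out, class = "transfer_stats")
}

#' @export
print.transfer_stats <- function(x, ...) {
  for (d in setdiff(names(x), "pooled")) {
    s <- x[[d]]
    cat(sprintf("%s: %d events, %d waters; mechanism shares (by waters): %s\n",
                d, s$n_events, s$waters_transferred,
                paste(sprintf("%s %.1f%%", s$mechanism_levels,
                              100 * s$fraction_waters), collapse = ", ")))
    if (is.finite(s$stoichiometry))
      cat(sprintf("   carrier %.2f oct / %.2f water per event -> %.2f oct per water\n",
                  s$mean_octanols, s$mean_waters, s$stoichiometry))
  }
  invisible(x)
}

#' Arrhenius activation energy from rate constant and prefactor
#'
#' `E_a = R T ln(A / k)` with R in kcal/(mol K). A negative barrier (A < k)
#' is flagged, not clipped.
#'
#' @param k rate constant (any units, same as `A`).
#' @param A pre-exponential factor.
#' @param T temperature, Kelvin.
#' @return object of class `"arrhenius_estimate"`: `k`, `A`, `T`, `Ea`
#'   (kcal/mol), `flagged`.
#' @export
arrhenius_ea <- function(k, A, T) {
  if (any(c(k, A, T) <= 0) || !all(is.finite(c(k, A, T))))
    stop("k, A and T must be positive and finite")
  Ea <- GAS_CONSTANT_KCAL * T * log(A / k)
  structure(list(k = k, A = A, T = T, Ea = Ea, flagged = Ea < 0),
            class = "arrhenius_estimate")
}

#' @export
print.arrhenius_estimate <- function(x, ...) {
  cat(sprintf("<arrhenius: k=%.4g, A=%.4g, T=%.0f K -> Ea=%.3f kcal/mol%s>\n",
              x$k, x$A, x$T, x$Ea, if (x$flagged) " [FLAGGED: Ea < 0]" else ""))
  invisible(x)
}

#' Forward/reverse hinge-transport barriers
#'
#' Rate constants are the per-direction water transfer rates normalised by
#' the layer concentrations according to the per-water reaction stoichiometry
#' `H2O(L1) + nu oct(L1) <-> H2O(L2) + nu oct(L2)`; concentrations are mean
#' per-frame molecule counts in each layer (the normalisation convention is
#' recorded in the output metadata). The prefactor convention is the caller's
#' choice: pass rates measured either as (a) new water-octanol HB formation
#' or (b) surface-water adsorption plus HB formation.
#'
#' @param events list of `transport_event`s (or event table).
#' @param assignments list of [assign_layers()] results.
#' @param T temperature, Kelvin.
#' @param A_fwd,A_rev prefactor rates (same units as the transfer rates:
#'   events per 10 ps).
#' @param prefactor label of the convention used for `A_fwd`/`A_rev`.
#' @param nu per-water stoichiometry; default = pooled mean octanols / mean
#'   waters of the events.
#' @param n_blocks blocks for the SEM of `E_a`.
#' @return list with `forward` and `reverse` [arrhenius_ea()] estimates,
#'   their block SEMs, `nu`, layer concentrations, and metadata.
#' @export
hinge_reaction_rates <- function(events, assignments, T = 300,
                                 A_fwd, A_rev,
                                 prefactor = c("hb_formation", "adsorption_hb"),
                                 nu = NULL, n_blocks = 3) {
  prefactor <- match.arg(prefactor)
  tab <- if (is.data.frame(events)) events else event_table(events)
  am <- .assign_matrix(assignments)
  elapsed <- am$times[length(am$times)] - am$times[1]
  stop_if_zero <- function(x, what) {
    if (!is.finite(x) || x <= 0) stop("zero ", what, " concentration")
    x
  }
  # species-resolved layer concentrations when the assignment carries the
  # roster species (set by assign_layers); otherwise raw member counts
  spv <- attr(assignments[[1]], "species")
  if (is.null(spv)) {
    # fall back: counts of all members per layer
    c_wL1 <- stop_if_zero(mean(colSums(am$mat == "layer1")), "layer1")
    c_oL1 <- c_wL1
    c_wL2 <- stop_if_zero(mean(colSums(am$mat == "layer2")), "layer2")
    c_oL2 <- c_wL2
  } else {
    w <- spv == "water"; o <- spv == "octanol"
    c_wL1 <- stop_if_zero(mean(colSums(am$mat[w, , drop = FALSE] == "layer1") +
                               colSums(am$mat[w, , drop = FALSE] == "water_surface")),
                          "layer1 water")
    c_oL1 <- stop_if_zero(mean(colSums(am$mat[o, , drop = FALSE] == "layer1")),
                          "layer1 octanol")
    c_wL2 <- stop_if_zero(mean(colSums(am$mat[w, , drop = FALSE] == "layer2")),
                          "layer2 water")
    c_oL2 <- stop_if_zero(mean(colSums(am$mat[o, , drop = FALSE] == "layer2")),
                          "layer2 octanol")
  }
  if (is.null(nu)) {
    hb <- tab[tab$mechanism != "diffusion", , drop = FALSE]
    nu <- if (nrow(hb)) mean(hb$n_octanol) / mean(hb$n_waters) else 1
  }
  rate_dir <- function(d, t_range = NULL) {
    dd <- tab[tab$direction == d, , drop = FALSE]
    el <- elapsed
    if (!is.null(t_range)) {
      dd <- dd[dd$t_start >= t_range[1] & dd$t_start < t_range[2], , drop = FALSE]
      el <- t_range[2] - t_range[1]
    }
    sum(dd$n_waters) / el * 10
  }
  k_of <- function(rate, cw, co) rate / (cw * co^nu)
  r_f <- rate_dir("L1->L2"); r_r <- rate_dir("L2->L1")
  if (r_f <= 0 || r_r <= 0) stop("no transfer events in one direction")
  k_f <- k_of(r_f, c_wL1, c_oL1)
  k_r <- k_of(r_r, c_wL2, c_oL2)
  fw <- arrhenius_ea(k_f, A_fwd, T)
  rv <- arrhenius_ea(k_r, A_rev, T)
  # block SEMs on Ea via per-block rates
  brk <- seq(am$times[1], am$times[length(am$times)], length.out = n_blocks + 1)
  ea_blocks <- function(d, A, cw, co) {
    vapply(seq_len(n_blocks), function(b) {
      rb <- rate_dir(d, brk[b:(b + 1)])
      if (rb <= 0) return(NA_real_)
      GAS_CONSTANT_KCAL * T * log(A / k_of(rb, cw, co))
    }, 0)
  }
  ef <- ea_blocks("L1->L2", A_fwd, c_wL1, c_oL1)
  er <- ea_blocks("L2->L1", A_rev, c_wL2, c_oL2)
  list(forward = fw, reverse = rv,
       sem_fwd = stats::sd(ef, na.rm = TRUE) / sqrt(sum(is.finite(ef))),
       sem_rev = stats::sd(er, na.rm = TRUE) / sqrt(sum(is.finite(er))),
       nu = nu,
       concentrations = c(water_L1 = c_wL1, octanol_L1 = c_oL1,
                          water_L2 = c_wL2, octanol_L2 = c_oL2),
       metadata = list(prefactor_convention = prefactor,
                       concentration_normalisation = "mean molecule count per frame",
                       rate_units = "waters per 10 ps"))
}
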