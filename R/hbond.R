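# Per-frame hydrogen-bond graphs and O-O cutoff clusters. The geometric HB
# criterion is the field-standard one: donor-acceptor O...O distance strictly
# below 3.5 A and an H-O...O angle at the donor oxygen of at most 30 degrees.
# Neighbor search uses cell lists sized >= cutoff; results are identical to a
# brute-force all-pairs scan (tested against one).

#' Geometric hydrogen-bond criteria
#' @param max_OO_distance donor-acceptor O...O cutoff, Angstrom (strict `<`).
#' @param max_HOO_angle H-O(donor)...O(acceptor) angle bound, degrees
#'   (inclusive `<=`).
#' @return object of class `"hb_criteria"`.
#' @export
hb_criteria <- function(max_OO_distance = 3.5, max_HOO_angle = 30) {
  if (max_OO_distance <= 0) stop("distance cutoff must be positive")
  if (max_HOO_angle <= 0 || max_HOO_angle > 180) stop("angle bound must be in (0, 180]")
  structure(list(max_OO_distance = max_OO_distance,
                 max_HOO_angle = max_HOO_angle), class = "hb_criteria")
}

# all unordered pairs (i < j, row indices into pos) with minimum-image
# distance strictly below cutoff, via a periodic cell list
neighbor_pairs <- function(pos, box, cutoff) {
  n <- nrow(pos)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  # wrap into primary cell for binning
  w <- pos
  for (k in 1:3) if (box$periodic[k]) {
    L <- box$L[k]; w[, k] <- w[, k] - L * floor(w[, k] / L)
  }
  ncell <- pmax(1L, floor(box$L / cutoff))
  size <- box$L / ncell
  cc <- sapply(1:3, function(k) pmin(floor(w[, k] / size[k]), ncell[k] - 1L))
  cc <- matrix(as.integer(cc), ncol = 3)
  cid <- cc[, 1] + ncell[1] * (cc[, 2] + ncell[2] * cc[, 3])
  by_cell <- split(seq_len(n), cid)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  pi_ <- integer(0); pj_ <- integer(0)
  ids <- as.integer(names(by_cell))
  coord_of <- function(id) {
    x <- id %% ncell[1]; r <- id %/% ncell[1]
    c(x, r %% ncell[2], r %/% ncell[2])
  }
  for (ci in seq_along(ids)) {
    a <- by_cell[[ci]]
    if (length(a) > 1L) {
      cmb <- utils::combn(a, 2L)
      pi_ <- c(pi_, cmb[1, ]); pj_ <- c(pj_, cmb[2, ])
    }
    cc0 <- coord_of(ids[ci])
    seen <- integer(0)
    for (o in seq_len(nrow(offs))) {
      dv <- offs[o, ]
      if (all(dv == 0)) next
      nc <- cc0 + dv
      ok <- TRUE
      for (k in 1:3) {
        if (box$periodic[k]) nc[k] <- nc[k] %% ncell[k]
        else if (nc[k] < 0 || nc[k] >= ncell[k]) { ok <- FALSE; break }
      }
      if (!ok) next
      nid <- nc[1] + ncell[1] * (nc[2] + ncell[2] * nc[3])
      if (nid <= ids[ci] || nid %in% seen) next  # process each cell pair once
      seen <- c(seen, nid)
      b <- by_cell[[as.character(nid)]]
      if (is.null(b)) next
      g <- expand.grid(i = a, j = b)
      pi_ <- c(pi_, g$i); pj_ <- c(pj_, g$j)
    }
  }
  if (!length(pi_)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  d <- minimum_image(pos[pi_, , drop = FALSE], pos[pj_, , drop = FALSE], box)
  d <- if (is.null(dim(d))) matrix(d, ncol = 3) else d
  dist <- sqrt(rowSums(d * d))
  keep <- dist < cutoff
  out <- data.frame(i = pmin(pi_[keep], pj_[keep]),
                    j = pmax(pi_[keep], pj_[keep]), dist = dist[keep])
  out[order(out$i, out$j), , drop = FALSE]
}

# oxygen table for HB/cluster work: one row per donor/acceptor O
.oxygen_table <- function(frame, members = NULL) {
  at <- frame$atoms
  ox <- at[at$role %in% c("water_O", "hydroxyl_O"), , drop = FALSE]
  if (!is.null(members)) ox <- ox[ox$mol %in% members, , drop = FALSE]
  ox
}

#' Detect hydrogen bonds in a frame
#'
#' An edge `(donor, acceptor, h)` is present iff the minimum-image O...O
#' distance is strictly below `max_OO_distance` and the angle at the donor
#' oxygen between its covalent O-H vector and the O...O vector is at most
#' `max_HOO_angle`. Water-water, water-octanol and octanol-octanol bonds all
#' use the same rule.
#'
#' @param frame a wrapped [md_frame()].
#' @param criteria an [hb_criteria()].
#' @return object of class `"hb_graph"`: list with `frame_time`, `nodes`
#'   (molecule ids) and `edges` (data frame donor, acceptor, h_atom,
#'   distance, angle).
#' @export
detect_hbonds <- function(frame, criteria = hb_criteria()) {
  at <- frame$atoms
  sp <- mol_species(frame)
  polar <- names(sp)[sp %in% c("water", "octanol")]
  ox <- .oxygen_table(frame)
  if (!all(polar %in% as.character(ox$mol))) {
    missing <- setdiff(polar, as.character(ox$mol))
    stop("molecule(s) lacking an O role: ", paste(missing, collapse = ", "))
  }
  hyd <- at[at$role %in% c("water_H", "hydroxyl_H"), , drop = FALSE]
  pos <- as.matrix(ox[, c("x", "y", "z")])
  prs <- neighbor_pairs(pos, frame$box, criteria$max_OO_distance)
  empty <- data.frame(donor = integer(), acceptor = integer(), h_atom = integer(),
                      distance = numeric(), angle = numeric())
  edges <- empty
  if (nrow(prs)) {
    # ordered pairs both ways: each O of the pair may donate
    oi <- c(prs$i, prs$j); oj <- c(prs$j, prs$i); dd <- c(prs$dist, prs$dist)
    dmol <- ox$mol[oi]; amol <- ox$mol[oj]
    # expand over the donor molecule's hydrogens
    hs <- split(hyd$atom, hyd$mol)
    nh <- lengths(hs[as.character(dmol)])
    rep_idx <- rep(seq_along(oi), nh)
    h_atom <- unlist(hs[as.character(dmol)], use.names = FALSE)
    if (length(rep_idx)) {
      o_d <- pos[oi[rep_idx], , drop = FALSE]
      o_a <- pos[oj[rep_idx], , drop = FALSE]
      hrow <- match(h_atom, at$atom)
      hp <- as.matrix(at[hrow, c("x", "y", "z")])
      v_oh <- minimum_image(o_d, hp, frame$box)
      v_oo <- minimum_image(o_d, o_a, frame$box)
      v_oh <- if (is.null(dim(v_oh))) matrix(v_oh, ncol = 3) else v_oh
      v_oo <- if (is.null(dim(v_oo))) matrix(v_oo, ncol = 3) else v_oo
      cosang <- rowSums(v_oh * v_oo) /
        (sqrt(rowSums(v_oh^2)) * sqrt(rowSums(v_oo^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      keep <- ang <= criteria$max_HOO_angle
      edges <- data.frame(donor = dmol[rep_idx][keep],
                          acceptor = amol[rep_idx][keep],
                          h_atom = h_atom[keep],
                          distance = dd[rep_idx][keep],
                          angle = ang[keep])
      edges <- edges[edges$donor != edges$acceptor, , drop = FALSE]
      edges <- edges[order(edges$donor, edges$acceptor, edges$h_atom), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(frame_time = frame$time, nodes = as.integer(polar), edges = edges),
            class = "hb_graph")
}

#' @export
print.hb_graph <- function(x, ...) {
  cat(sprintf("<hb_graph t=%.2f ps: %d nodes, %d hydrogen bonds>\n",
              x$frame_time, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# undirected molecule-pair edge keys of an hb_graph
.hb_pair_keys <- function(hbg) {
  if (!nrow(hbg$edges)) return(character(0))
  unique(paste(pmin(hbg$edges$donor, hbg$edges$acceptor),
               pmax(hbg$edges$donor, hbg$edges$acceptor), sep = "-"))
}

#' O-O cutoff clusters of molecules
#'
#' Molecules belong to the same cluster when their (hydroxyl/water) oxygens
#' are closer than `cutoff` (strict `<`, matching the HB distance criterion);
#' clusters are connected components of that proximity graph, ordered by
#' smallest member id.
#'
#' @param frame an [md_frame()].
#' @param member_ids molecule ids to cluster.
#' @param cutoff O-O distance cutoff, Angstrom.
#' @return list of clusters, each a list with `members`, `n_octanol`,
#'   `n_water`, `frame_time`; class `"molecule_cluster"` per element.
#' @export
find_clusters <- function(frame, member_ids, cutoff = 3.5) {
  member_ids <- as.integer(member_ids)
  if (!length(member_ids)) return(list())
  ox <- .oxygen_table(frame, member_ids)
  # octanol contributes its hydroxyl O; order rows by molecule id
  ox <- ox[order(ox$mol), , drop = FALSE]
  pos <- as.matrix(ox[, c("x", "y", "z")])
  prs <- neighbor_pairs(pos, frame$box, cutoff)
  g <- igraph::make_empty_graph(n = nrow(ox), directed = FALSE)
  if (nrow(prs)) g <- igraph::add_edges(g, rbind(prs$i, prs$j))
  comp <- igraph::components(g)$membership
  sp <- mol_species(frame)
  out <- lapply(split(seq_len(nrow(ox)), comp), function(idx) {
    mem <- sort(ox$mol[idx])
    structure(list(members = mem,
                   n_octanol = sum(sp[as.character(mem)] == "octanol"),
                   n_water = sum(sp[as.character(mem)] == "water"),
                   frame_time = frame$time),
              class = "molecule_cluster")
  })
  out <- out[order(vapply(out, function(cl) cl$members[1], 0))]
  names(out) <- NULL
  out
}

#' Hydrogen-bond formation and loss rates
#'
#' Counts edges (undirected molecule pairs) present at `t` but absent at
#' `t + dt` (loss) and vice versa (formation), normalised to events per
#' 10 ps. Optionally restricted to edges with at least one endpoint in
#' `subset`.
#'
#' @param trajectory an [md_trajectory()] (>= 2 frames).
#' @param criteria an [hb_criteria()].
#' @param subset optional molecule ids restricting the count.
#' @param hbgraphs optional precomputed list of [detect_hbonds()] outputs
#'   (one per frame), to avoid recomputation.
#' @param fine_interval sampling interval ps; must equal the trajectory's.
#' @return list with `formation_rate` and `loss_rate` (events per 10 ps),
#'   plus raw totals and the elapsed time.
#' @export
hb_turnover_rates <- function(trajectory, criteria = hb_criteria(),
                              subset = NULL, hbgraphs = NULL,
                              fine_interval = NULL) {
  nf <- length(trajectory$frames)
  if (nf < 2L) stop("need at least two frames for turnover rates")
  if (!is.null(fine_interval) &&
      abs(fine_interval - trajectory$sampling_interval) > 1e-9)
    stop("fine_interval must equal the trajectory sampling interval")
  if (is.null(hbgraphs))
    hbgraphs <- lapply(trajectory$frames, detect_hbonds, criteria = criteria)
  keep_key <- function(keys) {
    if (is.null(subset)) return(keys)
    ab <- strsplit(keys, "-", fixed = TRUE)
    keys[vapply(ab, function(p) any(as.integer(p) %in% subset), TRUE)]
  }
  lost <- formed <- 0L
  prev <- keep_key(.hb_pair_keys(hbgraphs[[1]]))
  for (i in 2:nf) {
    cur <- keep_key(.hb_pair_keys(hbgraphs[[i]]))
    lost <- lost + sum(!(prev %in% cur))
    formed <- formed + sum(!(cur %in% prev))
    prev <- cur
  }
  elapsed <- trajectory$frames[[nf]]$time - trajectory$frames[[1]]$time
  list(formation_rate = formed / elapsed * 10,
       loss_rate = lost / elapsed * 10,
       n_formed = formed, n_lost = lost, elapsed_ps = elapsed)
}
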