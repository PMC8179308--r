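# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately written with plain loops, separate from the package's
# vectorised / cell-list code paths.

# --- fixture builders --------------------------------------------------

# a water molecule with explicit H positions (no geometry assumptions)
w3 <- function(mol, o, h1 = o + c(0.96, 0, 0), h2 = o + c(-0.24, 0.93, 0),
               atom0 = (mol - 1) * 3 + 1) {
  data.frame(atom = atom0 + 0:2, mol = mol, species = "water",
             role = c("water_O", "water_H", "water_H"),
             element = c("O", "H", "H"),
             x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
             z = c(o[3], h1[3], h2[3]), stringsAsFactors = FALSE)
}

# a minimal octanol: hydroxyl O/H plus terminal C along `axis`
oct3 <- function(mol, o, axis = c(0, 0, 1), atom0 = 1000 + (mol - 1) * 10) {
  axis <- axis / sqrt(sum(axis^2))
  h <- o - 0.97 * axis
  cc <- o + 10.5 * axis
  data.frame(atom = atom0 + 0:2, mol = mol, species = "octanol",
             role = c("hydroxyl_O", "hydroxyl_H", "terminal_C"),
             element = c("O", "H", "C"),
             x = c(o[1], h[1], cc[1]), y = c(o[2], h[2], cc[2]),
             z = c(o[3], h[3], cc[3]), stringsAsFactors = FALSE)
}

rand_water_frame <- function(n, L = 15, seed = 1, Lz = L) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    o <- c(runif(1, 0, L), runif(1, 0, L), runif(1, 0, Lz))
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    w3(i, o, o + 0.96 * u1, o + 0.96 * u2)
  })
  md_frame(do.call(rbind, rows), box3(L, L, Lz))
}

# --- oracles -----------------------------------------------------------

# minimum image by scanning all 27 periodic image shifts
mi_oracle <- function(a, b, box) {
  best <- NULL; bestd <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    sh <- c(ix, iy, iz) * box$L * ifelse(box$periodic, 1, 0)
    d <- (b + sh) - a
    if (sum(d^2) < bestd) { bestd <- sum(d^2); best <- d }
  }
  best
}

# all-pairs, all-hydrogens hydrogen-bond scan
hb_oracle <- function(frame, criteria = hb_criteria()) {
  at <- frame$atoms
  ox <- at[at$role %in% c("water_O", "hydroxyl_O"), ]
  hs <- at[at$role %in% c("water_H", "hydroxyl_H"), ]
  out <- list()
  for (i in seq_len(nrow(ox))) for (j in seq_len(nrow(ox))) {
    if (ox$mol[i] == ox$mol[j]) next
    doo <- mi_oracle(c(ox$x[i], ox$y[i], ox$z[i]),
                     c(ox$x[j], ox$y[j], ox$z[j]), frame$box)
    if (sqrt(sum(doo^2)) >= criteria$max_OO_distance) next
    hh <- hs[hs$mol == ox$mol[i], ]
    for (k in seq_len(nrow(hh))) {
      doh <- mi_oracle(c(ox$x[i], ox$y[i], ox$z[i]),
                       c(hh$x[k], hh$y[k], hh$z[k]), frame$box)
      cosang <- sum(doh * doo) / (sqrt(sum(doh^2)) * sqrt(sum(doo^2)))
      ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      if (ang <= criteria$max_HOO_angle)
        out[[length(out) + 1L]] <- data.frame(
          donor = ox$mol[i], acceptor = ox$mol[j], h_atom = hh$atom[k])
    }
  }
  if (!length(out)) return(data.frame(donor = integer(), acceptor = integer(),
                                      h_atom = integer()))
  res <- do.call(rbind, out)
  res[order(res$donor, res$acceptor, res$h_atom), , drop = FALSE]
}

# union-find connected components over the brute-force O-O pair list
cluster_oracle <- function(frame, members, cutoff = 3.5) {
  at <- frame$atoms
  ox <- at[at$role %in% c("water_O", "hydroxyl_O") & at$mol %in% members, ]
  ox <- ox[order(ox$mol), ]
  n <- nrow(ox)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- mi_oracle(c(ox$x[i], ox$y[i], ox$z[i]),
                   c(ox$x[j], ox$y[j], ox$z[j]), frame$box)
    if (sqrt(sum(d^2)) < cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  parts <- split(ox$mol, roots)
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, 0, 1))]
}

# per-line analytic first-contact ITIM
itim_oracle <- function(frame, members, params) {
  at <- frame$atoms[frame$atoms$mol %in% members, ]
  radii <- params$atomic_radii
  rr <- ifelse(grepl("O$", at$role), radii[["O"]],
               ifelse(grepl("H$", at$role), radii[["H"]], radii[["C"]])) +
    params$probe_radius
  Lx <- frame$box$L[1]; Ly <- frame$box$L[2]
  nx <- max(1, round(Lx / params$grid_spacing))
  ny <- max(1, round(Ly / params$grid_spacing))
  sx <- Lx / nx; sy <- Ly / ny
  down <- params$direction == "down"
  hit <- integer(0)
  for (ix in 0:(nx - 1)) for (iy in 0:(ny - 1)) {
    lx <- ix * sx; ly <- iy * sy
    bz <- if (down) -Inf else Inf; bm <- NA_integer_
    for (k in seq_len(nrow(at))) {
      dx <- abs(at$x[k] - lx); dx <- min(dx, Lx - dx)
      dy <- abs(at$y[k] - ly); dy <- min(dy, Ly - dy)
      d2 <- dx^2 + dy^2
      if (d2 > rr[k]^2) next
      zc <- if (down) at$z[k] + sqrt(rr[k]^2 - d2) else at$z[k] - sqrt(rr[k]^2 - d2)
      if ((down && zc > bz) || (!down && zc < bz)) { bz <- zc; bm <- at$mol[k] }
    }
    if (!is.na(bm)) hit <- c(hit, bm)
  }
  sort(unique(hit))
}

# plain-loop 2D RDF histogram (ordered pairs, xy minimum image)
rdf2d_oracle <- function(frame, members, dr, r_max) {
  at <- frame$atoms
  ox <- at[at$role %in% c("water_O", "hydroxyl_O") & at$mol %in% members, ]
  n <- nrow(ox)
  Lx <- frame$box$L[1]; Ly <- frame$box$L[2]
  nb <- ceiling(r_max / dr)
  hist <- numeric(nb)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dx <- ox$x[j] - ox$x[i]; dx <- dx - Lx * floor(dx / Lx + 0.5)
    dy <- ox$y[j] - ox$y[i]; dy <- dy - Ly * floor(dy / Ly + 0.5)
    r <- sqrt(dx^2 + dy^2)
    if (r < r_max) { k <- floor(r / dr) + 1; hist[k] <- hist[k] + 1 }
  }
  rho <- n / (Lx * Ly)
  rc <- (seq_len(nb) - 0.5) * dr
  hist / (n * rho * 2 * pi * rc * dr)
}

# explicit-loop debounced transition enumeration (persistent runs)
transitions_oracle <- function(labels, persistence) {
  n <- length(labels)
  starts <- c(); lens <- c(); vals <- c()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1] == labels[i]) j <- j + 1
    starts <- c(starts, i); lens <- c(lens, j - i + 1); vals <- c(vals, labels[i])
    i <- j + 1
  }
  keep <- lens >= persistence
  vals <- vals[keep]; starts <- starts[keep]
  if (length(vals) >= 2) {
    drop <- c(FALSE, vals[-1] == vals[-length(vals)])
    vals <- vals[!drop]; starts <- starts[!drop]
  }
  if (length(vals) < 2)
    return(data.frame(from = character(), to = character(), frame = integer()))
  data.frame(from = vals[-length(vals)], to = vals[-1], frame = starts[-1])
}

# edge keys helper for comparisons
edge_keys <- function(edges) {
  if (!nrow(edges)) return(character(0))
  sort(paste(edges$donor, edges$acceptor, edges$h_atom, sep = "|"))
}
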