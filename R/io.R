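# File formats: GRO (fixed column, nm -> Angstrom on ingest) and an
# extended-XYZ dialect with box/time on the comment line. Molecule typing is
# driven by a residue-name map and per-species atom-role maps so files from
# different force fields can be ingested.

#' Default residue and atom-role maps
#'
#' Residues `SOL`/`WAT`/`HOH` map to water, `OCT`/`OCO`/`1OL` to octanol.
#' Water atoms `OW`->water_O, `HW1`/`HW2`->water_H; octanol `O`/`OA`/`OH`
#' ->hydroxyl_O, `HO`/`H10`->hydroxyl_H, `C8`->terminal_C, other `C*`->chain_C.
#'
#' @return list with elements `residues` (named character) and `roles`
#'   (named list of named character vectors per species).
#' @export
default_topology_map <- function() {
  list(
    residues = c(SOL = "water", WAT = "water", HOH = "water",
                 OCT = "octanol", OCO = "octanol", `1OL` = "octanol"),
    roles = list(
      water = c(OW = "water_O", HW1 = "water_H", HW2 = "water_H"),
      octanol = c(O = "hydroxyl_O", OA = "hydroxyl_O", OH = "hydroxyl_O",
                  HO = "hydroxyl_H", H10 = "hydroxyl_H", C8 = "terminal_C")
    )
  )
}

.role_for <- function(species, atom_name, map) {
  r <- map$roles[[species]][atom_name]
  r <- unname(r)
  if (is.na(r)) {
    if (species == "octanol" && grepl("^C", atom_name)) return("chain_C")
    return("other")
  }
  r
}

#' Read a GRO configuration file
#'
#' Coordinates are converted from nm to Angstrom on ingest. Only orthorhombic
#' box lines (3 numbers) are supported.
#'
#' @param path file path.
#' @param map topology map, see [default_topology_map()].
#' @param time frame time ps (GRO has no time field unless in the title).
#' @return an [md_frame()].
#' @export
read_gro <- function(path, map = default_topology_map(), time = 0) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[2]))
  rows <- ln[3:(2 + n)]
  resname <- trimws(substr(rows, 6, 10))
  atname <- trimws(substr(rows, 11, 15))
  resid <- as.integer(substr(rows, 1, 5))
  x <- as.numeric(substr(rows, 21, 28)) * 10
  y <- as.numeric(substr(rows, 29, 36)) * 10
  z <- as.numeric(substr(rows, 37, 44)) * 10
  bl <- as.numeric(strsplit(trimws(ln[3 + n]), "\\s+")[[1]])
  if (length(bl) < 3) stop("unsupported GRO box line")
  species <- unname(map$residues[resname])
  if (anyNA(species)) stop("unmapped residue names: ",
                           paste(unique(resname[is.na(species)]), collapse = ", "))
  role <- mapply(.role_for, species, atname, MoreArgs = list(map = map))
  # renumber molecules positionally (resid wraps at 100000 in GRO)
  mol <- cumsum(c(TRUE, resid[-1] != resid[-n] | resname[-1] != resname[-n]))
  at <- data.frame(atom = seq_len(n), mol = mol, species = species,
                   role = unname(role), element = substr(atname, 1, 1),
                   x = x, y = y, z = z, stringsAsFactors = FALSE)
  md_frame(at, box3(bl[1] * 10, bl[2] * 10, bl[3] * 10), time = time)
}

#' Write a GRO configuration file (Angstrom -> nm)
#' @param frame an [md_frame()].
#' @param path output path.
#' @param map topology map used to invert species/roles to residue/atom names.
#' @export
write_gro <- function(frame, path, map = default_topology_map()) {
  at <- frame$atoms
  res_of <- c(water = "SOL", octanol = "OCT")
  name_of <- function(species, role, i_in_mol) {
    switch(role,
           water_O = "OW", water_H = paste0("HW", i_in_mol),
           hydroxyl_O = "OA", hydroxyl_H = "HO", terminal_C = "C8",
           chain_C = paste0("C", i_in_mol), "X")
  }
  lines <- character(nrow(at) + 3)
  lines[1] <- sprintf("slabhinge frame t= %.4f ps", frame$time)
  lines[2] <- sprintf("%5d", nrow(at))
  hcount <- ccount <- 0L; last_mol <- -1L
  for (i in seq_len(nrow(at))) {
    if (at$mol[i] != last_mol) { hcount <- 0L; ccount <- 0L; last_mol <- at$mol[i] }
    idx <- if (at$role[i] == "water_H") { hcount <- hcount + 1L; hcount }
           else if (at$role[i] == "chain_C") { ccount <- ccount + 1L; ccount }
           else 0L
    lines[i + 2] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                            at$mol[i] %% 100000L, res_of[[at$species[i]]],
                            name_of(at$species[i], at$role[i], idx),
                            at$atom[i] %% 100000L,
                            at$x[i] / 10, at$y[i] / 10, at$z[i] / 10)
  }
  L <- frame$box$L / 10
  lines[nrow(at) + 3] <- sprintf("%10.5f%10.5f%10.5f", L[1], L[2], L[3])
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended-XYZ frame (or multi-frame trajectory)
#'
#' Comment-line dialect: `box="Lx Ly Lz" time=T` (Angstrom, ps); atom lines
#' `element x y z mol species role`.
#'
#' @param path file path.
#' @return an [md_frame()] if the file holds one frame, else an [md_trajectory()].
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  frames <- list(); i <- 1L
  while (i <= length(ln) && nzchar(trimws(ln[i]))) {
    n <- as.integer(trimws(ln[i]))
    cm <- ln[i + 1]
    bx <- regmatches(cm, regexec('box="([^"]+)"', cm))[[1]][2]
    L <- as.numeric(strsplit(trimws(bx), "\\s+")[[1]])
    tm <- regmatches(cm, regexec("time=([-0-9.eE+]+)", cm))[[1]][2]
    rows <- strsplit(trimws(ln[(i + 2):(i + 1 + n)]), "\\s+")
    at <- data.frame(
      atom = seq_len(n),
      mol = as.integer(vapply(rows, `[`, "", 5)),
      species = vapply(rows, `[`, "", 6),
      role = vapply(rows, `[`, "", 7),
      element = vapply(rows, `[`, "", 1),
      x = as.numeric(vapply(rows, `[`, "", 2)),
      y = as.numeric(vapply(rows, `[`, "", 3)),
      z = as.numeric(vapply(rows, `[`, "", 4)),
      stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      md_frame(at, box3(L[1], L[2], L[3]), time = as.numeric(tm))
    i <- i + 2L + n
  }
  if (length(frames) == 1L) frames[[1]] else md_trajectory(frames)
}

#' Write frame(s) in the extended-XYZ dialect of [read_xyz()]
#' @param x an [md_frame()] or [md_trajectory()].
#' @param path output path.
#' @export
write_xyz <- function(x, path) {
  frames <- if (inherits(x, "md_trajectory")) x$frames else list(x)
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    at <- fr$atoms
    writeLines(sprintf("%d", nrow(at)), con)
    writeLines(sprintf('box="%.6f %.6f %.6f" time=%.6f',
                       fr$box$L[1], fr$box$L[2], fr$box$L[3], fr$time), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %d %s %s",
                       at$element, at$x, at$y, at$z, at$mol, at$species, at$role),
               con)
  }
  invisible(path)
}

#' Read a columnar pressure-tensor series (time, Pxx, Pyy, Pzz in bar)
#' @param path whitespace-separated text, `#` comments allowed.
#' @param Lz box height, Angstrom.
#' @param n_interfaces number of interfaces in the periodic cell (default 2).
#' @return a [pressure_series()].
#' @export
read_pressure_series <- function(path, Lz, n_interfaces = 2) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("time", "Pxx", "Pyy", "Pzz"))
  pressure_series(d$time, d$Pxx, d$Pyy, d$Pzz, Lz = Lz, n_interfaces = n_interfaces)
}

#' Export a hydrogen-bond edge list as columnar text
#' @param hbg an `hb_graph` from [detect_hbonds()].
#' @param path output path.
#' @export
write_hb_edges <- function(hbg, path) {
  e <- hbg$edges
  utils::write.table(
    data.frame(frame_time = hbg$frame_time, donor = e$donor, acceptor = e$acceptor,
               h_atom = e$h_atom, distance = e$distance, angle = e$angle),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
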