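# Structure and trajectory text I/O.
#
# Native formats: GRO and (minimal) PDB for structures, and concatenated
# multi-frame GRO with velocity columns as the plain-text trajectory format
# for fixtures.  Binary trajectory dialects (XTC/TRR) are handled through a
# reader registry so the numerics core never touches format code: register a
# converter with register_trajectory_reader() if such data must be consumed.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.9994,
                     S = 32.06, P = 30.974, NA. = 22.98977, CL = 35.453,
                     M = 0, V = 0)  # M/V: massless virtual sites

.mass_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", name))
  if (nm %in% c("NA", "SOD")) return(.element_masses[["NA."]])
  if (nm %in% c("CL", "CLA")) return(.element_masses[["CL"]])
  el <- substr(nm, 1, 1)
  if (!el %in% names(.element_masses))
    stop("cannot assign a mass to atom name '", name, "'", call. = FALSE)
  .element_masses[[el]]
}

.water_resnames <- c("SOL", "WAT", "HOH", "TIP4", "W")
.ion_resnames <- c("NA", "CL", "NA+", "CL-", "SOD", "CLA", "ION")

#' Read a structure file
#'
#' Parses a GRO or PDB structure into a ([topology()], [frame()]) pair.
#' Residues named SOL/WAT/HOH are interpreted as rigid waters (3- or 4-site,
#' inferred from the per-residue atom count), NA/CL residues as ions, and
#' everything else as protein chains.  In GRO files (which carry no chain
#' identifiers) each protein residue index change starts a new residue and
#' chains are delimited by non-contiguous residue numbering or by residue
#' name `CHN` boundaries; for the package's own toy condensates each chain
#' is a single residue.
#'
#' @param path file path.
#' @param dialect `"gro"` or `"pdb"`; default guessed from the extension.
#' @return list with elements `topology` and `frame`.
#' @export
read_structure <- function(path, dialect = c("auto", "gro", "pdb")) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), paste0("file not found: ", path))
  if (dialect == "auto")
    dialect <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "gro"
  if (dialect == "gro") .read_gro(path) else .read_pdb(path)
}

.parse_gro_frame <- function(lines, offset, path) {
  title <- lines[offset]
  natoms <- suppressWarnings(as.integer(trimws(lines[offset + 1L])))
  if (is.na(natoms))
    stop("malformed GRO atom count at line ", offset + 1L, " of ", path,
         call. = FALSE)
  if (length(lines) < offset + 1L + natoms + 1L)
    stop("truncated GRO frame starting at line ", offset, " of ", path,
         call. = FALSE)
  at <- lines[offset + 1L + seq_len(natoms)]
  num <- function(lo, hi, what) {
    v <- suppressWarnings(as.numeric(substr(at, lo, hi)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("malformed GRO ", what, " at line ", offset + 1L + bad[1L],
           " of ", path, call. = FALSE)
    v
  }
  resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
  resname <- toupper(trimws(substr(at, 6, 10)))
  atname <- trimws(substr(at, 11, 15))
  pos <- cbind(num(21, 28, "x"), num(29, 36, "y"), num(37, 44, "z"))
  has_vel <- all(nchar(at) >= 68)
  vel <- if (has_vel)
    cbind(num(45, 52, "vx"), num(53, 60, "vy"), num(61, 68, "vz"))
  boxline <- trimws(lines[offset + 2L + natoms])
  if (!nzchar(boxline))
    stop("missing box line in GRO frame at line ", offset + 2L + natoms,
         " of ", path, call. = FALSE)
  bv <- suppressWarnings(as.numeric(strsplit(boxline, "\\s+")[[1]]))
  if (anyNA(bv)) stop("malformed GRO box line in ", path, call. = FALSE)
  if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-12))
    stop("triclinic boxes are not supported (", path, ")", call. = FALSE)
  box <- bv[1:3]
  tm <- 0
  if (grepl("t=", title)) {
    tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([0-9eE.+-]+).*", "\\1", title)))
    if (!is.finite(tm)) tm <- 0
  }
  list(resid = resid, resname = resname, atname = atname,
       positions = pos, velocities = vel, box = box, time = tm,
       next_offset = offset + 3L + natoms)
}

.topology_from_atoms <- function(resid, resname, atname) {
  is_w <- resname %in% .water_resnames
  is_i <- resname %in% .ion_resnames
  # waters: count sites per residue (must be homogeneous 3 or 4)
  n_waters <- 0L; wm <- water_model()
  if (any(is_w)) {
    key <- paste(resid[is_w], resname[is_w])
    sites <- as.integer(table(factor(key, levels = unique(key))))
    .assert(length(unique(sites)) == 1L && unique(sites) %in% c(1L, 3L, 4L),
            "waters must be rigid 1-, 3- or 4-site molecules")
    n_waters <- length(sites)
    wm <- switch(as.character(unique(sites)),
                 "1" = water_model("point"),
                 "3" = water_model3(),
                 "4" = water_model())
  }
  chains <- list()
  if (any(!is_w & !is_i)) {
    pid <- resid[!is_w & !is_i]
    pan <- atname[!is_w & !is_i]
    # one chain per maximal run of equal residue id... chains are delimited
    # by decreasing or jumping residue numbers; a single residue = one chain
    # for toy bead strings, consecutive residues belong to one chain
    brk <- c(TRUE, diff(pid) != 0L)
    chain_id <- cumsum(brk)
    for (k in unique(chain_id)) {
      sel <- chain_id == k
      chains[[k]] <- list(id = paste0("chain", k),
                          atom_names = pan[sel],
                          masses = vapply(pan[sel], .mass_from_name, 0))
    }
  }
  ions <- NULL
  if (any(is_i)) {
    ions <- data.frame(name = atname[is_i],
                       mass = vapply(atname[is_i], .mass_from_name, 0))
  }
  topology(chains, n_waters, wm, ions)
}

.read_gro <- function(path) {
  lines <- readLines(path)
  fr <- .parse_gro_frame(lines, 1L, path)
  top <- .topology_from_atoms(fr$resid, fr$resname, fr$atname)
  .assert(top$n_atoms == nrow(fr$positions), "atom count mismatch in GRO")
  list(topology = top,
       frame = frame(fr$positions, fr$box, fr$velocities, fr$time))
}

.read_pdb <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  .assert(length(cr) >= 1L, paste0("missing CRYST1 (box) record in ", path))
  g <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                    substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                    substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  .assert(all(is.finite(g)), "malformed CRYST1 record")
  .assert(all(abs(g[4:6] - 90) < 1e-6),
          "triclinic boxes are not supported (PDB angles != 90)")
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  .assert(length(at) > 0, paste0("no ATOM records in ", path))
  num <- function(lo, hi, what) {
    v <- suppressWarnings(as.numeric(substr(at, lo, hi)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("malformed PDB ", what, " in record ", bad[1L], " of ", path,
           call. = FALSE)
    v
  }
  pos <- cbind(num(31, 38, "x"), num(39, 46, "y"), num(47, 54, "z")) / 10
  resname <- toupper(trimws(substr(at, 18, 20)))
  resid <- suppressWarnings(as.integer(substr(at, 23, 26)))
  atname <- trimws(substr(at, 13, 16))
  top <- .topology_from_atoms(resid, resname, atname)
  list(topology = top, frame = frame(pos, g[1:3] / 10, NULL, 0))
}

# three-site rigid water (TIP3P-like), used when reading 3-site fixtures
#' @rdname water_model
#' @export
water_model3 <- function() {
  r_oh <- 0.09572; ang <- 104.52 * pi / 180
  m <- c(15.9994, 1.008, 1.008)
  xh <- r_oh * sin(ang / 2); zh <- r_oh * cos(ang / 2)
  s <- rbind(c(0, 0, 0), c(xh, 0, zh), c(-xh, 0, zh))
  com <- colSums(s * m) / sum(m)
  s <- sweep(s, 2, com)
  I <- c(sum(m * (s[, 2]^2 + s[, 3]^2)),
         sum(m * (s[, 1]^2 + s[, 3]^2)),
         sum(m * (s[, 1]^2 + s[, 2]^2)))
  structure(list(type = "three_site", n_sites = 3L,
                 site_names = c("OW", "HW1", "HW2"), masses = m,
                 charges = c(-0.834, 0.417, 0.417), sites = s, mass = sum(m),
                 principal_moments = I, sigma = 0.3151, epsilon = 0.6364,
                 symmetry_number = 2L), class = "ct_water_model")
}

#' Write a GRO structure or trajectory
#'
#' Writes one or several frames in GRO format (fixed precision: positions
#' to 0.001 nm, velocities to 0.0001 nm/ps).  Multiple frames are simply
#' concatenated, which is the package's plain-text trajectory format.
#'
#' @param path output file.
#' @param top a [topology()].
#' @param frames a single [frame()] or list of frames.
#' @param title title string prefix.
#' @export
write_gro <- function(path, top, frames, title = "condensotherm") {
  if (inherits(frames, "ct_frame")) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  lab <- .gro_labels(top)
  for (fr in frames) {
    .assert(nrow(fr$positions) == top$n_atoms, "frame/topology atom mismatch")
    writeLines(sprintf("%s t= %.4f", title, fr$time), con)
    writeLines(sprintf("%5d", top$n_atoms), con)
    if (is.null(fr$velocities)) {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         lab$resid %% 100000L, lab$resname, lab$atname,
                         seq_len(top$n_atoms) %% 100000L,
                         fr$positions[, 1], fr$positions[, 2], fr$positions[, 3]),
                 con)
    } else {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                         lab$resid %% 100000L, lab$resname, lab$atname,
                         seq_len(top$n_atoms) %% 100000L,
                         fr$positions[, 1], fr$positions[, 2], fr$positions[, 3],
                         fr$velocities[, 1], fr$velocities[, 2], fr$velocities[, 3]),
                 con)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3]), con)
  }
  invisible(path)
}

.gro_labels <- function(top) {
  resid <- integer(0); resname <- character(0); atname <- character(0)
  rid <- 0L
  for (ch in top$chains) {
    rid <- rid + 1L
    resid <- c(resid, rep(rid, length(ch$atom_names)))
    resname <- c(resname, rep("CHN", length(ch$atom_names)))
    atname <- c(atname, ch$atom_names)
  }
  if (top$n_waters > 0L) {
    ns <- top$water$n_sites
    resid <- c(resid, rid + rep(seq_len(top$n_waters), each = ns))
    resname <- c(resname, rep("SOL", top$n_waters * ns))
    atname <- c(atname, rep(top$water$site_names, top$n_waters))
    rid <- rid + top$n_waters
  }
  if (!is.null(top$ions)) {
    resid <- c(resid, rid + seq_len(nrow(top$ions)))
    resname <- c(resname, top$ions$name)
    atname <- c(atname, top$ions$name)
  }
  list(resid = resid, resname = resname, atname = atname)
}

# trajectory reader registry -------------------------------------------------

.traj_readers <- new.env(parent = emptyenv())

#' Register a trajectory reader adapter
#'
#' The numerics core reads trajectories only through this seam.  A reader is
#' a `function(path, topology)` returning a list of [frame()] objects.  The
#' `"gro"` dialect (concatenated GRO frames) is built in; binary dialects
#' such as XTC/TRR can be supported by registering a converter here.
#'
#' @param dialect file-type key, e.g. `"trr"`.
#' @param reader function(path, topology) -> list of frames.
#' @export
register_trajectory_reader <- function(dialect, reader) {
  .assert(is.function(reader), "reader must be a function(path, topology)")
  assign(dialect, reader, envir = .traj_readers)
  invisible(dialect)
}

#' Read trajectory frames
#'
#' @param path trajectory file.
#' @param top the matching [topology()].
#' @param dialect trajectory dialect; `"auto"` guesses from the extension.
#' @return list of [frame()] objects.
#' @export
read_frames <- function(path, top, dialect = "auto") {
  .assert(file.exists(path), paste0("file not found: ", path))
  if (dialect == "auto") dialect <- tolower(sub(".*\\.", "", path))
  if (dialect %in% c("gro", "txt", "trj")) {
    lines <- readLines(path)
    frames <- list(); off <- 1L
    while (off <= length(lines) && nzchar(trimws(lines[off]))) {
      fr <- .parse_gro_frame(lines, off, path)
      .assert(nrow(fr$positions) == top$n_atoms,
              "trajectory frame does not match topology atom count")
      frames[[length(frames) + 1L]] <-
        frame(fr$positions, fr$box, fr$velocities, fr$time)
      off <- fr$next_offset
    }
    .assert(length(frames) > 0L, paste0("no frames found in ", path))
    return(frames)
  }
  if (exists(dialect, envir = .traj_readers))
    return(get(dialect, envir = .traj_readers)(path, top))
  stop("no trajectory reader registered for dialect '", dialect,
       "'; see register_trajectory_reader()", call. = FALSE)
}
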