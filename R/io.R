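# Trajectory and topology readers/writers.
#
# Supported coordinate formats: LAMMPS text dump ("ITEM:" sections) and
# (multi-frame) GRO. XTC is a binary format with no installed R reader and
# is not supported; convert to GRO or LAMMPS dump upstream. Internal units
# are nm; LAMMPS dumps default to angstrom on ingest.

#' Read a topology sidecar
#'
#' Columnar whitespace-delimited text mapping each bead to its molecule,
#' species and role, with columns `bead`, `molecule`, `species`, `role`
#' (header required; `#` comments allowed). Species outside the built-in
#' vocabulary may be declared on comment lines of the form
#' `# species: NAME class` with class `pl`, `tg` or `other`.
#'
#' @param path path to the topology file.
#' @return list with `molecule` (integer per bead), `species` (per
#'   molecule id), `role` (per bead), `extra_species` (named character).
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path)
  decl <- grep("^#\\s*species:", lines, value = TRUE)
  extra <- NULL
  if (length(decl)) {
    parts <- strsplit(sub("^#\\s*species:\\s*", "", decl), "\\s+")
    # values = species labels, names = class ("pl"/"tg"/"other")
    extra <- setNames(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
  }
  tab <- read.table(text = lines, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("bead", "molecule", "species", "role")
  if (!all(need %in% names(tab)))
    stop("topology must have columns ", paste(need, collapse = ", "))
  tab <- tab[order(tab$bead), ]
  if (!identical(as.integer(tab$bead), seq_len(nrow(tab))))
    stop("topology bead indices must be 1..N without gaps")
  ids <- sort(unique(tab$molecule))
  if (!identical(as.integer(ids), seq_along(ids)))
    stop("topology molecule ids must be 1..M without gaps")
  sp <- tab$species[match(ids, tab$molecule)]
  if (any(tapply(tab$species, tab$molecule, function(s) length(unique(s))) != 1))
    stop("a molecule maps to more than one species in the topology")
  list(molecule = as.integer(tab$molecule), species = sp,
       role = as.character(tab$role), extra_species = extra)
}

# ---- LAMMPS dump ---------------------------------------------------------

.parse_dump_frame <- function(lines, start, index, scale) {
  i <- start
  expect <- function(pat) {
    if (i > length(lines) || !grepl(pat, lines[i]))
      stop("malformed LAMMPS dump at line ", i, ": expected ", pat)
  }
  expect("^ITEM: TIMESTEP"); step <- as.numeric(lines[i + 1]); i <- i + 2
  expect("^ITEM: NUMBER OF ATOMS"); nat <- as.integer(lines[i + 1]); i <- i + 2
  expect("^ITEM: BOX BOUNDS")
  bb <- do.call(rbind, lapply(lines[i + 1:3], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:2])))
  if (any(!is.finite(bb))) stop("malformed box bounds at line ", i + 1)
  i <- i + 4
  expect("^ITEM: ATOMS")
  cols <- strsplit(sub("^ITEM: ATOMS\\s*", "", lines[i]), "\\s+")[[1]]
  body <- lines[i + seq_len(nat)]
  if (length(body) < nat || anyNA(body))
    stop("frame ", index, " truncated: expected ", nat, " atom records")
  vals <- read.table(text = body, col.names = cols)
  xyz <- c("x", "y", "z")
  if (!all(c("id", xyz) %in% cols))
    stop("ITEM: ATOMS must include columns id x y z (line ", i, ")")
  vals <- vals[order(vals$id), ]
  list(step = step, nat = nat,
       box = (bb[, 2] - bb[, 1]) * scale,
       origin = bb[, 1] * scale,
       coords = as.matrix(vals[, xyz]) * scale,
       next_line = i + nat + 1)
}

#' Read a LAMMPS text dump
#'
#' @param path dump file with `ITEM:` sections; atom lines must carry
#'   columns `id x y z` (any order, extra columns ignored).
#' @param topology path to a topology sidecar ([read_topology()]).
#' @param length_unit unit of the dump coordinates; converted to nm.
#' @param time_per_step ns per LAMMPS timestep, used to convert the
#'   `TIMESTEP` counter to frame times (default 1e-5 ns = 10 fs).
#' @return a [trajectory()].
#' @export
read_lammps_dump <- function(path, topology,
                             length_unit = c("angstrom", "nm"),
                             time_per_step = 1e-5) {
  if (!file.exists(path)) stop("dump file not found: ", path)
  scale <- switch(match.arg(length_unit), angstrom = 0.1, nm = 1)
  top <- read_topology(topology)
  lines <- readLines(path)
  frames <- list(); i <- 1; k <- 0
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    k <- k + 1
    fr <- .parse_dump_frame(lines, i, k, scale)
    if (fr$nat != length(top$molecule))
      stop("frame ", k, ": ", fr$nat, " beads but topology declares ",
           length(top$molecule))
    if (k > 1 && fr$nat != nrow(frames[[1]]$coords))
      stop("frame ", k, ": bead count changed (", fr$nat, " vs ",
           nrow(frames[[1]]$coords), ")")
    coords <- sweep(fr$coords, 2, fr$origin)   # box origin to 0
    frames[[k]] <- bead_frame(coords, fr$box, top$molecule, top$species,
                              top$role, time = fr$step * time_per_step,
                              extra_species = top$extra_species)
    i <- fr$next_line
  }
  if (!k) stop("no frames found in ", path)
  trajectory(frames)
}

#' Write a trajectory as a LAMMPS text dump
#'
#' Inverse of [read_lammps_dump()]; used for round-tripping and for
#' exporting synthetic fixtures.
#'
#' @param traj a [trajectory()] or single [bead_frame()].
#' @param path output file.
#' @param length_unit unit to write (`"angstrom"` default).
#' @param time_per_step ns per timestep for the TIMESTEP counter.
#' @return `path`, invisibly.
#' @export
write_lammps_dump <- function(traj, path, length_unit = c("angstrom", "nm"),
                              time_per_step = 1e-5) {
  scale <- switch(match.arg(length_unit), angstrom = 10, nm = 1)
  frames <- if (inherits(traj, "bead_frame")) list(traj) else traj$frames
  con <- file(path, "w"); on.exit(close(con))
  for (f in frames) {
    writeLines(c("ITEM: TIMESTEP",
                 format(round(f$time / time_per_step), scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS",
                 as.character(nrow(f$coords)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("%.10g %.10g", 0, f$box * scale),
                 "ITEM: ATOMS id x y z"), con)
    writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(nrow(f$coords)),
                       f$coords[, 1] * scale, f$coords[, 2] * scale,
                       f$coords[, 3] * scale), con)
  }
  invisible(path)
}

# ---- GRO -----------------------------------------------------------------

#' Read a (multi-frame) GRO coordinate file
#'
#' Fixed-width GROMACS coordinate format, already in nm. Concatenated
#' frames are read as a trajectory; frame times are taken from `t=` in the
#' title line when present (ps, converted to ns), else numbered 0, 1, ...
#' ns. Molecule ids come from the residue number and species from the
#' residue name unless a topology sidecar overrides them.
#'
#' @param path GRO file.
#' @param topology optional topology sidecar; when given it supplies
#'   molecule/species/role (and must match the atom count).
#' @return a [trajectory()].
#' @export
read_gro <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("GRO file not found: ", path)
  lines <- readLines(path)
  top <- if (!is.null(topology)) read_topology(topology)
  frames <- list(); i <- 1; k <- 0
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    k <- k + 1
    title <- lines[i]
    nat <- as.integer(trimws(lines[i + 1]))
    if (is.na(nat)) stop("malformed atom count at line ", i + 1)
    body <- lines[i + 1 + seq_len(nat)]
    if (length(body) < nat || anyNA(body))
      stop("frame ", k, " truncated at line ", i + 1 + nat)
    resid <- as.integer(substr(body, 1, 5))
    resname <- trimws(substr(body, 6, 10))
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("malformed coordinate record in frame ", k)
    boxline <- as.numeric(strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]])
    tmatch <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
    tm <- if (length(tmatch)) as.numeric(sub("t=\\s*", "", tmatch)) / 1000
          else k - 1
    if (is.null(top)) {
      ids <- match(resid, unique(resid))
      frames[[k]] <- bead_frame(cbind(x, y, z), boxline[1:3], ids,
                                resname[match(seq_along(unique(resid)), ids)],
                                time = tm,
                                extra_species = NULL)
    } else {
      if (nat != length(top$molecule))
        stop("frame ", k, ": ", nat, " beads but topology declares ",
             length(top$molecule))
      frames[[k]] <- bead_frame(cbind(x, y, z), boxline[1:3], top$molecule,
                                top$species, top$role, time = tm,
                                extra_species = top$extra_species)
    }
    i <- i + nat + 3
  }
  if (!k) stop("no frames found in ", path)
  trajectory(frames)
}

#' Read a trajectory in any supported format
#'
#' Dispatcher over [read_lammps_dump()] and [read_gro()].
#'
#' @param path coordinate file.
#' @param format `"lammps-dump"` or `"gro"`.
#' @param topology topology sidecar path (required for LAMMPS dumps).
#' @param ... passed to the format reader.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("lammps-dump", "gro"),
                            topology = NULL, ...) {
  switch(match.arg(format),
         "lammps-dump" = read_lammps_dump(path, topology, ...),
         "gro" = read_gro(path, topology, ...))
}
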