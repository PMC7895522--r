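# BeadFrame: one time point of a coarse-grained configuration -- wrapped
# bead coordinates plus molecule / species / role labels.

# Closed default species vocabulary; topologies may extend it (see
# read_topology). PL species are the denominator of every TG/PL ratio.
PL_SPECIES <- c("DOPC", "DOPE", "DPPC", "DLPC", "DLPE", "POPC")
TG_SPECIES <- c("TG", "TOOP", "TOPP")
OTHER_SPECIES <- c("DAG", "CHOL")
BEAD_ROLES <- c("head", "glycerol", "tail", "other")

#' Known species vocabulary
#'
#' @param class one of `"all"`, `"pl"` (phospholipids), `"tg"`
#'   (triglycerides), `"other"` (DAG, cholesterol).
#' @return character vector of species labels.
#' @export
species_vocabulary <- function(class = c("all", "pl", "tg", "other")) {
  switch(match.arg(class),
         all = c(PL_SPECIES, TG_SPECIES, OTHER_SPECIES),
         pl = PL_SPECIES, tg = TG_SPECIES, other = OTHER_SPECIES)
}

#' Construct a bead frame
#'
#' A single configuration of a coarse-grained bilayer system: bead
#' coordinates in a periodic orthorhombic box plus the molecule id,
#' species and bead role of every bead. Coordinates are wrapped into the
#' primary box on construction; all downstream distances use the
#' minimum-image convention.
#'
#' @param coords N x 3 numeric matrix of bead positions, nm.
#' @param box length-3 numeric, box edges (Lx, Ly, Lz), nm, all > 0.
#' @param molecule integer vector (length N): molecule id of each bead.
#' @param species character vector: species label per molecule, indexed by
#'   molecule id (so `species[molecule]` labels every bead). Labels must
#'   come from [species_vocabulary()] unless `extra_species` widens it.
#' @param role character vector (length N) in
#'   `c("head", "glycerol", "tail", "other")`; defaults to `"other"`.
#' @param time frame time, ns.
#' @param extra_species additional species labels the topology declares
#'   (each assigned a class via names: `"pl"`, `"tg"` or `"other"`).
#' @return object of class `bead_frame`.
#' @export
bead_frame <- function(coords, box, molecule, species, role = NULL,
                       time = 0, extra_species = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive finite edge lengths")
  n <- nrow(coords)
  molecule <- as.integer(molecule)
  if (length(molecule) != n || anyNA(molecule))
    stop("every bead must map to exactly one molecule")
  nmol <- max(molecule, 0L)
  if (n > 0 && (min(molecule) < 1L)) stop("molecule ids must be >= 1")
  species <- as.character(species)
  if (length(species) != nmol)
    stop("species must label every molecule id 1..", nmol)
  vocab <- c(species_vocabulary("all"), unname(extra_species))
  bad <- setdiff(unique(species), vocab)
  if (length(bad))
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
         " (declare them via extra_species)")
  if (is.null(role)) role <- rep("other", n)
  role <- as.character(role)
  if (length(role) != n || !all(role %in% BEAD_ROLES))
    stop("role must be one of ", paste(BEAD_ROLES, collapse = "/"),
         " for every bead")
  structure(list(time = as.numeric(time), box = box,
                 coords = wrap_coords(coords, box),
                 molecule = molecule, species = species, role = role,
                 extra_species = extra_species),
            class = "bead_frame")
}

#' @export
print.bead_frame <- function(x, ...) {
  cat(sprintf("bead_frame: %d beads, %d molecules, box %.2f x %.2f x %.2f nm, t = %g ns\n",
              nrow(x$coords), length(x$species), x$box[1], x$box[2], x$box[3],
              x$time))
  print(table(x$species))
  invisible(x)
}

# Species class lookup honouring topology-declared extensions.
.species_class <- function(frame, labels) {
  cls <- rep("other", length(labels))
  cls[labels %in% PL_SPECIES] <- "pl"
  cls[labels %in% TG_SPECIES] <- "tg"
  ex <- frame$extra_species
  if (!is.null(ex) && !is.null(names(ex)))
    for (cl in c("pl", "tg", "other")) cls[labels %in% ex[names(ex) == cl]] <- cl
  cls
}

#' Molecule ids of a species class
#'
#' @param frame a [bead_frame()].
#' @param class `"pl"`, `"tg"` or `"other"`.
#' @return integer vector of molecule ids.
#' @export
molecules_of_class <- function(frame, class = c("pl", "tg", "other")) {
  class <- match.arg(class)
  which(.species_class(frame, frame$species) == class)
}

#' Molecule reference positions
#'
#' One position per molecule: beads are first made whole across the
#' periodic boundary (minimum-image unwrapped relative to the molecule's
#' first bead), then averaged unweighted, then wrapped back. This is the
#' default distance reference point for all molecule-level analyses; pass
#' `mode = "beads"` to distance-based operations that support it to use
#' minimum inter-bead distances instead.
#'
#' @param frame a [bead_frame()].
#' @param which optional integer vector of molecule ids (default all).
#' @return M x 3 matrix of wrapped positions, rownames = molecule ids.
#' @export
molecule_positions <- function(frame, which = NULL) {
  mol <- frame$molecule
  ids <- sort(unique(mol))
  ref_bead <- match(ids, mol)            # first bead of each molecule
  ref <- frame$coords[ref_bead, , drop = FALSE]
  disp <- min_image(frame$coords - ref[match(mol, ids), , drop = FALSE],
                    frame$box)
  sums <- rowsum(disp, mol)
  cnt <- as.vector(table(factor(mol, levels = ids)))
  pos <- wrap_coords(ref + sums / cnt, frame$box)
  rownames(pos) <- ids
  if (!is.null(which)) pos <- pos[match(which, ids), , drop = FALSE]
  pos
}

`%||%` <- function(a, b) if (is.null(a)) b else a
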