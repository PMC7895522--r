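# 2D lateral density and enrichment/depletion maps around a lens.

#' Time-averaged lateral number-density map of a species
#'
#' Bins molecule positions of one species on a lateral grid, averaged
#' over frames, in molecules / nm^2. With `alignment = "lens"` each frame
#' is recentred so the lens centroid (from [classify_tg()]) sits at the
#' box centre before binning; without a lens the frame is used as is.
#'
#' @param traj a [trajectory()] (or single [bead_frame()]).
#' @param species species label to map.
#' @param cell nm, grid cell edge (default 1).
#' @param alignment `"lens"` (default) or `"box"`.
#' @param ... lens-protocol parameters passed to [classify_tg()] when
#'   `alignment = "lens"`.
#' @return object of class `density_map`: `density` (nx x ny, nm^-2),
#'   `counts` (summed), `cell`, `box`, `n_frames`, `species`.
#' @export
lateral_density <- function(traj, species, cell = 1.0,
                            alignment = c("lens", "box"), ...) {
  alignment <- match.arg(alignment)
  frames <- if (inherits(traj, "bead_frame")) list(traj) else traj$frames
  if (!any(frames[[1]]$species == species))
    stop("species ", species, " absent from the system")
  box <- frames[[1]]$box
  nx <- max(1L, round(box[1] / cell)); ny <- max(1L, round(box[2] / cell))
  counts <- matrix(0, nx, ny)
  for (f in frames) {
    pos <- molecule_positions(f)
    ids <- as.integer(rownames(pos))
    shift <- c(0, 0)
    if (alignment == "lens") {
      cl <- classify_tg(f, ...)
      if (length(cl$lens)) {
        lens_pos <- pos[match(cl$lens, ids), , drop = FALSE]
        cen <- vapply(1:2, function(k) {
          th <- lens_pos[, k] / box[k] * 2 * pi
          atan2(mean(sin(th)), mean(cos(th))) / (2 * pi) * box[k]
        }, 0)
        shift <- box[1:2] / 2 - cen
      }
    }
    sel <- ids[f$species[ids] == species]
    p <- pos[match(sel, ids), 1:2, drop = FALSE]
    p <- sweep(p, 2, shift, "+") %% rep(box[1:2], each = nrow(p))
    ix <- pmin(floor(p[, 1] / box[1] * nx), nx - 1)
    iy <- pmin(floor(p[, 2] / box[2] * ny), ny - 1)
    tab <- table(ix + nx * iy)
    counts[as.integer(names(tab)) + 1] <- counts[as.integer(names(tab)) + 1] +
      as.integer(tab)
  }
  area <- (box[1] / nx) * (box[2] / ny)
  structure(list(density = counts / (length(frames) * area), counts = counts,
                 cell = c(box[1] / nx, box[2] / ny), box = box,
                 n_frames = length(frames), species = species),
            class = "density_map")
}

#' Enrichment/depletion map of a species
#'
#' Cell-wise local fraction of species X among a background set, divided
#' by the bulk fraction: `E = [rho_X / (rho_X + rho_bg)] / x_bulk`.
#' E > 1 marks enrichment, E < 1 depletion. Cells whose expected total
#' count over the averaging window falls below `floor_count` are masked
#' (`NA`).
#'
#' @param map_x [lateral_density()] map of the species of interest.
#' @param map_bg [lateral_density()] map summed over the background
#'   species (same grid and frames); pass the total of X + background.
#' @param bulk_fraction bulk fraction of X among X + background in (0, 1);
#'   `NULL` (default) computes it from the same maps, which makes the
#'   density-weighted mean enrichment exactly 1.
#' @param floor_count minimum expected molecules per cell over the window
#'   (default 5).
#' @return object of class `enrichment_map`: `enrichment` (matrix, `NA`
#'   where masked), `bulk_fraction`, `mask`, plus grid metadata.
#' @export
enrichment <- function(map_x, map_bg, bulk_fraction = NULL, floor_count = 5) {
  if (!identical(dim(map_x$density), dim(map_bg$density)) ||
      !isTRUE(all.equal(map_x$cell, map_bg$cell)))
    stop("maps must share an identical grid")
  tot <- map_bg$density       # background map must already include X
  if (any(tot - map_x$density < -1e-9))
    stop("map_bg must be the summed map of X plus background species")
  if (is.null(bulk_fraction))
    bulk_fraction <- sum(map_x$counts) / sum(map_bg$counts)
  if (bulk_fraction <= 0 || bulk_fraction >= 1)
    stop("bulk fraction must be in (0, 1)")
  frac <- map_x$density / tot
  e <- frac / bulk_fraction
  mask <- map_bg$counts < floor_count
  e[mask] <- NA_real_
  structure(list(enrichment = e, bulk_fraction = bulk_fraction, mask = mask,
                 cell = map_x$cell, box = map_x$box,
                 species = map_x$species),
            class = "enrichment_map")
}

#' @export
print.enrichment_map <- function(x, ...) {
  rng <- range(x$enrichment, na.rm = TRUE)
  cat(sprintf(paste0("enrichment_map (%s): %d x %d cells, bulk fraction ",
                     "%.3g, range %.2f-%.2f, %d masked\n"),
              x$species, nrow(x$enrichment), ncol(x$enrichment),
              x$bulk_fraction, rng[1], rng[2], sum(x$mask)))
  invisible(x)
}

#' Write a lateral map as matrix text
#'
#' One row of whitespace-separated values per grid line; `NA` for masked
#' cells. Readable back with [as.matrix()] + [read.table()].
#'
#' @param map a `density_map` or `enrichment_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  m <- if (inherits(map, "enrichment_map")) map$enrichment else map$density
  write.table(format(m, digits = 8), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
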