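# Periodic-box geometry: wrapping, minimum-image displacements and
# cell-list neighbour searches. All boxes are orthorhombic, periodic in
# all three axes; coordinates are stored wrapped into [0, L).

#' Wrap coordinates into the primary periodic box
#'
#' @param coords N x 3 numeric matrix, nm.
#' @param box length-3 numeric, box edges (Lx, Ly, Lz) in nm.
#' @return N x 3 matrix with every coordinate in `[0, L)` per axis.
#' @export
wrap_coords <- function(coords, box) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(box) == 3, all(box > 0))
  out <- coords - sweep(floor(sweep(coords, 2, box, "/")), 2, box, "*")
  # guard against x == L from floating-point roundoff at the boundary
  for (k in 1:3) out[out[, k] >= box[k], k] <- 0
  out
}

# Minimum-image displacement a - b (both n x 3, recycled), per axis.
min_image <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Minimum-image distances between two coordinate sets
#'
#' Pairwise minimum-image Euclidean distances; used by the brute-force
#' reference paths and for small systems.
#'
#' @param a,b matrices of positions (n x 3, m x 3), nm.
#' @param box box edges, nm.
#' @return n x m matrix of distances.
#' @export
min_image_dist <- function(a, b, box) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

# Cell-list bins. Returns list(id = 0-based cell id per point, n = cells
# per axis). Cell width >= cutoff whenever the axis admits >= 1 cell.
.cell_bins <- function(pos, box, cutoff) {
  n <- pmax(1L, as.integer(floor(box / cutoff)))
  w <- box / n
  ix <- pmin(as.integer(floor(pos[, 1] / w[1])), n[1] - 1L)
  iy <- pmin(as.integer(floor(pos[, 2] / w[2])), n[2] - 1L)
  iz <- pmin(as.integer(floor(pos[, 3] / w[3])), n[3] - 1L)
  list(id = ix + n[1] * (iy + n[2] * iz), n = n)
}

# Neighbour cell ids (0-based) for each point, one offset at a time.
.shift_cells <- function(bins, ox, oy, oz) {
  n <- bins$n
  id <- bins$id
  ix <- id %% n[1]; rest <- id %/% n[1]
  iy <- rest %% n[2]; iz <- rest %/% n[2]
  jx <- (ix + ox) %% n[1]; jy <- (iy + oy) %% n[2]; jz <- (iz + oz) %% n[3]
  jx + n[1] * (jy + n[2] * jz)
}

.offsets27 <- as.matrix(expand.grid(ox = -1:1, oy = -1:1, oz = -1:1))

#' Pairs of points within a cutoff (periodic cell-list search)
#'
#' Finds all unordered pairs `(i, j)`, `i < j`, whose minimum-image
#' distance is at most `cutoff`. Neighbour candidates come from a periodic
#' cell list; distances are then evaluated exactly, so the result is
#' identical to an all-pairs search.
#'
#' @param pos n x 3 matrix of wrapped positions, nm.
#' @param box box edges, nm.
#' @param cutoff nm; must be below half the smallest box edge.
#' @return two-column integer matrix of pair indices (possibly 0 rows).
#' @export
neighbor_pairs <- function(pos, box, cutoff) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (cutoff >= min(box) / 2)
    stop("cutoff (", cutoff, " nm) must be < half the smallest box edge; ",
         "periodic self-images would be ambiguous")
  if (n < 2) return(matrix(integer(0), 0, 2))
  bins <- .cell_bins(pos, box, cutoff)
  by_cell <- split(seq_len(n), bins$id)
  cell_of <- match(as.character(bins$id), names(by_cell))
  ii <- integer(0); jj <- integer(0)
  for (r in seq_len(nrow(.offsets27))) {
    o <- .offsets27[r, ]
    nb <- .shift_cells(bins, o[1], o[2], o[3])
    slot <- match(as.character(nb), names(by_cell))
    keep <- !is.na(slot)
    if (!any(keep)) next
    cand <- by_cell[slot[keep]]
    len <- lengths(cand)
    a <- rep.int(which(keep), len)
    b <- unlist(cand, use.names = FALSE)
    sel <- a < b
    ii <- c(ii, a[sel]); jj <- c(jj, b[sel])
  }
  if (!length(ii)) return(matrix(integer(0), 0, 2))
  key <- (ii - 1) * n + jj          # dedupe aliased periodic candidates
  first <- !duplicated(key)
  ii <- ii[first]; jj <- jj[first]
  d <- min_image(pos[ii, , drop = FALSE] - pos[jj, , drop = FALSE], box)
  ok <- rowSums(d * d) <= cutoff^2
  cbind(ii[ok], jj[ok])
}

#' Minimum distance from each query point to a reference set
#'
#' For each row of `a`, the minimum-image distance to the nearest point of
#' `b`, computed with a periodic cell list (exact, capped at `cap`).
#' Distances larger than `cap` are reported as `Inf`, which is all the
#' classification logic ever needs.
#'
#' @param a n x 3 query positions, nm. @param b m x 3 reference positions.
#' @param box box edges, nm.
#' @param cap nm; distances beyond this are reported as `Inf`.
#' @return numeric vector of length n.
#' @export
nearest_dist <- function(a, b, box, cap) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  if (n == 0) return(numeric(0))
  if (nrow(b) == 0) return(rep(Inf, n))
  if (cap >= min(box) / 2)
    stop("cap (", cap, " nm) must be < half the smallest box edge")
  bins_b <- .cell_bins(b, box, cap)
  by_cell <- split(seq_len(nrow(b)), bins_b$id)
  bins_a <- .cell_bins(a, box, cap)
  best <- rep(Inf, n)
  for (r in seq_len(nrow(.offsets27))) {
    o <- .offsets27[r, ]
    nb <- .shift_cells(bins_a, o[1], o[2], o[3])
    slot <- match(as.character(nb), names(by_cell))
    keep <- !is.na(slot)
    if (!any(keep)) next
    cand <- by_cell[slot[keep]]
    len <- lengths(cand)
    ai <- rep.int(which(keep), len)
    bi <- unlist(cand, use.names = FALSE)
    d <- min_image(a[ai, , drop = FALSE] - b[bi, , drop = FALSE], box)
    dist2 <- rowSums(d * d)
    agg <- tapply(dist2, ai, min)
    idx <- as.integer(names(agg))
    best[idx] <- pmin(best[idx], sqrt(unname(agg)))
  }
  best[best > cap] <- Inf
  best
}
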