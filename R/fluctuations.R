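# Bending modulus estimation from membrane height fluctuations.
#
# For a tensionless membrane the Helfrich spectrum is
#   <|h_q|^2> = kT / (A kappa q^4)
# with h_q = (1/N) sum_r h(r) exp(-i q r) (discrete Fourier convention)
# and A the projected area. kappa here is the *bilayer* modulus; the
# monolayer modulus used in curvature-stress bookkeeping is kappa / 2.

# Minimum-image wavevector components of an N-point axis of length L.
.q_axis <- function(N, L) {
  k <- 0:(N - 1)
  k[k > N / 2] <- k[k > N / 2] - N
  2 * pi * k / L
}

.q_grid <- function(Nx, Ny, Lx, Ly) {
  qx <- .q_axis(Nx, Lx); qy <- .q_axis(Ny, Ly)
  sqrt(outer(qx^2, rep(1, Ny)) + outer(rep(1, Nx), qy^2))
}

#' Extract bilayer height fields from a frame
#'
#' Bins the reference beads (role `"glycerol"` by default) of each leaflet
#' onto an `Nx x Ny` lateral grid and averages their z per cell. Leaflets
#' are assigned by z relative to the mean reference-bead height. Empty
#' cells are filled from the nearest occupied cell and counted; more than
#' 20% empty cells is an error (grid too fine for the bead density).
#'
#' @param frame a [bead_frame()].
#' @param grid integer length-2 `(Nx, Ny)` (a scalar is squared).
#' @param role bead role used as the surface reference.
#' @return list of class `height_field`: `mid` (bilayer midplane field,
#'   leaflet average, Nx x Ny, nm), `upper`, `lower`, `box`, `empty_frac`.
#' @export
extract_height_field <- function(frame, grid = c(32, 32), role = "glycerol") {
  if (length(grid) == 1) grid <- c(grid, grid)
  sel <- frame$role == role
  if (!any(sel)) sel <- rep(TRUE, length(frame$role)) # no roles declared
  xyz <- frame$coords[sel, , drop = FALSE]
  mid_z <- mean(xyz[, 3])
  upper <- xyz[, 3] >= mid_z
  bin_leaflet <- function(pts) {
    ix <- pmin(floor(pts[, 1] / frame$box[1] * grid[1]), grid[1] - 1)
    iy <- pmin(floor(pts[, 2] / frame$box[2] * grid[2]), grid[2] - 1)
    cell <- ix + grid[1] * iy
    m <- matrix(NA_real_, grid[1], grid[2])
    agg <- tapply(pts[, 3], cell, mean)
    m[as.integer(names(agg)) + 1] <- agg
    m
  }
  up <- bin_leaflet(xyz[upper, , drop = FALSE])
  lo <- bin_leaflet(xyz[!upper, , drop = FALSE])
  empty <- mean(is.na(up)) / 2 + mean(is.na(lo)) / 2
  if (empty > 0.2)
    stop(sprintf("%.0f%% of grid cells are empty; the grid is too fine ",
                 100 * empty), "for the bead density")
  fill <- function(m) {
    if (!anyNA(m)) return(m)
    nas <- which(is.na(m), arr.ind = TRUE)
    occ <- which(!is.na(m), arr.ind = TRUE)
    for (r in seq_len(nrow(nas))) {
      # periodic nearest occupied cell
      d <- pmin(abs(occ[, 1] - nas[r, 1]), grid[1] - abs(occ[, 1] - nas[r, 1]))^2 +
           pmin(abs(occ[, 2] - nas[r, 2]), grid[2] - abs(occ[, 2] - nas[r, 2]))^2
      m[nas[r, 1], nas[r, 2]] <- m[occ[which.min(d), 1], occ[which.min(d), 2]]
    }
    m
  }
  up <- fill(up); lo <- fill(lo)
  structure(list(mid = (up + lo) / 2, upper = up, lower = lo,
                 box = frame$box, empty_frac = empty),
            class = "height_field")
}

#' Bending modulus from the Fourier fluctuation spectrum
#'
#' Computes per-mode mean squared Fourier amplitudes of a sequence of
#' height fields, averages them in q-shells of width `2 pi / L`, and fits
#' the Helfrich `kT / (A kappa q^4)` law. kappa is estimated (in kT) from
#' the mean of `q^4 <|h_q|^2>` over the fit range -- each mode is an
#' unbiased sample of `1 / (A kappa)` -- and the log-log slope over the
#' shells is reported as a diagnostic (ideal: -4).
#'
#' @param fields list of Nx x Ny height matrices (nm), or of
#'   [extract_height_field()] results (their `mid` fields are used).
#' @param box length-2 (Lx, Ly) nm; taken from the fields if present.
#' @param q_range nm^-1, `c(qmin, qmax)` fit window, or `NULL` for the
#'   default: the four smallest nonzero shells capped at 1.0 nm^-1.
#' @return object of class `fluctuation_spectrum`: `q` (shell centres),
#'   `Sq` (shell-mean <|h_q|^2>), `kappa` (bilayer, kT), `kappa_b`
#'   (monolayer = kappa/2), `slope` (log-log diagnostic), `fit_range`,
#'   `n_frames`, `no_undulation` flag.
#' @export
kappa_fourier <- function(fields, box = NULL, q_range = NULL) {
  if (inherits(fields[[1]], "height_field")) {
    if (is.null(box)) box <- fields[[1]]$box[1:2]
    fields <- lapply(fields, `[[`, "mid")
  }
  if (is.null(box)) stop("box (Lx, Ly) is required")
  if (length(box) == 1) box <- c(box, box)
  Nx <- nrow(fields[[1]]); Ny <- ncol(fields[[1]])
  A <- box[1] * box[2]
  q <- .q_grid(Nx, Ny, box[1], box[2])
  S <- matrix(0, Nx, Ny)
  for (h in fields) {
    hq <- fft(h - mean(h)) / (Nx * Ny)
    S <- S + Mod(hq)^2
  }
  S <- S / length(fields)
  dq <- 2 * pi / max(box)
  shell <- round(q / dq)
  keep <- shell > 0
  shell_q <- tapply(q[keep], shell[keep], mean)
  shell_S <- tapply(S[keep], shell[keep], mean)
  if (is.null(q_range)) {
    qs <- sort(shell_q)
    q_range <- c(0, min(1.0, qs[min(4, length(qs))] + dq / 2))
  }
  in_rng <- shell_q > q_range[1] & shell_q <= q_range[2]
  if (sum(in_rng) < 3)
    stop("fewer than 3 q-shells in the fit range; widen q_range or the box")
  mode_rng <- keep & q > q_range[1] & q <= q_range[2]
  x <- mean((q^4 * S)[mode_rng])
  no_und <- !is.finite(x) || x <= 0
  kappa <- if (no_und) Inf else 1 / (A * x)
  slope <- if (no_und) NA_real_ else
    unname(coef(lm(log(shell_S[in_rng]) ~ log(shell_q[in_rng])))[2])
  if (no_und)
    warning("no measurable undulation: spectrum is flat/zero, kappa diverges")
  structure(list(q = as.numeric(shell_q), Sq = as.numeric(shell_S),
                 kappa = kappa, kappa_b = kappa / 2, slope = slope,
                 fit_range = q_range, area = A, grid = c(Nx, Ny),
                 n_frames = length(fields), no_undulation = no_und),
            class = "fluctuation_spectrum")
}

#' @export
print.fluctuation_spectrum <- function(x, ...) {
  cat(sprintf(paste0("fluctuation_spectrum: kappa = %.3g kT (monolayer ",
                     "%.3g kT), slope %.2f, %d frames\n"),
              x$kappa, x$kappa_b, x$slope, x$n_frames))
  invisible(x)
}

# Exact expectation of the patch-mean variance for a Helfrich field on an
# N-point grid: sum over nonzero modes of |D_p(q)|^2 / (A q^4), where D_p
# is the p-cell Dirichlet (boxcar) kernel. kT = 1 (kappa in kT units).
.patch_variance_constant <- function(p, Nx, Ny, Lx, Ly) {
  dir_kernel <- function(N, p) {
    k <- 0:(N - 1)
    out <- rep(1, N)
    nz <- k != 0
    out[nz] <- abs(sin(pi * k[nz] * p / N) / (p * sin(pi * k[nz] / N)))
    out
  }
  Dx <- dir_kernel(Nx, p); Dy <- dir_kernel(Ny, p)
  q <- .q_grid(Nx, Ny, Lx, Ly)
  W <- outer(Dx^2, Dy^2)
  nz <- q > 0
  sum(W[nz] / q[nz]^4) / (Lx * Ly)
}

#' Bending modulus from real-space patch variances
#'
#' Real-space counterpart of [kappa_fourier()]: the variance (across patch
#' positions and frames) of the mean height of `p x p`-cell patches,
#' relative to the frame mean, scales as `K(p) / kappa` where `K(p)` is
#' the exact lattice sum of the discrete Helfrich spectrum filtered by the
#' patch boxcar kernel. One kappa estimate per patch size is averaged.
#'
#' @param fields as in [kappa_fourier()].
#' @param box length-2 (Lx, Ly) nm.
#' @param patch_cells integer vector of patch edge lengths in grid cells;
#'   must divide the grid. Default: powers of 2 from 2 to N/4.
#' @return list: `kappa` (bilayer, kT), `kappa_b`, `per_patch` (named
#'   estimates), `variances`, `patch_cells`.
#' @export
kappa_realspace <- function(fields, box = NULL, patch_cells = NULL) {
  if (inherits(fields[[1]], "height_field")) {
    if (is.null(box)) box <- fields[[1]]$box[1:2]
    fields <- lapply(fields, `[[`, "mid")
  }
  if (is.null(box)) stop("box (Lx, Ly) is required")
  if (length(box) == 1) box <- c(box, box)
  Nx <- nrow(fields[[1]]); Ny <- ncol(fields[[1]])
  if (is.null(patch_cells)) {
    patch_cells <- 2^(1:20)
    patch_cells <- patch_cells[patch_cells <= min(Nx, Ny) / 4]
  }
  if (any(Nx %% patch_cells != 0 | Ny %% patch_cells != 0))
    stop("patch_cells must divide the grid dimensions")
  vars <- vapply(patch_cells, function(p) {
    vals <- unlist(lapply(fields, function(h) {
      h <- h - mean(h)
      # p x p block means via row/col aggregation
      rb <- rowsum(h, rep(seq_len(Nx / p), each = p)) / p
      cb <- t(rowsum(t(rb), rep(seq_len(Ny / p), each = p))) / p
      as.numeric(cb)
    }))
    mean(vals^2)
  }, 0)
  if (all(vars == 0)) stop("flat fields: no undulation to fit")
  monotone <- !is.unsorted(rev(vars), strictly = FALSE)
  Kp <- vapply(patch_cells, .patch_variance_constant, 0, Nx = Nx, Ny = Ny,
               Lx = box[1], Ly = box[2])
  per <- Kp / vars
  kappa <- mean(per)
  if (!monotone && length(patch_cells) > 1) {
    warning("patch variance is not monotone decreasing with patch size; ",
            "fit rejected")
    kappa <- NA_real_
  }
  list(kappa = kappa, kappa_b = kappa / 2,
       per_patch = setNames(per, paste0("p", patch_cells)),
       variances = setNames(vars, paste0("p", patch_cells)),
       patch_cells = patch_cells)
}
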