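# Lateral pressure profile (LPP) processing.
#
# pi(z) = P_T(z) - P_N(z) with P_T = (P_xx + P_yy)/2 and P_N = P_zz.
# Derived metrics: the hydrophobic chain pressure pi_CH (Simpson integral
# of the positive pi(z) region between the two glycerol minima, 0.01 A
# bins) and the first-moment spontaneous-curvature combination
# -int_0^{Lz/2} z pi(z) dz = kappa_b c0 per leaflet.

#' Construct a pressure profile
#'
#' @param z strictly increasing slab centres, nm, midplane at z = 0 (use
#'   `recenter = TRUE` to shift the profile's symmetry point onto 0).
#' @param P_N normal pressure P_zz per slab, bar. May be a matrix with one
#'   column per replica.
#' @param P_T tangential pressure (P_xx + P_yy)/2 per slab, bar; same
#'   shape as `P_N`.
#' @param L_z box height, nm (default: span of the z grid).
#' @param recenter re-centre z on the profile's mirror-symmetry point.
#' @param tension_tol mN/m; warn when `|integral of pi dz|` exceeds this
#'   (default 0.1) since the analysis assumes a tension-free bilayer.
#' @return object of class `pressure_profile`: `z`, `P_N`, `P_T`, `pi`
#'   (replica means), per-replica matrices, `pi_sd`, `L_z`, `tension_mN_m`.
#' @export
pressure_profile <- function(z, P_N, P_T, L_z = NULL, recenter = FALSE,
                             tension_tol = 0.1) {
  z <- as.numeric(z)
  if (any(diff(z) <= 0)) stop("z grid must be strictly increasing")
  P_N <- as.matrix(P_N); P_T <- as.matrix(P_T)
  if (nrow(P_N) != length(z) || !identical(dim(P_N), dim(P_T)))
    stop("P_N and P_T must have one row per z value and equal shapes")
  pi_rep <- P_T - P_N
  pi_mean <- rowMeans(pi_rep)
  if (recenter) {
    z <- z - .symmetry_center(z, pi_mean)
  }
  if (is.null(L_z)) L_z <- diff(range(z))
  tension <- BAR_NM_TO_MN_M * .simpson_nonuniform(z, pi_mean)
  if (abs(tension) > tension_tol)
    warning(sprintf(paste0("profile carries net tension %.3g mN/m ",
                           "(tolerance %g); curvature metrics assume a ",
                           "tension-free bilayer"), tension, tension_tol))
  structure(list(z = z, P_N = rowMeans(P_N), P_T = rowMeans(P_T),
                 pi = pi_mean,
                 pi_sd = if (ncol(pi_rep) > 1) apply(pi_rep, 1, sd) else
                   rep(0, length(z)),
                 replicas = pi_rep, n_replicas = ncol(pi_rep),
                 L_z = L_z, tension_mN_m = tension),
            class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf(paste0("pressure_profile: %d slabs over [%.2f, %.2f] nm, ",
                     "%d replica(s), tension %.3g mN/m\n"),
              length(x$z), min(x$z), max(x$z), x$n_replicas, x$tension_mN_m))
  invisible(x)
}

# Mirror-symmetry point of a curve: grid search over the central half of
# the domain minimising the integrated squared asymmetry.
.symmetry_center <- function(z, y) {
  lo <- min(z); hi <- max(z)
  cand <- seq(lo + 0.25 * (hi - lo), hi - 0.25 * (hi - lo), length.out = 201)
  score <- vapply(cand, function(c0) {
    u <- seq(0, min(c0 - lo, hi - c0), length.out = 101)[-1]
    a <- approx(z, y, c0 + u, rule = 2)$y
    b <- approx(z, y, c0 - u, rule = 2)$y
    mean((a - b)^2)
  }, 0)
  cand[which.min(score)]
}

# Composite Simpson rules. Uniform grid with an odd number of points;
# even counts fall back to trapezoid on the final interval.
.simpson_uniform <- function(y, h) {
  n <- length(y)
  if (n < 2) return(0)
  if (n == 2) return(h * (y[1] + y[2]) / 2)
  m <- if (n %% 2 == 1) n else n - 1
  i <- seq_len(m)
  w <- rep(c(4, 2), length.out = m - 2)
  s <- h / 3 * (y[1] + y[m] + sum(w * y[2:(m - 1)]))
  if (m < n) s <- s + h * (y[n - 1] + y[n]) / 2
  s
}

# Simpson on a possibly non-uniform grid: resample to a fine uniform grid.
.simpson_nonuniform <- function(z, y, n_min = 2001) {
  if (length(z) < 2) return(0)
  h <- diff(range(z)) / (n_min - 1)
  zz <- seq(min(z), max(z), length.out = n_min)
  .simpson_uniform(approx(z, y, zz)$y, h)
}

#' Load a per-slab stress/pressure table
#'
#' Whitespace-delimited text with a header naming columns `z` plus either
#' stress components `Sxx Syy Szz` (convention `"stress-volume"`,
#' bar * nm^3, converted via `P = -S / V_slab`) or pressure components
#' `Pxx Pyy Pzz` (bar). Replicated component columns (e.g. `Pxx_1`,
#' `Pxx_2`, ...) are read as replicas. Slab volume comes from a comment
#' line `# slab_volume: <nm^3>`.
#'
#' @param path table file.
#' @param convention `"pressure"` or `"stress-volume"`.
#' @param length_unit unit of the z column (converted to nm).
#' @param recenter re-centre the midplane at z = 0 (default TRUE).
#' @param ... passed to [pressure_profile()].
#' @return a [pressure_profile()].
#' @export
load_stress_table <- function(path, convention = c("pressure", "stress-volume"),
                              length_unit = c("nm", "angstrom"),
                              recenter = TRUE, ...) {
  convention <- match.arg(convention)
  zscale <- switch(match.arg(length_unit), nm = 1, angstrom = 0.1)
  lines <- readLines(path)
  tab <- read.table(text = lines, header = TRUE, comment.char = "#")
  if (!"z" %in% names(tab)) stop("stress table must have a 'z' column")
  z <- tab$z * zscale
  if (any(diff(z) <= 0)) stop("z column must be strictly increasing")
  grab <- function(stem) {
    cols <- grep(paste0("^", stem, "(_[0-9]+)?$"), names(tab), value = TRUE)
    if (!length(cols)) return(NULL)
    as.matrix(tab[cols])
  }
  if (convention == "stress-volume") {
    Sxx <- grab("Sxx"); Syy <- grab("Syy"); Szz <- grab("Szz")
    if (is.null(Sxx) || is.null(Syy) || is.null(Szz))
      stop("stress-volume convention needs columns Sxx, Syy, Szz")
    vol_line <- grep("^#\\s*slab_volume:", lines, value = TRUE)
    if (!length(vol_line))
      stop("stress-volume convention requires a '# slab_volume: <nm^3>' ",
           "comment line")
    V <- as.numeric(sub("^#\\s*slab_volume:\\s*", "", vol_line[1]))
    if (!is.finite(V) || V <= 0) stop("invalid slab volume: ", V)
    P_N <- -Szz / V
    P_T <- -(Sxx + Syy) / (2 * V)
  } else {
    Pxx <- grab("Pxx"); Pyy <- grab("Pyy"); Pzz <- grab("Pzz")
    if (is.null(Pxx) || is.null(Pyy) || is.null(Pzz))
      stop("pressure convention needs columns Pxx, Pyy, Pzz")
    P_N <- Pzz
    P_T <- (Pxx + Pyy) / 2
  }
  pressure_profile(z, P_N, P_T, recenter = recenter, ...)
}

# Deepest local minima of pi(z) adjacent to the midplane, one per side;
# anchors for the glycerol-region integration bounds.
.auto_minima <- function(profile) {
  z <- profile$z; y <- profile$pi
  n <- length(y)
  loc <- which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1
  left <- loc[z[loc] < 0]; right <- loc[z[loc] > 0]
  if (!length(left) || !length(right))
    stop("no local minima flanking the midplane; pass minima = c(z1, z2) ",
         "explicitly")
  c(z[left[which.min(y[left])]], z[right[which.min(y[right])]])
}

#' Hydrophobic chain pressure pi_CH
#'
#' Integral of the positive region of the lateral pressure profile,
#' `max(pi(z), 0)`, between the two glycerol minima `z1 < 0 < z2`,
#' evaluated by Simpson's rule on a 0.01 angstrom (0.001 nm) grid and
#' converted to mN/m (1 bar nm = 0.1 mN/m). Minima are auto-detected as
#' the deepest local minima flanking the midplane unless given.
#'
#' @param profile a [pressure_profile()].
#' @param minima `"auto"` or numeric `c(z1, z2)` in nm with z1 < 0 < z2.
#' @param bin nm, integration bin (default 0.001 nm = 0.01 angstrom).
#' @return list: `pi_ch` (mN/m, replica mean), `sd` (across replicas),
#'   `minima` (nm), `per_replica`.
#' @export
chain_pressure <- function(profile, minima = "auto", bin = 0.001) {
  if (identical(minima, "auto")) minima <- .auto_minima(profile)
  if (length(minima) != 2 || minima[1] >= 0 || minima[2] <= 0)
    stop("minima must satisfy z1 < 0 < z2")
  if (minima[1] < min(profile$z) || minima[2] > max(profile$z))
    stop("minima outside the z grid")
  zz <- seq(minima[1], minima[2], by = bin)
  if (zz[length(zz)] < minima[2]) zz <- c(zz, minima[2])
  h <- zz[2] - zz[1]
  per <- apply(profile$replicas, 2, function(y) {
    f <- pmax(approx(profile$z, y, zz)$y, 0)
    BAR_NM_TO_MN_M * .simpson_uniform(f, h)
  })
  list(pi_ch = mean(per), sd = if (length(per) > 1) sd(per) else 0,
       minima = minima, per_replica = per)
}

#' First moment of the LPP: kappa_b * c0 per leaflet
#'
#' Evaluates `kappa_b c0 = -integral_0^{Lz/2} z pi(z) dz` for the upper
#' leaflet and its mirror image for the lower leaflet (sign convention
#' such that two identical leaflets give equal values), by Simpson's rule
#' on a fine uniform grid. Dividing by a monolayer bending modulus gives
#' the spontaneous curvature `c0`.
#'
#' @param profile a [pressure_profile()] with midplane at z = 0 and a grid
#'   spanning both leaflets.
#' @param kappa_b monolayer bending modulus in kT, or `NULL` to skip the
#'   `c0` conversion.
#' @param temperature K, used to express kT in mN/m nm^2 (default 310).
#' @param bin nm, integration bin (default 0.001).
#' @return list: `kb_c0` (mN/m nm, leaflet average), `kb_c0_leaflets`
#'   (upper, lower), `asymmetry` (upper - lower), `c0` (1/nm, `NA` without
#'   `kappa_b`), `sd` across replicas.
#' @export
first_moment_curvature <- function(profile, kappa_b = NULL, temperature = 310,
                                   bin = 0.001) {
  half <- profile$L_z / 2
  if (max(profile$z) < half * 0.5 || min(profile$z) > -half * 0.5)
    stop("z grid does not span a full leaflet")
  hi <- min(half, max(profile$z)); lo <- max(-half, min(profile$z))
  moment <- function(y, a, b) {
    zz <- seq(a, b, by = bin)
    if (zz[length(zz)] < b) zz <- c(zz, b)
    h <- zz[2] - zz[1]
    f <- approx(profile$z, y, zz)$y
    s <- -.simpson_uniform(abs(zz) * f, h)
    BAR_NM_TO_MN_M * s
  }
  per_up <- apply(profile$replicas, 2, moment, a = 0, b = hi)
  per_lo <- apply(profile$replicas, 2, moment, a = lo, b = 0)
  up <- mean(per_up); lo_m <- mean(per_lo)
  avg <- (per_up + per_lo) / 2
  kb_c0 <- mean(avg)
  kT_unit <- kT(temperature, "mN/m nm^2")
  c0 <- if (is.null(kappa_b)) NA_real_ else kb_c0 / (kappa_b * kT_unit)
  list(kb_c0 = kb_c0, kb_c0_leaflets = c(upper = up, lower = lo_m),
       asymmetry = up - lo_m, c0 = c0,
       sd = if (length(avg) > 1) sd(avg) else 0)
}

#' Monolayer curvature stress kappa_b * c0^2
#'
#' @param kappa_b monolayer bending modulus, kT.
#' @param c0 monolayer spontaneous curvature, 1/nm.
#' @param kappa_sd,c0_sd optional SDs for error propagation.
#' @return list: `stress` (kT/nm^2), `sd`.
#' @export
curvature_stress <- function(kappa_b, c0, kappa_sd = 0, c0_sd = 0) {
  if (kappa_b <= 0) stop("kappa_b must be > 0")
  stress <- kappa_b * c0^2
  sd_out <- sqrt((c0^2 * kappa_sd)^2 + (2 * kappa_b * c0 * c0_sd)^2)
  list(stress = stress, sd = sd_out)
}
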