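# Synthetic-data generators with known ground truth.
#
# Every analysis stage in the package is testable at desk scale against
# these generators. Bead-level realism is deliberately minimal (2-3 beads
# per lipid at fixed internal geometry): sufficient for distance,
# clustering and leaflet logic, not for energetics. Each generator is
# deterministic under a fixed seed and attaches its parameters as a
# `synthetic_spec` attribute.

.with_spec <- function(x, generator, params, seed) {
  attr(x, "synthetic_spec") <- list(generator = generator, params = params,
                                    seed = seed)
  x
}

#' Synthetic-spec metadata of a generated object
#' @param x an object produced by a `gen_*` generator.
#' @return list with `generator`, `params`, `seed` (or `NULL`).
#' @export
synthetic_spec <- function(x) attr(x, "synthetic_spec")

# Jittered square-lattice xy sites filling an L x L box.
.lattice_sites <- function(n, L, spacing, jitter, exclude_center_radius = 0) {
  nside <- ceiling(L / spacing)
  g <- (seq_len(nside) - 0.5) * (L / nside)
  sites <- as.matrix(expand.grid(x = g, y = g))
  if (exclude_center_radius > 0) {
    d <- sqrt((sites[, 1] - L / 2)^2 + (sites[, 2] - L / 2)^2)
    sites <- sites[d >= exclude_center_radius, , drop = FALSE]
  }
  if (nrow(sites) < n)
    stop("box too small: ", nrow(sites), " lattice sites for ", n,
         " molecules")
  sites <- sites[sample.int(nrow(sites), n), , drop = FALSE]
  sites + matrix(runif(2 * n, -jitter, jitter), n, 2)
}

#' Generate a planar bilayer frame
#'
#' Two leaflets of jittered-lattice lipids (head/glycerol/tail beads at
#' fixed z offsets from the midplane) with species assigned per the
#' composition, plus optionally uniformly diluted TG molecules between
#' the leaflets.
#'
#' @param species_counts named integer vector of molecule counts; TG
#'   species are placed between the leaflets, all others on the leaflet
#'   lattice.
#' @param apl nm^2 area per lipid on the lattice (default 0.64).
#' @param Lz box height, nm (default 12).
#' @param thickness nm between the two glycerol planes (default 4).
#' @param tg_mode `"uniform"`: TG placed uniformly at random near the
#'   midplane; `"none"`: TG counts ignored.
#' @param jitter nm of uniform positional jitter (default 0.12).
#' @param time frame time, ns.
#' @param seed RNG seed (`set.seed`) for reproducibility.
#' @return a [bead_frame()]; ground-truth labels in attributes
#'   `leaflet` (+1/-1 per molecule, 0 for TG) and `synthetic_spec`.
#' @export
gen_bilayer_frame <- function(species_counts, apl = 0.64, Lz = 12,
                              thickness = 4, tg_mode = c("uniform", "none"),
                              jitter = 0.12, time = 0, seed = NULL) {
  tg_mode <- match.arg(tg_mode)
  if (!is.null(seed)) set.seed(seed)
  counts <- species_counts[species_counts > 0]
  is_tg <- names(counts) %in% species_vocabulary("tg")
  n_tg <- if (tg_mode == "none") 0L else sum(counts[is_tg])
  lip_counts <- counts[!is_tg]
  n_lip <- sum(lip_counts)
  if (n_lip < 2) stop("need at least one lipid per leaflet")
  n_up <- ceiling(n_lip / 2)
  L <- max(sqrt(n_up * apl) * 1.02, 2 * 5.2)  # keep cutoffs < L/2 workable
  mid <- Lz / 2
  # species labels interleaved so each leaflet gets an even split
  labels <- rep(names(lip_counts), lip_counts)
  labels <- labels[order(rep(seq_along(lip_counts), lip_counts),
                         seq_len(n_lip))]
  idx <- unlist(lapply(seq_along(lip_counts), function(i)
    which(labels == names(lip_counts)[i])))
  leaflet <- integer(n_lip)
  for (sp in names(lip_counts)) {
    w <- which(labels == sp)
    leaflet[w] <- rep(c(1L, -1L), length.out = length(w))
  }
  coords <- list(); mol <- list(); role <- list()
  mol_id <- 0L
  species_per_mol <- character(0)
  leaflet_out <- integer(0)
  for (side in c(1L, -1L)) {
    sel <- which(leaflet == side)
    if (!length(sel)) next
    xy <- .lattice_sites(length(sel), L, sqrt(apl), jitter)
    for (j in seq_along(sel)) {
      mol_id <- mol_id + 1L
      sp <- labels[sel[j]]
      species_per_mol <- c(species_per_mol, sp)
      leaflet_out <- c(leaflet_out, side)
      zg <- mid + side * thickness / 2
      if (sp == "CHOL") {
        z <- c(zg, zg - side * 1.0)
        r <- c("other", "tail")
      } else {
        z <- c(zg + side * 0.45, zg, zg - side * 1.0)
        r <- c("head", "glycerol", "tail")
      }
      nb <- length(z)
      coords[[mol_id]] <- cbind(xy[j, 1] + runif(nb, -jitter, jitter),
                                xy[j, 2] + runif(nb, -jitter, jitter),
                                z + runif(nb, -jitter, jitter))
      mol[[mol_id]] <- rep(mol_id, nb)
      role[[mol_id]] <- r
    }
  }
  if (n_tg > 0) {
    tg_labels <- rep(names(counts[is_tg]), counts[is_tg])
    for (j in seq_len(n_tg)) {
      mol_id <- mol_id + 1L
      species_per_mol <- c(species_per_mol, tg_labels[j])
      leaflet_out <- c(leaflet_out, 0L)
      cx <- runif(1, 0, L); cy <- runif(1, 0, L)
      cz <- mid + runif(1, -0.8, 0.8)
      coords[[mol_id]] <- cbind(cx + runif(3, -0.3, 0.3),
                                cy + runif(3, -0.3, 0.3),
                                cz + runif(3, -0.3, 0.3))
      mol[[mol_id]] <- rep(mol_id, 3L)
      role[[mol_id]] <- c("glycerol", "tail", "tail")
    }
  }
  fr <- bead_frame(do.call(rbind, coords), c(L, L, Lz),
                   unlist(mol), species_per_mol, unlist(role), time = time)
  attr(fr, "leaflet") <- leaflet_out
  .with_spec(fr, "gen_bilayer_frame",
             list(species_counts = as.list(counts), apl = apl, Lz = Lz,
                  thickness = thickness, tg_mode = tg_mode), seed)
}

#' Implant a TG lens into a bilayer frame
#'
#' Inserts `n_tg` TG molecules uniformly filling a biconvex (oblate
#' spheroid) volume between the leaflets at the box centre, displacing
#' the leaflet beads outward over the lens footprint, and records the
#' implanted membership.
#'
#' @param frame a [bead_frame()] (e.g. from [gen_bilayer_frame()]).
#' @param n_tg number of TG molecules to implant (0 returns the frame
#'   unchanged).
#' @param radius nm, lateral lens radius.
#' @param thickness nm, full lens thickness at the centre (default 5).
#' @param clearance nm of extra leaflet displacement above the lens
#'   surface (default 1.2).
#' @param tg_species species label of the implanted TG.
#' @param seed RNG seed.
#' @return a [bead_frame()] with attribute `lens_members` (implanted TG
#'   molecule ids).
#' @export
implant_lens <- function(frame, n_tg, radius, thickness = 5, clearance = 1.2,
                         tg_species = "TG", seed = NULL) {
  if (n_tg == 0) return(frame)
  if (!is.null(seed)) set.seed(seed)
  box <- frame$box
  if (2 * radius >= min(box[1], box[2]))
    stop("lens does not fit in the box")
  cx <- box[1] / 2; cy <- box[2] / 2; cz <- box[3] / 2
  h0 <- thickness / 2
  # uniform sampling inside the spheroid by rejection
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n_tg) {
    m <- 2 * (n_tg - nrow(pts)) + 20
    u <- cbind(runif(m, -1, 1), runif(m, -1, 1), runif(m, -1, 1))
    keep <- rowSums(u^2) <= 1
    pts <- rbind(pts, u[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n_tg), , drop = FALSE]
  centers <- cbind(cx + pts[, 1] * radius, cy + pts[, 2] * radius,
                   cz + pts[, 3] * h0)
  # displace leaflet beads outward over the (slightly widened) footprint
  co <- frame$coords
  rho2 <- (co[, 1] - cx)^2 + (co[, 2] - cy)^2
  Rb <- radius + clearance
  inside <- rho2 < Rb^2
  bump <- sqrt(pmax(1 - rho2[inside] / Rb^2, 0)) * (h0 + clearance)
  above <- co[inside, 3] >= cz
  co[inside, 3] <- co[inside, 3] + ifelse(above, bump, -bump)
  # append TG beads (3 per molecule, tight)
  n0 <- max(frame$molecule)
  tg_mol <- rep(n0 + seq_len(n_tg), each = 3)
  jit <- matrix(runif(9 * n_tg, -0.25, 0.25), ncol = 3)
  tg_beads <- centers[rep(seq_len(n_tg), each = 3), ] + jit
  fr <- bead_frame(rbind(co, tg_beads), box,
                   c(frame$molecule, tg_mol),
                   c(frame$species, rep(tg_species, n_tg)),
                   c(frame$role, rep(c("glycerol", "tail", "tail"), n_tg)),
                   time = frame$time, extra_species = frame$extra_species)
  attr(fr, "lens_members") <- n0 + seq_len(n_tg)
  attr(fr, "leaflet") <- c(attr(frame, "leaflet"), rep(0L, n_tg))
  .with_spec(fr, "implant_lens",
             list(n_tg = n_tg, radius = radius, thickness = thickness,
                  clearance = clearance), seed)
}

#' Generate a lens/bilayer coexistence frame with exact classification
#'
#' Purpose-built fixture for the diluted-TG protocol: a dense TG lens at
#' the box centre whose every molecule is farther than the TG-PL cutoff
#' from all PLs, exactly `n_pl` PL molecules all of which lie in the
#' lens-free region, and exactly `n_free_tg` diluted TG placed among the
#' PLs (each within PL contact, away from the lens and from each other).
#' [classify_tg()] at default parameters therefore returns exactly
#' `n_lens_tg` lens, `n_free_tg` diluted and a percentage of
#' `100 * n_free_tg / n_pl`.
#'
#' @param n_lens_tg TG molecules in the lens.
#' @param n_free_tg diluted TG molecules.
#' @param n_pl PL molecules (split across the two leaflets).
#' @param pl_species species label of the PLs.
#' @param lens_half_thickness nm (default 3).
#' @param apl nm^2 area per lipid (default 0.64).
#' @param seed RNG seed.
#' @return a [bead_frame()] with ground-truth attributes `lens_members`,
#'   `free_members` and `synthetic_spec`.
#' @export
gen_coexistence_frame <- function(n_lens_tg, n_free_tg, n_pl,
                                  pl_species = "DOPC",
                                  lens_half_thickness = 3, apl = 0.64,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- 1.15                      # TG packing in the lens, nm
  h0 <- lens_half_thickness
  # grow the lens radius until the spheroid lattice holds n_lens_tg sites
  r <- max(3, sqrt(n_lens_tg * spacing^3 / (4 / 3 * pi * h0)))
  repeat {
    g <- seq(-r, r, by = spacing)
    gz <- seq(-h0 + 0.3, h0 - 0.3, by = spacing)
    sites <- as.matrix(expand.grid(x = g, y = g, z = gz))
    ok <- sites[, 1]^2 / r^2 + sites[, 2]^2 / r^2 +
      sites[, 3]^2 / h0^2 <= 1
    if (sum(ok) >= n_lens_tg) break
    r <- r * 1.12
  }
  sites <- sites[ok, , drop = FALSE]
  ord <- order(sites[, 1]^2 + sites[, 2]^2 + sites[, 3]^2)
  lens_xyz <- sites[ord[seq_len(n_lens_tg)], , drop = FALSE]
  r_eff <- sqrt(max(lens_xyz[, 1]^2 + lens_xyz[, 2]^2))
  R_clear <- r_eff + 3.2               # PLs farther than 2.8 nm from lens
  # PL lattice outside the clearance disc; box sized to hold them and to
  # leave an annulus beyond the clearance for the diluted TG
  n_up <- ceiling(n_pl / 2)
  L <- max(sqrt(n_up * apl + pi * R_clear^2) * 1.15,
           2 * (R_clear + 4.5))
  Lz <- max(14, 2 * (h0 + 4))
  mid <- Lz / 2
  bead_rows <- list(); mol_ids <- list(); roles <- list()
  k <- 0L
  add_mol <- function(xyz, r) {
    k <<- k + 1L
    bead_rows[[k]] <<- xyz
    mol_ids[[k]] <<- rep(k, nrow(xyz))
    roles[[k]] <<- r
  }
  for (i in seq_len(n_lens_tg)) {
    c0 <- c(L / 2 + lens_xyz[i, 1], L / 2 + lens_xyz[i, 2],
            mid + lens_xyz[i, 3])
    add_mol(matrix(c0, 3, 3, byrow = TRUE) +
              matrix(runif(9, -0.2, 0.2), 3, 3),
            c("glycerol", "tail", "tail"))
  }
  n_lens_mols <- k
  for (side in c(1L, -1L)) {
    n_here <- if (side == 1L) n_up else n_pl - n_up
    if (!n_here) next
    xy <- .lattice_sites(n_here, L, sqrt(apl), 0.1,
                         exclude_center_radius = R_clear)
    for (j in seq_len(n_here)) {
      zg <- mid + side * 2
      add_mol(cbind(xy[j, 1] + runif(3, -0.1, 0.1),
                    xy[j, 2] + runif(3, -0.1, 0.1),
                    c(zg + side * 0.45, zg, zg - side * 1.0) +
                      runif(3, -0.1, 0.1)),
              c("head", "glycerol", "tail"))
    }
  }
  pl_ids <- (n_lens_mols + 1L):k
  # diluted TG: midplane positions among the PLs, mutually >= 2 nm apart,
  # >= R_clear + 2.6 from the lens axis (so >= margin from every lens TG)
  free_xy <- matrix(0, 0, 2)
  while (nrow(free_xy) < n_free_tg) {
    p <- runif(2, 0, L)
    d_center <- sqrt(sum((p - L / 2)^2))
    if (d_center < R_clear + 2.6 || d_center > L / 2 - 1) next
    if (nrow(free_xy) &&
        min(sqrt((free_xy[, 1] - p[1])^2 + (free_xy[, 2] - p[2])^2)) < 2)
      next
    free_xy <- rbind(free_xy, p)
  }
  for (j in seq_len(n_free_tg))
    add_mol(cbind(free_xy[j, 1] + runif(3, -0.2, 0.2),
                  free_xy[j, 2] + runif(3, -0.2, 0.2),
                  mid + runif(3, -0.3, 0.3)),
            c("glycerol", "tail", "tail"))
  free_ids <- if (n_free_tg) (max(pl_ids) + 1L):k else integer(0)
  species <- c(rep("TG", n_lens_mols), rep(pl_species, n_pl),
               rep("TG", n_free_tg))
  fr <- bead_frame(do.call(rbind, bead_rows), c(L, L, Lz),
                   unlist(mol_ids), species, unlist(roles))
  attr(fr, "lens_members") <- seq_len(n_lens_mols)
  attr(fr, "free_members") <- free_ids
  .with_spec(fr, "gen_coexistence_frame",
             list(n_lens_tg = n_lens_tg, n_free_tg = n_free_tg, n_pl = n_pl,
                  lens_half_thickness = lens_half_thickness), seed)
}

#' Generate a trajectory with a lens appearing at a known time
#'
#' All TG start dispersed (mutually > 4 nm apart, so every frame before
#' formation has only singleton clusters); from the first frame at or
#' after `formation_ns` a compact blob of `n_blob` TG (pairwise within
#' the clustering cutoff) exists at the box centre and persists to the
#' end. Remaining TG stay dispersed and > 4 nm from the blob.
#'
#' @param formation_ns ground-truth formation time, ns (Inf for a
#'   trajectory where no lens ever forms).
#' @param total_ns trajectory length, ns.
#' @param dt_ns frame spacing, ns (default 1).
#' @param n_blob TG molecules in the lens (default 30).
#' @param n_free dispersed TG (default 8).
#' @param n_pl PL molecules on the leaflet lattice (default 200).
#' @param L lateral box edge, nm (default 30).
#' @param seed RNG seed.
#' @return a [trajectory()] with attributes `formation_ns` (snapped to
#'   the frame grid), `lens_members` and `synthetic_spec`.
#' @export
gen_lens_trajectory <- function(formation_ns, total_ns = 100, dt_ns = 1,
                                n_blob = 30, n_free = 8, n_pl = 200,
                                L = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Lz <- 12; mid <- Lz / 2
  times <- seq(0, total_ns, by = dt_ns)
  # static PL scaffold
  pl_xy <- .lattice_sites(n_pl, L, sqrt(L^2 / n_pl) * 0.98, 0.1)
  pl_side <- rep(c(1, -1), length.out = n_pl)
  # dispersed TG on a sparse jittered lattice: neighbouring sites stay
  # > 3.5 nm apart even after jitter, so no spurious clusters form
  scatter_xy <- function(n, keepout) {
    .lattice_sites(n, L, 4.3, 0.15, exclude_center_radius = keepout)
  }
  n_tg <- n_blob + n_free
  frames <- lapply(times, function(t) {
    formed <- t >= formation_ns
    tg_pos <- if (formed) {
      u <- matrix(0, 0, 3)
      while (nrow(u) < n_blob) {
        m <- cbind(runif(n_blob, -1, 1), runif(n_blob, -1, 1),
                   runif(n_blob, -1, 1))
        u <- rbind(u, m[rowSums(m^2) <= 1, , drop = FALSE])
      }
      blob <- sweep(u[seq_len(n_blob), , drop = FALSE], 2, c(1.5, 1.5, 1),
                    "*")
      blob <- sweep(blob, 2, c(L / 2, L / 2, mid), "+")
      free <- scatter_xy(n_free, keepout = 1.5 + 4.2)
      rbind(blob, cbind(free, mid + runif(n_free, -0.5, 0.5)))
    } else {
      disp <- scatter_xy(n_tg, keepout = 0)
      cbind(disp, mid + runif(n_tg, -0.5, 0.5))
    }
    n_mol <- n_pl + n_tg
    pl_beads <- cbind(rep(pl_xy[, 1], each = 2) + runif(2 * n_pl, -0.1, 0.1),
                      rep(pl_xy[, 2], each = 2) + runif(2 * n_pl, -0.1, 0.1),
                      mid + rep(pl_side, each = 2) * c(2.45, 2.0) +
                        runif(2 * n_pl, -0.1, 0.1))
    tg_beads <- tg_pos[rep(seq_len(n_tg), each = 3), ] +
      matrix(runif(9 * n_tg, -0.2, 0.2), ncol = 3)
    bead_frame(rbind(pl_beads, tg_beads), c(L, L, Lz),
               c(rep(seq_len(n_pl), each = 2),
                 n_pl + rep(seq_len(n_tg), each = 3)),
               c(rep("DOPC", n_pl), rep("TG", n_tg)),
               c(rep(c("head", "glycerol"), n_pl),
                 rep(c("glycerol", "tail", "tail"), n_tg)),
               time = t)
  })
  traj <- trajectory(frames)
  snapped <- if (is.finite(formation_ns))
    times[match(TRUE, times >= formation_ns)] else NA_real_
  attr(traj, "formation_ns") <- snapped
  attr(traj, "lens_members") <- n_pl + seq_len(n_blob)
  .with_spec(traj, "gen_lens_trajectory",
             list(formation_ns = formation_ns, total_ns = total_ns,
                  dt_ns = dt_ns, n_blob = n_blob, n_free = n_free), seed)
}

#' Draw replicate nucleation waiting times
#'
#' Exponential waiting times with rate `lambda`, censored at `t_max`
#' (the null constant-rate nucleation model). Optionally materialises a
#' [gen_lens_trajectory()] per replica with the lens appearing at the
#' drawn time.
#'
#' @param lambda nucleation rate, 1/us.
#' @param n_replicas number of replicas.
#' @param t_max censoring horizon, us (default 1.5).
#' @param seed RNG seed.
#' @param trajectories also build synthetic trajectories (slower).
#' @param ... passed to [gen_lens_trajectory()] when `trajectories`.
#' @return data frame `(replica, time, censored)` (times in us, censored
#'   entries at `t_max`), with attribute `trajectories` when requested.
#' @export
gen_nucleation_replicas <- function(lambda, n_replicas, t_max = 1.5,
                                    seed = NULL, trajectories = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  t <- if (lambda > 0) rexp(n_replicas, lambda) else rep(Inf, n_replicas)
  censored <- t > t_max
  out <- data.frame(replica = seq_len(n_replicas),
                    time = ifelse(censored, t_max, t), censored = censored)
  if (trajectories) {
    attr(out, "trajectories") <- lapply(seq_len(n_replicas), function(i)
      gen_lens_trajectory(if (censored[i]) Inf else t[i] * 1000,
                          total_ns = t_max * 1000, ...))
  }
  .with_spec(out, "gen_nucleation_replicas",
             list(lambda = lambda, n_replicas = n_replicas, t_max = t_max),
             seed)
}

#' Sample height fields from a Helfrich spectrum
#'
#' Independent frames whose discrete Fourier modes obey
#' `<|h_q|^2> = kT / (A kappa q^4)` (kT = 1, kappa in kT): white noise is
#' filtered by `sqrt` of the target spectrum, which preserves reality of
#' the field and gives every mode its exact target variance.
#'
#' @param kappa bilayer bending modulus, kT.
#' @param L box edge, nm (square box).
#' @param grid points per side (default 64).
#' @param n_frames number of independent frames.
#' @param seed RNG seed.
#' @return list of `grid x grid` height matrices (nm) with attribute
#'   `synthetic_spec`.
#' @export
gen_helfrich_fields <- function(kappa, L, grid = 64, n_frames = 100,
                                seed = NULL) {
  stopifnot(kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- grid
  q <- .q_grid(N, N, L, L)
  A <- L^2
  S <- matrix(0, N, N)
  nz <- q > 0
  S[nz] <- 1 / (A * kappa * q[nz]^4)
  amp <- sqrt(S)
  fields <- lapply(seq_len(n_frames), function(i) {
    w <- matrix(rnorm(N * N), N, N)
    F <- fft(w) * amp * N          # |fft(w)_q|^2 averages N^2
    Re(fft(F, inverse = TRUE)) / (N * N)
  })
  .with_spec(fields, "gen_helfrich_fields",
             list(kappa = kappa, L = L, grid = grid, n_frames = n_frames),
             seed)
}

# Gaussian integral over [a, b]: int amp * exp(-(z-mu)^2 / (2 s^2)) dz
.gauss_int <- function(amp, mu, s, a, b) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  amp * s * sqrt(pi / 2) * (erf((b - mu) / (s * sqrt(2))) -
                              erf((a - mu) / (s * sqrt(2))))
}

# First moment int z * amp * exp(-(z-mu)^2/(2 s^2)) dz over [a, b]
.gauss_moment <- function(amp, mu, s, a, b) {
  amp * (s^2 * (exp(-(a - mu)^2 / (2 * s^2)) - exp(-(b - mu)^2 / (2 * s^2))) +
           mu / amp * .gauss_int(amp, mu, s, a, b))
}

#' Generate an analytic lateral pressure profile with closed-form truth
#'
#' Two positive Gaussian chain lobes at `+/- z_chain` plus two negative
#' compact-support quartic "glycerol" wells whose support starts exactly
#' at `+/- z_edge` (well centres at `+/- (z_edge + well_width)`), with
#' the well depth chosen so the total tension is exactly zero. Inside
#' `[-z_edge, z_edge]` the profile equals the strictly positive chain
#' sum, so the positive-region integral over that window and the leaflet
#' first moments have exact closed forms (Gaussian error functions plus
#' polynomial well terms), attached as ground truth.
#'
#' @param amplitude bar, chain-lobe peak (default 100).
#' @param sigma nm, chain-lobe width (default 0.5).
#' @param z_chain nm, chain-lobe centre (default 1).
#' @param z_edge nm, inner edge of the glycerol wells; the closed-form
#'   integration window is `[-z_edge, z_edge]` (default 2.1).
#' @param well_width nm, half-width of the compact wells (default 0.35).
#' @param asymmetry multiplicative factor on the upper-leaflet chain lobe
#'   (1 = symmetric).
#' @param L_z nm, box height; grid spans `[-L_z/2, L_z/2]` (default 7).
#' @param dz nm, table spacing (default 0.001 = the 0.01 angstrom
#'   convention).
#' @param n_replicas identical replica columns to emit.
#' @param noise_sd bar, optional iid noise per replica (default 0).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return a [pressure_profile()] with attribute `truth`: list
#'   `pi_ch_mN_m` (over the `minima` window), `kb_c0_upper`,
#'   `kb_c0_lower` (mN/m nm), `minima` (= `+/- z_edge`, to pass to
#'   [chain_pressure()] explicitly), `auto_minima` (the actual local
#'   minima, at the well centres), `tension` (0 by construction).
#' @export
gen_stress_profile <- function(amplitude = 100, sigma = 0.5, z_chain = 1,
                               z_edge = 2.1, well_width = 0.35,
                               asymmetry = 1, L_z = 7, dz = 0.001,
                               n_replicas = 1, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  half <- L_z / 2
  wc <- z_edge + well_width               # well centre
  if (wc + well_width >= half)
    stop("glycerol wells extend past the grid; increase L_z")
  z <- seq(-half, half, by = dz)
  a_up <- amplitude * asymmetry; a_lo <- amplitude
  chain <- function(zz) a_up * exp(-(zz - z_chain)^2 / (2 * sigma^2)) +
    a_lo * exp(-(zz + z_chain)^2 / (2 * sigma^2))
  well_shape <- function(zz, c0) {
    u <- (zz - c0) / well_width
    ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  pos_total <- .gauss_int(a_up, z_chain, sigma, -half, half) +
    .gauss_int(a_lo, -z_chain, sigma, -half, half)
  well_area <- 16 / 15 * well_width          # per unit depth
  depth <- pos_total / (2 * well_area)       # net-zero tension
  pi_z <- chain(z) - depth * (well_shape(z, wc) + well_shape(z, -wc))
  reps <- matrix(rep(pi_z, n_replicas), ncol = n_replicas)
  if (noise_sd > 0)
    reps <- reps + matrix(rnorm(length(reps), 0, noise_sd), nrow = length(z))
  # wells vanish identically inside [-z_edge, z_edge] and the chain sum is
  # strictly positive, so max(pi, 0) = pi there: pure Gaussian integrals
  pi_ch_bar_nm <- .gauss_int(a_up, z_chain, sigma, -z_edge, z_edge) +
    .gauss_int(a_lo, -z_chain, sigma, -z_edge, z_edge)
  # leaflet first moments -int_0^half z pi dz (upper) and the z -> -z
  # mirror (lower); the well lies fully inside (0, half), and by symmetry
  # about its centre contributes depth * well_area * wc to int z pi dz
  m_up <- -(.gauss_moment(a_up, z_chain, sigma, 0, half) +
              .gauss_moment(a_lo, -z_chain, sigma, 0, half) -
              depth * well_area * wc)
  m_lo <- -(.gauss_moment(a_lo, z_chain, sigma, 0, half) +
              .gauss_moment(a_up, -z_chain, sigma, 0, half) -
              depth * well_area * wc)
  prof <- pressure_profile(z, P_N = matrix(0, length(z), n_replicas),
                           P_T = reps, L_z = L_z, tension_tol = 1)
  attr(prof, "truth") <- list(
    pi_ch_mN_m = BAR_NM_TO_MN_M * pi_ch_bar_nm,
    kb_c0_upper = BAR_NM_TO_MN_M * m_up,
    kb_c0_lower = BAR_NM_TO_MN_M * m_lo,
    minima = c(-z_edge, z_edge), auto_minima = c(-wc, wc), tension = 0)
  .with_spec(prof, "gen_stress_profile",
             list(amplitude = amplitude, sigma = sigma, z_chain = z_chain,
                  z_edge = z_edge, well_width = well_width,
                  asymmetry = asymmetry, L_z = L_z, dz = dz), seed)
}

#' Generate a diluted-TG relaxation series
#'
#' Exponential approach to a plateau,
#' `c(t) = plateau * (1 - exp(-t / tau))`, optionally with Gaussian noise
#' and an injection transient
#' `+ amp * exp(-(t - t_inj) / tau)` after `t_inj`, returned in the same
#' per-frame form [diluted_series()] produces (counts against a fixed PL
#' pool).
#'
#' @param plateau equilibrium diluted-TG percentage.
#' @param tau ns, relaxation time (default 300).
#' @param noise_sd percentage-points of iid Gaussian noise (default 0).
#' @param duration_us series length, us (default 4.5).
#' @param dt_ns frame spacing, ns (default 10).
#' @param n_pl PL pool size used to convert percentages to counts
#'   (default 1000).
#' @param injection_time_us optional injection time, us.
#' @param injection_amplitude percentage-points added at injection.
#' @param seed RNG seed.
#' @return a `diluted_tg_series` data frame with attribute
#'   `synthetic_spec`.
#' @export
gen_relaxation_series <- function(plateau, tau = 300, noise_sd = 0,
                                  duration_us = 4.5, dt_ns = 10,
                                  n_pl = 1000, injection_time_us = NULL,
                                  injection_amplitude = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_us * 1000, by = dt_ns)
  pct <- plateau * (1 - exp(-t / tau))
  if (!is.null(injection_time_us)) {
    after <- t >= injection_time_us * 1000
    pct[after] <- pct[after] +
      injection_amplitude * exp(-(t[after] - injection_time_us * 1000) / tau)
  }
  if (noise_sd > 0) pct <- pct + rnorm(length(t), 0, noise_sd)
  pct <- pmax(pct, 0)
  out <- data.frame(time = t, n_lens = NA_integer_,
                    n_diluted = round(pct / 100 * n_pl),
                    n_boundary = NA_integer_, n_pl_free = n_pl,
                    percent = pct)
  class(out) <- c("diluted_tg_series", "data.frame")
  .with_spec(out, "gen_relaxation_series",
             list(plateau = plateau, tau = tau, noise_sd = noise_sd,
                  duration_us = duration_us, dt_ns = dt_ns,
                  injection_time_us = injection_time_us,
                  injection_amplitude = injection_amplitude), seed)
}
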