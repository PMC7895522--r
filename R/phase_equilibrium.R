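# Equilibrium diluted-TG quantification: the concentration of TG
# dissolved in the bilayer coexisting with a lens is the package's proxy
# for the TG chemical potential.
#
# Protocol: lens TG = within `tg_tg` (5 nm) of another TG AND farther than
# `tg_pl` (2.8 nm) from every PL; the lens-free bilayer = all lipid
# molecules at least `margin` (2.5 nm) from the lens; diluted TG = non-lens
# TG inside the lens-free region; the remaining TG (the lens rim, where
# molecules exchange continuously with the lens) are a third, excluded
# class. Concentration = 100 * N_TG,free / N_PL,free.

#' Classify TG molecules into lens / diluted / boundary sets
#'
#' @param frame a [bead_frame()].
#' @param tg_tg nm, TG-TG association cutoff (default 5).
#' @param tg_pl nm, TG-PL contact cutoff (default 2.8).
#' @param margin nm, distance from the lens defining the lens-free bilayer
#'   (default 2.5).
#' @param denominator `"pl"` (default): lens-free PL molecules only;
#'   `"lipids"`: all lens-free non-TG lipids (DAG/CHOL included).
#' @param mode distance reference, see [cluster_tg()] (`"molecule"` uses
#'   molecule mean positions).
#' @return list of class `tg_classification`: integer molecule-id vectors
#'   `lens`, `diluted`, `boundary`, `lens_free_pl` (the denominator set),
#'   `percent` (100 * diluted / lens-free PL), and `params`.
#' @export
classify_tg <- function(frame, tg_tg = 5.0, tg_pl = 2.8, margin = 2.5,
                        denominator = c("pl", "lipids"),
                        mode = c("molecule", "beads")) {
  denominator <- match.arg(denominator)
  mode <- match.arg(mode)
  box <- frame$box
  if (max(tg_tg, tg_pl, margin) >= min(box) / 2)
    stop("cutoffs must be < half the smallest box edge")
  pl <- molecules_of_class(frame, "pl")
  if (!length(pl)) stop("frame contains no phospholipid molecules; ",
                        "the TG/PL ratio is undefined")
  tg <- molecules_of_class(frame, "tg")
  other <- molecules_of_class(frame, "other")
  if (!length(tg))
    return(structure(list(lens = integer(0), diluted = integer(0),
                          boundary = integer(0), lens_free_pl = pl,
                          percent = 0,
                          params = list(tg_tg = tg_tg, tg_pl = tg_pl,
                                        margin = margin,
                                        denominator = denominator)),
                     class = "tg_classification"))
  pos_all <- molecule_positions(frame)
  ids <- as.integer(rownames(pos_all))
  p_tg <- pos_all[match(tg, ids), , drop = FALSE]
  p_pl <- pos_all[match(pl, ids), , drop = FALSE]
  if (mode == "beads") {
    # bead-resolved distances: replace molecule points by all their beads
    sel_tg <- frame$molecule %in% tg
    sel_pl <- frame$molecule %in% pl
    b_tg <- frame$coords[sel_tg, , drop = FALSE]
    b_tg_mol <- frame$molecule[sel_tg]
    b_pl <- frame$coords[sel_pl, , drop = FALSE]
    d_tgtg_b <- nearest_other_tg_bead(b_tg, b_tg_mol, box, tg_tg)
    d_tgtg <- tapply(d_tgtg_b, b_tg_mol, min)[as.character(tg)]
    d_tgpl_b <- nearest_dist(b_tg, b_pl, box, tg_pl)
    d_tgpl <- tapply(d_tgpl_b, b_tg_mol, min)[as.character(tg)]
  } else {
    d_tgtg <- nearest_other(p_tg, box, tg_tg)
    d_tgpl <- nearest_dist(p_tg, p_pl, box, tg_pl)
  }
  is_lens <- d_tgtg <= tg_tg & d_tgpl > tg_pl
  lens <- tg[is_lens]
  p_lens <- p_tg[is_lens, , drop = FALSE]
  # lens-free bilayer: lipids at least `margin` from every lens TG
  free_of_lens <- function(pos) nearest_dist(pos, p_lens, box, margin) >= margin
  lens_free_pl <- pl[free_of_lens(p_pl)]
  denom_ids <- lens_free_pl
  if (denominator == "lipids" && length(other)) {
    p_other <- pos_all[match(other, ids), , drop = FALSE]
    denom_ids <- c(lens_free_pl, other[free_of_lens(p_other)])
  }
  nonlens <- tg[!is_lens]
  p_nonlens <- p_tg[!is_lens, , drop = FALSE]
  in_free <- free_of_lens(p_nonlens)
  diluted <- nonlens[in_free]
  boundary <- nonlens[!in_free]
  percent <- if (length(denom_ids)) 100 * length(diluted) / length(denom_ids)
             else NA_real_
  structure(list(lens = lens, diluted = diluted, boundary = boundary,
                 lens_free_pl = lens_free_pl, percent = percent,
                 params = list(tg_tg = tg_tg, tg_pl = tg_pl, margin = margin,
                               denominator = denominator)),
            class = "tg_classification")
}

# Nearest neighbour distance within one point set (excluding self).
nearest_other <- function(pos, box, cap) {
  n <- nrow(pos)
  if (n < 2) return(rep(Inf, n))
  pr <- neighbor_pairs(pos, box, cap)
  best <- rep(Inf, n)
  if (nrow(pr)) {
    d <- min_image(pos[pr[, 1], , drop = FALSE] - pos[pr[, 2], , drop = FALSE],
                   box)
    dd <- sqrt(rowSums(d * d))
    for (side in 1:2) {
      agg <- tapply(dd, pr[, side], min)
      idx <- as.integer(names(agg))
      best[idx] <- pmin(best[idx], unname(agg))
    }
  }
  best
}

# Bead-level nearest distance to a bead of a *different* TG molecule.
nearest_other_tg_bead <- function(beads, bead_mol, box, cap) {
  n <- nrow(beads)
  pr <- neighbor_pairs(beads, box, cap)
  best <- rep(Inf, n)
  if (nrow(pr)) {
    keep <- bead_mol[pr[, 1]] != bead_mol[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
    if (nrow(pr)) {
      d <- min_image(beads[pr[, 1], , drop = FALSE] -
                       beads[pr[, 2], , drop = FALSE], box)
      dd <- sqrt(rowSums(d * d))
      for (side in 1:2) {
        agg <- tapply(dd, pr[, side], min)
        idx <- as.integer(names(agg))
        best[idx] <- pmin(best[idx], unname(agg))
      }
    }
  }
  best
}

#' Per-frame diluted-TG time series
#'
#' Applies [classify_tg()] to every frame; no smoothing is applied.
#'
#' @param traj a [trajectory()].
#' @param ... parameters forwarded to [classify_tg()].
#' @return data frame of class `diluted_tg_series`: `time` (ns), `n_lens`,
#'   `n_diluted`, `n_boundary`, `n_pl_free`, `percent`.
#' @export
diluted_series <- function(traj, ...) {
  rows <- lapply(seq_along(traj$frames), function(i) {
    cl <- tryCatch(classify_tg(traj$frames[[i]], ...),
                   error = function(e) stop("frame ", i, ": ",
                                            conditionMessage(e)))
    data.frame(time = traj$frames[[i]]$time, n_lens = length(cl$lens),
               n_diluted = length(cl$diluted),
               n_boundary = length(cl$boundary),
               n_pl_free = length(cl$lens_free_pl), percent = cl$percent)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diluted_tg_series", "data.frame")
  out
}

#' Plateau statistics of diluted-TG series
#'
#' Averages each replica's series over a trailing window, then reports the
#' mean and standard deviation across replicas. Stationarity inside the
#' window is checked by comparing the two half-window means; a difference
#' above 2 within-replica SDs triggers a warning.
#'
#' @param series a `diluted_tg_series` or list of them (one per replica).
#' @param window us of trailing trajectory to average (default 1.5);
#'   alternatively a length-2 numeric giving an explicit `(from, to)` ns
#'   interval, which is how pre/post-injection comparisons are done.
#' @return list of class `plateau_stats`: `mean`, `sd` (across replicas;
#'   0 for a single replica), `replica_means`, `n_replicas`, `window_ns`.
#' @export
plateau_stats <- function(series, window = 1.5) {
  if (inherits(series, "data.frame")) series <- list(series)
  if (!length(series)) stop("at least one replica series is required")
  pick <- function(s) {
    if (length(window) == 2) {
      lo <- window[1]; hi <- window[2]
    } else {
      hi <- max(s$time); lo <- hi - window * 1000
      if (lo < min(s$time) - 1e-9)
        stop("plateau window (", window, " us) exceeds the trajectory span")
    }
    sub <- s[s$time >= lo & s$time <= hi, ]
    if (!nrow(sub)) stop("no frames inside the plateau window")
    sub
  }
  subs <- lapply(series, pick)
  means <- vapply(subs, function(s) mean(s$percent), 0)
  for (s in subs) {
    half <- (min(s$time) + max(s$time)) / 2
    a <- s$percent[s$time <= half]; b <- s$percent[s$time > half]
    if (length(a) > 1 && length(b) > 1 && sd(s$percent) > 0 &&
        abs(mean(a) - mean(b)) > 2 * sd(s$percent))
      warning("plateau window looks non-stationary: half-window means differ ",
              "by > 2 SD")
  }
  structure(list(mean = mean(means),
                 sd = if (length(means) > 1) sd(means) else 0,
                 replica_means = means, n_replicas = length(means),
                 window_ns = if (length(window) == 2) window else
                   c(max(subs[[1]]$time) - window * 1000, max(subs[[1]]$time))),
            class = "plateau_stats")
}

#' @export
print.plateau_stats <- function(x, ...) {
  cat(sprintf("diluted TG plateau: %.3g +/- %.3g %% (n = %d replicas)\n",
              x$mean, x$sd, x$n_replicas))
  invisible(x)
}

#' Detect lens dissolution
#'
#' For a trajectory that starts with a lens, returns the earliest time
#' after which no TG aggregate of `min_size` or more ever reappears
#' (dissolution must be permanent; transient dips do not qualify), or
#' `NA` if the lens persists to the end.
#'
#' @param traj a [trajectory()].
#' @param min_size minimum aggregate size counting as a lens (default 25).
#' @param cutoff nm, single-linkage cutoff (default 3.5).
#' @return dissolution time in ns, or `NA_real_` if no dissolution.
#' @export
detect_dissolution <- function(traj, min_size = 25, cutoff = 3.5) {
  sizes <- vapply(traj$frames, function(f) {
    cl <- cluster_tg(f, cutoff)
    if (length(cl$sizes)) max(cl$sizes) else 0L
  }, 0L)
  if (sizes[1] < min_size)
    stop("no lens (aggregate >= ", min_size, ") in the first frame")
  above <- sizes >= min_size
  if (above[length(above)]) return(NA_real_)
  last_above <- max(which(above))
  traj$times[last_above + 1]
}

#' Spatial extent of a lens
#'
#' Per-axis `max - min` of the lens TG molecule positions after making the
#' lens whole across the periodic boundary (coordinates unwrapped about
#' the lens' circular mean per axis).
#'
#' @param frame a [bead_frame()].
#' @param lens integer vector of lens TG molecule ids (e.g. from
#'   [classify_tg()]).
#' @return named numeric `(dx, dy, dz)` in nm.
#' @export
lens_extent <- function(frame, lens) {
  if (!length(lens)) stop("lens is empty; extent undefined")
  pos <- molecule_positions(frame, lens)
  out <- numeric(3)
  for (k in 1:3) {
    L <- frame$box[k]
    theta <- pos[, k] / L * 2 * pi
    center <- atan2(mean(sin(theta)), mean(cos(theta))) / (2 * pi) * L
    d <- pos[, k] - center
    d <- d - L * round(d / L)
    out[k] <- max(d) - min(d)
  }
  setNames(out, c("dx", "dy", "dz"))
}

#' Excess TG of a nucleation setup
#'
#' The difference between the nominal TG/PL percentage of the nucleation
#' setup (6% in the reference experiments) and the equilibrium diluted-TG
#' percentage of the same composition.
#'
#' @param nominal nominal TG/PL percent (default 6).
#' @param equilibrium equilibrium diluted-TG percent.
#' @return excess TG, percent.
#' @examples
#' excess_tg(6, 1.1)  # 4.9
#' @export
excess_tg <- function(nominal = 6, equilibrium) {
  stopifnot(nominal >= 0, equilibrium >= 0)
  nominal - equilibrium
}
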