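# Lens nucleation detection and kinetics.
#
# A lens "forms" when an aggregate of at least `min_size` TG molecules
# (single-linkage components at a 3.5 nm cutoff) stays above the size
# threshold for at least `persistence` ns. Rates are the inverse of the
# replica-averaged formation time; relative nucleation energies follow
# from rate ~ exp(-E_nucl / kT).

#' Single-linkage clustering of TG molecules
#'
#' Partitions the TG molecules of a frame into connected components where
#' two molecules are linked iff their minimum-image distance is at most
#' `cutoff` (directly or through a chain of such links). Neighbour
#' candidates come from a periodic cell list; the result is exact.
#'
#' @param frame a [bead_frame()].
#' @param cutoff nm, single-linkage cutoff (default 3.5). Must be below
#'   half the smallest box edge.
#' @param mode `"molecule"`: distances between molecule mean positions
#'   (default); `"beads"`: minimum inter-bead distance between molecules.
#' @return list with `members` (list of integer vectors of TG molecule
#'   ids, decreasing size), `sizes`, and `tg_ids` (all TG molecule ids).
#' @export
cluster_tg <- function(frame, cutoff = 3.5, mode = c("molecule", "beads")) {
  mode <- match.arg(mode)
  tg <- molecules_of_class(frame, "tg")
  if (!length(tg))
    return(list(members = list(), sizes = integer(0), tg_ids = integer(0)))
  if (mode == "molecule") {
    pos <- molecule_positions(frame, tg)
    pr <- neighbor_pairs(pos, frame$box, cutoff)
  } else {
    sel <- frame$molecule %in% tg
    pos <- frame$coords[sel, , drop = FALSE]
    bead_mol <- match(frame$molecule[sel], tg)
    bp <- neighbor_pairs(pos, frame$box, cutoff)
    pr <- unique(cbind(pmin(bead_mol[bp[, 1]], bead_mol[bp[, 2]]),
                       pmax(bead_mol[bp[, 1]], bead_mol[bp[, 2]])))
    pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(tg), directed = FALSE)
  if (nrow(pr)) g <- igraph::add_edges(g, t(pr))
  comp <- igraph::components(g)$membership
  members <- split(tg, comp)
  members <- members[order(-lengths(members))]
  names(members) <- NULL
  list(members = members, sizes = lengths(members), tg_ids = tg)
}

# Largest-overlap successor of cluster `prev` among `clusters`.
.match_cluster <- function(prev, clusters) {
  if (!length(clusters)) return(0L)
  ov <- vapply(clusters, function(m) length(intersect(m, prev)), 0L)
  if (max(ov) == 0L) 0L else which.max(ov)
}

#' Detect spontaneous lens formation in a trajectory
#'
#' Scans the per-frame single-linkage partitions for the earliest time `t`
#' at which an aggregate of at least `min_size` TG molecules exists and --
#' tracked across frames by maximal membership overlap -- keeps at least
#' `min_size` members at every sampled frame within `[t, t + persistence]`.
#' If no such window exists the trajectory is censored.
#'
#' @param traj a [trajectory()].
#' @param min_size minimum aggregate size (default 25 TG molecules).
#' @param persistence ns the aggregate must persist (default 5).
#' @param cutoff nm, single-linkage cutoff (default 3.5).
#' @param mode distance reference, see [cluster_tg()].
#' @return object of class `lens_track`: `formation_time` (ns, `NA` if
#'   censored), `censored`, `candidates` (data frame of onset/size/
#'   persistence of every aggregate that ever reached `min_size`),
#'   `lens_members` (TG ids of the formed lens at onset), `partitions`
#'   (per-frame cluster lists), `params`, `total_time` (us).
#' @export
detect_lens_formation <- function(traj, min_size = 25, persistence = 5,
                                  cutoff = 3.5, mode = "molecule") {
  times <- traj$times
  if (length(times) > 1 && max(diff(times)) > persistence)
    stop("frame spacing (", max(diff(times)), " ns) exceeds the persistence ",
         "window (", persistence, " ns); the stability criterion is untestable")
  parts <- lapply(traj$frames, cluster_tg, cutoff = cutoff, mode = mode)
  nf <- length(parts)
  cand <- list()
  formation <- NA_real_; lens_members <- integer(0)
  for (i in seq_len(nf)) {
    big <- which(parts[[i]]$sizes >= min_size)
    for (ci in big) {
      # skip aggregates that are continuations of one already seen
      if (i > 1) {
        prevs <- parts[[i - 1]]
        j <- .match_cluster(parts[[i]]$members[[ci]], prevs$members)
        if (j > 0 && prevs$sizes[j] >= min_size) next
      }
      # follow the aggregate forward until it drops below min_size
      cur <- parts[[i]]$members[[ci]]
      k <- i
      while (k < nf) {
        nxt <- .match_cluster(cur, parts[[k + 1]]$members)
        if (nxt == 0L || parts[[k + 1]]$sizes[nxt] < min_size) break
        cur <- parts[[k + 1]]$members[[nxt]]
        k <- k + 1
      }
      persisted <- times[k] - times[i]
      cand[[length(cand) + 1]] <- data.frame(
        onset = times[i], size = parts[[i]]$sizes[ci], persisted = persisted)
      # an aggregate that merely survives to the last frame without
      # covering the persistence window does not count as formed
      if (is.na(formation) && persisted >= persistence) {
        formation <- times[i]
        lens_members <- parts[[i]]$members[[ci]]
      }
    }
    if (!is.na(formation)) break
  }
  structure(list(
    formation_time = formation, censored = is.na(formation),
    candidates = if (length(cand)) do.call(rbind, cand) else
      data.frame(onset = numeric(0), size = integer(0), persisted = numeric(0)),
    lens_members = lens_members, partitions = parts,
    params = list(cutoff = cutoff, min_size = min_size,
                  persistence = persistence, mode = mode),
    total_time = traj$total_time), class = "lens_track")
}

#' @export
print.lens_track <- function(x, ...) {
  if (x$censored)
    cat(sprintf("lens_track: censored at %g us (no stable aggregate >= %d)\n",
                x$total_time, x$params$min_size))
  else
    cat(sprintf("lens_track: lens of %d TG formed at %g ns\n",
                length(x$lens_members), x$formation_time))
  invisible(x)
}

#' Nucleation rate from replica formation times
#'
#' The rate is the inverse of the mean formation time over replicas, with
#' the error propagated as `sd(t) / mean(t)^2`. When every replica is
#' censored the rate is 0 and the error bar is `1 / total_time`. Mixed
#' censoring (some replicas form, some not) imputes censored replicas at
#' `total_time`, giving a lower-bound rate, and flags it.
#'
#' @param tracks list of [detect_lens_formation()] results, or a numeric
#'   vector of formation times in us with `censored` supplied separately.
#' @param total_time censoring horizon, us (default 1.5).
#' @param censored logical vector when `tracks` is numeric.
#' @param average `"time"` (default): invert the mean time, the quoted
#'   reading of "rate = inverse of the (replica-averaged) formation time";
#'   `"rate"`: average the inverse times instead.
#' @return object of class `nucleation_estimate`: `times` (us), `censored`,
#'   `rate` (1/us), `rate_error`, `mixed_censoring` flag, `average`.
#' @export
nucleation_rate <- function(tracks, total_time = 1.5, censored = NULL,
                            average = c("time", "rate")) {
  average <- match.arg(average)
  if (is.numeric(tracks)) {
    times <- tracks
    if (is.null(censored)) censored <- rep(FALSE, length(times))
  } else {
    if (!length(tracks)) stop("at least one replica is required")
    censored <- vapply(tracks, `[[`, TRUE, "censored")
    times <- vapply(tracks, function(t)
      if (t$censored) NA_real_ else t$formation_time / 1000, 0)
  }
  if (!length(times)) stop("at least one replica is required")
  if (all(censored))
    return(structure(list(times = rep(total_time, length(times)),
                          censored = censored, rate = 0,
                          rate_error = 1 / total_time,
                          mixed_censoring = FALSE, average = average),
                     class = "nucleation_estimate"))
  t_used <- ifelse(censored, total_time, times)
  rate <- if (average == "time") 1 / mean(t_used) else mean(1 / t_used)
  err <- if (length(t_used) > 1) {
    if (average == "time") sd(t_used) / mean(t_used)^2 else sd(1 / t_used)
  } else 0
  structure(list(times = t_used, censored = censored, rate = rate,
                 rate_error = err, mixed_censoring = any(censored),
                 average = average),
            class = "nucleation_estimate")
}

#' @export
print.nucleation_estimate <- function(x, ...) {
  cat(sprintf("nucleation rate: %.4g +/- %.4g 1/us (n = %d%s)\n",
              x$rate, x$rate_error, length(x$times),
              if (x$mixed_censoring) ", mixed censoring: lower bound" else ""))
  invisible(x)
}

#' Relative nucleation energy of a composition versus a reference
#'
#' With rate ~ exp(-E_nucl / kT), the energy in kT units is
#' `E/kT = -log(rate * tau0)` for an attempt time `tau0`; the reported
#' quantity is the ratio `E(composition) / E(reference)`, with DOPC as the
#' conventional reference. The ratio depends on the (unobservable) `tau0`
#' normalisation, so a sensitivity band over a tenfold `tau0` range is
#' returned alongside.
#'
#' @param est,ref [nucleation_rate()] estimates; both rates must be > 0.
#' @param tau0 attempt time, ns (default 1).
#' @return list: `ratio`, `relative_error` (propagated from rate errors),
#'   `E_kT`, `E_ref_kT`, `tau0`, `tau0_sensitivity` (ratio at tau0/10 and
#'   10*tau0).
#' @export
relative_nucleation_energy <- function(est, ref, tau0 = 1) {
  if (est$rate <= 0 || ref$rate <= 0)
    stop("undefined energy: rate must be > 0 (all replicas censored?)")
  tau_us <- tau0 / 1000
  eval_ratio <- function(tau) {
    e <- -log(est$rate * tau); er <- -log(ref$rate * tau)
    if (er == 0) stop("reference energy is zero at tau0 = ", tau * 1000,
                      " ns; ratio undefined")
    e / er
  }
  E <- -log(est$rate * tau_us); Er <- -log(ref$rate * tau_us)
  ratio <- eval_ratio(tau_us)
  # sigma_E = sigma_rate / rate (dE/drate = -1/rate in kT units)
  sE <- est$rate_error / est$rate
  sEr <- ref$rate_error / ref$rate
  rel_err <- if (E == 0) Inf else sqrt((sE / E)^2 + (sEr / Er)^2)
  list(ratio = ratio, relative_error = rel_err, E_kT = E, E_ref_kT = Er,
       tau0 = tau0,
       tau0_sensitivity = c(tau0_x0.1 = eval_ratio(tau_us / 10),
                            tau0_x10 = eval_ratio(tau_us * 10)))
}
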