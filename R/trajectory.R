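# Trajectory and composition bookkeeping.

#' Construct a trajectory
#'
#' A time-ordered sequence of [bead_frame()]s from one simulation replica.
#' Frame times must be strictly increasing and the composition (species
#' counts) constant across frames.
#'
#' @param frames list of `bead_frame` objects.
#' @param replica_id identifier of the replica (integer or string).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, replica_id = 1L) {
  if (!length(frames) || !all(vapply(frames, inherits, TRUE, "bead_frame")))
    stop("frames must be a non-empty list of bead_frame objects")
  times <- vapply(frames, `[[`, 0, "time")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  nb <- vapply(frames, function(f) nrow(f$coords), 0L)
  if (length(unique(nb)) != 1)
    stop("bead count changes across frames (", paste(unique(nb), collapse = " vs "),
         "); trajectory is structurally inconsistent")
  comp0 <- sort(table(frames[[1]]$species))
  for (i in seq_along(frames)[-1])
    if (!identical(sort(table(frames[[i]]$species)), comp0))
      stop("composition changes at frame ", i)
  structure(list(frames = frames, replica_id = replica_id,
                 times = times,
                 total_time = (times[length(times)] - times[1]) / 1000),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %g-%g ns, replica %s\n",
              length(x$frames), x$times[1], x$times[length(x$times)],
              as.character(x$replica_id)))
  invisible(x)
}

#' Composition specification
#'
#' Species counts plus the TG/PL ratio in percent, the unit in which all
#' neutral-lipid concentrations are reported (100 * N_TG / N_PL, never
#' mol% of total lipid).
#'
#' @param species_counts named integer vector, molecules per species.
#' @param tg_species label(s) counted as the neutral lipid (default: every
#'   species of class `"tg"` in the standard vocabulary).
#' @param pl_species labels counted as phospholipid (default: standard PL
#'   vocabulary).
#' @return object of class `composition_spec` with fields
#'   `species_counts`, `tg_species`, `tg_pl_ratio` (percent).
#' @export
composition_spec <- function(species_counts,
                             tg_species = species_vocabulary("tg"),
                             pl_species = species_vocabulary("pl")) {
  counts <- as.integer(species_counts)
  names(counts) <- names(species_counts)
  if (any(counts < 0)) stop("species counts must be >= 0")
  n_pl <- sum(counts[names(counts) %in% pl_species])
  if (n_pl == 0) stop("at least one phospholipid species is required ",
                      "(TG/PL ratio undefined)")
  n_tg <- sum(counts[names(counts) %in% tg_species])
  structure(list(species_counts = counts,
                 tg_species = intersect(names(counts), tg_species),
                 n_tg = n_tg, n_pl = n_pl,
                 tg_pl_ratio = 100 * n_tg / n_pl),
            class = "composition_spec")
}

#' @export
print.composition_spec <- function(x, ...) {
  cat("composition:",
      paste(sprintf("%d %s", x$species_counts, names(x$species_counts)),
            collapse = " + "),
      sprintf("| TG/PL = %.3g%%\n", x$tg_pl_ratio))
  invisible(x)
}

#' Summarise the composition of a trajectory or frame
#'
#' @param x a [trajectory()] or [bead_frame()].
#' @param ... passed to [composition_spec()] (`tg_species`, `pl_species`).
#' @return a [composition_spec()].
#' @examples
#' # 3200 DOPC + 192 TG is a 6% TG/PL system
#' @export
composition_summary <- function(x, ...) {
  frame <- if (inherits(x, "trajectory")) x$frames[[1]] else x
  if (!inherits(frame, "bead_frame")) stop("x must be a trajectory or bead_frame")
  tab <- table(frame$species)
  cls <- .species_class(frame, names(tab))
  args <- list(...)
  if (is.null(args$pl_species)) args$pl_species <- names(tab)[cls == "pl"]
  if (is.null(args$tg_species)) args$tg_species <- names(tab)[cls == "tg"]
  do.call(composition_spec,
          c(list(species_counts = setNames(as.integer(tab), names(tab))), args))
}
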