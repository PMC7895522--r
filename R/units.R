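# Unit conventions: nm / ns / bar / kT internally.
# 1 bar * nm = 0.1 mN/m ; kT(310 K) = 4.28e-21 J = 4.28 mN/m * nm^2.

BOLTZMANN_J_PER_K <- 1.380649e-23
BAR_NM_TO_MN_M <- 0.1

#' Thermal energy in useful unit systems
#'
#' Thermal energy `kT` at a given temperature, expressed either in joules
#' or in `mN/m * nm^2` (the natural unit when combining bending moduli in
#' kT with curvatures in 1/nm and stresses in mN/m).
#'
#' @param temperature temperature in kelvin (default 310, physiological).
#' @param unit `"J"` or `"mN/m nm^2"`.
#' @return numeric scalar, `kT` in the requested unit.
#' @examples
#' kT(310)               # ~4.28e-21 J
#' kT(310, "mN/m nm^2")  # ~4.28
#' @export
kT <- function(temperature = 310, unit = c("J", "mN/m nm^2")) {
  stopifnot(is.numeric(temperature), temperature > 0)
  unit <- match.arg(unit)
  e_j <- BOLTZMANN_J_PER_K * temperature
  switch(unit,
    "J" = e_j,
    # mN/m * nm^2 = 1e-3 N/m * 1e-18 m^2 = 1e-21 J
    "mN/m nm^2" = e_j / 1e-21
  )
}

#' Analysis configuration
#'
#' Bundles the temperature and the distance/time cutoffs shared across
#' analysis stages, so a whole study can be parameterised in one place.
#' Defaults are the values used throughout the nucleation and phase
#' coexistence analyses.
#'
#' @param temperature kelvin; enters every energy expressed in kT.
#' @param cluster_cutoff nm, single-linkage TG-TG cutoff for lens detection.
#' @param min_lens_size minimum TG aggregate size that counts as a lens.
#' @param persistence ns a candidate aggregate must persist to count as
#'   formed.
#' @param total_time microseconds; censoring horizon of nucleation runs.
#' @param tg_tg nm, TG-TG association cutoff of the diluted-TG protocol.
#' @param tg_pl nm, TG-PL contact cutoff of the diluted-TG protocol.
#' @param margin nm, distance from the lens defining the lens-free bilayer.
#' @param plateau_window microseconds of trailing trajectory averaged for
#'   the diluted-TG plateau.
#' @param tau0 ns, attempt-time normalisation used when converting rates to
#'   relative nucleation energies.
#' @param seed integer seed recorded with the configuration.
#' @return object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(temperature = 310,
                            cluster_cutoff = 3.5, min_lens_size = 25,
                            persistence = 5, total_time = 1.5,
                            tg_tg = 5.0, tg_pl = 2.8, margin = 2.5,
                            plateau_window = 1.5, tau0 = 1,
                            seed = NULL) {
  stopifnot(temperature > 0)
  cuts <- c(cluster_cutoff = cluster_cutoff, min_lens_size = min_lens_size,
            persistence = persistence, total_time = total_time,
            tg_tg = tg_tg, tg_pl = tg_pl, margin = margin,
            plateau_window = plateau_window, tau0 = tau0)
  if (any(cuts <= 0)) stop("all cutoffs and windows must be > 0")
  structure(list(temperature = temperature, kT_J = kT(temperature),
                 cluster_cutoff = cluster_cutoff,
                 min_lens_size = as.integer(min_lens_size),
                 persistence = persistence, total_time = total_time,
                 tg_tg = tg_tg, tg_pl = tg_pl, margin = margin,
                 plateau_window = plateau_window, tau0 = tau0,
                 seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path path to a flat YAML key-value file; keys are the arguments
#'   of [analysis_config()]. Unknown keys are an error.
#' @return an `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration (nm / ns / bar / kT units)\n")
  cat(sprintf("  temperature %g K (kT = %.3g J)\n", x$temperature, x$kT_J))
  cat(sprintf("  lens: cutoff %g nm, min size %d, persistence %g ns, horizon %g us\n",
              x$cluster_cutoff, x$min_lens_size, x$persistence, x$total_time))
  cat(sprintf("  diluted TG: tg-tg %g nm, tg-pl %g nm, margin %g nm, window %g us\n",
              x$tg_tg, x$tg_pl, x$margin, x$plateau_window))
  invisible(x)
}
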