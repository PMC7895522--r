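# Multi-composition studies: per-composition nucleation, equilibrium and
# mechanics metrics plus the cross-composition correlation analyses
# (nucleation energy vs excess TG; diluted TG vs chain pressure and vs
# monolayer curvature stress).

#' Ordinary least squares with Pearson correlation
#'
#' @param x,y paired finite metric values, length >= 3.
#' @return list: `slope`, `intercept`, `r` (Pearson; defined as 0 for a
#'   constant `y`), `n`, `se_slope`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 paired finite points are required")
  if (var(x) == 0) stop("undefined fit: x has zero variance")
  if (var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r = 0, n = length(x),
                se_slope = 0))
  fit <- lm(y ~ x)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  se <- sqrt(sum(fit$residuals^2) / (n - 2) / sxx)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = unname(cor(x, y)), n = n, se_slope = se)
}

#' Run a multi-composition synthetic study
#'
#' Executes the analysis stages over a list of compositions and collects
#' a per-composition results table plus the standard correlation fits.
#' Each composition entry provides either raw inputs (trajectories,
#' pressure profiles, diluted-TG series) or synthetic-generation
#' parameters; this runner generates what is missing with the package's
#' generators, which keeps a full study reproducible from a config and a
#' seed.
#'
#' @param compositions named list; each element is a list with fields
#'   (all optional unless noted):
#'   \describe{
#'     \item{label}{composition label, e.g. `"+20 mol% DAG"`; defaults to
#'       the element name.}
#'     \item{tg_pl_ratio}{nominal TG/PL percent of the nucleation setup
#'       (default 6).}
#'     \item{nucleation_rate_true}{1/us; replicate waiting times are
#'       drawn from this rate (synthetic path).}
#'     \item{replica_times}{alternatively, explicit formation times (us)
#'       with `censored` logical.}
#'     \item{diluted_plateau_true}{equilibrium diluted-TG percent used by
#'       the relaxation-series generator.}
#'     \item{diluted_series}{alternatively, a list of
#'       `diluted_tg_series` replicas.}
#'     \item{profile}{a [pressure_profile()], or parameters for
#'       [gen_stress_profile()] as a list.}
#'     \item{kappa_b}{monolayer bending modulus, kT (default 10).}
#'   }
#' @param config an [analysis_config()] (defaults apply otherwise).
#' @param reference label of the reference composition for relative
#'   nucleation energies (default: first composition).
#' @param n_replicas replicas for the synthetic nucleation stage
#'   (default 3).
#' @param seed master seed; per-composition seeds are derived from it.
#' @return object of class `study_result`: `table` (data frame, one row
#'   per composition), `correlations` (list of [correlate()] fits),
#'   `config`, `reference`, `errors` (per-composition failure messages).
#' @export
run_study <- function(compositions, config = analysis_config(),
                      reference = NULL, n_replicas = 3, seed = 1) {
  if (is.null(names(compositions)))
    names(compositions) <- paste0("composition_", seq_along(compositions))
  labels <- vapply(seq_along(compositions), function(i)
    compositions[[i]]$label %||% names(compositions)[i], "")
  if (is.null(reference)) reference <- labels[1]
  errors <- list()
  rows <- vector("list", length(compositions))
  ests <- vector("list", length(compositions))
  for (i in seq_along(compositions)) {
    cmp <- compositions[[i]]
    row <- list(composition = labels[i],
                tg_pl_ratio = cmp$tg_pl_ratio %||% 6)
    res <- tryCatch({
      seed_i <- (seed * 1009 + i * 7919) %% 2147483647
      # nucleation stage
      if (!is.null(cmp$replica_times)) {
        est <- nucleation_rate(cmp$replica_times,
                               total_time = config$total_time,
                               censored = cmp$censored %||%
                                 rep(FALSE, length(cmp$replica_times)))
      } else if (!is.null(cmp$nucleation_rate_true)) {
        draws <- gen_nucleation_replicas(cmp$nucleation_rate_true,
                                         n_replicas,
                                         t_max = config$total_time,
                                         seed = seed_i)
        est <- nucleation_rate(draws$time, total_time = config$total_time,
                               censored = draws$censored)
      } else est <- NULL
      ests[[i]] <- est
      row$rate <- if (!is.null(est)) est$rate else NA_real_
      row$rate_err <- if (!is.null(est)) est$rate_error else NA_real_
      # equilibrium stage
      series <- cmp$diluted_series
      if (is.null(series) && !is.null(cmp$diluted_plateau_true))
        series <- lapply(1:2, function(r)
          gen_relaxation_series(cmp$diluted_plateau_true,
                                noise_sd = cmp$diluted_noise_sd %||% 0.1,
                                seed = seed_i + r))
      if (!is.null(series)) {
        ps <- plateau_stats(series, window = config$plateau_window)
        row$diluted_plateau <- ps$mean
        row$diluted_sd <- ps$sd
        row$excess_tg <- excess_tg(row$tg_pl_ratio, ps$mean)
      } else {
        row$diluted_plateau <- NA_real_; row$diluted_sd <- NA_real_
        row$excess_tg <- NA_real_
      }
      # mechanics stage
      prof <- cmp$profile
      if (is.list(prof) && !inherits(prof, "pressure_profile"))
        prof <- do.call(gen_stress_profile, prof)
      if (!is.null(prof)) {
        kb <- cmp$kappa_b %||% 10
        truth <- attr(prof, "truth")
        minima <- if (!is.null(truth)) truth$minima else "auto"
        pc <- chain_pressure(prof, minima = minima)
        fm <- first_moment_curvature(prof, kappa_b = kb,
                                     temperature = config$temperature)
        cs <- curvature_stress(kb, fm$c0)
        row$pi_ch <- pc$pi_ch
        row$kb_c0 <- fm$kb_c0
        row$c0 <- fm$c0
        row$kappa_b <- kb
        row$curvature_stress <- cs$stress
      } else {
        row$pi_ch <- NA_real_; row$kb_c0 <- NA_real_; row$c0 <- NA_real_
        row$kappa_b <- NA_real_; row$curvature_stress <- NA_real_
      }
      row
    }, error = function(e) {
      errors[[labels[i]]] <<- conditionMessage(e)
      row$rate <- NA_real_
      row
    })
    rows[[i]] <- res
  }
  fields <- c("composition", "tg_pl_ratio", "rate", "rate_err",
              "diluted_plateau", "diluted_sd", "excess_tg", "pi_ch",
              "kb_c0", "c0", "kappa_b", "curvature_stress")
  tab <- do.call(rbind, lapply(rows, function(r) {
    missing <- setdiff(fields, names(r))
    r[missing] <- NA_real_
    as.data.frame(r[fields], stringsAsFactors = FALSE)
  }))
  # relative nucleation energies vs the reference composition
  ref_i <- match(reference, labels)
  tab$enucl_ratio <- NA_real_; tab$enucl_ratio_err <- NA_real_
  if (!is.na(ref_i) && !is.null(ests[[ref_i]]) && ests[[ref_i]]$rate > 0) {
    for (i in seq_along(ests)) {
      if (is.null(ests[[i]]) || ests[[i]]$rate <= 0) next
      en <- relative_nucleation_energy(ests[[i]], ests[[ref_i]],
                                       tau0 = config$tau0)
      tab$enucl_ratio[i] <- en$ratio
      tab$enucl_ratio_err[i] <- en$relative_error
    }
  }
  cors <- list()
  safe_cor <- function(x, y) tryCatch(correlate(x, y),
                                      error = function(e) NULL)
  cors$enucl_vs_excess <- safe_cor(tab$excess_tg, tab$enucl_ratio)
  cors$diluted_vs_pi_ch <- safe_cor(tab$pi_ch, tab$diluted_plateau)
  cors$diluted_vs_curvature_stress <-
    safe_cor(tab$curvature_stress, tab$diluted_plateau)
  structure(list(table = tab, correlations = cors, config = config,
                 reference = reference, seed = seed, errors = errors),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", nrow(x$table), "compositions (reference:",
      x$reference, ")\n")
  print(x$table, digits = 3)
  for (nm in names(x$correlations)) {
    f <- x$correlations[[nm]]
    if (!is.null(f))
      cat(sprintf("  %s: slope %.3g, r = %.3f (n = %d)\n",
                  nm, f$slope, f$r, f$n))
  }
  if (length(x$errors))
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write a study report
#'
#' Emits `study_report.json` (full table, correlations, config and seed)
#' and `study_table.tsv` into a directory. Deterministic for fixed
#' inputs and seed: re-running the same study writes byte-identical
#' files.
#'
#' @param result a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
write_study_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "study_table.tsv")
  write.table(result$table, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  js <- file.path(dir, "study_report.json")
  payload <- list(
    reference = result$reference, seed = result$seed,
    config = unclass(result$config),
    table = result$table,
    correlations = lapply(result$correlations, function(f)
      if (is.null(f)) NULL else f[c("slope", "intercept", "r", "n")]),
    errors = result$errors)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(js)
}
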