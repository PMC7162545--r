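# Random-parameter robustness screen over the Dl/Cact/Toll model.
#
# The five free rate constants (lambda_d, lambda_dc, beta_o, gamma, kappa)
# are each drawn log-uniformly over six orders of magnitude [1e-3, 1e3].
# Each draw is simulated at dosages 0.5/1/2, scored against the observed
# 1x/2x/4x borders with the fitted-threshold least-squares error, and
# classified robust when every border error is below the cutoff (1.5).

FREE_PARAMS <- c("lambda_d", "lambda_dc", "beta_o", "gamma", "kappa")

#' Screen configuration
#'
#' @param n_sets Number of random parameter sets to draw.
#' @param lo,hi Sampling bounds for every free parameter (log-uniform).
#' @param seed RNG seed; the screen is a pure function of the configuration.
#' @param cutoff Robustness cutoff on each border error, default 1.5.
#' @param observations Border observation table ([border_observations()] by
#'   default).
#' @param base_params A [mech_params()] object providing everything that is
#'   not sampled (Toll width, weighting factors, compartment count, t_end).
#' @param geom A [geometry_params()] object for the length-scale ratio and
#'   nuclear gradients.
#' @param dosages Dosage multipliers simulated per set.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(n_sets = 5000L, lo = 1e-3, hi = 1e3, seed = 1L,
                          cutoff = 1.5, observations = border_observations(),
                          base_params = mech_params(),
                          geom = geometry_params(),
                          dosages = c(0.5, 1, 2)) {
  lo <- check_scalar(lo, "lo", positive = TRUE)
  hi <- check_scalar(hi, "hi", positive = TRUE)
  if (lo > hi) stop_invalid("need lo <= hi")
  n_sets <- as.integer(n_sets)
  if (n_sets < 0L) stop_invalid("n_sets must be >= 0")
  structure(list(n_sets = n_sets, lo = lo, hi = hi, seed = as.integer(seed),
                 cutoff = cutoff, observations = observations,
                 base_params = base_params, geom = geom, dosages = dosages),
            class = "screen_config")
}

# Log-uniform draw matrix for sets 1..n; row i is deterministic given
# (seed, i) because the stream position depends only on i.
sample_parameter_matrix <- function(config, n = config$n_sets) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  m <- matrix(runif(n * length(FREE_PARAMS)), nrow = n, byrow = TRUE)
  m <- exp(log(config$lo) + m * (log(config$hi) - log(config$lo)))
  colnames(m) <- FREE_PARAMS
  m
}

#' Draw the free parameters for one screen index
#'
#' Each of `lambda_d`, `lambda_dc`, `beta_o`, `gamma`, `kappa` is drawn
#' log-uniformly on \[`lo`, `hi`\]; the draw is deterministic given the
#' configuration seed and the index.
#'
#' @param config A [screen_config()].
#' @param index Set index (1-based).
#' @return A [mech_params()] object with the sampled rates filled in.
#' @export
sample_parameters <- function(config, index) {
  stopifnot(inherits(config, "screen_config"))
  index <- as.integer(index)
  if (index < 1L) stop_invalid("index must be >= 1")
  v <- sample_parameter_matrix(config, n = index)[index, ]
  p <- config$base_params
  p[FREE_PARAMS] <- as.list(unname(v))
  p
}

#' Evaluate one mechanistic parameter set for robustness
#'
#' Simulates the model at dosages 0.5/1/2, derives nuclear free-Dl
#' gradients, fits a concentration threshold per gene border, classifies
#' robustness, and records the length-scale ratio, amplitude ratios and the
#' dorsal residual (free Dl at x = 1 over the gradient amplitude) per
#' genotype. Numerical failures are recorded, never raised.
#'
#' @param params A [mech_params()] object.
#' @param config A [screen_config()].
#' @return A one-row data.frame (`screen_record`): sampled rates, per-border
#'   errors, `robust`, `status` (`"robust"`, `"not-robust"`,
#'   `"expression-lost"`, `"solver-failed"`), `rho`, amplitudes and ratios,
#'   and dorsal residuals.
#' @export
evaluate_parameter_set <- function(params, config) {
  stopifnot(inherits(params, "mech_params"), inherits(config, "screen_config"))
  rec <- data.frame(lambda_d = params$lambda_d, lambda_dc = params$lambda_dc,
                    beta_o = params$beta_o, gamma = params$gamma,
                    kappa = params$kappa,
                    e_sna = NA_real_, e_sogv = NA_real_, e_sogd = NA_real_,
                    robust = FALSE, status = "solver-failed",
                    rho = NA_real_,
                    amp_1x = NA_real_, amp_2x = NA_real_, amp_4x = NA_real_,
                    amp_1x_2x = NA_real_, amp_4x_2x = NA_real_,
                    dres_1x = NA_real_, dres_2x = NA_real_, dres_4x = NA_real_,
                    stringsAsFactors = FALSE)
  rec$rho <- tryCatch(length_scale_ratio(params, config$geom),
                      error = function(e) NA_real_)

  sims <- tryCatch({
    lapply(config$dosages, function(d) {
      p <- params
      p$dosage <- d
      simulate_dl(p)
    })
  }, error = function(e) NULL)
  if (is.null(sims)) return(rec)

  names(sims) <- GENOTYPES
  grads <- lapply(sims, nuclear_gradient, geom = config$geom)
  x <- sims[["2x"]]$x
  amps <- vapply(grads, max, numeric(1))
  rec$amp_1x <- amps[["1x"]]; rec$amp_2x <- amps[["2x"]]
  rec$amp_4x <- amps[["4x"]]
  if (amps[["2x"]] > 0) {
    rec$amp_1x_2x <- amps[["1x"]] / amps[["2x"]]
    rec$amp_4x_2x <- amps[["4x"]] / amps[["2x"]]
  }
  for (g in GENOTYPES)
    if (amps[[g]] > 0)
      rec[[paste0("dres_", g)]] <- grads[[g]][length(x)] / amps[[g]]

  if (all(amps <= 0)) {
    rec$status <- "expression-lost"
    return(rec)
  }
  fits <- lapply(GENES, function(gene) {
    obs <- config$observations[config$observations$gene == gene, , drop = FALSE]
    fit_threshold(grads, obs, gene = gene, x = x)
  })
  errs <- vapply(fits, function(f) f$error, numeric(1))
  rec$e_sna <- errs[1L]; rec$e_sogv <- errs[2L]; rec$e_sogd <- errs[3L]
  rec$robust <- classify_robust(errs, cutoff = config$cutoff)
  lost <- vapply(fits, function(f) anyNA(f$borders), logical(1))
  rec$status <- if (rec$robust) "robust"
                else if (any(lost)) "expression-lost"
                else "not-robust"
  rec
}

#' Run the random robustness screen
#'
#' Embarrassingly parallel in structure (records are independent given the
#' seed-indexed draws); run here as a simple loop, optionally streaming each
#' record to newline-delimited JSON as it completes.
#'
#' @param config A [screen_config()].
#' @param out_file Optional path; each completed record is appended as one
#'   JSON line, so interrupted runs keep their partial results.
#' @param progress Print a progress line every `progress` sets (0 = quiet).
#' @return A data.frame of class `screen_records` with one row per set
#'   (column `index` carries the draw index).
#' @export
run_screen <- function(config, out_file = NULL, progress = 0L) {
  stopifnot(inherits(config, "screen_config"))
  if (config$n_sets == 0L) {
    out <- data.frame()
    class(out) <- c("screen_records", "data.frame")
    return(out)
  }
  m <- sample_parameter_matrix(config)
  if (!is.null(out_file) && file.exists(out_file)) file.remove(out_file)
  rows <- vector("list", config$n_sets)
  for (i in seq_len(config$n_sets)) {
    p <- config$base_params
    p[FREE_PARAMS] <- as.list(unname(m[i, ]))
    rec <- evaluate_parameter_set(p, config)
    rec <- cbind(index = i, seed = config$seed, rec)
    rows[[i]] <- rec
    if (!is.null(out_file))
      cat(jsonlite::toJSON(as.list(rec), auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = out_file, append = TRUE)
    if (progress > 0L && i %% progress == 0L)
      message(sprintf("screen: %d/%d (%d robust so far)", i, config$n_sets,
                      sum(vapply(rows[seq_len(i)], function(r) r$robust,
                                 logical(1)))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_records", "data.frame")
  out
}

#' Ensemble summary of a screen
#'
#' Summarizes the robust subset: the fraction with length-scale ratio above
#' one (shuttling), the range of the Toll saturation constant kappa, the
#' amplitude-ratio ranges, and the dorsal residual of free Dl.
#'
#' @param records A [run_screen()] result.
#' @return A list of class `screen_summary` with counts, fractions and
#'   ranges; `empty = TRUE` (with a warning) when there are no robust sets.
#' @export
summarize_ensemble <- function(records) {
  rb <- records[isTRUE_vec(records$robust), , drop = FALSE]
  n <- nrow(records)
  if (nrow(rb) == 0L) {
    warning("no robust parameter sets in this screen")
    return(structure(list(empty = TRUE, n_sets = n, n_robust = 0L),
                     class = "screen_summary"))
  }
  structure(list(
    empty = FALSE,
    n_sets = n,
    n_robust = nrow(rb),
    robust_fraction = nrow(rb) / n,
    frac_rho_gt_1 = mean(rb$rho > 1),
    kappa_range = range(rb$kappa),
    amp_1x_2x_range = range(rb$amp_1x_2x),
    amp_4x_2x_range = range(rb$amp_4x_2x),
    dres_2x_q95 = as.numeric(quantile(rb$dres_2x, 0.95)),
    status_counts = table(records$status)
  ), class = "screen_summary")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.screen_summary <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("Screen summary: %d sets, none robust\n", x$n_sets))
    return(invisible(x))
  }
  cat(sprintf("Screen summary: %d/%d robust (%.2f%%)\n", x$n_robust,
              x$n_sets, 100 * x$robust_fraction))
  cat(sprintf("  fraction rho > 1 among robust: %.3f\n", x$frac_rho_gt_1))
  cat(sprintf("  robust kappa in [%.3g, %.3g]\n", x$kappa_range[1L],
              x$kappa_range[2L]))
  cat(sprintf("  amplitude ratios: 1x/2x in [%.3g, %.3g], 4x/2x in [%.3g, %.3g]\n",
              x$amp_1x_2x_range[1L], x$amp_1x_2x_range[2L],
              x$amp_4x_2x_range[1L], x$amp_4x_2x_range[2L]))
  invisible(x)
}
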