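# Dosage statistics: log-log sensitivity slopes, weighted qPCR summaries,
# bootstrap amplitude-ratio distributions, normal-overlap probabilities, the
# canonical nc14 amplitude curve, and the amplitude-pair SSE optimization.

#' Log-log dosage sensitivity slope
#'
#' Experimental estimate of the dosage-sensitivity coefficient: the best-fit
#' slope of log(measurement) against log(dosage) by ordinary least squares
#' over all individual measurements, reported with a 68% confidence interval
#' (plus or minus one standard error of the slope).
#'
#' @param dosages Dosage multiplier per measurement (e.g. 0.5, 1, 2).
#' @param measurements Positive per-embryo measurements (border positions or
#'   gradient widths); non-positive values are dropped with a warning.
#' @return A list with `slope`, `ci68` (one slope standard error), `n`.
#' @export
loglog_sensitivity <- function(dosages, measurements) {
  if (length(dosages) != length(measurements))
    stop_invalid("dosages and measurements must have equal length")
  bad <- !is.finite(measurements) | measurements <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive measurement(s) excluded")
    dosages <- dosages[!bad]
    measurements <- measurements[!bad]
  }
  if (length(unique(dosages)) < 2L)
    stop_invalid("need measurements at >= 2 distinct dosages")
  fit <- lm(log(measurements) ~ log(dosages))
  s <- summary(fit)$coefficients
  list(slope = unname(s[2L, 1L]), ci68 = unname(s[2L, 2L]),
       n = length(measurements))
}

#' Weighted qPCR summary per genotype
#'
#' From a table of per-well delta-CT values (dl CT minus actin CT), computes
#' for each genotype g and biological-replicate/run combination i the
#' technical-replicate mean `y_i,g` and SD `s_i,g` (combinations with fewer
#' than two valid technical replicates are discarded), then the
#' inverse-SD-weighted mean and the weighted s.e.m.
#'
#' \deqn{\bar y_g = \sum_i w_{i,g} y_{i,g}, \quad
#'       S_g = \sqrt{\frac{1}{n-1} \sum_i w_{i,g}(y_{i,g}-\bar y_g)^2 \Big/
#'             \frac{1}{n}\sum_i w_{i,g}}, \quad
#'       w_{i,g} = \frac{1/s_{i,g}}{\sum_j 1/s_{j,g}}}
#'
#' The s.e.m. formula is transcribed as printed in the source methodology;
#' `sem = "conventional"` instead uses the usual weighted-variance s.e.m.
#' \eqn{\sqrt{\sum_i w_i (y_i - \bar y)^2 / (n-1)}} for comparison.
#'
#' @param table Data.frame with columns `genotype`, `replicate` (biological
#'   replicate / run identifier) and `delta_ct`; `NA` delta-CT values are
#'   treated as failed wells.
#' @param sem `"weighted"` (default, literal formula) or `"conventional"`.
#' @param max_weight Cap applied to the unnormalized weights `1/s_i` when a
#'   technical SD is zero (declared convention), default `1e6`.
#' @return A data.frame per genotype: `genotype`, `mean`, `sem`, `n` (number
#'   of retained replicate combinations; `sem` is `NA` when n = 1).
#' @export
qpcr_weighted_stats <- function(table, sem = c("weighted", "conventional"),
                                max_weight = 1e6) {
  sem <- match.arg(sem)
  need <- c("genotype", "replicate", "delta_ct")
  if (!all(need %in% names(table)))
    stop_invalid("table needs columns ", paste(need, collapse = ", "))
  table <- table[is.finite(table$delta_ct), , drop = FALSE]
  out <- lapply(split(table, table$genotype), function(tg) {
    reps <- split(tg$delta_ct, tg$replicate)
    reps <- reps[vapply(reps, length, integer(1)) >= 2L]   # >= 2 technical
    n <- length(reps)
    if (n == 0L)
      return(data.frame(genotype = tg$genotype[1L], mean = NA_real_,
                        sem = NA_real_, n = 0L))
    y <- vapply(reps, mean, numeric(1))
    s <- vapply(reps, sd, numeric(1))
    wraw <- ifelse(s > 0, 1 / s, max_weight)
    w <- wraw / sum(wraw)
    ybar <- sum(w * y)
    S <- if (n < 2L) NA_real_
         else if (sem == "weighted")
           sqrt(sum(w * (y - ybar)^2) / (n - 1) / (sum(w) / n))
         else sqrt(sum(w * (y - ybar)^2) / (n - 1))
    data.frame(genotype = tg$genotype[1L], mean = ybar, sem = S, n = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative mRNA abundance from delta-CT summaries
#'
#' Fold change relative to a reference genotype under the standard
#' 2^-(ddCT) model, with first-order error propagation of the weighted
#' s.e.m.s.
#'
#' @param stats A [qpcr_weighted_stats()] result.
#' @param reference Reference genotype, default `"2x"`.
#' @return A data.frame per genotype: `genotype`, `fold`, `fold_sem`.
#' @export
relative_abundance <- function(stats, reference = "2x") {
  if (!reference %in% stats$genotype)
    stop_invalid("reference genotype ", reference, " not in table")
  ref <- stats[stats$genotype == reference, , drop = FALSE]
  fold <- 2^(-(stats$mean - ref$mean))
  se2 <- ifelse(stats$genotype == reference, 0,
                stats$sem^2 + ref$sem^2)
  data.frame(genotype = stats$genotype, fold = fold,
             fold_sem = fold * log(2) * sqrt(se2))
}

#' Canonical nc14 amplitude curve and per-embryo peak amplitudes
#'
#' Each embryo's gradient-amplitude time course over nc14 is normalized to
#' its maximum and its time axis stretched so nc14 lasts one unit; the
#' stretched curves are averaged on a common grid to give the canonical
#' curve. Each raw trace is then refit to the canonical curve by a
#' least-squares scale factor, and the embryo's peak amplitude is the scale
#' factor times the canonical maximum.
#'
#' @param traces List of amplitude traces; each a list with `time`,
#'   `amplitude`, and the nc14 demarcations `t_start` (beginning of nc14)
#'   and `t_gastr` (gastrulation). Traces missing a demarcation are excluded.
#' @param n_grid Grid size on the unit nc14 interval.
#' @return A list of class `canonical_curve`: `curve` (data.frame `tau`,
#'   `value`), `peaks` (per retained embryo), `excluded` (count).
#' @export
canonical_amplitude_curve <- function(traces, n_grid = 61L) {
  ok <- vapply(traces, function(tr) {
    !is.null(tr$t_start) && !is.null(tr$t_gastr) &&
      is.finite(tr$t_start) && is.finite(tr$t_gastr) &&
      tr$t_gastr > tr$t_start
  }, logical(1))
  excluded <- sum(!ok)
  traces <- traces[ok]
  if (length(traces) == 0L) stop_invalid("no qualifying traces")
  grid <- seq(0, 1, length.out = n_grid)
  crop <- lapply(traces, function(tr) {
    keep <- tr$time >= tr$t_start & tr$time <= tr$t_gastr
    tau <- (tr$time[keep] - tr$t_start) / (tr$t_gastr - tr$t_start)
    list(tau = tau, a = tr$amplitude[keep])
  })
  norm <- vapply(crop, function(cr)
    approx(cr$tau, cr$a / max(cr$a), xout = grid, rule = 2)$y,
    numeric(n_grid))
  canonical <- rowMeans(norm)
  peaks <- vapply(crop, function(cr) {
    k <- approx(grid, canonical, xout = cr$tau, rule = 2)$y
    scale <- sum(cr$a * k) / sum(k^2)
    scale * max(canonical)
  }, numeric(1))
  structure(list(curve = data.frame(tau = grid, value = canonical),
                 peaks = unname(peaks), excluded = excluded),
            class = "canonical_curve")
}

#' Bootstrap distribution of an amplitude ratio
#'
#' Resamples each genotype's peak amplitudes with replacement and forms the
#' ratio of resampled means.
#'
#' @param peaks_num,peaks_den Peak amplitudes for the numerator and
#'   denominator genotypes (>= 2 each).
#' @param n_boot Number of bootstrap replicates, default 10000.
#' @param seed RNG seed.
#' @return A list with `mean`, `sd` and the replicate vector `ratios`.
#' @export
bootstrap_amplitude_ratios <- function(peaks_num, peaks_den, n_boot = 1e4,
                                       seed = 1L) {
  if (length(peaks_num) < 2L || length(peaks_den) < 2L)
    stop_invalid("need >= 2 peaks per genotype")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ratios <- vapply(seq_len(n_boot), function(i)
    mean(sample(peaks_num, replace = TRUE)) /
      mean(sample(peaks_den, replace = TRUE)),
    numeric(1))
  list(mean = mean(ratios), sd = sd(ratios), ratios = ratios)
}

#' Probability mass of a normal distribution on an interval
#'
#' `P(lo < X < hi)` for `X ~ Normal(mean, sd)`; used to quantify the overlap
#' between experimentally measured amplitude-ratio distributions and the
#' range favored by the robust model ensemble.
#'
#' @param mean,sd Normal moments (`sd > 0`).
#' @param lo,hi Interval bounds (`lo < hi`).
#' @return The probability.
#' @export
normal_range_probability <- function(mean, sd, lo, hi) {
  sd <- check_scalar(sd, "sd", positive = TRUE)
  if (lo >= hi) stop_invalid("need lo < hi")
  pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
}

#' Optimal 1x and 4x gradient amplitudes against observed borders
#'
#' Grid search for the amplitude scalings of the averaged 1x and 4x
#' gradients (the 2x amplitude is fixed at one) that best predict the
#' observed gene-expression borders. Thresholds are calibrated per gene on
#' the 2x curve at its observed border; predicted borders for the scaled 1x
#' and 4x curves are threshold crossings, and the objective is the summed
#' squared z-score of predicted versus observed borders.
#'
#' @param curves Named list (`"1x"`, `"2x"`, `"4x"`) of averaged gradient
#'   curves, each a data.frame with `x` and `mean` (or `value`) on x >= 0.
#' @param obs Border observation table ([border_observations()] format).
#' @param alpha_grid Candidate amplitudes, default `seq(0.25, 2.5, 0.01)`.
#' @param lost_penalty_x Model border when a scaled curve never reaches the
#'   threshold, as in [border_error()].
#' @return A list of class `amplitude_pair_fit`: `alpha_1x`, `alpha_4x`,
#'   `sse` (minimized), `surface` (matrix over the grid, 1x rows x 4x
#'   columns), `alpha_grid`, `feasible` (matrix; `FALSE` where
#'   `alpha_1x > 1` or `alpha_4x < 1`).
#' @export
optimize_amplitude_pair <- function(curves, obs,
                                    alpha_grid = seq(0.25, 2.5, by = 0.01),
                                    lost_penalty_x = 0) {
  for (g in GENOTYPES)
    if (is.null(curves[[g]])) stop_invalid("curves must include ", g)
  val <- function(cu) if (!is.null(cu$mean)) cu$mean else cu$value
  pos <- lapply(curves, function(cu) {
    keep <- cu$x >= 0
    list(x = cu$x[keep], y = val(cu)[keep])
  })
  genes <- unique(obs$gene)
  # per-gene threshold from the 2x curve at its observed 2x border
  thetas <- vapply(genes, function(gene) {
    xb <- obs$x_exp[obs$gene == gene & obs$genotype == "2x"]
    approx(pos[["2x"]]$x, pos[["2x"]]$y, xout = xb)$y
  }, numeric(1))

  # the SSE is separable in (alpha_1x, alpha_4x): accumulate the per-alpha
  # error of each genotype, then form the surface as an outer sum
  err_g <- function(genotype) {
    cu <- pos[[genotype]]
    e <- numeric(length(alpha_grid))
    for (gi in seq_along(genes)) {
      row <- obs[obs$gene == genes[gi] & obs$genotype == genotype, ][1L, ]
      for (ai in seq_along(alpha_grid)) {
        b <- extract_border(alpha_grid[ai] * cu$y, thetas[gi], x = cu$x)
        xm <- if (b$expressed) b$x_b else lost_penalty_x
        e[ai] <- e[ai] + ((xm - row$x_exp) / row$sigma_exp)^2
      }
    }
    e
  }
  e1 <- err_g("1x")
  e4 <- err_g("4x")
  surface <- outer(e1, e4, "+")
  i <- which.min(e1)
  j <- which.min(e4)
  feasible <- outer(alpha_grid <= 1, alpha_grid >= 1, "&")
  structure(list(alpha_1x = alpha_grid[i], alpha_4x = alpha_grid[j],
                 sse = e1[i] + e4[j], surface = surface,
                 alpha_grid = alpha_grid, feasible = feasible),
            class = "amplitude_pair_fit")
}

#' @export
print.amplitude_pair_fit <- function(x, ...) {
  cat(sprintf(
    "Best-fit amplitudes: alpha_1x = %.2f, alpha_4x = %.2f (SSE %.3g)%s\n",
    x$alpha_1x, x$alpha_4x, x$sse,
    if (x$alpha_1x > 1 || x$alpha_4x < 1) " [outside feasible region]" else ""))
  invisible(x)
}
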