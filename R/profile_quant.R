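# Quantification of per-embryo DV intensity profiles: Gaussian-with-tail
# fits of the Dl gradient, normalization, grid averaging, and canonical-
# template fits of gene-expression profiles with half-max borders.

#' Fit a Gaussian-with-tail model to a Dl gradient profile
#'
#' Least-squares fit of
#' `I(x) = A exp(-(x - mu)^2 / 2 sigma^2) + M |x - mu| + B`
#' to one embryo's nuclear-intensity profile. `mu` is a ventral-midline
#' offset nuisance parameter used later to align embryos for averaging.
#' Three starts are tried (data-driven moments, wide, narrow) and the best
#' converged fit kept; the goodness of fit is the coefficient of
#' determination.
#'
#' @param profile Data.frame with columns `x` (DV coordinate in \[-1, 1\])
#'   and `intensity`.
#' @return A list of class `dl_gradient_fit`: `A`, `B`, `M`, `sigma`, `mu`,
#'   `gof`, `converged`, `fitted` (fitted values on `profile$x`).
#' @export
fit_dl_gradient <- function(profile) {
  x <- profile$x
  y <- profile$intensity
  if (length(x) < 10L)
    stop_invalid("need at least 10 profile points")
  model <- function(p, x)
    p[1L] * exp(-(x - p[5L])^2 / (2 * p[4L]^2)) + p[3L] * abs(x - p[5L]) + p[2L]

  a0 <- max(y) - min(y)
  mu0 <- x[which.max(y)]
  starts <- list(
    c(A = a0, B = min(y), M = -0.1 * a0, sigma = 0.15, mu = mu0),
    c(A = a0, B = min(y), M = 0, sigma = 0.4, mu = 0),
    c(A = a0, B = min(y), M = 0, sigma = 0.08, mu = mu0))

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + M * abs(x - mu) + B,
        data = data.frame(x = x, y = y),
        start = as.list(s),
        lower = c(A = 0, B = -Inf, M = -Inf, sigma = 1e-4, mu = -1),
        upper = c(A = Inf, B = Inf, M = Inf, sigma = 2, mu = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    out <- list(A = NA_real_, B = NA_real_, M = NA_real_, sigma = NA_real_,
                mu = NA_real_, gof = 0, converged = FALSE, fitted = NULL)
    class(out) <- "dl_gradient_fit"
    return(out)
  }
  p <- coef(best$fit)
  sst <- sum((y - mean(y))^2)
  gof <- if (sst > 0) 1 - best$rss / sst else as.numeric(best$rss == 0)
  out <- list(A = unname(p["A"]), B = unname(p["B"]), M = unname(p["M"]),
              sigma = unname(p["sigma"]), mu = unname(p["mu"]),
              gof = min(gof, 1), converged = TRUE,
              fitted = as.numeric(predict(best$fit)))
  class(out) <- "dl_gradient_fit"
  out
}

#' @export
print.dl_gradient_fit <- function(x, ...) {
  if (!x$converged) cat("Dl gradient fit: failed to converge (gof = 0)\n")
  else cat(sprintf(
    "Dl gradient fit: A = %.4g, B = %.4g, M = %.4g, sigma = %.4g, mu = %.4g (gof %.3f)\n",
    x$A, x$B, x$M, x$sigma, x$mu, x$gof))
  invisible(x)
}

#' Normalize a profile by its own Gaussian fit
#'
#' Applies `X = (I - B - 0.7 M) / A` pointwise, putting every embryo on a
#' common intensity scale (peak-adjusted value maps to 1, basal-adjusted
#' value to 0).
#'
#' @param profile Data.frame with columns `x`, `intensity`.
#' @param fit A [fit_dl_gradient()] result for this profile.
#' @return The profile with `intensity` replaced by the normalized values;
#'   the fitted midline offset is carried in attribute `"mu"`.
#' @export
normalize_profile <- function(profile, fit) {
  stopifnot(inherits(fit, "dl_gradient_fit"))
  if (!fit$converged || !is.finite(fit$A) || fit$A <= 0)
    stop_invalid("cannot normalize: fit invalid or A <= 0")
  out <- profile
  out$intensity <- (profile$intensity - fit$B - 0.7 * fit$M) / fit$A
  attr(out, "mu") <- fit$mu
  out
}

#' Average normalized profiles on a fixed DV grid
#'
#' Aligns each profile by its fitted ventral midline, interpolates linearly
#' to a 301-point grid spanning x = -1 to 1, and takes the arithmetic mean
#' at each grid point. Points outside an embryo's sampled range are excluded
#' from that embryo's contribution (no extrapolation); grid points averaged
#' over fewer embryos than supplied are flagged.
#'
#' @param profiles List of normalized profiles (from [normalize_profile()],
#'   which attaches the alignment offset as attribute `"mu"`; a missing
#'   attribute means already aligned).
#' @param n_grid Grid size, default 301.
#' @return A data.frame with columns `x`, `mean`, `sd`, `n`, `edge`
#'   (`TRUE` where fewer than all embryos contributed).
#' @export
average_gradients <- function(profiles, n_grid = 301L) {
  if (length(profiles) < 2L)
    stop_invalid("need at least 2 profiles to average")
  grid <- seq(-1, 1, length.out = n_grid)
  vals <- vapply(profiles, function(p) {
    mu <- attr(p, "mu")
    if (is.null(mu)) mu <- 0
    approx(p$x - mu, p$intensity, xout = grid, rule = 1)$y
  }, numeric(n_grid))
  n <- rowSums(!is.na(vals))
  data.frame(
    x = grid,
    mean = rowMeans(vals, na.rm = TRUE),
    sd = apply(vals, 1L, sd, na.rm = TRUE),
    n = n,
    edge = n < length(profiles))
}

#' Canonical gene-expression template
#'
#' Smoothed-pulse template for a gene-expression domain: the difference of
#' two logistic sigmoids in `|x|`, with edges at `lo` and `hi` and edge
#' steepness `s` (the half-max points sit at the edges when they are well
#' separated). Unit amplitude, zero background. This template family stands
#' in for externally derived canonical profiles and is validated on
#' synthetic data.
#'
#' @param x DV coordinate(s) in \[-1, 1\].
#' @param lo,hi Ventral and dorsal edge of the expression domain, in \[0, 1\]
#'   coordinates on the half axis; use `lo = -hi` for a ventral (sna-like)
#'   domain open at the midline.
#' @param s Edge steepness (DV units), default 0.01.
#' @return Template value(s) in \[0, 1\].
#' @export
canonical_profile <- function(x, lo, hi, s = 0.01) {
  u <- abs(x)
  plogis((u - lo) / s) - plogis((u - hi) / s)
}

#' Fit gene-expression borders via the canonical template
#'
#' Fits amplitude, background and the domain edges of the canonical
#' template to a gene-expression intensity profile; for sna-like (ventral)
#' domains only the dorsal edge is free, for sog-like (lateral) domains both
#' the location and the width of the domain are free. The reported borders
#' are the half-max crossings of the fitted template. Fits with goodness of
#' fit below the cutoff are flagged excluded.
#'
#' @param profile Data.frame with columns `x`, `intensity`.
#' @param gene `"sna"` (ventral domain) or `"sog"` (lateral domain).
#' @param gof_cutoff Exclusion cutoff on the coefficient of determination,
#'   default 0.8.
#' @param steepness Template edge steepness held fixed during the fit.
#' @return A list of class `gene_border_fit`: `gene`, `borders` (dorsal
#'   border for sna; ventral and dorsal borders for sog), `A`, `B`, `gof`,
#'   `excluded`.
#' @export
fit_gene_borders <- function(profile, gene = c("sna", "sog"),
                             gof_cutoff = 0.8, steepness = 0.01) {
  gene <- match.arg(gene)
  x <- profile$x
  y <- profile$intensity
  u <- abs(x)
  a0 <- max(y) - min(y)
  failed <- list(gene = gene, borders = NULL, A = NA_real_, B = NA_real_,
                 gof = 0, excluded = TRUE)
  class(failed) <- "gene_border_fit"

  fit <- tryCatch({
    if (gene == "sna") {
      hi0 <- quantile(u[y > min(y) + a0 / 2], 0.95, names = FALSE)
      minpack.lm::nlsLM(
        y ~ A * (plogis((u + hi) / steepness) - plogis((u - hi) / steepness)) + B,
        data = data.frame(u = u, y = y),
        start = list(A = a0, B = min(y), hi = hi0),
        lower = c(A = 0, B = -Inf, hi = 1e-3),
        upper = c(A = Inf, B = Inf, hi = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      on <- u[y > min(y) + a0 / 2]
      lo0 <- quantile(on, 0.05, names = FALSE)
      hi0 <- quantile(on, 0.95, names = FALSE)
      minpack.lm::nlsLM(
        y ~ A * (plogis((u - lo) / steepness) - plogis((u - hi) / steepness)) + B,
        data = data.frame(u = u, y = y),
        start = list(A = a0, B = min(y), lo = lo0, hi = hi0),
        lower = c(A = 0, B = -Inf, lo = 0, hi = 1e-3),
        upper = c(A = Inf, B = Inf, lo = 1, hi = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed)

  p <- coef(fit)
  if (!is.finite(p["A"]) || p["A"] <= 0) return(failed)
  rss <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  gof <- if (sst > 0) min(1, 1 - rss / sst) else as.numeric(rss == 0)

  # half-max crossings of the fitted unit template on a dense half-axis grid
  lo <- if (gene == "sna") -p[["hi"]] else p[["lo"]]
  hi <- p[["hi"]]
  ug <- seq(0, 1, length.out = 4001L)
  tv <- canonical_profile(ug, lo, hi, steepness)
  half <- max(tv) / 2
  above <- tv >= half
  borders <- numeric(0)
  dn <- which(above[-length(above)] & !above[-1L])
  up <- which(!above[-length(above)] & above[-1L])
  interp <- function(i) {
    ug[i] + (tv[i] - half) / (tv[i] - tv[i + 1L]) * (ug[i + 1L] - ug[i])
  }
  if (gene == "sna") {
    if (length(dn) >= 1L) borders <- interp(dn[1L])
  } else {
    if (length(up) >= 1L) borders <- c(borders, interp(up[1L]))
    if (length(dn) >= 1L) borders <- c(borders, interp(dn[length(dn)]))
  }
  if (length(borders) == 0L) return(failed)

  out <- list(gene = gene, borders = unname(borders), A = unname(p["A"]),
              B = unname(p["B"]), gof = gof, excluded = gof < gof_cutoff)
  class(out) <- "gene_border_fit"
  out
}

#' @export
print.gene_border_fit <- function(x, ...) {
  cat(sprintf("%s border fit: gof %.3f%s\n", x$gene, x$gof,
              if (x$excluded) " [excluded]" else ""))
  if (!is.null(x$borders))
    cat("  borders:", paste(round(x$borders, 4), collapse = ", "), "\n")
  invisible(x)
}
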