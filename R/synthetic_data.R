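# Synthetic-data generator: emulates every input the real study measured —
# per-embryo nuclear-intensity profiles, gene-expression profiles with known
# borders, nc14 amplitude time courses, and qPCR delta-CT tables — with the
# ground truth emitted alongside, so every pipeline stage can be tested
# without raw imaging data.

#' Synthetic-data configuration
#'
#' Defaults mirror the study conditions: three genotypes at relative doses
#' 0.5/1/2; Dl-gradient truths with the measured per-genotype widths
#' (0.13/0.15/0.17), tail slope -0.1 and raw-fluorescence basal level 0.4;
#' gene-border truths at the measured mean border positions; about 100
#' nuclei per DV profile; multiplicative intensity noise of 5% CV with a
#' small additive floor; qPCR structure of 3 runs x 3 biological x 3
#' technical replicates; and nc14 durations drawn between 40 and 70 minutes
#' with amplitude-ratio truths 0.5 (1x:2x) and 1.7 (4x:2x).
#'
#' @param seed Master RNG seed; every generator is deterministic given the
#'   configuration.
#' @param n_embryos Embryos per genotype for profile generators.
#' @param gradient_truth Named list of [empirical_params()] per genotype.
#' @param gene_truth Data.frame with `gene`, `genotype`, `lo`, `hi` domain
#'   edges (the planted borders); defaults from the measured border table
#'   (sna domain from the midline to its dorsal border, sog between its
#'   ventral and dorsal borders).
#' @param noise_cv Multiplicative intensity noise (lognormal, CV scale).
#' @param noise_add Additive Gaussian noise SD.
#' @param jitter_sd SD of the random ventral-midline offset per embryo.
#' @param n_nuclei Sampled nuclei per profile.
#' @param gene_steepness Edge steepness of generated gene-expression pulses.
#' @param qpcr_doses Named relative doses per genotype.
#' @param qpcr_runs,qpcr_bio,qpcr_tech qPCR replicate structure.
#' @param qpcr_run_sd,qpcr_bio_sd,qpcr_tech_sd Noise SDs (CT units) for run
#'   offsets, biological and technical variation.
#' @param qpcr_dropout Probability that a technical well fails (no CT).
#' @param amp_peaks Named true peak amplitudes per genotype.
#' @param amp_t_range Range (min) of nc14 durations.
#' @param amp_noise Additive SD on amplitude traces.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_embryos = 40L,
                         gradient_truth = list(
                           "1x" = empirical_params(alpha = 0.5, sigma = 0.13),
                           "2x" = empirical_params(alpha = 1, sigma = 0.15),
                           "4x" = empirical_params(alpha = 2, sigma = 0.17)),
                         gene_truth = NULL,
                         noise_cv = 0.05, noise_add = 0.02,
                         jitter_sd = 0.01, n_nuclei = 100L,
                         gene_steepness = 0.02,
                         qpcr_doses = c("1x" = 0.5, "2x" = 1, "4x" = 2),
                         qpcr_runs = 3L, qpcr_bio = 3L, qpcr_tech = 3L,
                         qpcr_run_sd = 0.2, qpcr_bio_sd = 0.3,
                         qpcr_tech_sd = 0.15, qpcr_dropout = 0.05,
                         amp_peaks = c("1x" = 0.5, "2x" = 1, "4x" = 1.7),
                         amp_t_range = c(40, 70), amp_noise = 0.03) {
  if (is.null(gene_truth)) {
    obs <- border_observations()
    sna <- obs[obs$gene == "sna", ]
    sogv <- obs[obs$gene == "sogv", ]
    sogd <- obs[obs$gene == "sogd", ]
    gene_truth <- rbind(
      data.frame(gene = "sna", genotype = sna$genotype, lo = 0,
                 hi = sna$x_exp),
      data.frame(gene = "sog", genotype = sogv$genotype, lo = sogv$x_exp,
                 hi = sogd$x_exp[match(sogv$genotype, sogd$genotype)]))
  }
  stopifnot(noise_cv >= 0, noise_add >= 0, jitter_sd >= 0, n_embryos >= 1)
  structure(list(seed = as.integer(seed), n_embryos = as.integer(n_embryos),
                 gradient_truth = gradient_truth, gene_truth = gene_truth,
                 noise_cv = noise_cv, noise_add = noise_add,
                 jitter_sd = jitter_sd, n_nuclei = as.integer(n_nuclei),
                 gene_steepness = gene_steepness,
                 qpcr_doses = qpcr_doses, qpcr_runs = qpcr_runs,
                 qpcr_bio = qpcr_bio, qpcr_tech = qpcr_tech,
                 qpcr_run_sd = qpcr_run_sd, qpcr_bio_sd = qpcr_bio_sd,
                 qpcr_tech_sd = qpcr_tech_sd, qpcr_dropout = qpcr_dropout,
                 amp_peaks = amp_peaks, amp_t_range = amp_t_range,
                 amp_noise = amp_noise),
            class = "synth_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# stage-specific sub-seeds derived stably from the master seed
stage_seed <- function(config, stage) {
  config$seed * 8L + match(stage, c("profiles", "genes", "amplitude", "qpcr"))
}

#' Synthetic per-embryo Dl gradient profiles
#'
#' Samples nuclear positions on \[-1, 1\], evaluates the genotype's gradient
#' truth with a random midline offset, and applies multiplicative
#' (lognormal) then additive Gaussian noise.
#'
#' @param config A [synth_config()].
#' @return A data.frame with columns `embryo_id`, `genotype`, `x`,
#'   `intensity`; the truth (gradient parameters and per-embryo midline
#'   offsets) is attached as attribute `"truth"`.
#' @export
synth_embryo_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(stage_seed(config, "profiles"), {
    rows <- list()
    offsets <- list()
    for (g in names(config$gradient_truth)) {
      truth <- config$gradient_truth[[g]]
      for (e in seq_len(config$n_embryos)) {
        id <- sprintf("%s_%03d", g, e)
        x <- sort(runif(config$n_nuclei, -1, 1))
        mu <- rnorm(1, 0, config$jitter_sd)
        i0 <- eval_gradient(truth, pmin(1, pmax(-1, x - mu)))
        int <- i0 * exp(rnorm(length(x), 0, config$noise_cv)) +
          rnorm(length(x), 0, config$noise_add)
        rows[[id]] <- data.frame(embryo_id = id, genotype = g, x = x,
                                 intensity = int)
        offsets[[id]] <- mu
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(gradient = config$gradient_truth,
                               mu = unlist(offsets))
    out
  })
}

#' Synthetic gene-expression profiles with planted borders
#'
#' Smoothed-pulse expression domains (sna from the ventral midline to its
#' dorsal border; sog between its ventral and dorsal borders) with
#' multiplicative and additive noise; the planted borders are the half-max
#' points of the noiseless pulse.
#'
#' @param config A [synth_config()].
#' @return A data.frame with columns `embryo_id`, `genotype`, `gene`, `x`,
#'   `intensity`, and the planted borders as attribute `"truth"`.
#' @export
synth_gene_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(stage_seed(config, "genes"), {
    rows <- list()
    for (k in seq_len(nrow(config$gene_truth))) {
      tr <- config$gene_truth[k, ]
      lo <- if (tr$gene == "sna") -tr$hi else tr$lo
      for (e in seq_len(config$n_embryos)) {
        id <- sprintf("%s_%s_%03d", tr$gene, tr$genotype, e)
        x <- sort(runif(config$n_nuclei, -1, 1))
        i0 <- canonical_profile(x, lo, tr$hi, config$gene_steepness)
        int <- i0 * exp(rnorm(length(x), 0, config$noise_cv)) +
          rnorm(length(x), 0, config$noise_add)
        rows[[id]] <- data.frame(embryo_id = id, genotype = tr$genotype,
                                 gene = tr$gene, x = x, intensity = int)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- config$gene_truth
    out
  })
}

#' Synthetic nc14 amplitude traces
#'
#' A shared canonical amplitude shape (smooth rise through nc14), a
#' per-embryo nc14 duration drawn from the configured range, per-genotype
#' peak scaling and additive noise; both nc14 demarcation times are
#' included.
#'
#' @param config A [synth_config()].
#' @return A list of traces (each with `time`, `amplitude`, `t_start`,
#'   `t_gastr`, `genotype`), with the truth (shape and peaks) as attribute
#'   `"truth"`.
#' @export
synth_amplitude_traces <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  shape <- function(tau) sin(pi * tau / 2)^2   # unit peak at end of nc14
  with_seed(stage_seed(config, "amplitude"), {
    traces <- list()
    for (g in names(config$amp_peaks)) {
      for (e in seq_len(config$n_embryos)) {
        Tnc <- runif(1, config$amp_t_range[1L], config$amp_t_range[2L])
        t_start <- runif(1, 5, 15)
        time <- seq(t_start - 5, t_start + Tnc + 5, by = 1)
        tau <- pmin(1, pmax(0, (time - t_start) / Tnc))
        amp <- config$amp_peaks[[g]] * shape(tau) +
          rnorm(length(time), 0, config$amp_noise)
        traces[[sprintf("%s_%03d", g, e)]] <-
          list(time = time, amplitude = amp, t_start = t_start,
               t_gastr = t_start + Tnc, genotype = g)
      }
    }
    attr(traces, "truth") <- list(peaks = config$amp_peaks, shape = shape)
    traces
  })
}

#' Synthetic qPCR delta-CT table
#'
#' Delta-CT = -log2(dose) + run offset + biological noise + technical
#' noise, over the configured runs x biological x technical structure, with
#' random well dropouts.
#'
#' @param config A [synth_config()].
#' @return A data.frame with columns `genotype`, `run`, `bio`, `replicate`
#'   (run/biological combination identifier), `tech`, `delta_ct` (`NA` for
#'   dropped wells); true doses attached as attribute `"truth"`.
#' @export
synth_qpcr <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(stage_seed(config, "qpcr"), {
    rows <- list()
    run_off <- rnorm(config$qpcr_runs, 0, config$qpcr_run_sd)
    for (g in names(config$qpcr_doses)) {
      base <- -log2(config$qpcr_doses[[g]])
      bio_off <- rnorm(config$qpcr_bio, 0, config$qpcr_bio_sd)
      for (r in seq_len(config$qpcr_runs)) for (b in seq_len(config$qpcr_bio)) {
        dct <- base + run_off[r] + bio_off[b] +
          rnorm(config$qpcr_tech, 0, config$qpcr_tech_sd)
        dct[runif(config$qpcr_tech) < config$qpcr_dropout] <- NA_real_
        rows[[paste(g, r, b)]] <- data.frame(
          genotype = g, run = r, bio = b,
          replicate = sprintf("run%d_bio%d", r, b),
          tech = seq_len(config$qpcr_tech), delta_ct = dct)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(doses = config$qpcr_doses)
    out
  })
}
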