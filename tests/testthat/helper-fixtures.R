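# Small programmatic fixtures shared across tests.

# noiseless Gaussian-with-tail profile on a regular DV grid (evaluated
# directly so shifted profiles stay exact beyond the domain edges)
grid_profile <- function(params, n = 201L, mu = 0, scale = 1, offset = 0) {
  x <- seq(-1, 1, length.out = n)
  v <- params$alpha * (exp(-(x - mu)^2 / (2 * params$sigma^2)) +
                         params$m * abs(x - mu) + params$b)
  data.frame(x = x, intensity = scale * v + offset)
}

# log-uniform draw helper for property tests
runif_log <- function(n, lo = 1e-3, hi = 1e3) {
  exp(runif(n, log(lo), log(hi)))
}

# observation table built from given per-genotype borders for one gene
obs_for <- function(gene, borders, sigma_exp = 0.02) {
  data.frame(gene = gene, genotype = c("1x", "2x", "4x"),
             x_exp = borders, sigma_exp = sigma_exp)
}
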