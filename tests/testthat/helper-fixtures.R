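# Shared fixtures, built once per test run. The synthetic default model
# set is the generating truth for every simulation-based check.

fx_models <- default_shift_models("E")
fx_prior <- default_overlap_prior(fx_models, n_per_class = 150, seed = 97)
fx_prot <- simulate_protein(100, seed = 13)

# two-class toy model table on real class labels (Ala-H, Asp-H)
toy_models <- function(mu1 = c(55, 19), mu2 = c(54, 41), sd = c(1, 1),
                       r = 0) {
  df <- data.frame(aa = c("A", "D"), ss = c("H", "H"),
                   mu_ca = c(mu1[1], mu2[1]), mu_cb = c(mu1[2], mu2[2]),
                   sd_ca = sd[1], sd_cb = sd[2],
                   cov = r * sd[1] * sd[2], n = 1000)
  rownames(df) <- paste(df$aa, df$ss, sep = ":")
  structure(df, variant = "E", class = c("shift_models", "data.frame"))
}

# hand-built two-class overlap prior
toy_prior <- function(omega, weights = diag(omega)) {
  structure(list(omega = omega, weights = weights, gly = NULL),
            class = "overlap_prior")
}

# draw n points from a bivariate normal given mean, sds and correlation
rbvn <- function(n, mu, sd, r) {
  sig <- matrix(c(sd[1]^2, r * sd[1] * sd[2], r * sd[1] * sd[2],
                  sd[2]^2), 2)
  sweep(matrix(stats::rnorm(2 * n), n, 2) %*% chol(sig), 2, mu, "+")
}
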