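# Class statistics, covariance variants, cysteine splitting and the
# Q-statistic covariance refinement.

test_that("class statistics use n-1 denominators", {
  st <- class_statistics(c(70, 72), c(30, 32))
  expect_equal(st$mu_ca, 71)
  expect_equal(st$mu_cb, 31)
  expect_equal(st$sd_ca, sqrt(2), tolerance = 1e-12)
  expect_equal(st$sd_cb, sqrt(2), tolerance = 1e-12)
  expect_equal(st$cov, 2)
  expect_equal(st$n, 2)

  # zero-variance degenerate case
  z <- class_statistics(rep(50, 3), rep(30, 3))
  expect_equal(c(z$sd_ca, z$sd_cb, z$cov), c(0, 0, 0))

  # univariate (glycine) path
  g <- class_statistics(c(44, 46))
  expect_equal(g$mu_ca, 45)
  expect_true(is.na(g$mu_cb))

  expect_error(class_statistics(70, 30), "insufficient")
})

test_that("sample statistics converge to generating parameters", {
  mm <- fx_models["A:H", ]
  set.seed(101)
  x <- rbvn(50000, c(mm$mu_ca, mm$mu_cb), c(mm$sd_ca, mm$sd_cb), -0.3)
  st <- class_statistics(x[, 1], x[, 2])
  # 2% relative error on every generating parameter
  expect_lt(abs(st$mu_ca / mm$mu_ca - 1), 0.02)
  expect_lt(abs(st$mu_cb / mm$mu_cb - 1), 0.02)
  expect_lt(abs(st$sd_ca / mm$sd_ca - 1), 0.02)
  expect_lt(abs(st$sd_cb / mm$sd_cb - 1), 0.02)
  r_hat <- st$cov / (st$sd_ca * st$sd_cb)
  expect_lt(abs(r_hat / -0.3 - 1), 0.02)
})

test_that("covariance matrix variants assemble per their definitions", {
  # three SS rows with equal n: pooled variance is the plain mean
  df <- data.frame(aa = "A", ss = c("H", "E", "C"),
                   mu_ca = 55, mu_cb = 19,
                   sd_ca = 2, sd_cb = 1, cov = c(1, 2, 3), n = 100)
  rownames(df) <- paste(df$aa, df$ss, sep = ":")
  ms <- structure(df, variant = "E", class = c("shift_models", "data.frame"))

  expect_equal(class_covariance(ms, "A", "H", "A"),
               matrix(c(4, 0, 0, 1), 2, dimnames = list(c("ca", "cb"),
                                                        c("ca", "cb"))))
  expect_equal(class_covariance(ms, "A", "E", "D")[1, 2], 2)  # mean cov
  expect_equal(class_covariance(ms, "A", "C", "C")[1, 2], 2)  # pooled cov
  expect_equal(class_covariance(ms, "A", "H", "B")[1, 2], 0)
  expect_equal(class_covariance(ms, "A", "H", "E")[1, 2], 1)

  # variant E is the identity mapping onto the stored class entries
  m <- fx_models["A:H", ]
  sig <- class_covariance(fx_models, "A", "H", "E")
  expect_equal(unname(diag(sig)), c(m$sd_ca^2, m$sd_cb^2))
  expect_equal(sig[1, 2], m$cov)

  expect_error(class_covariance(fx_models, "G", "H"), "glycine")
})

test_that("assembled matrices are symmetric positive semi-definite for all classes and variants", {
  keys <- model_keys(include_glycine = FALSE)
  for (variant in c("A", "B", "C", "D", "E")) {
    for (i in seq_len(nrow(keys))) {
      sig <- class_covariance(fx_models, keys$aa[i], keys$ss[i], variant)
      expect_identical(sig[1, 2], sig[2, 1])
      expect_true(all(eigen(sig, only.values = TRUE)$values >= -1e-12))
    }
  }
})

test_that("cysteine oxidation states split by K-means with a stable label rule", {
  set.seed(21)
  ox <- rbvn(200, c(55.5, 41.0), c(1, 1), 0)
  red <- rbvn(200, c(59.5, 28.0), c(1, 1), 0)
  ca <- c(ox[, 1], red[, 1]); cb <- c(ox[, 2], red[, 2])
  lab <- split_cysteine_states(ca, cb, seed = 1)
  expect_identical(lab, rep(c("oxidized", "reduced"), each = 200))
  # restart stability: a different seed gives the identical partition
  expect_identical(lab, split_cysteine_states(ca, cb, seed = 2))
  expect_error(split_cysteine_states(rep(55, 5), rep(30, 5)), "degenerate")
})

test_that("Q statistic matches its closed form and invariances", {
  expect_equal(q_statistic(0.5, 0.5), 0)
  expect_equal(q_statistic(1, 0), 1)
  expect_equal(q_statistic(0.3, 0.1), (0.2 / 0.4)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(q_statistic(0.3, 0.1), 0.79370, tolerance = 1e-5)
  # symmetry and scale invariance over generated cases
  set.seed(5)
  a <- runif(50, 0.01, 2); b <- runif(50, 0.01, 2); s <- runif(50, 0.1, 10)
  q <- q_statistic(a, b)
  expect_true(all(q >= 0 & q <= 1))
  expect_equal(q, q_statistic(b, a))
  expect_equal(q, q_statistic(s * a, s * b))
  expect_error(q_statistic(0, 0), "undefined")
  expect_error(q_statistic(-1, 2), "non-negative")
})

make_q_entries <- function(q_values, r_values, n_pairs = 60, seed = 6) {
  set.seed(seed)
  s <- 0.6; d <- s * q_values^3
  qual <- data.frame(entry_id = sprintf("e%02d", seq_along(q_values)),
                     rmsd_ca = (s + d) / 2, rmsd_cb = (s - d) / 2)
  devs <- stats::setNames(lapply(r_values, function(r)
    rbvn(n_pairs, c(0, 0), c(1, 1), r)), qual$entry_id)
  list(qualities = qual, deviations = devs)
}

test_that("Q-statistic selection recovers a planted correlation split", {
  set.seed(6)
  qv <- c(runif(15, 0.05, 0.29), runif(15, 0.31, 0.8))
  e <- make_q_entries(qv, rep(c(-0.4, 0), each = 15))
  sel <- select_entries_by_q(e$qualities, e$deviations)
  expect_gte(sel$q_cutoff, 0.25)
  expect_lte(sel$q_cutoff, 0.35)
  expect_setequal(sel$selected, sprintf("e%02d", 1:15))
  expect_lt(sel$p_value, 0.01)
  expect_lt(sel$r_selected, sel$r_rejected)
  # deterministic under input permutation
  perm <- sample(30)
  sel2 <- select_entries_by_q(e$qualities[perm, ], e$deviations[perm])
  expect_identical(sel$selected, sel2$selected)
  expect_identical(sel$q_cutoff, sel2$q_cutoff)
})

test_that("Q-statistic selection keeps everything without signal or admissible splits", {
  e <- make_q_entries(runif(30, 0.05, 0.8), rep(-0.3, 30), seed = 5)
  sel <- select_entries_by_q(e$qualities, e$deviations)
  expect_length(sel$selected, 30)
  expect_gte(sel$p_value, 0.01)
  # too few entries for any split
  e12 <- make_q_entries(runif(12, 0.05, 0.8), rep(-0.3, 12), seed = 7)
  sel12 <- select_entries_by_q(e12$qualities, e12$deviations)
  expect_length(sel12$selected, 12)
  expect_equal(sel12$p_value, 1)
})

test_that("fit_shift_models recovers generating parameters from a large corpus", {
  sim <- simulate_corpus(fx_models, n_per_class = 2000, seed = 5,
                         n_entries = 40)
  fit <- fit_shift_models(sim$corpus, variant = "E")
  expect_identical(dim(fit), dim(fx_models))
  expect_identical(rownames(fit), rownames(fx_models))
  dmu <- abs(c(fit$mu_ca - fx_models$mu_ca, fit$mu_cb - fx_models$mu_cb))
  dsd <- abs(c(fit$sd_ca / fx_models$sd_ca,
               fit$sd_cb / fx_models$sd_cb) - 1)
  dcv <- abs(fit$cov / fx_models$cov - 1)
  expect_lt(median(dmu, na.rm = TRUE), 0.05)
  expect_lt(median(dsd, na.rm = TRUE), 0.05)
  expect_lt(median(dcv, na.rm = TRUE), 0.10)
})

test_that("fit_shift_models reports missing classes", {
  gly_only <- data.frame(entry_id = "e1", residue_index = 1:10,
                         amino_acid = "G",
                         secondary_structure = rep(c("H", "E"), 5),
                         ca_shift = rnorm(10, 45), cb_shift = NA_real_)
  expect_error(fit_shift_models(gly_only), "class")
})

test_that("E_revised covariances beat E on a half-decorrelated corpus", {
  sim <- simulate_corpus(fx_models, n_per_class = 80, seed = 2,
                         n_entries = 40, frac_decorrelated = 0.5)
  fitE <- fit_shift_models(sim$corpus, variant = "E")
  fitR <- fit_shift_models(sim$corpus, variant = "E_revised",
                           qualities = sim$qualities)
  errE <- mean(abs(fitE$cov - fx_models$cov), na.rm = TRUE)
  errR <- mean(abs(fitR$cov - fx_models$cov), na.rm = TRUE)
  expect_lt(errR, errE)
  sel <- attr(fitR, "selection")
  # selected entries are exactly the correlated ones
  good <- unique(sim$corpus$entry_id[!sim$corpus$decorrelated])
  expect_setequal(sel$selected, good)
  # means and sds are untouched by the refinement
  expect_equal(fitR$mu_ca, fitE$mu_ca)
  expect_equal(fitR$sd_ca, fitE$sd_ca)
})
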