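# Chi-square scoring, class probabilities, compositions, residuals and
# the two optimizers.

test_that("chi-square statistic matches hand-computed values", {
  expect_equal(chi_square_pair(c(55, 19), c(55, 19), diag(2)), 0)
  expect_equal(chi_square_pair(c(56, 19), c(55, 19), diag(2)), 1)
  sig <- matrix(c(4, 2, 2, 4), 2)
  expect_equal(chi_square_pair(c(1, 1), c(0, 0), sig), 1 / 3,
               tolerance = 1e-12)
  expect_error(chi_square_pair(c(1, 1), c(0, 0), matrix(1, 2, 2)),
               "singular")
})

test_that("exp(-chi/2) equals the numerically integrated 2-df upper tail", {
  for (chi in c(0.1, 0.5, 1, 2, 5, 10, 20)) {
    tail_num <- stats::integrate(stats::dchisq, chi, Inf, df = 2,
                                 rel.tol = 1e-12)$value
    expect_equal(exp(-chi / 2), tail_num, tolerance = 1e-10)
  }
})

test_that("class probabilities behave at the mean, under swap, and at chi = 2", {
  m <- fx_models["A:H", ]
  p <- class_probabilities(c(m$mu_ca, m$mu_cb), fx_models)
  expect_equal(unname(p["A:H"]), 1)
  expect_identical(names(which.max(p)), "A:H")
  # distant classes may underflow to exactly zero; none can be negative
  expect_true(all(p >= 0))

  # order invariance of unordered pairs
  pair <- c(58.7, 31.2)
  expect_equal(class_probabilities(pair, fx_models),
               class_probabilities(rev(pair), fx_models))

  # a pair at squared Mahalanobis distance 2 scores exp(-1)
  sig <- class_covariance(fx_models, "A", "H", "E")
  a <- sqrt(2 / (sig[2, 2] / det(sig)))  # chi(dx, 0) = 2
  p2 <- class_probabilities(c(m$mu_ca + a, m$mu_cb), fx_models,
                            ordered = TRUE)
  expect_equal(unname(p2["A:H"]), exp(-1), tolerance = 1e-12)
  expect_equal(unname(p2["A:H"]), 0.36788, tolerance = 1e-5)
})

test_that("estimated composition is a normalized 57-vector dominated by the source class", {
  expect_error(estimate_composition(matrix(numeric(0), 0, 2), fx_models),
               "empty")
  m <- fx_models["A:H", ]
  pairs <- matrix(rep(c(m$mu_ca, m$mu_cb), each = 200), ncol = 2)
  y <- estimate_composition(pairs, fx_models)
  expect_length(y, 57)
  expect_equal(sum(y), 1, tolerance = 1e-9)
  expect_identical(names(which.max(y)), "A:H")
})

test_that("sequence composition counts non-glycine residues and renormalizes", {
  y <- sequence_composition("AAAA", "HHHH")
  expect_equal(unname(y["A:H"]), 1)
  expect_equal(sum(y), 1)
  y2 <- sequence_composition("AG", "HH")
  expect_equal(unname(y2["A:H"]), 1)  # glycine dropped
  y3 <- sequence_composition("AC", "HE")
  expect_equal(unname(y3[c("A:H", "C:E")]), c(0.5, 0.5))
  expect_error(sequence_composition("AX", "HH"), "unknown residue")
  expect_error(sequence_composition("AA", "H"), "length")
})

test_that("weighted residual matches hand evaluation and its zero", {
  tp <- toy_prior(matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
                  weights = c(1, 1))
  y_seq <- c(0.5, 0.5)          # y_seq %*% omega = (0.55, 0.45)
  expect_equal(weighted_residual(c(0.55, 0.45), y_seq, tp), 0)
  expect_equal(weighted_residual(c(0.65, 0.35), y_seq, tp), 0.2,
               tolerance = 1e-12)
  tp$weights <- c(0.5, 1)
  expect_equal(weighted_residual(c(0.65, 0.35), y_seq, tp), 0.15,
               tolerance = 1e-12)
})

test_that("grid search recovers known offsets on model-drawn datasets", {
  errs2 <- errs0 <- numeric(5)
  for (s in 1:5) {
    prot <- simulate_protein(100, seed = s + 10)
    d2 <- simulate_spin_systems(prot$sequence, prot$ss, fx_models,
                                true_offset = 2.0, seed = s + 10)
    f2 <- refcorr(d2$pairs, prot$sequence, prot$ss, fx_models, fx_prior)
    errs2[s] <- coef(f2) - 2.0
    d0 <- simulate_spin_systems(prot$sequence, prot$ss, fx_models,
                                true_offset = 0, seed = s + 10)
    errs0[s] <- coef(refcorr(d0$pairs, prot$sequence, prot$ss, fx_models,
                             fx_prior))
    expect_equal(nrow(residuals(f2)), 100)  # 50 + 50 proposals
    expect_lte(abs(f2$correction - f2$m1), 1 + 2 / 49)
  }
  expect_lt(median(abs(errs2)), 0.12)
  expect_lte(median(abs(errs0)), 0.2)
})

test_that("grid search is deterministic and equivariant under global shifts", {
  prot <- fx_prot
  d <- simulate_spin_systems(prot$sequence, prot$ss, fx_models,
                             true_offset = 0.7, seed = 3)
  f1 <- refcorr(d$pairs, prot$sequence, prot$ss, fx_models, fx_prior)
  f2 <- refcorr(d$pairs, prot$sequence, prot$ss, fx_models, fx_prior)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$curve, f2$curve)
  # shifting every carbon by +1 moves the correction by +1 (within one
  # round-2 grid step plus round-1 aliasing)
  f3 <- refcorr(d$pairs + 1.0, prot$sequence, prot$ss, fx_models, fx_prior)
  expect_lt(abs(coef(f3) - coef(f1) - 1.0), 0.05)
})

test_that("a sparse dataset triggers the completeness warning but still fits", {
  d <- simulate_spin_systems(fx_prot$sequence, fx_prot$ss, fx_models,
                             true_offset = 1.0, missing_fraction = 0.6,
                             seed = 5)
  expect_warning(
    fit <- refcorr(d$pairs, fx_prot$sequence, fx_prot$ss, fx_models,
                   fx_prior),
    "complete")
  expect_lt(abs(coef(fit) - 1.0), 1)
})

test_that("assigned-mode correction recovers offsets by differential evolution", {
  # each row carries ~1 ppm of class width, so the estimator's standard
  # error is ~1/sqrt(rows) ppm; the +-0.05 check needs a large protein
  errs <- numeric(5)
  for (s in 1:5) {
    prot <- simulate_protein(800, seed = s + 20)
    a <- simulate_assigned_table(prot$sequence, prot$ss, fx_models,
                                 true_offset = 1.5, seed = s + 20)
    fit <- refcorr_assigned(a$table, fx_models, seed = s)
    errs[s] <- coef(fit) - 1.5
    # objective shape: truth beats +-2 ppm
    obj <- shiftref:::assigned_objective_fn(a$table, fx_models, "E")
    expect_lt(obj(1.5), obj(-0.5))
    expect_lt(obj(1.5), obj(3.5))
  }
  expect_lt(median(abs(errs)), 0.05)
})

test_that("assigned-mode correction is deterministic and validates input", {
  a <- simulate_assigned_table(fx_prot$sequence, fx_prot$ss, fx_models,
                               true_offset = -2.2, seed = 9)
  f1 <- refcorr_assigned(a$table, fx_models, seed = 4)
  f2 <- refcorr_assigned(a$table, fx_models, seed = 4)
  expect_identical(coef(f1), coef(f2))
  expect_error(refcorr_assigned(a$table[0, ], fx_models), "insufficient")
  gly <- a$table[a$table$amino_acid == "G", ]
  expect_error(refcorr_assigned(gly, fx_models), "insufficient")
})
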