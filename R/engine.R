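# Spin-system scoring against the class models, composition estimation
# under candidate reference corrections, and the correction optimizers
# (two-round grid search; differential evolution for assigned data).

#' Chi-square statistic of a shift pair under one class model
#'
#' The squared Mahalanobis distance
#' \eqn{\chi^* = (v - \mu) \Sigma^{-1} (v - \mu)^T} of an (ordered)
#' (Ca, Cb) pair from a class mean under a 2x2 covariance matrix. Under
#' the class's bivariate normal model \eqn{\chi^*} follows a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param v length-2 numeric, the (Ca, Cb) pair (ppm).
#' @param mu length-2 numeric class mean.
#' @param sigma 2x2 covariance matrix; must be invertible.
#' @return non-negative scalar.
#' @export
chi_square_pair <- function(v, mu, sigma) {
  if (abs(det(sigma)) < .Machine$double.eps)
    stop("singular covariance matrix")
  d <- as.numeric(v - mu)
  as.numeric(d %*% solve(sigma) %*% d)
}

# Precompute per-model quantities for vectorized scoring: means, inverse
# covariance coefficients, and the composition column each model maps to.
build_engine <- function(models, variant = attr(models, "variant")) {
  biv <- models[models$aa != "G", ]
  # composition space spanned by the models, in canonical order; the full
  # table yields the standard 57 classes, toy tables a subset
  comp <- intersect(composition_classes(),
                    class_label(merge_cys(biv$aa), biv$ss))
  pars <- lapply(seq_len(nrow(biv)), function(i) {
    m <- biv[i, ]
    sig <- class_covariance(models, m$aa, m$ss, variant)
    dt <- sig[1, 1] * sig[2, 2] - sig[1, 2]^2
    if (dt <= .Machine$double.eps)
      stop("singular covariance matrix for class ",
           class_label(m$aa, m$ss))
    list(mu1 = m$mu_ca, mu2 = m$mu_cb,
         i11 = sig[2, 2] / dt, i12 = -sig[1, 2] / dt, i22 = sig[1, 1] / dt,
         col = match(class_label(merge_cys(m$aa), m$ss), comp))
  })
  gly <- models[models$aa == "G", ]
  list(pars = pars, comp = comp, gly = gly, variant = variant)
}

# chi-square values of all (ca, cb) pairs under one precomputed model;
# vectorized over pairs
chi_vec <- function(p, ca, cb) {
  dx <- ca - p$mu1; dy <- cb - p$mu2
  p$i11 * dx^2 + 2 * p$i12 * dx * dy + p$i22 * dy^2
}

# n x 57 matrix of class probabilities exp(-chi/2); unordered pairs take
# the larger probability over the two orderings; the two cysteine-state
# models accumulate into the single cysteine composition column
prob_matrix <- function(engine, a, b, ordered = FALSE) {
  out <- matrix(0, length(a), length(engine$comp))
  for (p in engine$pars) {
    pr <- exp(-chi_vec(p, a, b) / 2)
    if (!ordered) pr <- pmax(pr, exp(-chi_vec(p, b, a) / 2))
    out[, p$col] <- out[, p$col] + pr
  }
  colnames(out) <- engine$comp
  out
}

#' Class probabilities of one spin system
#'
#' Scores a (Ca, Cb) pair against all 60 bivariate class models: each
#' model yields \eqn{p = P(\chi^2_2 \ge \chi^*) = \exp(-\chi^*/2)}, the
#' upper-tail probability of the 2-df chi-square distribution. For
#' unordered pairs both orderings are evaluated and the larger probability
#' kept per model, making the result order-invariant. The two cysteine
#' oxidation states are merged by summation, giving 57 values.
#'
#' @param pair length-2 numeric (Ca, Cb) shifts.
#' @param models a `shift_models` table.
#' @param ordered is the pair known to be (Ca, Cb) in that order?
#' @param variant covariance variant; defaults to the table's tag.
#' @return named numeric vector of 57 unnormalized probabilities in (0, 1]
#'   (cysteine entries may reach 2 before normalization).
#' @export
class_probabilities <- function(pair, models, ordered = FALSE,
                                variant = attr(models, "variant")) {
  engine <- build_engine(models, variant)
  drop(prob_matrix(engine, pair[1], pair[2], ordered = ordered))
}

#' Estimated residue-type composition of a dataset
#'
#' Applies a candidate reference correction (subtracted from every carbon
#' shift), computes each pair's normalized 57-class probability vector,
#' and averages the vectors over pairs, yielding the estimated
#' composition Y'. Pairs whose probability mass underflows to zero in all
#' classes (far outliers) are dropped from the average.
#'
#' @param pairs two-column matrix of (unordered) shift pairs.
#' @param models a `shift_models` table.
#' @param correction candidate reference correction (ppm).
#' @param ordered treat column 1 as Ca and column 2 as Cb.
#' @param variant covariance variant.
#' @return normalized composition vector of length 57.
#' @export
estimate_composition <- function(pairs, models, correction = 0,
                                 ordered = FALSE,
                                 variant = attr(models, "variant")) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("empty dataset: no spin-system pairs")
  engine <- build_engine(models, variant)
  drop(composition_grid(engine, pairs, correction, ordered = ordered))
}

# K x 57 matrix of estimated compositions at each candidate correction;
# shares the per-model work across the whole candidate grid
composition_grid <- function(engine, pairs, candidates, ordered = FALSE) {
  K <- length(candidates)
  a0 <- pairs[, 1]; b0 <- pairs[, 2]
  out <- matrix(0, K, length(engine$comp),
                dimnames = list(NULL, engine$comp))
  for (k in seq_len(K)) {
    pm <- prob_matrix(engine, a0 - candidates[k], b0 - candidates[k],
                      ordered = ordered)
    rs <- rowSums(pm)
    ok <- rs > 0
    if (!any(ok)) next
    out[k, ] <- colSums(pm[ok, , drop = FALSE] / rs[ok]) / sum(ok)
  }
  out
}

#' Residue-type composition implied by the protein sequence
#'
#' Counts (residue type, secondary structure) occurrences over the
#' non-glycine residues and normalizes; glycine is excluded from the
#' composition space and the mass renormalized.
#'
#' @param sequence,ss equal-length sequence and H/E/C strings.
#' @return normalized composition vector of length 57.
#' @export
sequence_composition <- function(sequence, ss) {
  v <- validate_sequence(sequence, ss)
  keep <- v$seq != "G"
  if (!any(keep)) stop("sequence contains only glycine residues")
  lab <- class_label(v$seq[keep], v$ss[keep])
  comp <- composition_classes()
  y <- as.numeric(table(factor(lab, levels = comp)))
  names(y) <- comp
  y / sum(y)
}

#' Weighted composition residual
#'
#' The objective minimized over candidate corrections:
#' \eqn{\sum_i \omega_i |Y'_i - (Y \Omega)_i|}, where Y' is the estimated
#' composition, Y the sequence composition, \eqn{\Omega} the prediction
#' overlap matrix and \eqn{\omega} its diagonal weights.
#'
#' @param y_est estimated composition (length 57, normalized).
#' @param y_seq sequence composition (length 57, normalized).
#' @param prior an `overlap_prior`.
#' @return non-negative scalar.
#' @export
weighted_residual <- function(y_est, y_seq, prior) {
  yhat <- apply_prior(y_seq, prior)
  sum(prior$weights * abs(y_est - yhat))
}

# index of the minimum with ties broken toward the smallest |candidate|
argmin_tied <- function(res, cand) {
  i <- which(res <= min(res) + 1e-12)
  i[which.min(abs(cand[i]))]
}

#' Two-round grid search for the reference correction
#'
#' Round 1 evaluates the weighted composition residual at 50 evenly spaced
#' candidate corrections over the search range (default [-5, 5] ppm); the
#' minimizer is the raw correction M1. Round 2 evaluates 50 evenly spaced
#' candidates over [M1 - 1, M1 + 1]; its minimizer is the final correction
#' M2. Ties break toward the candidate of smallest absolute value. The
#' corrected shifts are observed minus M2.
#'
#' @param pairs two-column matrix of unordered shift pairs.
#' @param sequence,ss protein sequence and secondary-structure strings.
#' @param models a `shift_models` table.
#' @param prior an `overlap_prior` (identity prior for the unweighted
#'   ablation).
#' @param search length-2 numeric search range (ppm).
#' @param n_grid candidates per round.
#' @param variant covariance variant.
#' @return list with `m1`, `m2`, `final_residual`, `curve` (100-row
#'   data.frame of candidate, residual, round), `method = "grid"`.
#' @export
grid_search_correction <- function(pairs, sequence, ss, models, prior,
                                   search = c(-5, 5), n_grid = 50,
                                   variant = attr(models, "variant")) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("empty dataset: no spin-system pairs")
  v <- validate_sequence(sequence, ss)
  n_expected <- sum(v$seq != "G")
  completeness <- nrow(pairs) / n_expected
  if (completeness < 0.5)
    warning(sprintf(
      "dataset is %.0f%% complete (below the 50%% working assumption)",
      100 * completeness))
  engine <- build_engine(models, variant)
  y_seq <- sequence_composition(sequence, ss)
  yhat <- apply_prior(y_seq, prior)
  w <- prior$weights

  eval_round <- function(cand) {
    comp <- composition_grid(engine, pairs, cand)
    as.numeric(abs(sweep(comp, 2, yhat)) %*% w)
  }

  cand1 <- seq(search[1], search[2], length.out = n_grid)
  res1 <- eval_round(cand1)
  m1 <- cand1[argmin_tied(res1, cand1)]
  cand2 <- seq(m1 - 1, m1 + 1, length.out = n_grid)
  res2 <- eval_round(cand2)
  i2 <- argmin_tied(res2, cand2)
  curve <- data.frame(candidate = c(cand1, cand2),
                      residual = c(res1, res2),
                      round = rep(1:2, each = n_grid))
  list(m1 = m1, m2 = cand2[i2], final_residual = res2[i2], curve = curve,
       completeness = completeness, method = "grid")
}

# objective for assigned data: mean chi-square of each row under its own
# class model at candidate correction c (cysteine: min over the two states)
assigned_objective_fn <- function(table, models, variant) {
  usable <- table$amino_acid != "G" &
    is.finite(table$ca_shift) & is.finite(table$cb_shift)
  tab <- table[usable, , drop = FALSE]
  if (nrow(tab) < 5)
    stop("insufficient data: need at least 5 non-glycine rows with both ",
         "shifts, got ", nrow(tab))
  par_of <- function(aa, ss) {
    sig <- class_covariance(models, aa, ss, variant)
    m <- get_model(models, aa, ss)
    dt <- sig[1, 1] * sig[2, 2] - sig[1, 2]^2
    c(m$mu_ca, m$mu_cb, sig[2, 2] / dt, -sig[1, 2] / dt, sig[1, 1] / dt)
  }
  aa1 <- ifelse(tab$amino_acid == "C", "C_ox", tab$amino_acid)
  P1 <- t(mapply(par_of, aa1, tab$secondary_structure))
  is_cys <- tab$amino_acid == "C"
  P2 <- P1
  if (any(is_cys))
    P2[is_cys, ] <- t(mapply(par_of, rep("C_red", sum(is_cys)),
                             tab$secondary_structure[is_cys]))
  ca <- tab$ca_shift; cb <- tab$cb_shift
  chi_of <- function(P, c0) {
    dx <- ca - c0 - P[, 1]; dy <- cb - c0 - P[, 2]
    P[, 3] * dx^2 + 2 * P[, 4] * dx * dy + P[, 5] * dy^2
  }
  function(c0) mean(pmin(chi_of(P1, c0), chi_of(P2, c0)))
}

#' Reference correction from assigned shifts by differential evolution
#'
#' With assignments known, each row needs only one model evaluation: the
#' objective is the mean chi-square statistic of the rows under their own
#' (residue type, secondary structure) models at a candidate correction,
#' with cysteine rows scored as the better of the two oxidation-state
#' models. The smooth 1-D objective is minimized by seeded differential
#' evolution over `bounds`.
#'
#' @param table assigned-shift data.frame (`residue_index`, `amino_acid`,
#'   `secondary_structure`, `ca_shift`, `cb_shift`); needs at least 5
#'   non-glycine rows with both shifts.
#' @param models a `shift_models` table.
#' @param bounds search interval (ppm).
#' @param seed integer seed for the optimizer.
#' @param n_pop,n_iter differential-evolution population size and
#'   generation count.
#' @param variant covariance variant.
#' @return list with `m1` = `m2` (the optimum), `final_residual` (mean
#'   chi-square at the optimum), `curve` (objective sampled on a 100-point
#'   grid for plotting), `method = "de"`.
#' @export
assigned_correction <- function(table, models, bounds = c(-10, 10),
                                seed = 1L, n_pop = 40, n_iter = 50,
                                variant = attr(models, "variant")) {
  obj <- assigned_objective_fn(table, models, variant)
  fit <- de_optimize(obj, lower = bounds[1], upper = bounds[2],
                     n_pop = n_pop, n_iter = n_iter, seed = seed)
  cand <- seq(bounds[1], bounds[2], length.out = 100)
  curve <- data.frame(candidate = cand,
                      residual = vapply(cand, obj, numeric(1)),
                      round = 1L)
  list(m1 = fit$par, m2 = fit$par, final_residual = fit$value,
       curve = curve, completeness = NA_real_, method = "de")
}

# classic rand/1/bin differential evolution on a box; deterministic given
# the seed
de_optimize <- function(fn, lower, upper, n_pop = 40, n_iter = 50,
                        F = 0.8, CR = 0.9, seed = 1L) {
  d <- length(lower)
  with_seed(seed, {
    pop <- matrix(stats::runif(n_pop * d, lower, upper), n_pop, d,
                  byrow = TRUE)
    val <- apply(pop, 1, fn)
    for (g in seq_len(n_iter)) {
      for (i in seq_len(n_pop)) {
        r <- sample(setdiff(seq_len(n_pop), i), 3)
        trial <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, trial, pop[i, ])
        trial <- pmin(pmax(trial, lower), upper)
        v <- fn(trial)
        if (v <= val[i]) { pop[i, ] <- trial; val[i] <- v }
      }
    }
    best <- which.min(val)
    list(par = as.numeric(pop[best, ]), value = val[best])
  })
}
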