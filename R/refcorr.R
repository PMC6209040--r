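# User-facing estimator interface: refcorr() fits the reference-offset
# correction to unassigned spin-system pairs (or a grouped peak list) and
# refcorr_assigned() to an assigned shift table; both return a classed
# object with the usual accessor methods.

#' Fit a carbon-13 reference correction to unassigned spin systems
#'
#' Estimates the constant referencing offset present in a set of unordered
#' (Ca, Cb) spin-system pairs by minimizing the weighted difference
#' between the residue-type composition estimated from the shifts and the
#' composition implied by the protein sequence, mapped through the
#' prediction-overlap prior. The default optimizer is the two-round grid
#' search; `optimizer = "de"` minimizes the same residual by differential
#' evolution over the search range.
#'
#' The reported correction equals the estimated offset in the data;
#' corrected shifts are observed minus correction (see
#' [predict.refcorr()]).
#'
#' @param pairs two-column matrix or data.frame of unordered shift pairs
#'   (ppm), e.g. from [spin_systems_to_pairs()] or
#'   [simulate_spin_systems()].
#' @param sequence protein sequence (one-letter string).
#' @param ss secondary-structure string over H/E/C, same length.
#' @param models a `shift_models` table; defaults to the synthetic
#'   built-in set.
#' @param prior an `overlap_prior`; `NULL` simulates the default prior
#'   from `models` ([default_overlap_prior()]); use [identity_prior()]
#'   for the unweighted ablation.
#' @param optimizer `"grid"` (two-round grid search) or `"de"`.
#' @param search search range for the correction (ppm).
#' @param seed integer seed (recorded in the fit; used by the `"de"`
#'   optimizer and the default prior simulation).
#' @param variant covariance variant; defaults to the model table's tag.
#' @return an object of class `refcorr` with components `correction`
#'   (the final value M2), `m1`, `final_residual`, `curve`, `optimizer`,
#'   `completeness`, `seed` and the inputs; supported methods:
#'   `print`, `summary`, `coef`, `plot`, `residuals`, `predict`.
#' @examples
#' models <- default_shift_models()
#' prot <- simulate_protein(60, seed = 7)
#' sim <- simulate_spin_systems(prot$sequence, prot$ss, models,
#'                              true_offset = 1.4, seed = 7)
#' fit <- refcorr(sim$pairs, prot$sequence, prot$ss, models,
#'                prior = identity_prior())
#' coef(fit)
#' @export
refcorr <- function(pairs, sequence, ss, models = default_shift_models(),
                    prior = NULL, optimizer = c("grid", "de"),
                    search = c(-5, 5), seed = 1L,
                    variant = attr(models, "variant")) {
  optimizer <- match.arg(optimizer)
  cl <- match.call()
  if (inherits(pairs, "spin_pairs_sim")) pairs <- pairs$pairs
  pairs <- as.matrix(pairs)
  if (is.null(prior)) prior <- default_overlap_prior(models, seed = seed)

  if (optimizer == "grid") {
    res <- grid_search_correction(pairs, sequence, ss, models, prior,
                                  search = search, variant = variant)
  } else {
    engine <- build_engine(models, variant)
    yhat <- apply_prior(sequence_composition(sequence, ss), prior)
    obj <- function(c0) {
      comp <- composition_grid(engine, pairs, c0)
      sum(prior$weights * abs(drop(comp) - yhat))
    }
    fit <- de_optimize(obj, search[1], search[2], seed = seed)
    cand <- seq(search[1], search[2], length.out = 100)
    res <- list(m1 = fit$par, m2 = fit$par, final_residual = fit$value,
                curve = data.frame(candidate = cand,
                                   residual = vapply(cand, obj, numeric(1)),
                                   round = 1L),
                completeness = nrow(pairs) /
                  sum(strsplit(sequence, "")[[1]] != "G"),
                method = "de")
  }
  new_refcorr(res, pairs = pairs, sequence = sequence, ss = ss,
              variant = variant, seed = seed, call = cl,
              mode = "unassigned")
}

#' Fit a carbon-13 reference correction to assigned shifts
#'
#' The assigned-mode estimator: every table row is scored only against its
#' own (residue type, secondary structure) class model, and the mean
#' chi-square objective is minimized by seeded differential evolution.
#' See [assigned_correction()] for the objective.
#'
#' @param table assigned-shift data.frame (see [read_assigned_table()]).
#' @param models a `shift_models` table.
#' @param bounds search interval (ppm).
#' @param seed integer seed for the optimizer.
#' @param variant covariance variant.
#' @param ... passed to [assigned_correction()].
#' @return an object of class `refcorr`.
#' @export
refcorr_assigned <- function(table, models = default_shift_models(),
                             bounds = c(-10, 10), seed = 1L,
                             variant = attr(models, "variant"), ...) {
  cl <- match.call()
  res <- assigned_correction(table, models, bounds = bounds, seed = seed,
                             variant = variant, ...)
  new_refcorr(res, pairs = NULL, sequence = NULL, ss = NULL,
              variant = variant, seed = seed, call = cl, mode = "assigned",
              table = table)
}

new_refcorr <- function(res, pairs, sequence, ss, variant, seed, call,
                        mode, table = NULL) {
  structure(list(correction = res$m2, m1 = res$m1,
                 final_residual = res$final_residual, curve = res$curve,
                 optimizer = res$method, completeness = res$completeness,
                 mode = mode, variant = variant, seed = seed,
                 pairs = pairs, table = table, sequence = sequence,
                 ss = ss, call = call),
            class = "refcorr")
}

#' @export
print.refcorr <- function(x, ...) {
  cat("13C reference correction (", x$mode, ", ", x$optimizer, ")\n",
      sep = "")
  cat("  correction:", sprintf("%+.3f ppm", x$correction),
      " (round 1:", sprintf("%+.3f", x$m1), ")\n")
  cat("  final residual:", format(x$final_residual, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.refcorr <- function(object, ...) {
  print(object)
  n <- if (!is.null(object$pairs)) nrow(object$pairs)
       else nrow(object$table)
  cat("  spin systems / rows:", n, "\n")
  if (!is.null(object$completeness) && is.finite(object$completeness))
    cat("  completeness:", sprintf("%.0f%%", 100 * object$completeness),
        "\n")
  cat("  model variant:", object$variant, "  seed:", object$seed, "\n")
  invisible(object)
}

#' @export
coef.refcorr <- function(object, ...) {
  c(correction = object$correction)
}

#' Residual curve of a fitted correction
#'
#' @param object a `refcorr` fit.
#' @param ... unused.
#' @return the data.frame of (candidate, residual, round) points the
#'   optimizer evaluated.
#' @export
residuals.refcorr <- function(object, ...) object$curve

#' Correct chemical shifts with a fitted reference correction
#'
#' Applies `corrected = observed - correction` to carbon shifts.
#'
#' @param object a `refcorr` fit.
#' @param newdata numeric vector/matrix of carbon shifts, a peak
#'   data.frame with a `c` column, or an assigned table with
#'   `ca_shift`/`cb_shift` columns; defaults to the data the fit was made
#'   from.
#' @param ... unused.
#' @return the input with every carbon shift reduced by the correction.
#' @export
predict.refcorr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- if (!is.null(object$pairs)) object$pairs else object$table
  m2 <- object$correction
  if (is.data.frame(newdata) && "c" %in% names(newdata)) {
    newdata$c <- newdata$c - m2
  } else if (is.data.frame(newdata) && "ca_shift" %in% names(newdata)) {
    newdata$ca_shift <- newdata$ca_shift - m2
    newdata$cb_shift <- newdata$cb_shift - m2
  } else {
    newdata <- newdata - m2
  }
  newdata
}

#' Plot the residual curve of a fitted correction
#'
#' Residual versus candidate correction for each optimizer round, with
#' the selected correction marked.
#'
#' @param x a `refcorr` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.refcorr <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$candidate, cv$residual, col = cv$round, pch = 20,
                 xlab = "candidate correction (ppm)",
                 ylab = "weighted composition residual", ...)
  graphics::abline(v = x$correction, lty = 2)
  graphics::legend("topright", legend = c("round 1", "round 2", "M2"),
                   col = c(1, 2, 1), pch = c(20, 20, NA),
                   lty = c(NA, NA, 2), bty = "n")
  invisible(x)
}
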