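# Prediction-overlap matrix and classifier weights: the Bayesian prior
# that maps a true residue-type composition into the composition the
# chi-square classifier is expected to report.

new_overlap_prior <- function(omega, weights, gly = NULL) {
  structure(list(omega = omega, weights = weights, gly = gly),
            class = "overlap_prior")
}

#' Prediction-overlap matrix and weights from a corpus
#'
#' For every corpus record of known class t, the record's normalized
#' 57-class probability vector (see [class_probabilities()]) is computed;
#' row t of the overlap matrix is the average of these vectors over the
#' class-t records, renormalized to sum 1. Rows index the true class,
#' columns the predicted class, so a true composition Y maps to the
#' expected predicted composition Y %*% omega, and mass is conserved. The
#' diagonal entries are the classifier weights: classes whose models
#' overlap little with others keep their mass and get weight near 1.
#' Cysteine oxidation states are pooled into the single cysteine
#' composition class per secondary structure. Records are scored with the
#' same unordered-pair handling the correction engine uses, so that
#' compositions estimated by the engine are directly comparable with
#' Y %*% omega.
#'
#' @param corpus assigned-shift records (`amino_acid`,
#'   `secondary_structure`, `ca_shift`, `cb_shift`); glycine rows feed the
#'   optional 3x3 glycine block only.
#' @param models a `shift_models` table.
#' @param include_glycine also build the 3x3 glycine-class overlap block
#'   (disabled by default; the correction engine ignores glycine).
#' @param ordered score corpus pairs as ordered (Ca, Cb) pairs instead of
#'   the engine's unordered convention.
#' @param variant covariance variant.
#' @return an `overlap_prior`: `omega` (57x57 row-stochastic matrix),
#'   `weights` (its diagonal), and optionally `gly` (3x3 block plus
#'   weights).
#' @export
overlap_prior <- function(corpus, models, include_glycine = FALSE,
                          ordered = FALSE,
                          variant = attr(models, "variant")) {
  engine <- build_engine(models, variant)
  comp <- engine$comp
  ok <- corpus$amino_acid != "G" &
    is.finite(corpus$ca_shift) & is.finite(corpus$cb_shift)
  rec <- corpus[ok, , drop = FALSE]
  true_class <- class_label(merge_cys(rec$amino_acid),
                            rec$secondary_structure)
  missing <- setdiff(comp, unique(true_class))
  if (length(missing))
    stop("corpus has no records for class(es): ",
         paste(missing, collapse = ", "))
  pm <- prob_matrix(engine, rec$ca_shift, rec$cb_shift, ordered = ordered)
  rs <- rowSums(pm)
  keep <- rs > 0
  pm <- pm[keep, , drop = FALSE] / rs[keep]
  fac <- factor(true_class[keep], levels = comp)
  omega <- rowsum(pm, fac) / as.numeric(table(fac))
  omega <- omega / rowSums(omega)
  dimnames(omega) <- list(comp, comp)

  gly <- NULL
  if (include_glycine) {
    g <- corpus[corpus$amino_acid == "G" & is.finite(corpus$ca_shift), ,
                drop = FALSE]
    gm <- engine$gly
    if (nrow(g) && nrow(gm) == 3) {
      p <- vapply(seq_len(3), function(j)
        exp(-((g$ca_shift - gm$mu_ca[j]) / gm$sd_ca[j])^2 / 2),
        numeric(nrow(g)))
      p <- p / rowSums(p)
      fg <- factor(g$secondary_structure, levels = gm$ss)
      og <- rowsum(p, fg) / as.numeric(table(fg))
      og <- og / rowSums(og)
      dimnames(og) <- list(class_label("G", gm$ss), class_label("G", gm$ss))
      gly <- list(omega = og, weights = diag(og))
    }
  }
  new_overlap_prior(omega, stats::setNames(diag(omega), comp), gly)
}

#' Identity overlap prior
#'
#' The no-prior ablation: identity overlap matrix and unit weights, under
#' which the residual compares the estimated composition directly with
#' the raw sequence composition.
#'
#' @return an `overlap_prior`.
#' @export
identity_prior <- function() {
  comp <- composition_classes()
  omega <- diag(57)
  dimnames(omega) <- list(comp, comp)
  new_overlap_prior(omega, stats::setNames(rep(1, 57), comp))
}

#' Default overlap prior simulated from a model set
#'
#' Builds the prediction-overlap prior by simulating a balanced corpus
#' from the class models themselves and calling [overlap_prior()]. This is
#' the package's self-consistent default when no external corpus is
#' available.
#'
#' @param models a `shift_models` table.
#' @param n_per_class simulated records per class.
#' @param seed integer seed.
#' @param ... passed to [overlap_prior()].
#' @return an `overlap_prior`.
#' @export
default_overlap_prior <- function(models, n_per_class = 200, seed = 97L,
                                  ...) {
  sim <- simulate_corpus(models, n_per_class = n_per_class, seed = seed)
  overlap_prior(sim$corpus, models, ...)
}

#' Classifier weights of an overlap prior
#'
#' @param prior an `overlap_prior`.
#' @return the 57 diagonal entries of the overlap matrix, unmodified.
#' @export
classifier_weights <- function(prior) prior$weights

#' Apply the overlap prior to a composition vector
#'
#' Computes \eqn{\hat{Y}' = Y \Omega}; for a row-stochastic overlap matrix
#' the total mass is conserved, so a normalized composition stays
#' normalized.
#'
#' @param y composition vector of length 57.
#' @param prior an `overlap_prior`.
#' @return composition vector of length 57.
#' @export
apply_prior <- function(y, prior) {
  if (length(y) != nrow(prior$omega))
    stop("composition vector has length ", length(y), ", expected ",
         nrow(prior$omega))
  drop(y %*% prior$omega)
}

#' @export
print.overlap_prior <- function(x, ...) {
  cat("Prediction-overlap prior: ", nrow(x$omega), "x", ncol(x$omega),
      " matrix\n", sep = "")
  cat("  diagonal weights: min ", round(min(x$weights), 3), ", median ",
      round(stats::median(x$weights), 3), ", max ",
      round(max(x$weights), 3), "\n", sep = "")
  if (!is.null(x$gly)) cat("  glycine 3x3 block present\n")
  invisible(x)
}
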