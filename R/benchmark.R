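# Simulation harness for measuring correction accuracy under controlled
# conditions: random proteins, model-drawn spin systems, known offsets.

#' Benchmark correction accuracy on simulated datasets
#'
#' Runs the robustness experiment: for each of `n_datasets` replicates a
#' random protein is simulated, spin systems (or an assigned table) are
#' drawn from `truth_models` with a true offset uniform on
#' `offset_range`, optionally thinned, and the requested estimator is run
#' with `fit_models`/`prior`. Replicate `i` uses seed
#' `(seed - 1) * 10000 + i`, so the base seed indexes disjoint seed
#' blocks.
#'
#' @param truth_models generating `shift_models` table.
#' @param fit_models `shift_models` table given to the estimator
#'   (defaults to `truth_models`).
#' @param prior `overlap_prior` for the unassigned estimator; `NULL`
#'   simulates the default prior once from `fit_models`.
#' @param mode `"unassigned"` (two-round grid search) or `"assigned"`
#'   (differential evolution on the per-row chi-square objective).
#' @param n_datasets number of replicates.
#' @param length protein length (residues).
#' @param offset_range range the true offsets are drawn from (ppm).
#' @param missing_fraction fraction of spin systems dropped per dataset.
#' @param seed base seed.
#' @return data.frame with one row per replicate: `dataset`, `seed`,
#'   `true_offset`, `estimate`, `error`.
#' @export
correction_benchmark <- function(truth_models, fit_models = truth_models,
                                 prior = NULL,
                                 mode = c("unassigned", "assigned"),
                                 n_datasets = 100, length = 120,
                                 offset_range = c(-3, 3),
                                 missing_fraction = 0, seed = 1L) {
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  if (mode == "unassigned" && is.null(prior))
    prior <- default_overlap_prior(fit_models, seed = seed)
  out <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    seed_i <- (seed - 1L) * 10000L + i
    prot <- simulate_protein(length, seed = seed_i)
    off <- with_seed(seed_i, stats::runif(1, offset_range[1],
                                          offset_range[2]))
    if (mode == "unassigned") {
      d <- simulate_spin_systems(prot$sequence, prot$ss, truth_models,
                                 true_offset = off,
                                 missing_fraction = missing_fraction,
                                 seed = seed_i)
      fit <- suppressWarnings(
        refcorr(d$pairs, prot$sequence, prot$ss, fit_models, prior,
                seed = seed_i))
    } else {
      d <- simulate_assigned_table(prot$sequence, prot$ss, truth_models,
                                   true_offset = off,
                                   missing_fraction = missing_fraction,
                                   seed = seed_i)
      fit <- refcorr_assigned(d$table, fit_models, seed = seed_i)
    }
    out[[i]] <- data.frame(dataset = i, seed = seed_i, true_offset = off,
                           estimate = coef(fit)[["correction"]])
  }
  res <- do.call(rbind, out)
  res$error <- res$estimate - res$true_offset
  res
}
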