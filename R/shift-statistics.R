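# Per-class bivariate statistics, covariance-matrix variants, cysteine
# oxidation-state splitting and the RMSD/Q-statistic covariance refinement.

#' Sample statistics of one chemical-shift class
#'
#' Means, standard deviations and the Ca/Cb covariance of one
#' (residue type, secondary structure) class, with n-1 denominators
#' throughout. Glycine classes pass `cb = NULL` and get univariate
#' statistics.
#'
#' @param ca numeric vector of alpha-carbon shifts (ppm).
#' @param cb numeric vector of beta-carbon shifts (ppm), or `NULL` for a
#'   Ca-only (glycine) class.
#' @return list with `mu_ca`, `mu_cb`, `sd_ca`, `sd_cb`, `cov`, `n`
#'   (`NA` for the Cb fields of a univariate class).
#' @examples
#' class_statistics(c(70, 72), c(30, 32))  # mu (71, 31), sd 1.414, cov 2
#' @export
class_statistics <- function(ca, cb = NULL) {
  if (!is.null(cb)) {
    keep <- is.finite(ca) & is.finite(cb)
    ca <- ca[keep]; cb <- cb[keep]
  } else ca <- ca[is.finite(ca)]
  n <- length(ca)
  if (n < 2)
    stop("insufficient data: need at least 2 complete observations, got ", n)
  if (is.null(cb))
    return(list(mu_ca = mean(ca), mu_cb = NA_real_, sd_ca = stats::sd(ca),
                sd_cb = NA_real_, cov = NA_real_, n = n))
  list(mu_ca = mean(ca), mu_cb = mean(cb),
       sd_ca = stats::sd(ca), sd_cb = stats::sd(cb),
       cov = stats::cov(ca, cb), n = n)
}

#' Assemble the 2x2 covariance matrix of a class under a model variant
#'
#' The five variants differ in whether variances and covariances are
#' secondary-structure specific and whether the off-diagonal is used at
#' all: variant A uses variances pooled across secondary structures and a
#' zero off-diagonal; B uses SS-specific variances, zero off-diagonal;
#' C pools both variances and the covariance across SS; D uses SS-specific
#' variances with the off-diagonal set to the plain mean of the three
#' SS-specific covariances; E (and E_revised, which differs only in how
#' the stored covariances were refined) uses the SS-specific variances and
#' covariance directly. Pooled statistics are weighted by class sample
#' sizes (n - 1 weights).
#'
#' @param models a `shift_models` table.
#' @param aa model residue class (e.g. `"A"`, `"C_ox"`); glycine is
#'   univariate and is rejected.
#' @param ss secondary structure, one of `"H"`, `"E"`, `"C"`.
#' @param variant one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"E_revised"`;
#'   defaults to the variant tag of `models`.
#' @return symmetric 2x2 covariance matrix (ppm^2).
#' @export
class_covariance <- function(models, aa, ss,
                             variant = attr(models, "variant")) {
  variant <- match.arg(variant, c("A", "B", "C", "D", "E", "E_revised"))
  if (aa == "G")
    stop("glycine has no bivariate model; no 2x2 covariance matrix exists")
  m <- get_model(models, aa, ss)
  all_ss <- models[models$aa == aa, ]
  w <- pmax(all_ss$n - 1, 1)
  pooled_var_ca <- sum(w * all_ss$sd_ca^2) / sum(w)
  pooled_var_cb <- sum(w * all_ss$sd_cb^2) / sum(w)
  pooled_cov <- sum(w * all_ss$cov) / sum(w)
  mean_cov <- mean(all_ss$cov)
  sig <- switch(variant,
    A = matrix(c(pooled_var_ca, 0, 0, pooled_var_cb), 2),
    B = matrix(c(m$sd_ca^2, 0, 0, m$sd_cb^2), 2),
    C = matrix(c(pooled_var_ca, pooled_cov, pooled_cov, pooled_var_cb), 2),
    D = matrix(c(m$sd_ca^2, mean_cov, mean_cov, m$sd_cb^2), 2),
    matrix(c(m$sd_ca^2, m$cov, m$cov, m$sd_cb^2), 2))  # E, E_revised
  dimnames(sig) <- list(c("ca", "cb"), c("ca", "cb"))
  sig
}

#' Split cysteine records into oxidation states by K-means
#'
#' Disulfide-bonded (oxidized) and free-thiol (reduced) cysteines have
#' widely separated Cb shifts (roughly 41 vs 28 ppm), so a single bivariate
#' Gaussian fits cysteine poorly. K-means with K = 2 on the raw (Ca, Cb)
#' ppm values, 10 restarts, separates the two modes; the cluster with the
#' larger mean Cb is labelled oxidized.
#'
#' @param ca,cb numeric vectors of cysteine shifts for one secondary
#'   structure.
#' @param seed integer seed for the restart sequence (restored afterwards).
#' @return character vector over `"oxidized"`/`"reduced"`, one per point.
#' @export
split_cysteine_states <- function(ca, cb, seed = 1L) {
  pts <- cbind(ca, cb)
  if (nrow(unique(pts)) < 2)
    stop("degenerate cysteine cluster: all (Ca, Cb) points identical")
  km <- with_seed(seed, stats::kmeans(pts, centers = 2, nstart = 10))
  ox_cluster <- which.max(km$centers[, 2])
  ifelse(km$cluster == ox_cluster, "oxidized", "reduced")
}

#' RMSD-comparison Q statistic
#'
#' Compares the alpha- and beta-carbon RMSDs (between predicted and
#' observed shifts) of one corpus entry:
#' \eqn{Q = (|r_a - r_b| / (|r_a| + |r_b|))^{1/3}}. Small Q means the two
#' RMSDs agree, the signature of shifts measured in a single experiment;
#' the cube root symmetrizes the otherwise highly skewed ratio. Q is
#' scale-invariant and symmetric in its arguments, and lies in [0, 1].
#'
#' @param rmsd_ca,rmsd_cb non-negative RMSDs (ppm); vectorized.
#' @return numeric vector of Q values in [0, 1].
#' @examples
#' q_statistic(0.3, 0.1)  # (0.2/0.4)^(1/3)
#' @export
q_statistic <- function(rmsd_ca, rmsd_cb) {
  if (any(rmsd_ca < 0) || any(rmsd_cb < 0))
    stop("RMSD values must be non-negative")
  s <- abs(rmsd_ca) + abs(rmsd_cb)
  if (any(s == 0))
    stop("Q is undefined when both RMSDs are zero")
  (abs(rmsd_ca - rmsd_cb) / s)^(1 / 3)
}

# two-sample test for equality of correlations via Fisher's r-to-z
fisher_r_test <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) return(1)
  r1 <- min(max(r1, -0.999999), 0.999999)
  r2 <- min(max(r2, -0.999999), 0.999999)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

#' Select corpus entries for covariance refinement by Q-statistic scan
#'
#' Entries whose Ca and Cb shifts come from different spectra carry weak
#' or destroyed Ca/Cb correlation; their per-entry Q statistics tend to be
#' large. The scan sorts entries by Q, tries every observed Q value as a
#' cutoff, splits entries into a low-Q and a high-Q group, computes the
#' correlation between Ca and Cb deviations (from class means) pooled
#' within each group, and tests the two correlations for difference with
#' a Fisher r-to-z two-sample test. The cutoff with the smallest p-value
#' wins and the low-Q group is selected for covariance re-estimation.
#'
#' @param qualities data.frame with columns `entry_id`, `rmsd_ca`,
#'   `rmsd_cb` (one row per entry).
#' @param deviations named list (by `entry_id`) of two-column matrices of
#'   paired (Ca, Cb) deviations from class means.
#' @param min_group minimum number of entries allowed in either group;
#'   candidate cutoffs violating it are skipped. If no admissible split
#'   exists all entries are selected with `p_value = 1`.
#' @param alpha significance gate: when even the best split's p-value is
#'   not below `alpha` there is no evidence of a decorrelated subgroup
#'   and all entries are kept.
#' @return list of class `q_selection` with `q_cutoff`, `r_selected`,
#'   `r_rejected`, `p_value`, `selected` (entry ids) and the per-entry
#'   `q` values.
#' @export
select_entries_by_q <- function(qualities, deviations, min_group = 10,
                                alpha = 0.01) {
  stopifnot(all(c("entry_id", "rmsd_ca", "rmsd_cb") %in% names(qualities)))
  q <- q_statistic(qualities$rmsd_ca, qualities$rmsd_cb)
  ids <- as.character(qualities$entry_id)
  deviations <- deviations[ids]
  ord <- order(q, ids)           # deterministic, input-order independent
  q <- q[ord]; ids <- ids[ord]; deviations <- deviations[ord]
  n_entries <- length(ids)

  pooled_cor <- function(mats) {
    d <- do.call(rbind, mats)
    if (nrow(d) < 4) return(list(r = 0, n = nrow(d)))
    list(r = stats::cor(d[, 1], d[, 2]), n = nrow(d))
  }

  best <- list(p = Inf, cut = NA_real_, k = NA_integer_,
               r1 = NA_real_, r2 = NA_real_)
  for (k in seq_len(n_entries - 1)) {
    # cutoff at the k-th sorted Q: low group = entries 1..k
    if (k < min_group || (n_entries - k) < min_group) next
    if (k < n_entries && q[k] == q[k + 1]) next  # not a valid boundary
    lo <- pooled_cor(deviations[seq_len(k)])
    hi <- pooled_cor(deviations[(k + 1):n_entries])
    p <- fisher_r_test(lo$r, lo$n, hi$r, hi$n)
    if (p < best$p) best <- list(p = p, cut = q[k], k = k,
                                 r1 = lo$r, r2 = hi$r)
  }

  if (!is.finite(best$p) || is.na(best$cut) || best$p >= alpha) {
    all_cor <- pooled_cor(deviations)
    res <- list(q_cutoff = max(q), r_selected = all_cor$r,
                r_rejected = NA_real_,
                p_value = if (is.finite(best$p)) best$p else 1,
                selected = ids, q = stats::setNames(q, ids))
  } else {
    res <- list(q_cutoff = best$cut, r_selected = best$r1,
                r_rejected = best$r2, p_value = best$p,
                selected = ids[seq_len(best$k)],
                q = stats::setNames(q, ids))
  }
  class(res) <- "q_selection"
  res
}

#' @export
print.q_selection <- function(x, ...) {
  cat("Q-statistic entry selection\n")
  cat("  cutoff Q :", format(x$q_cutoff, digits = 4), "\n")
  cat("  selected :", length(x$selected), "of", length(x$q), "entries\n")
  cat("  r (selected / rejected):", format(x$r_selected, digits = 3), "/",
      format(x$r_rejected, digits = 3), "  p =",
      format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Fit the full set of class models from an assigned-shift corpus
#'
#' Pipeline: split cysteines into oxidation states per secondary structure
#' (K-means, unless the corpus already carries a `cys_state` column),
#' group records by (residue class, secondary structure), and compute
#' per-class means, standard deviations and covariances (n-1 denominators).
#' For `variant = "E_revised"` the covariances (only) are then re-estimated
#' from the subset of corpus entries selected by the Q-statistic scan
#' ([select_entries_by_q()]), which discards entries whose Ca/Cb pairing
#' looks decorrelated.
#'
#' @param corpus data.frame with columns `entry_id`, `residue_index`,
#'   `amino_acid` (one-letter), `secondary_structure` (H/E/C), `ca_shift`,
#'   `cb_shift` (NA allowed; always NA for glycine); optionally `cys_state`
#'   (`"oxidized"`/`"reduced"`).
#' @param variant covariance variant tag stored on the result; see
#'   [class_covariance()].
#' @param qualities per-entry RMSD table (columns `entry_id`, `rmsd_ca`,
#'   `rmsd_cb`); required for `variant = "E_revised"`.
#' @param min_group passed to [select_entries_by_q()].
#' @param seed seed for the cysteine K-means restarts.
#' @return a `shift_models` table covering all 63 class keys; for
#'   E_revised the selection report is attached as attribute `selection`.
#' @export
fit_shift_models <- function(corpus, variant = "E", qualities = NULL,
                             min_group = 10, seed = 1L) {
  variant <- match.arg(variant, c("A", "B", "C", "D", "E", "E_revised"))
  need <- c("amino_acid", "secondary_structure", "ca_shift", "cb_shift")
  stopifnot(all(need %in% names(corpus)))
  if (!"entry_id" %in% names(corpus)) corpus$entry_id <- "entry1"

  corpus$model_aa <- as.character(corpus$amino_acid)
  cys <- corpus$model_aa == "C"
  if (any(cys)) {
    if ("cys_state" %in% names(corpus) &&
        !anyNA(corpus$cys_state[cys])) {
      st <- corpus$cys_state[cys]
    } else {
      st <- rep(NA_character_, sum(cys))
      for (s in SS_TYPES) {
        in_ss <- corpus$secondary_structure[cys] == s
        if (!any(in_ss)) next
        st[in_ss] <- split_cysteine_states(
          corpus$ca_shift[cys][in_ss], corpus$cb_shift[cys][in_ss],
          seed = seed)
      }
    }
    corpus$model_aa[cys] <- ifelse(st == "oxidized", "C_ox", "C_red")
  }

  keys <- model_keys(include_glycine = TRUE)
  complete <- ifelse(corpus$model_aa == "G",
                     is.finite(corpus$ca_shift),
                     is.finite(corpus$ca_shift) & is.finite(corpus$cb_shift))
  counts <- mapply(function(a, s)
    sum(corpus$model_aa == a & corpus$secondary_structure == s & complete),
    keys$aa, keys$ss)
  if (any(counts < 2))
    stop("missing or underpopulated class(es): ",
         paste(class_label(keys$aa, keys$ss)[counts < 2], collapse = ", "))

  rows <- lapply(seq_len(nrow(keys)), function(i) {
    aa <- keys$aa[i]; ss <- keys$ss[i]
    sel <- corpus$model_aa == aa & corpus$secondary_structure == ss & complete
    st <- if (aa == "G") class_statistics(corpus$ca_shift[sel])
          else class_statistics(corpus$ca_shift[sel], corpus$cb_shift[sel])
    data.frame(aa = aa, ss = ss, mu_ca = st$mu_ca, mu_cb = st$mu_cb,
               sd_ca = st$sd_ca, sd_cb = st$sd_cb, cov = st$cov, n = st$n)
  })
  models <- new_shift_models(do.call(rbind, rows), variant)

  if (variant == "E_revised") {
    if (is.null(qualities))
      stop("variant E_revised requires per-entry `qualities` (RMSDs)")
    usable <- complete & corpus$model_aa != "G"
    key_of <- class_label(corpus$model_aa, corpus$secondary_structure)
    dev_ca <- corpus$ca_shift - models[key_of, "mu_ca"]
    dev_cb <- corpus$cb_shift - models[key_of, "mu_cb"]
    deviations <- lapply(split(which(usable), corpus$entry_id[usable]),
                         function(i) cbind(dev_ca[i], dev_cb[i]))
    qualities <- qualities[as.character(qualities$entry_id) %in%
                             names(deviations), , drop = FALSE]
    selection <- select_entries_by_q(qualities, deviations,
                                     min_group = min_group)
    in_sel <- corpus$entry_id %in% selection$selected
    for (i in which(models$aa != "G")) {
      sel <- corpus$model_aa == models$aa[i] &
        corpus$secondary_structure == models$ss[i] & complete & in_sel
      if (sum(sel) >= 2)
        models$cov[i] <- stats::cov(corpus$ca_shift[sel],
                                    corpus$cb_shift[sel])
    }
    attr(models, "selection") <- selection
  }
  models
}
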