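# Synthetic-data generators: assigned-shift corpora with controllable
# entry quality, unassigned spin-system datasets with a known reference
# offset, and 3D HN(CO)CACB-style peak lists with amide-root jitter.
# All generators are pure functions of their arguments and seed.

# one bivariate-normal draw matrix (n x 2) for a model row
draw_class <- function(m, n, decorrelate = FALSE) {
  if (m$aa == "G") return(cbind(stats::rnorm(n, m$mu_ca, m$sd_ca), NA_real_))
  cv <- if (decorrelate) 0 else m$cov
  sig <- matrix(c(m$sd_ca^2, cv, cv, m$sd_cb^2), 2)
  z <- matrix(stats::rnorm(2 * n), n, 2)
  sweep(z %*% chol(sig), 2, c(m$mu_ca, m$mu_cb), "+")
}

#' Simulate a random protein (sequence plus secondary structure)
#'
#' Residues are drawn uniformly over the 20 standard amino acids and the
#' per-residue secondary structure uniformly over H/E/C, the composition
#' used throughout the package's simulation studies.
#'
#' @param length number of residues.
#' @param seed integer seed.
#' @return list with `sequence` and `ss` strings.
#' @export
simulate_protein <- function(length, seed = 1L) {
  with_seed(seed, {
    list(sequence = paste(sample(AA_STANDARD, length, replace = TRUE),
                          collapse = ""),
         ss = paste(sample(SS_TYPES, length, replace = TRUE), collapse = ""))
  })
}

#' Simulate an assigned-shift corpus with entry-quality structure
#'
#' Draws `n_per_class` records from every class model and distributes them
#' over `n_entries` synthetic corpus entries. A fraction of entries can be
#' marked low-quality: their records are drawn with the Ca/Cb covariance
#' zeroed (emulating shifts assembled from separate spectra) and their
#' fabricated per-entry RMSD pair gives a large Q statistic, so the
#' Q-statistic selection scan has a recoverable signal.
#'
#' @param models generating `shift_models` table.
#' @param n_per_class records drawn per class (>= 2).
#' @param seed integer seed.
#' @param n_entries number of synthetic entries.
#' @param frac_decorrelated fraction of entries drawn with zero Ca/Cb
#'   covariance.
#' @param q_good,q_bad ranges the per-entry Q values are drawn from for
#'   correlated and decorrelated entries.
#' @return list with `corpus` (ShiftRecord data.frame, including the true
#'   `cys_state` and a `decorrelated` flag) and `qualities` (`entry_id`,
#'   `rmsd_ca`, `rmsd_cb`).
#' @export
simulate_corpus <- function(models, n_per_class = 100, seed = 1L,
                            n_entries = 40, frac_decorrelated = 0,
                            q_good = c(0.05, 0.25), q_bad = c(0.35, 0.8)) {
  stopifnot(n_per_class >= 2)
  with_seed(seed, {
    n_bad <- round(frac_decorrelated * n_entries)
    entry_ids <- sprintf("syn%03d", seq_len(n_entries))
    entry_bad <- seq_len(n_entries) <= n_bad  # ids are synthetic; no bias
    q_of <- ifelse(entry_bad,
                   stats::runif(n_entries, q_bad[1], q_bad[2]),
                   stats::runif(n_entries, q_good[1], q_good[2]))
    # invert Q = (d/s)^(1/3) at total RMSD s to fabricate the two RMSDs
    s <- stats::runif(n_entries, 0.4, 0.8)
    d <- s * q_of^3
    qualities <- data.frame(entry_id = entry_ids,
                            rmsd_ca = (s + d) / 2, rmsd_cb = (s - d) / 2)
    recs <- lapply(seq_len(nrow(models)), function(i) {
      m <- models[i, ]
      entry <- sample(entry_ids, n_per_class, replace = TRUE)
      bad <- entry_bad[match(entry, entry_ids)]
      x <- matrix(NA_real_, n_per_class, 2)
      if (any(!bad)) x[!bad, ] <- draw_class(m, sum(!bad))
      if (any(bad)) x[bad, ] <- draw_class(m, sum(bad), decorrelate = TRUE)
      data.frame(entry_id = entry,
                 residue_index = seq_len(n_per_class),
                 amino_acid = merge_cys(m$aa),
                 secondary_structure = m$ss,
                 ca_shift = x[, 1], cb_shift = x[, 2],
                 cys_state = if (m$aa == "C_ox") "oxidized"
                             else if (m$aa == "C_red") "reduced"
                             else NA_character_,
                 decorrelated = bad)
    })
    list(corpus = do.call(rbind, recs), qualities = qualities)
  })
}

#' Simulate an unassigned spin-system dataset with a known offset
#'
#' For every non-glycine residue of the protein, draws a (Ca, Cb) pair
#' from its (residue type, secondary structure) class model (cysteines
#' pick an oxidation state at random), adds the global reference offset
#' `true_offset` to both carbons, randomly drops a fraction of the spin
#' systems, and randomizes the within-pair order (the pairs are unordered,
#' as produced by peak grouping).
#'
#' @param sequence,ss protein sequence and H/E/C string of equal length.
#' @param models generating `shift_models` table.
#' @param true_offset reference error added to every carbon (ppm).
#' @param missing_fraction fraction of spin systems dropped (in [0, 1)).
#' @param seed integer seed.
#' @return list of class `spin_pairs_sim`: `pairs` (two-column matrix
#'   `shift_a`/`shift_b`), `sequence`, `ss`, `true_offset`,
#'   `truth` (residue index, model class and SS per retained pair).
#' @export
simulate_spin_systems <- function(sequence, ss, models, true_offset = 0,
                                  missing_fraction = 0, seed = 1L) {
  v <- validate_sequence(sequence, ss)
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  with_seed(seed, {
    idx <- which(v$seq != "G")
    aa <- v$seq[idx]
    cys <- aa == "C"
    if (any(cys))
      aa[cys] <- sample(c("C_ox", "C_red"), sum(cys), replace = TRUE)
    x <- t(vapply(seq_along(idx), function(i) {
      draw_class(get_model(models, aa[i], v$ss[idx[i]]), 1)[1, ]
    }, numeric(2)))
    x <- x + true_offset
    n_drop <- ceiling(missing_fraction * nrow(x))
    keep <- seq_len(nrow(x))
    if (n_drop > 0) keep <- sort(sample(keep, nrow(x) - n_drop))
    swap <- stats::runif(length(keep)) < 0.5
    pairs <- cbind(shift_a = ifelse(swap, x[keep, 2], x[keep, 1]),
                   shift_b = ifelse(swap, x[keep, 1], x[keep, 2]))
    structure(list(pairs = pairs, sequence = sequence, ss = ss,
                   true_offset = true_offset,
                   truth = data.frame(residue_index = idx[keep],
                                      aa = aa[keep], ss = v$ss[idx[keep]])),
              class = "spin_pairs_sim")
  })
}

#' Simulate an assigned chemical-shift table with a known offset
#'
#' Same generator as [simulate_spin_systems()] but the residue identity
#' and secondary structure of each retained row are kept, yielding the
#' input of the assigned-mode estimator. Glycine rows carry Ca only.
#'
#' @inheritParams simulate_spin_systems
#' @param include_glycine keep glycine (Ca-only) rows.
#' @return list with `table` (an assigned-shift data.frame), `sequence`,
#'   `ss`, `true_offset`.
#' @export
simulate_assigned_table <- function(sequence, ss, models, true_offset = 0,
                                    missing_fraction = 0, seed = 1L,
                                    include_glycine = TRUE) {
  v <- validate_sequence(sequence, ss)
  with_seed(seed, {
    idx <- seq_along(v$seq)
    if (!include_glycine) idx <- which(v$seq != "G")
    aa <- v$seq[idx]
    model_aa <- aa
    cys <- aa == "C"
    if (any(cys))
      model_aa[cys] <- sample(c("C_ox", "C_red"), sum(cys), replace = TRUE)
    x <- t(vapply(seq_along(idx), function(i) {
      draw_class(get_model(models, model_aa[i], v$ss[idx[i]]), 1)[1, ]
    }, numeric(2)))
    x <- x + true_offset
    x[aa == "G", 2] <- NA_real_
    n_drop <- ceiling(missing_fraction * length(idx))
    keep <- seq_along(idx)
    if (n_drop > 0) keep <- sort(sample(keep, length(idx) - n_drop))
    tab <- data.frame(residue_index = idx[keep], amino_acid = aa[keep],
                      secondary_structure = v$ss[idx[keep]],
                      ca_shift = x[keep, 1], cb_shift = x[keep, 2])
    list(table = tab, sequence = sequence, ss = ss,
         true_offset = true_offset)
  })
}

#' Simulate an HN(CO)CACB-style 3D peak list
#'
#' Each residue gets an amide root drawn uniformly over (7.5-9.5) ppm 1H
#' and (105-130) ppm 15N, rejected until its jitter-normalized distance to
#' every existing root is at least `min_sep`; the residue then emits two
#' peaks (one for glycine) sharing that root with independent per-peak
#' jitter, carrying the residue's Ca and Cb shifts (offset applied).
#'
#' @inheritParams simulate_spin_systems
#' @param h_jitter_sd,n_jitter_sd per-peak root jitter (ppm); defaults are
#'   typical digital resolutions.
#' @param min_sep minimum jitter-normalized distance between amide roots;
#'   the default keeps residues resolvable at the grouping stage's
#'   tolerance inflation and chi-square cutoff, whose linking reach is
#'   roughly 12 normalized units.
#' @return list with `peaks` (data.frame `h`, `n`, `c`, `intensity`,
#'   `line`), `truth` (peak-to-residue map), `sequence`, `ss`,
#'   `true_offset`.
#' @export
simulate_peak_list <- function(sequence, ss, models, true_offset = 0,
                               h_jitter_sd = 0.004, n_jitter_sd = 0.04,
                               min_sep = 20, seed = 1L) {
  v <- validate_sequence(sequence, ss)
  with_seed(seed, {
    nres <- length(v$seq)
    roots <- matrix(NA_real_, nres, 2)
    for (i in seq_len(nres)) {
      repeat {
        cand <- c(stats::runif(1, 7.5, 9.5), stats::runif(1, 105, 130))
        if (i == 1) break
        d <- sqrt(((roots[seq_len(i - 1), 1] - cand[1]) / h_jitter_sd)^2 +
                  ((roots[seq_len(i - 1), 2] - cand[2]) / n_jitter_sd)^2)
        if (min(d, na.rm = TRUE) >= min_sep) break
      }
      roots[i, ] <- cand
    }
    aa <- v$seq
    model_aa <- aa
    cys <- aa == "C"
    if (any(cys))
      model_aa[cys] <- sample(c("C_ox", "C_red"), sum(cys), replace = TRUE)
    rows <- lapply(seq_len(nres), function(i) {
      x <- draw_class(get_model(models, model_aa[i], v$ss[i]), 1)[1, ]
      x <- x + true_offset
      carbons <- if (aa[i] == "G") x[1] else x
      data.frame(residue = i,
                 h = roots[i, 1] + stats::rnorm(length(carbons), 0, h_jitter_sd),
                 n = roots[i, 2] + stats::rnorm(length(carbons), 0, n_jitter_sd),
                 c = carbons)
    })
    pk <- do.call(rbind, rows)
    peaks <- data.frame(h = pk$h, n = pk$n, c = pk$c,
                        intensity = NA_real_, line = seq_len(nrow(pk)))
    list(peaks = peaks,
         truth = data.frame(line = peaks$line, residue = pk$residue),
         sequence = sequence, ss = ss, true_offset = true_offset)
  })
}
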