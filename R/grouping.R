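# Grouping of 3D HN(CO)CACB peaks into spin systems by shared amide
# 1H/15N root: per-dimension match-tolerance estimation from mutual
# nearest neighbours, density-based clustering with a chi-square distance
# cutoff, and an iterative loop that inflates tolerances for leftovers.

#' Estimate per-dimension match tolerances from a peak list
#'
#' Peaks belonging to the same spin system share an amide root and differ
#' only by jitter, so the 1H and 15N distances between mutual nearest
#' neighbours in the (h, n) plane estimate the jitter scale. The tolerance
#' for each dimension is 3 times the median absolute mutual-neighbour
#' distance in that dimension, floored at 0.001 ppm (1H) and 0.01 ppm
#' (15N).
#'
#' @param peaks data.frame with columns `h`, `n` (ppm).
#' @param inflation multiplier on the median intra-pair distance.
#' @return list with `tol_h` and `tol_n` (ppm, strictly positive).
#' @export
estimate_match_tolerances <- function(peaks, inflation = 3) {
  if (nrow(peaks) < 4)
    stop("insufficient peaks: tolerance estimation needs at least 4, got ",
         nrow(peaks))
  d <- as.matrix(stats::dist(cbind(peaks$h, peaks$n)))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  mutual <- which(nn[nn] == seq_along(nn) & seq_along(nn) < nn)
  if (!length(mutual))
    return(list(tol_h = 0.001, tol_n = 0.01))
  i <- mutual; j <- nn[mutual]
  list(tol_h = max(inflation * stats::median(abs(peaks$h[i] - peaks$h[j])),
                   0.001),
       tol_n = max(inflation * stats::median(abs(peaks$n[i] - peaks$n[j])),
                   0.01))
}

#' Cluster peaks into candidate spin systems
#'
#' Density-based clustering in the tolerance-normalized (h, n) plane: two
#' peaks are neighbours when their squared normalized distance
#' \eqn{(\Delta h/tol_h)^2 + (\Delta n/tol_n)^2} is at most `chi2_cutoff`
#' (default 9, a 3-sigma-per-dimension equivalent); clusters are the
#' connected components of the neighbour relation, with minimum cluster
#' size 1 so that glycine singletons survive. Clusters of 3 peaks keep
#' their closest pair as a group and return the extra peak as ungrouped;
#' clusters of 4 or more (coincident amide roots) are flagged ambiguous.
#' Peaks are sorted internally by (h, n, c), making the result invariant
#' under input order.
#'
#' @param peaks data.frame with columns `h`, `n`, `c` and (optionally)
#'   `line`; `line` defaults to the row number.
#' @param tolerances list with `tol_h`, `tol_n` (see
#'   [estimate_match_tolerances()]).
#' @param chi2_cutoff squared normalized distance defining the
#'   neighbourhood.
#' @return list with `groups` (each a list with `lines`, `root_h`,
#'   `root_n`, `carbons`), `ungrouped` and `ambiguous` (vectors of peak
#'   line ids).
#' @export
group_spin_systems <- function(peaks, tolerances, chi2_cutoff = 9) {
  stopifnot(tolerances$tol_h > 0, tolerances$tol_n > 0, chi2_cutoff > 0)
  if (!"line" %in% names(peaks)) peaks$line <- seq_len(nrow(peaks))
  peaks <- peaks[order(peaks$h, peaks$n, peaks$c), , drop = FALSE]
  n <- nrow(peaks)
  hs <- peaks$h / tolerances$tol_h
  ns <- peaks$n / tolerances$tol_n
  d2 <- outer(hs, hs, "-")^2 + outer(ns, ns, "-")^2
  adj <- d2 <= chi2_cutoff

  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      if (comp[k]) next
      comp[k] <- cur
      queue <- c(queue, which(adj[k, ] & comp == 0L))
    }
  }

  groups <- list(); ungrouped <- integer(0); ambiguous <- integer(0)
  make_group <- function(idx) {
    list(lines = peaks$line[idx], root_h = mean(peaks$h[idx]),
         root_n = mean(peaks$n[idx]), carbons = peaks$c[idx])
  }
  for (cid in seq_len(cur)) {
    idx <- which(comp == cid)
    if (length(idx) <= 2) {
      groups[[length(groups) + 1]] <- make_group(idx)
    } else if (length(idx) == 3) {
      dd <- d2[idx, idx]; diag(dd) <- Inf
      best <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      pair <- idx[sort(best)]
      groups[[length(groups) + 1]] <- make_group(pair)
      ungrouped <- c(ungrouped, peaks$line[setdiff(idx, pair)])
    } else {
      ambiguous <- c(ambiguous, peaks$line[idx])
    }
  }
  list(groups = groups, ungrouped = sort(ungrouped),
       ambiguous = sort(ambiguous))
}

#' Iteratively group a peak list into spin systems
#'
#' First pass: tolerance estimation ([estimate_match_tolerances()]) and
#' clustering ([group_spin_systems()]). A singleton after the first pass
#' is either a genuine glycine (one peak per spin system) or one orphan
#' of a pair whose jitter exceeded the tolerances, and the two cannot be
#' told apart locally; later rounds therefore pool the singletons and
#' ungrouped extras, inflate the tolerances (re-estimated on the pool,
#' capped at twice the previous round's values), and accept only
#' mutual-nearest-neighbour pairings within the chi-square cutoff --
#' a stricter rule than first-pass clustering, so well-separated glycines
#' are not forced together. Iteration stops when a round adds no pair,
#' or after `max_iter` rounds; every peak ends in a group of size 1 or 2
#' or flagged ambiguous.
#'
#' @param peaks data.frame with columns `h`, `n`, `c` (a `line` column is
#'   added if absent).
#' @param chi2_cutoff see [group_spin_systems()].
#' @param max_iter maximum grouping rounds.
#' @return list of class `spin_grouping`: `groups`, `ambiguous`,
#'   `tolerances` (first-round estimate), `iterations` (rounds that
#'   changed the grouping).
#' @export
group_peaks <- function(peaks, chi2_cutoff = 9, max_iter = 5) {
  if (!"line" %in% names(peaks)) peaks$line <- seq_len(nrow(peaks))
  tol <- estimate_match_tolerances(peaks)
  res <- group_spin_systems(peaks, tol, chi2_cutoff)
  groups <- res$groups
  ambiguous <- res$ambiguous
  ungrouped <- res$ungrouped
  iterations <- 1L
  cur_tol <- tol

  for (round in seq_len(max_iter - 1)) {
    sizes <- vapply(groups, function(g) length(g$lines), integer(1))
    singles <- which(sizes == 1)
    pool_lines <- c(ungrouped,
                    vapply(groups[singles], function(g) g$lines, numeric(1)))
    if (length(pool_lines) < 2) break
    sub <- peaks[peaks$line %in% pool_lines, , drop = FALSE]
    cur_tol <- list(tol_h = 2 * cur_tol$tol_h, tol_n = 2 * cur_tol$tol_n)
    if (nrow(sub) >= 4) {
      est <- tryCatch(estimate_match_tolerances(sub), error = function(e) NULL)
      if (!is.null(est))
        cur_tol <- list(tol_h = min(est$tol_h, cur_tol$tol_h),
                        tol_n = min(est$tol_n, cur_tol$tol_n))
    }
    # mutual-nearest-neighbour pairing within the inflated cutoff
    hs <- sub$h / cur_tol$tol_h; ns <- sub$n / cur_tol$tol_n
    d2 <- outer(hs, hs, "-")^2 + outer(ns, ns, "-")^2
    diag(d2) <- Inf
    nn <- apply(d2, 1, which.min)
    i <- which(nn[nn] == seq_along(nn) & seq_along(nn) < nn &
                 d2[cbind(seq_along(nn), nn)] <= chi2_cutoff)
    if (!length(i)) break
    iterations <- iterations + 1L
    paired_lines <- sub$line[c(i, nn[i])]
    groups <- groups[!(sizes == 1 & vapply(groups, function(g)
      g$lines[1] %in% paired_lines, logical(1)))]
    ungrouped <- setdiff(ungrouped, paired_lines)
    for (k in i) {
      idx <- c(k, nn[k])
      groups[[length(groups) + 1]] <-
        list(lines = sub$line[idx], root_h = mean(sub$h[idx]),
             root_n = mean(sub$n[idx]), carbons = sub$c[idx])
    }
  }
  # any remaining ungrouped extras stay singleton groups
  if (length(ungrouped))
    for (ln in ungrouped) {
      r <- which(peaks$line == ln)
      groups[[length(groups) + 1]] <-
        list(lines = ln, root_h = peaks$h[r], root_n = peaks$n[r],
             carbons = peaks$c[r])
    }
  structure(list(groups = groups, ambiguous = sort(ambiguous),
                 tolerances = tol, iterations = iterations),
            class = "spin_grouping")
}

#' @export
print.spin_grouping <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$lines), integer(1))
  cat("Spin-system grouping:", length(x$groups), "groups (",
      sum(sizes == 2), "pairs,", sum(sizes == 1), "singletons ) in",
      x$iterations, "iteration(s)\n")
  cat("  tolerances: 1H", format(x$tolerances$tol_h, digits = 3), "ppm, 15N",
      format(x$tolerances$tol_n, digits = 3), "ppm\n")
  if (length(x$ambiguous))
    cat("  ambiguous peaks:", length(x$ambiguous), "\n")
  invisible(x)
}

#' Carbon shift pairs from spin-system groups
#'
#' Two-peak groups become unordered carbon pairs; singleton groups
#' (glycine candidates, which lack a beta carbon) and ambiguous peaks are
#' excluded. The excluded counts are attached as attributes.
#'
#' @param grouping a `spin_grouping` from [group_peaks()].
#' @return two-column matrix (`shift_a`, `shift_b`) with attributes
#'   `n_singletons`, `n_ambiguous` and `roots` (the amide roots of the
#'   retained pairs).
#' @export
spin_systems_to_pairs <- function(grouping) {
  sizes <- vapply(grouping$groups, function(g) length(g$lines), integer(1))
  twos <- grouping$groups[sizes == 2]
  pairs <- if (length(twos))
    t(vapply(twos, function(g) g$carbons, numeric(2)))
  else matrix(numeric(0), 0, 2)
  colnames(pairs) <- c("shift_a", "shift_b")
  roots <- if (length(twos))
    data.frame(root_h = vapply(twos, `[[`, numeric(1), "root_h"),
               root_n = vapply(twos, `[[`, numeric(1), "root_n"))
  else data.frame(root_h = numeric(0), root_n = numeric(0))
  structure(pairs, n_singletons = sum(sizes == 1),
            n_ambiguous = length(grouping$ambiguous), roots = roots)
}
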