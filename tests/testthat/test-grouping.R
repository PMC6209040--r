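# Match-tolerance estimation, spin-system clustering and the iterative
# grouping loop.

# peak list with explicit roots and per-residue jitter scale
make_pairs <- function(n_res, h_sd = 0.004, n_sd = 0.04, wide = NULL,
                       min_sep = 40, seed = 9) {
  set.seed(seed)
  rh <- rn <- numeric(n_res)
  for (i in seq_len(n_res)) {
    repeat {
      ch <- runif(1, 7.5, 9.5); cn <- runif(1, 105, 130)
      if (i == 1 ||
          min(sqrt(((rh[seq_len(i - 1)] - ch) / h_sd)^2 +
                   ((rn[seq_len(i - 1)] - cn) / n_sd)^2)) >= min_sep) break
    }
    rh[i] <- ch; rn[i] <- cn
  }
  w <- rep(1, n_res)
  if (!is.null(wide)) w[sample(n_res, wide)] <- 5
  pk <- do.call(rbind, lapply(seq_len(n_res), function(i) data.frame(
    h = rh[i] + rnorm(2, 0, h_sd * w[i]),
    n = rn[i] + rnorm(2, 0, n_sd * w[i]),
    c = c(55, 30), intensity = NA_real_)))
  pk$line <- seq_len(nrow(pk))
  pk
}

pair_correct <- function(g) {
  sizes <- vapply(g$groups, function(x) length(x$lines), integer(1))
  sum(vapply(g$groups[sizes == 2], function(x) {
    l <- sort(x$lines); l[2] - l[1] == 1 && l[1] %% 2 == 1
  }, logical(1)))
}

test_that("match tolerances track the generating jitter and floor at zero jitter", {
  pk <- make_pairs(100, seed = 3)
  tol <- estimate_match_tolerances(pk)
  # nominal value is 3 x median |pair difference| ~ 2.9 sigma
  expect_gt(tol$tol_h / 0.004, 1.5); expect_lt(tol$tol_h / 0.004, 4)
  expect_gt(tol$tol_n / 0.04, 1.5); expect_lt(tol$tol_n / 0.04, 4)

  pk0 <- make_pairs(10, h_sd = 1e-9, n_sd = 1e-9, min_sep = 1, seed = 4)
  tol0 <- estimate_match_tolerances(pk0)
  expect_equal(tol0$tol_h, 0.001)
  expect_equal(tol0$tol_n, 0.01)

  expect_error(estimate_match_tolerances(pk[1:3, ]), "insufficient")
})

test_that("clustering groups coincident peaks, keeps isolated singletons, flags crowds", {
  tol <- list(tol_h = 0.01, tol_n = 0.1)
  pk <- data.frame(h = c(8.0, 8.0, 9.0), n = c(120, 120, 110),
                   c = c(55, 30, 45))
  res <- group_spin_systems(pk, tol)
  sizes <- vapply(res$groups, function(g) length(g$lines), integer(1))
  expect_setequal(sizes, c(2, 1))
  expect_length(res$ungrouped, 0)

  # 3-peak cluster: closest pair kept, extra returned ungrouped
  pk3 <- data.frame(h = c(8.0, 8.001, 8.02), n = c(120, 120, 120.05),
                    c = c(55, 30, 45))
  res3 <- group_spin_systems(pk3, tol)
  expect_length(res3$ungrouped, 1)
  expect_identical(sort(res3$groups[[1]]$lines), c(1L, 2L))

  # 4 coincident peaks are ambiguous
  pk4 <- data.frame(h = rep(8.0, 4) + c(0, 1e-4, 2e-4, 3e-4),
                    n = rep(120, 4), c = c(55, 30, 56, 31))
  res4 <- group_spin_systems(pk4, tol)
  expect_length(res4$ambiguous, 4)
  expect_length(res4$groups, 0)
})

test_that("grouping partitions every peak and is input-order invariant", {
  pk <- make_pairs(80, wide = 8, seed = 12)
  g <- group_peaks(pk)
  lines_out <- c(unlist(lapply(g$groups, `[[`, "lines")), g$ambiguous)
  expect_setequal(lines_out, pk$line)
  expect_identical(anyDuplicated(lines_out), 0L)

  set.seed(1)
  g2 <- group_peaks(pk[sample(nrow(pk)), ])
  key <- function(g) sort(vapply(g$groups, function(x)
    paste(sort(x$lines), collapse = "-"), character(1)))
  expect_identical(key(g), key(g2))
})

test_that("synthetic peak lists are recovered nearly perfectly at default jitter", {
  pk <- make_pairs(100, seed = 21)
  g <- group_peaks(pk)
  expect_gte(pair_correct(g) / 100, 0.95)
})

test_that("iterative grouping rescues wide-jitter pairs and is idempotent on clean lists", {
  pk <- make_pairs(100, wide = 10, seed = 9)
  g <- group_peaks(pk)
  expect_lte(g$iterations, 3)
  expect_equal(pair_correct(g), 100)
  sizes <- vapply(g$groups, function(x) length(x$lines), integer(1))
  expect_true(all(sizes <= 2))

  # clean list: single effective iteration, and regrouping the grouped
  # list changes nothing
  pk_clean <- make_pairs(50, seed = 2)
  g1 <- group_peaks(pk_clean)
  expect_identical(g1$iterations, 1L)
  g2 <- group_peaks(pk_clean)
  expect_identical(vapply(g1$groups, function(x)
    paste(sort(x$lines), collapse = "-"), character(1)),
    vapply(g2$groups, function(x)
      paste(sort(x$lines), collapse = "-"), character(1)))
})

test_that("coincident amide roots are reported ambiguous, not mispaired", {
  pk <- make_pairs(20, seed = 5)
  # duplicate residue 1's root: 4 peaks share one (h, n) neighbourhood
  clash <- pk[1:2, ]
  clash$h <- clash$h + 1e-4
  clash$c <- c(61, 69)
  clash$line <- nrow(pk) + 1:2
  g <- group_peaks(rbind(pk, clash))
  expect_true(all(c(1, 2, clash$line) %in% g$ambiguous))
})

test_that("spin systems convert to unordered pairs with exclusions accounted", {
  groups <- list(
    list(lines = c(1, 2), root_h = 8, root_n = 120, carbons = c(56.2, 30.1)),
    list(lines = 3, root_h = 9, root_n = 112, carbons = 45.0))
  grouping <- structure(list(groups = groups, ambiguous = c(4L, 5L, 6L, 7L),
                             tolerances = list(tol_h = 0.01, tol_n = 0.1),
                             iterations = 1L), class = "spin_grouping")
  pairs <- spin_systems_to_pairs(grouping)
  expect_identical(nrow(pairs), 1L)
  expect_equal(sort(as.numeric(pairs[1, ])), c(30.1, 56.2))
  expect_identical(attr(pairs, "n_singletons"), 1L)
  expect_identical(attr(pairs, "n_ambiguous"), 4L)
})
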