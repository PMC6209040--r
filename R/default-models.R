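# Synthetic default parameter set.
#
# Real deployments derive class statistics from a large re-referenced
# assigned-shift corpus via fit_shift_models(). The package ships, built in
# code, a synthetic default set assembled from field-typical random-coil
# Ca/Cb chemical shifts plus standard secondary-structure offsets; it is
# the generating truth for every simulation in the test-suite and is NOT a
# corpus-derived table.

# random-coil (Ca, Cb) expectations in ppm; glycine has no Cb
RANDOM_COIL <- matrix(c(
  52.5, 19.1,   # A
  55.4, 40.7,   # C_ox (disulfide-bonded)
  58.2, 28.0,   # C_red (free thiol)
  54.2, 41.1,   # D
  56.6, 29.9,   # E
  57.7, 39.6,   # F
  55.0, 29.0,   # H
  61.1, 38.8,   # I
  56.2, 33.1,   # K
  55.1, 42.4,   # L
  55.4, 32.9,   # M
  53.1, 38.9,   # N
  63.3, 32.1,   # P
  55.7, 29.4,   # Q
  56.0, 30.9,   # R
  58.3, 63.8,   # S
  61.8, 69.8,   # T
  62.2, 32.9,   # V
  57.5, 29.6,   # W
  57.9, 38.8,   # Y
  45.1, NA      # G
), ncol = 2, byrow = TRUE,
  dimnames = list(c("A", "C_ox", "C_red", "D", "E", "F", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "G"),
                  c("ca", "cb")))

# secondary-structure offsets (ppm): helix raises Ca and lowers Cb,
# strand does the opposite
SS_OFFSET <- list(H = c(ca = 2.8, cb = -0.6),
                  E = c(ca = -1.6, cb = 2.2),
                  C = c(ca = 0.0, cb = 0.0))

# per-SS spreads (ppm); strand distributions are the broadest
SS_SD <- list(H = c(ca = 1.0, cb = 1.1),
              E = c(ca = 1.2, cb = 1.4),
              C = c(ca = 1.1, cb = 1.2))

#' Synthetic default chemical-shift class models
#'
#' Builds the complete set of 60 bivariate (Ca, Cb) class models plus the
#' 3 univariate glycine models from field-typical random-coil shifts,
#' secondary-structure offsets and spreads. Most classes carry a mild
#' negative Ca/Cb correlation (-0.3); oxidized cysteine is positively
#' correlated (+0.3), mirroring the sign structure seen in re-referenced
#' corpora. These parameters are synthetic: they stand in for statistics a
#' user would normally derive from an assigned-shift corpus with
#' [fit_shift_models()], and they are the generating truth used by the
#' package's simulators.
#'
#' @param variant covariance-matrix variant label stored on the set; one of
#'   `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"E_revised"`. Affects only how
#'   [class_covariance()] assembles 2x2 matrices, not the stored statistics.
#' @param n nominal per-class sample count recorded in the table (used as
#'   pooling weight).
#' @return a `shift_models` data.frame with one row per class key and
#'   columns `aa`, `ss`, `mu_ca`, `mu_cb`, `sd_ca`, `sd_cb`, `cov`, `n`.
#' @examples
#' m <- default_shift_models()
#' subset(m, aa == "A")
#' @export
default_shift_models <- function(variant = "E", n = 1000L) {
  variant <- match.arg(variant, c("A", "B", "C", "D", "E", "E_revised"))
  keys <- model_keys(include_glycine = TRUE)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    aa <- keys$aa[i]; ss <- keys$ss[i]
    mu <- RANDOM_COIL[aa, ] + SS_OFFSET[[ss]]
    sd <- SS_SD[[ss]]
    if (aa == "G") {
      data.frame(aa = aa, ss = ss, mu_ca = mu[["ca"]], mu_cb = NA_real_,
                 sd_ca = sd[["ca"]], sd_cb = NA_real_, cov = NA_real_, n = n)
    } else {
      r <- if (aa == "C_ox") 0.3 else -0.3
      data.frame(aa = aa, ss = ss, mu_ca = mu[["ca"]], mu_cb = mu[["cb"]],
                 sd_ca = sd[["ca"]], sd_cb = sd[["cb"]],
                 cov = r * sd[["ca"]] * sd[["cb"]], n = n)
    }
  })
  out <- do.call(rbind, rows)
  new_shift_models(out, variant)
}

new_shift_models <- function(df, variant) {
  rownames(df) <- class_label(df$aa, df$ss)
  structure(df, variant = variant, class = c("shift_models", "data.frame"))
}

#' @export
print.shift_models <- function(x, ...) {
  cat("Chemical-shift class models (variant ", attr(x, "variant"), "): ",
      sum(x$aa != "G"), " bivariate + ", sum(x$aa == "G"),
      " glycine classes\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' @export
summary.shift_models <- function(object, ...) {
  cat("Shift class models, variant", attr(object, "variant"), "\n")
  cat("  classes:", nrow(object), " (", sum(object$aa != "G"), "bivariate )\n")
  cat("  total n:", sum(object$n), "\n")
  ok <- !is.na(object$cov)
  r <- object$cov[ok] / (object$sd_ca[ok] * object$sd_cb[ok])
  cat("  Ca/Cb correlation range: [", round(min(r), 3), ",",
      round(max(r), 3), "]\n")
  invisible(object)
}

get_model <- function(models, aa, ss) {
  i <- which(models$aa == aa & models$ss == ss)
  if (!length(i)) stop("no model for class ", class_label(aa, ss))
  models[i[1], ]
}
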