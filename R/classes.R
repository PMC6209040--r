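# Class-key bookkeeping for the amino-acid x secondary-structure model space.
#
# Model space: 20 non-glycine residue classes (cysteine split into oxidized
# and reduced) x 3 secondary structures = 60 bivariate (Ca, Cb) models, plus
# 3 univariate glycine (Ca-only) models.
# Composition space: 19 non-glycine residue types (cysteine states merged)
# x 3 secondary structures = 57 classes.

SS_TYPES <- c("H", "E", "C")

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_NONGLY <- setdiff(AA_STANDARD, "G")

# 20 non-glycine model residue classes, cysteine split by oxidation state
AA_MODEL <- c("A", "C_ox", "C_red", "D", "E", "F", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Class keys of the bivariate and glycine models
#'
#' The model space has 63 (amino-acid class, secondary structure) keys:
#' 60 bivariate models -- 20 non-glycine residue classes (18 standard
#' residues plus oxidized and reduced cysteine) crossed with helix (H),
#' strand (E) and coil (C) -- and 3 univariate glycine models (glycine has
#' no beta carbon).
#'
#' @param include_glycine logical; include the three Ca-only glycine keys.
#' @return a data.frame with columns `aa` (model class label) and `ss`.
#' @export
model_keys <- function(include_glycine = TRUE) {
  aa <- AA_MODEL
  if (include_glycine) aa <- c(aa, "G")
  out <- expand.grid(ss = SS_TYPES, aa = aa,
                     stringsAsFactors = FALSE)[, c("aa", "ss")]
  rownames(out) <- NULL
  out
}

#' Labels of the 57 composition classes
#'
#' Composition vectors over residue type and secondary structure use 19
#' non-glycine residue types (the two cysteine oxidation states merged into
#' one cysteine class) crossed with H/E/C, giving 57 entries. Labels have
#' the form `"A:H"`.
#'
#' @return character vector of length 57.
#' @export
composition_classes <- function() {
  as.vector(t(outer(AA_NONGLY, SS_TYPES, paste, sep = ":")))
}

# map a model residue class to its composition residue type
merge_cys <- function(aa) ifelse(aa %in% c("C_ox", "C_red"), "C", aa)

class_label <- function(aa, ss) paste(aa, ss, sep = ":")

# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

validate_sequence <- function(sequence, ss) {
  seq_chr <- toupper(strsplit(sequence, "")[[1]])
  ss_chr <- toupper(strsplit(ss, "")[[1]])
  if (length(seq_chr) != length(ss_chr))
    stop("sequence and secondary-structure string differ in length (",
         length(seq_chr), " vs ", length(ss_chr), ")")
  bad <- setdiff(unique(seq_chr), AA_STANDARD)
  if (length(bad))
    stop("unknown residue letter(s) in sequence: ", paste(bad, collapse = ", "))
  bad_ss <- setdiff(unique(ss_chr), SS_TYPES)
  if (length(bad_ss))
    stop("secondary-structure string must use H/E/C; found: ",
         paste(bad_ss, collapse = ", "))
  list(seq = seq_chr, ss = ss_chr)
}
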