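# Readers and writers: sparky-style peak lists, NMR-STAR 3.1 / TSV
# assigned-shift tables, FASTA sequences, secondary-structure strings,
# model-parameter and overlap-matrix files, and the correction report.
# TSV dialect: tab separation, '.' decimal, no locale dependence.

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3), AA3)

#' Read a sparky-style 3D peak list
#'
#' Accepts whitespace-separated peak lists with an optional leading
#' assignment column, three shift columns and an optional intensity
#' column. Comment lines (`#`) and a header line (starting with
#' `Assignment` or `w1`) are skipped. The order of the three shift
#' columns is given by `dims`.
#'
#' @param path file path.
#' @param dims character vector naming the shift-column order; any
#'   permutation of `c("H", "N", "C")`.
#' @return data.frame with columns `h`, `n`, `c`, `intensity`, `line`
#'   (source line number).
#' @export
read_peak_list <- function(path, dims = c("H", "N", "C")) {
  stopifnot(setequal(dims, c("H", "N", "C")))
  lines <- readLines(path)
  if (!length(lines)) stop("empty peak list: ", path)
  rows <- list()
  for (ln in seq_along(lines)) {
    txt <- trimws(lines[ln])
    if (!nzchar(txt) || startsWith(txt, "#")) next
    tok <- strsplit(txt, "[[:space:]]+")[[1]]
    if (tolower(tok[1]) %in% c("assignment", "w1")) next  # header
    has_label <- is.na(suppressWarnings(as.numeric(tok[1])))
    sh <- if (has_label) tok[-1] else tok
    if (length(sh) < 3)
      stop("line ", ln, ": expected 3 shift columns, got ", length(sh))
    vals <- suppressWarnings(as.numeric(sh[1:3]))
    if (anyNA(vals))
      stop("line ", ln, ": non-numeric shift field in '", txt, "'")
    intensity <- if (length(sh) >= 4)
      suppressWarnings(as.numeric(sh[4])) else NA_real_
    rows[[length(rows) + 1]] <-
      data.frame(h = vals[match("H", dims)], n = vals[match("N", dims)],
                 c = vals[match("C", dims)], intensity = intensity,
                 line = ln)
  }
  if (!length(rows)) stop("no data lines in peak list: ", path)
  do.call(rbind, rows)
}

#' Write a sparky-style peak list
#'
#' @param peaks data.frame with columns `h`, `n`, `c` and optionally
#'   `intensity`.
#' @param path output path.
#' @param dims shift-column order to write.
#' @export
write_peak_list <- function(peaks, path, dims = c("H", "N", "C")) {
  cols <- list(H = peaks$h, N = peaks$n, C = peaks$c)
  m <- cbind(cols[[dims[1]]], cols[[dims[2]]], cols[[dims[3]]])
  header <- paste(c("Assignment", paste0("w", 1:3)), collapse = "\t")
  body <- sprintf("?-?\t%.4f\t%.4f\t%.4f", m[, 1], m[, 2], m[, 3])
  writeLines(c(header, body), path)
  invisible(path)
}

star_quote <- function(x) ifelse(grepl("[[:space:]]", x), shQuote(x), x)

#' Read an assigned chemical-shift table
#'
#' Reads either an NMR-STAR 3.1 file (the `_Atom_chem_shift` loop; CA and
#' CB rows are joined per residue) or the equivalent TSV dialect with
#' columns `residue_index`, `amino_acid`, `secondary_structure`
#' (optional), `ca_shift`, `cb_shift`. Residues with neither CA nor CB
#' are dropped. Secondary structure can be supplied as an H/E/C string
#' (`ss`), attached by residue index; it overrides any column present.
#'
#' @param path file path.
#' @param ss optional secondary-structure string (one letter per residue
#'   of the full sequence, indexed by `residue_index`).
#' @param format `"auto"` (detect a `_Atom_chem_shift` loop), `"star"` or
#'   `"tsv"`.
#' @return data.frame with columns `residue_index`, `amino_acid`,
#'   `secondary_structure`, `ca_shift`, `cb_shift`.
#' @export
read_assigned_table <- function(path, ss = NULL,
                                format = c("auto", "star", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto")
    format <- if (any(grepl("_Atom_chem_shift\\.", lines))) "star" else "tsv"
  tab <- if (format == "star") parse_star_shifts(lines, path)
         else {
           d <- utils::read.delim(path, stringsAsFactors = FALSE)
           need <- c("residue_index", "amino_acid", "ca_shift", "cb_shift")
           if (!all(need %in% names(d)))
             stop("TSV assigned table must have columns: ",
                  paste(need, collapse = ", "))
           if (!"secondary_structure" %in% names(d))
             d$secondary_structure <- NA_character_
           d[, c("residue_index", "amino_acid", "secondary_structure",
                 "ca_shift", "cb_shift")]
         }
  tab <- tab[is.finite(tab$ca_shift) | is.finite(tab$cb_shift), ,
             drop = FALSE]
  if (anyDuplicated(tab$residue_index))
    stop("duplicate residue indices in assigned table")
  if (!is.null(ss)) {
    ss_chr <- map_ss_letters(ss)
    tab$secondary_structure <- ss_chr[tab$residue_index]
  }
  rownames(tab) <- NULL
  tab
}

parse_star_shifts <- function(lines, path) {
  loop_starts <- which(trimws(lines) == "loop_")
  if (!length(loop_starts))
    stop("no chemical-shift loop found in ", path)
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character(0)
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    tags <- sub("^_Atom_chem_shift\\.", "", tags)
    rows <- list()
    while (i <= length(lines) && !grepl("^\\s*stop_", lines[i])) {
      txt <- trimws(lines[i]); i <- i + 1
      if (!nzchar(txt) || startsWith(txt, "#")) next
      tok <- strsplit(txt, "[[:space:]]+")[[1]]
      if (length(tok) != length(tags))
        stop("malformed NMR-STAR loop row: '", txt, "'")
      rows[[length(rows) + 1]] <- stats::setNames(as.list(tok), tags)
    }
    d <- do.call(rbind, lapply(rows, as.data.frame))
    need <- c("Comp_index_ID", "Comp_ID", "Atom_ID", "Val")
    if (!all(need %in% names(d)))
      stop("chemical-shift loop lacks tag(s): ",
           paste(setdiff(need, names(d)), collapse = ", "))
    d <- d[d$Atom_ID %in% c("CA", "CB"), , drop = FALSE]
    idx <- as.integer(d$Comp_index_ID)
    aa <- unname(AA3[toupper(d$Comp_ID)])
    val <- as.numeric(d$Val)
    res <- sort(unique(idx))
    out <- data.frame(residue_index = res,
                      amino_acid = aa[match(res, idx)],
                      secondary_structure = NA_character_,
                      ca_shift = NA_real_, cb_shift = NA_real_)
    for (k in seq_along(idx)) {
      r <- match(idx[k], res)
      if (d$Atom_ID[k] == "CA") out$ca_shift[r] <- val[k]
      else out$cb_shift[r] <- val[k]
    }
    return(out)
  }
  stop("no chemical-shift loop found in ", path)
}

#' Write an assigned chemical-shift table
#'
#' @param table assigned-shift data.frame.
#' @param path output path.
#' @param format `"star"` (a minimal NMR-STAR 3.1 `_Atom_chem_shift`
#'   loop) or `"tsv"`.
#' @export
write_assigned_table <- function(table, path, format = c("tsv", "star")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    hdr <- c("data_shiftref", "", "save_assigned_chemical_shifts", "loop_",
             paste0("  _Atom_chem_shift.",
                    c("ID", "Comp_index_ID", "Comp_ID", "Atom_ID",
                      "Atom_type", "Val")))
    rows <- character(0); id <- 0
    for (r in seq_len(nrow(table))) {
      aa3 <- AA1TO3[[table$amino_acid[r]]]
      for (atom in c("CA", "CB")) {
        v <- if (atom == "CA") table$ca_shift[r] else table$cb_shift[r]
        if (!is.finite(v)) next
        id <- id + 1
        rows <- c(rows, sprintf("  %d %d %s %s C %.4f", id,
                                table$residue_index[r], aa3, atom, v))
      }
    }
    writeLines(c(hdr, rows, "stop_", "save_"), path)
  }
  invisible(path)
}

# JPred-style letters: H -> helix, E -> strand, everything else -> coil
map_ss_letters <- function(ss) {
  ch <- toupper(strsplit(ss, "")[[1]])
  ifelse(ch == "H", "H", ifelse(ch == "E", "E", "C"))
}

#' Read a protein sequence
#'
#' Accepts a FASTA file, a plain-text file holding the sequence, or a
#' literal sequence string.
#'
#' @param x path or sequence string.
#' @return upper-case one-letter sequence string.
#' @export
read_sequence <- function(x) {
  if (!file.exists(x)) return(toupper(gsub("[[:space:]]", "", x)))
  lines <- readLines(x)
  if (length(lines) && startsWith(trimws(lines[1]), ">")) {
    fa <- seqinr::read.fasta(x, seqtype = "AA", as.string = TRUE)
    return(toupper(as.character(fa[[1]])))
  }
  toupper(gsub("[[:space:]]", "", paste(lines, collapse = "")))
}

#' Read a secondary-structure string
#'
#' Accepts a path or a literal string; letters are mapped H -> H, E -> E
#' and everything else (including JPred's `-`) -> C.
#'
#' @param x path or H/E/C (or JPred-letter) string.
#' @return H/E/C string.
#' @export
read_ss <- function(x) {
  raw <- if (file.exists(x))
    gsub("[[:space:]]", "", paste(readLines(x), collapse = ""))
  else gsub("[[:space:]]", "", x)
  paste(map_ss_letters(raw), collapse = "")
}

#' Write / read a model-parameter table
#'
#' Flat TSV with one row per class key (`aa`, `ss`, `mu_ca`, `mu_cb`,
#' `sd_ca`, `sd_cb`, `cov`, `n`) plus a `variant` column.
#'
#' @param models a `shift_models` table.
#' @param path file path.
#' @return `read_shift_models()` returns the `shift_models` table.
#' @export
write_shift_models <- function(models, path) {
  df <- as.data.frame(models)
  df$variant <- attr(models, "variant")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_shift_models
#' @export
read_shift_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  variant <- df$variant[1]
  df$variant <- NULL
  new_shift_models(df, variant)
}

#' Write / read an overlap prior
#'
#' Labeled TSV matrix with class-key row and column headers; the weights
#' are the diagonal and are restored on read.
#'
#' @param prior an `overlap_prior`.
#' @param path file path.
#' @return `read_overlap_prior()` returns the `overlap_prior`.
#' @export
write_overlap_prior <- function(prior, path) {
  utils::write.table(prior$omega, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_overlap_prior
#' @export
read_overlap_prior <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  new_overlap_prior(m, stats::setNames(diag(m), rownames(m)))
}

#' Write the outputs of a fitted correction
#'
#' Writes, into `outdir`: `report.json` (correction values, final
#' residual, optimizer, seed and call), a corrected data file (peak list,
#' assigned table or pair TSV, every carbon shift minus the correction,
#' 1H/15N untouched), `residual_curve.tsv`, and optionally a residual
#' plot (`residual_plot.png`).
#'
#' @param fit a `refcorr` object.
#' @param outdir output directory (created if missing).
#' @param peaks optional peak data.frame to correct and write instead of
#'   the fit's own input.
#' @param plot also write the residual plot.
#' @return invisibly, the named vector of written paths.
#' @export
write_refcorr_outputs <- function(fit, outdir, peaks = NULL, plot = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(outdir, "report.json"),
             curve = file.path(outdir, "residual_curve.tsv"))
  report <- list(correction = fit$correction, m1 = fit$m1,
                 final_residual = fit$final_residual,
                 optimizer = fit$optimizer, mode = fit$mode,
                 variant = fit$variant, seed = fit$seed,
                 completeness = fit$completeness,
                 call = paste(deparse(fit$call), collapse = " "))
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(fit$curve, paths[["curve"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(peaks)) {
    paths[["corrected"]] <- file.path(outdir, "corrected_peaks.txt")
    write_peak_list(predict(fit, peaks), paths[["corrected"]])
  } else if (fit$mode == "assigned") {
    paths[["corrected"]] <- file.path(outdir, "corrected_shifts.tsv")
    write_assigned_table(predict(fit), paths[["corrected"]])
  } else {
    paths[["corrected"]] <- file.path(outdir, "corrected_pairs.tsv")
    utils::write.table(as.data.frame(predict(fit)), paths[["corrected"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (plot) {
    paths[["plot"]] <- file.path(outdir, "residual_plot.png")
    grDevices::png(paths[["plot"]], width = 800, height = 500)
    plot(fit)
    grDevices::dev.off()
  }
  invisible(paths)
}
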