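#' Read labeled scores from a delimited text file
#'
#' Parse a comma- or tab-delimited table (delimiter sniffed from the header
#' line; a header row is required) holding one score column and one truth
#' label column, e.g. a spike-in gold standard. Row order is preserved.
#'
#' @param path Path to the delimited file.
#' @param score_col,label_col Column names holding the score and the truth
#'   label. Defaults `"score"` and `"label"`.
#' @param positive Label value denoting the true positive class. Default
#'   `"1"`.
#' @return A [labeled_scores()] tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("score,label", "0.9,1", "0.1,0"), f)
#' read_scores(f)
#' @export
read_scores <- function(path, score_col = "score", label_col = "label",
                        positive = "1") {
  tab <- read_sniffed(path)
  for (col in c(score_col, label_col)) {
    if (!col %in% names(tab)) {
      rlang::abort(paste0("missing column `", col, "` in ", path),
        class = "rocsurface_missing_column")
    }
  }
  score <- suppressWarnings(as.double(tab[[score_col]]))
  if (anyNA(score)) {
    bad <- which(is.na(score))
    rlang::abort(
      paste0("unparseable score in column `", score_col, "`, row(s) ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "rocsurface_unparseable_score")
  }
  lab_raw <- as.character(tab[[label_col]])
  labeled_scores(score, lab_raw, positive = as.character(positive))
}

#' Read an operating-point curve from a delimited text file
#'
#' Build a `rocs_curve` from user-provided FPR, TPR and FDR columns rather
#' than from raw scores. Rows are re-ordered to non-decreasing TPR (input
#' order preserved among ties), TDR is derived as `1 - FDR`, and thresholds
#' are synthesized as the descending row index since the original cutoffs
#' are unknown. Class counts are unavailable from such a table and are
#' recorded as `NA`; all metrics work without them.
#'
#' @param path Path to the delimited file.
#' @param fpr_col,tpr_col,fdr_col Column names. Defaults `"FPR"`, `"TPR"`,
#'   `"FDR"`.
#' @return A `rocs_curve` tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("FPR,TPR,FDR", "0,0.5,0", "0.5,1,0.2"), f)
#' read_curve(f)
#' @export
read_curve <- function(path, fpr_col = "FPR", tpr_col = "TPR",
                       fdr_col = "FDR") {
  tab <- read_sniffed(path)
  for (col in c(fpr_col, tpr_col, fdr_col)) {
    if (!col %in% names(tab)) {
      rlang::abort(paste0("missing column `", col, "` in ", path),
        class = "rocsurface_missing_column")
    }
  }
  df <- tibble::tibble(
    fpr = as.double(tab[[fpr_col]]),
    tpr = as.double(tab[[tpr_col]]),
    fdr = as.double(tab[[fdr_col]])
  )
  bad <- which(!stats::complete.cases(df) |
                 df$fpr < 0 | df$fpr > 1 | df$tpr < 0 | df$tpr > 1 |
                 df$fdr < 0 | df$fdr > 1)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("FPR/TPR/FDR values outside [0, 1] in row(s) ",
             paste(utils::head(bad, 5), collapse = ", ")),
      class = "rocsurface_invalid_input")
  }
  df <- df[order(df$tpr), ]  # stable: ties keep input order
  df$tdr <- 1 - df$fdr
  df$threshold <- as.double(rev(seq_len(nrow(df))))
  new_rocs_curve(df[, c("threshold", "fpr", "tpr", "fdr", "tdr")])
}

#' Write an operating-point curve to CSV
#'
#' Writes the `FPR`, `TPR`, `FDR` columns in the schema that [read_curve()]
#' reads back, so a curve round-trips through disk with its AUC, VUS and
#' FCAUC intact.
#'
#' @param curve A `rocs_curve` or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  curve <- validate_rocs_curve(curve)
  readr::write_csv(
    tibble::tibble(FPR = curve$fpr, TPR = curve$tpr, FDR = curve$fdr),
    path)
  invisible(path)
}

# Read a delimited table, sniffing comma vs tab from the header line.
read_sniffed <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path),
      class = "rocsurface_invalid_input")
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}
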