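#' Parse a sample sheet describing a multi-assay ChIP-seq experiment
#'
#' The sample sheet is a CSV file with header columns `filepath`, `condition`,
#' `is_control` and `replicate`, one row per sequenced sample. Conditions are
#' enumerated in a stable order with the control condition(s) first, so that
#' shuffled input rows yield an identical sheet.
#'
#' @param path path to the CSV file, or a data.frame with the same columns.
#' @param no_control set to `TRUE` to allow a sheet without any control
#'   (input/WCE) sample; otherwise a missing control is an error.
#' @return A `sample_sheet` object: a data.frame with columns `filepath`,
#'   `condition`, `is_control`, `replicate`, rows ordered controls first then
#'   treatments grouped by condition, with attribute `conditions` (control
#'   conditions first).
#' @examples
#' df <- data.frame(
#'   filepath = c("wce1.bam", "wce2.bam", "k4a.bam", "k4b.bam"),
#'   condition = c("WCE", "WCE", "H3K4me3", "H3K4me3"),
#'   is_control = c(TRUE, TRUE, FALSE, FALSE),
#'   replicate = c(1, 2, 1, 2))
#' parse_sample_sheet(df)
#' @export
parse_sample_sheet <- function(path, no_control = FALSE) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("sample sheet not found: ", path)
    read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("filepath", "condition", "is_control", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("sample sheet has zero rows")

  df <- df[required]
  df$filepath <- as.character(df$filepath)
  df$condition <- as.character(df$condition)
  df$is_control <- .as_flag(df$is_control)
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$is_control)) stop("is_control must be TRUE/FALSE (or 0/1, yes/no)")
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  key <- paste(df$condition, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(df$filepath))
    stop("duplicate filepath(s) in sample sheet")
  if (!any(df$is_control) && !no_control)
    stop("sample sheet contains no control sample; pass no_control = TRUE ",
         "to analyse treatment-only data")

  # stable canonical order: controls first, then treatments, conditions
  # alphabetically and replicates ascending within each condition
  df <- df[order(!df$is_control, df$condition, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  conds <- c(unique(df$condition[df$is_control]),
             unique(df$condition[!df$is_control]))
  structure(df, conditions = conds, class = c("sample_sheet", "data.frame"))
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[v %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("Sample sheet: %d samples, %d condition(s) [%s]\n",
              nrow(x), length(attr(x, "conditions")),
              paste(attr(x, "conditions"), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}
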