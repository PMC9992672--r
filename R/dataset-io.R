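#' Write an expression dataset to a tab-separated file
#'
#' One header row; first column `sample_id`, second column `label`
#' (`early`/`late`), then one column per feature headed by its id. Values are
#' written with full double precision so a read round-trip is bit-exact. If
#' the dataset carries planted truth features they can be written to a
#' sidecar file, one feature id per line.
#'
#' @param dataset an [expression_dataset()].
#' @param path output file path.
#' @param truth_path optional path for the truth sidecar.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, truth_path = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  df <- data.frame(sample_id = dataset$sample_ids,
                   label = as.character(dataset$labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.data.frame(dataset$values, check.names = FALSE)
  # format() with digits = 17 guarantees read.delim reproduces the doubles
  vals[] <- lapply(vals, function(x) sprintf("%.17g", x))
  df <- cbind(df, vals)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (!is.null(truth_path) && !is.null(dataset$truth)) {
    writeLines(dataset$truth, truth_path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read an expression dataset from a tab-separated file
#'
#' Expects the format written by [write_dataset()]. Malformed input (missing
#' `sample_id`/`label` columns, duplicate feature or sample ids, labels
#' outside `early`/`late`, non-numeric or negative expression cells) raises a
#' parse error naming the offending line.
#'
#' @param path input file path.
#' @param truth_path optional truth sidecar (one feature id per line).
#' @return an [expression_dataset()].
#' @export
read_dataset <- function(path, truth_path = NULL) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L || header[1] != "sample_id" || header[2] != "label") {
    stop_parse(paste0("line 1: header must start with 'sample_id' and ",
                      "'label' followed by at least one feature column"))
  }
  feats <- header[-(1:2)]
  dup <- unique(feats[duplicated(feats)])
  if (length(dup) > 0) {
    stop_parse("line 1: duplicate feature id(s): %s",
               paste(dup, collapse = ", "))
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "", comment.char = "")
  if (nrow(df) == 0L) stop_parse("line 2: no sample rows")
  bad_label <- which(!df$label %in% c("early", "late"))
  if (length(bad_label) > 0) {
    stop_parse("line %d: label '%s' is not 'early' or 'late'",
               bad_label[1] + 1L, df$label[bad_label[1]])
  }
  dup_s <- which(duplicated(df$sample_id))
  if (length(dup_s) > 0) {
    stop_parse("line %d: duplicate sample id '%s'",
               dup_s[1] + 1L, df$sample_id[dup_s[1]])
  }
  values <- matrix(NA_real_, nrow = nrow(df), ncol = length(feats),
                   dimnames = list(df$sample_id, feats))
  for (j in seq_along(feats)) {
    col <- df[[feats[j]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      stop_parse("line %d: non-numeric value '%s' in feature '%s'",
                 bad[1] + 1L, col[bad[1]], feats[j])
    }
    values[, j] <- num
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop_parse("line %d: negative value in feature '%s'",
               neg[1, 1] + 1L, feats[neg[1, 2]])
  }
  truth <- NULL
  if (!is.null(truth_path)) {
    truth <- readLines(truth_path)
    truth <- truth[nzchar(truth)]
  }
  expression_dataset(values, df$label, truth = truth)
}
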