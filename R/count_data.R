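#' Gene-by-sample count container with sample metadata
#'
#' Bundles a non-negative integer count matrix with the sample sheet that
#' describes each library (fraction, condition, time point, replicate). All
#' downstream stages take this container or a plain matrix plus sample sheet.
#'
#' @param counts integer matrix, genes in rows (unique rownames), samples in
#'   columns (colnames matching `samples$sample`).
#' @param samples data frame with columns `sample`, `fraction`
#'   (`"trap"`/`"total"`), `condition` (`"control"`/`"LTP"`), `timepoint`
#'   (minutes), `replicate`.
#' @return An object of class `"count_data"`: a list with elements `counts`
#'   and `samples`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample = paste0("s", 1:4), fraction = "trap",
#'   condition = rep(c("control", "LTP"), 2), timepoint = 60,
#'   replicate = rep(1:2, each = 2))
#' cd <- count_data(m, sheet)
count_data <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("'counts' must have unique rownames (gene identifiers)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  samples <- as.data.frame(samples)
  required <- c("sample", "fraction", "condition", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample sheet lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (!identical(sort(colnames(counts)), sort(as.character(samples$sample)))) {
    stop("colnames(counts) and samples$sample must agree")
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (anyNA(samples[required])) stop("every sample needs complete metadata")
  structure(list(counts = counts, samples = samples), class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("count_data: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("fractions: ", paste(unique(x$samples$fraction), collapse = ", "), "\n")
  cat("timepoints:", paste(sort(unique(x$samples$timepoint)), collapse = ", "),
      "min\n")
  invisible(x)
}

#' Subset a count_data object by sample metadata
#'
#' @param x a [count_data] object.
#' @param fraction,condition,timepoint optional filters; `NULL` keeps all.
#' @return A `count_data` with the matching samples.
#' @export
subset_samples <- function(x, fraction = NULL, condition = NULL,
                           timepoint = NULL) {
  stopifnot(inherits(x, "count_data"))
  keep <- rep(TRUE, nrow(x$samples))
  if (!is.null(fraction)) keep <- keep & x$samples$fraction %in% fraction
  if (!is.null(condition)) keep <- keep & x$samples$condition %in% condition
  if (!is.null(timepoint)) keep <- keep & x$samples$timepoint %in% timepoint
  if (!any(keep)) stop("no samples match the requested subset")
  count_data(x$counts[, keep, drop = FALSE], x$samples[keep, , drop = FALSE])
}

#' Write / read counts and sample sheets as TSV
#'
#' Plain tab-separated text with a header line; lines starting with `#` are
#' treated as comments on read.
#'
#' @param x a [count_data] object.
#' @param counts_file,samples_file file paths.
#' @return `write_count_data` returns the paths invisibly; `read_count_data`
#'   returns a [count_data].
#' @export
write_count_data <- function(x, counts_file, samples_file) {
  stopifnot(inherits(x, "count_data"))
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_file, samples = samples_file))
}

#' @rdname write_count_data
#' @export
read_count_data <- function(counts_file, samples_file) {
  df <- utils::read.delim(counts_file, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  samples <- utils::read.delim(samples_file, comment.char = "#")
  count_data(m, samples)
}
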