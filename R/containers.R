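#' Gene-by-sample expression matrix with Zeitgeber-time metadata
#'
#' Lightweight container for a diurnal time-course experiment: a numeric
#' matrix (genes in rows, samples in columns) plus per-sample metadata
#' (Zeitgeber time in hours, replicate id, age label). All downstream
#' analyses (`detect_cycling()`, `sog_scan()`, `fit_time_model()`, ...)
#' consume this container.
#'
#' @param values Numeric matrix, genes x samples, with gene ids as rownames.
#' @param zt Numeric vector of Zeitgeber times (hours in `[0, 24)`), one per
#'   column.
#' @param replicate Replicate ids, one per column (defaults to a counter
#'   within each time point).
#' @param age Age label for the whole matrix (single string) or one per
#'   column.
#' @return An object of class `zt_matrix`: a list with elements `values`
#'   (the matrix, columns renamed `<age>_ZT<h>_rep<k>`) and `samples` (a
#'   data.frame with columns `sample`, `age`, `zt`, `replicate`).
#' @examples
#' m <- matrix(rnorm(12), 2, 6, dimnames = list(c("g1", "g2"), NULL))
#' x <- zt_matrix(m, zt = rep(c(1, 13), each = 3), age = "young")
#' x
#' @export
zt_matrix <- function(values, zt, replicate = NULL, age = "age1") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  }
  zt <- as.numeric(zt)
  if (length(zt) != ncol(values)) stop("`zt` must have one entry per column")
  if (any(!is.finite(zt)) || any(zt < 0) || any(zt >= 24)) {
    stop("`zt` values must lie in [0, 24)")
  }
  if (length(age) == 1L) age <- rep(age, ncol(values))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(zt), paste(age, zt), FUN = seq_along)
  }
  samples <- data.frame(
    sample = paste0(age, "_ZT", zt, "_rep", replicate),
    age = as.character(age), zt = zt, replicate = as.character(replicate),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(samples$sample)) stop("duplicated (age, zt, replicate) sample labels")
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples), class = "zt_matrix")
}

#' @export
print.zt_matrix <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<zt_matrix> %d genes x %d samples | ages: %s | ZT: %s | replicates/time-point: %s\n",
    nrow(x$values), ncol(x$values),
    paste(unique(s$age), collapse = ","),
    paste(sort(unique(s$zt)), collapse = ","),
    paste(unique(table(paste(s$age, s$zt))), collapse = ",")
  ))
  invisible(x)
}

#' @export
dim.zt_matrix <- function(x) dim(x$values)

# time-point x replicate value matrix for one gene (rows in zt order);
# the unit consumed by the permutation machinery
gene_replicate_matrix <- function(x, gene, age = NULL) {
  stopifnot(inherits(x, "zt_matrix"))
  keep <- if (is.null(age)) rep(TRUE, ncol(x$values)) else x$samples$age == age
  v <- x$values[gene, keep]
  zt <- x$samples$zt[keep]
  zts <- sort(unique(zt))
  reps <- max(table(zt))
  out <- matrix(NA_real_, length(zts), reps, dimnames = list(zts, NULL))
  for (i in seq_along(zts)) {
    vi <- v[zt == zts[i]]
    out[i, seq_along(vi)] <- vi
  }
  attr(out, "zt") <- zts
  out
}

#' Write / read an expression matrix as TSV
#'
#' Plain-text round-trip for [zt_matrix] objects. The first column holds the
#' gene id; remaining columns are named `<age>_ZT<h>_rep<k>` and carry the
#' sample metadata in their names.
#'
#' @param x A [zt_matrix].
#' @param path File path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns a [zt_matrix].
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "zt_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  meta <- regmatches(colnames(m), regexec("^(.+)_ZT([0-9.]+)_rep(.+)$", colnames(m)))
  if (any(lengths(meta) != 4L)) {
    stop("column names must follow <age>_ZT<h>_rep<k>")
  }
  meta <- do.call(rbind, meta)
  zt_matrix(m, zt = as.numeric(meta[, 3]), replicate = meta[, 4], age = meta[, 2])
}

#' Write / read a single-trace time series as TSV
#'
#' Traces are data.frames with columns `time_h`, `value` and optionally
#' `replicate` (luminescence-style recordings, hours vs intensity).
#'
#' @param trace Data frame with columns `time_h`, `value` (and optionally
#'   `replicate`).
#' @param path File path.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(all(c("time_h", "value") %in% names(trace)))
  utils::write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("time_h", "value") %in% names(df))) {
    stop("trace TSV must have columns time_h, value")
  }
  df
}
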