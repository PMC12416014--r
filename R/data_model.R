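#' Construct a longitudinal dataset
#'
#' Bundles long-format longitudinal measurements into the container used by
#' all fitting and simulation functions. One element per measurement; rows
#' are grouped by subject in order of first appearance, and measurements
#' within a subject keep their input order (no sorting by time is imposed).
#'
#' @param id subject identifier per measurement (coerced to character).
#' @param time numeric measurement time per measurement.
#' @param y numeric response per measurement; must be finite. Strict
#'   positivity is only required by the transformation functions, not here.
#' @param true_label optional integer cluster label, either one per
#'   measurement (constant within subject) or one per subject.
#'
#' @return An object of class `longitudinal_data`: a list with per-row
#'   fields `id`, `time`, `y`, `sidx` (subject index 1..n per row), and
#'   per-subject fields `subjects`, `p` (measurements per subject),
#'   `true_labels` (or `NULL`), plus counts `n` (subjects) and
#'   `N` (total measurements).
#' @export
#' @examples
#' d <- longitudinal_data(id = c("a", "a", "b"), time = c(0, 1, 0), y = c(1, 2, 3))
#' d$n; d$N; d$p
longitudinal_data <- function(id, time, y, true_label = NULL) {
  id <- as.character(id)
  time <- as.numeric(time)
  y <- as.numeric(y)
  if (length(id) == 0L) stop("empty dataset: no measurements")
  if (length(time) != length(id) || length(y) != length(id))
    stop("id, time and y must have equal length")
  if (anyNA(time) || any(!is.finite(time))) stop("non-finite time values")
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite response values")

  subjects <- unique(id)
  sidx <- match(id, subjects)
  p <- tabulate(sidx, nbins = length(subjects))

  labels <- NULL
  if (!is.null(true_label)) {
    true_label <- as.integer(true_label)
    if (length(true_label) == length(id)) {
      labels <- integer(length(subjects))
      for (i in seq_along(subjects)) {
        li <- unique(true_label[sidx == i])
        if (length(li) != 1L)
          stop("true_label not constant within subject ", subjects[i])
        labels[i] <- li
      }
    } else if (length(true_label) == length(subjects)) {
      labels <- true_label
    } else {
      stop("true_label must have one entry per measurement or per subject")
    }
  }

  structure(
    list(id = id, time = time, y = y, sidx = sidx,
         subjects = subjects, p = p, true_labels = labels,
         n = length(subjects), N = length(id)),
    class = "longitudinal_data"
  )
}

#' @export
print.longitudinal_data <- function(x, ...) {
  cat("Longitudinal dataset:", x$n, "subjects,", x$N, "measurements\n")
  cat("  measurements per subject:", if (length(unique(x$p)) == 1L)
    x$p[1] else paste0("ragged [", min(x$p), ", ", max(x$p), "]"), "\n")
  cat("  time range: [", min(x$time), ", ", max(x$time), "]\n", sep = "")
  if (!is.null(x$true_labels))
    cat("  true labels present (", length(unique(x$true_labels)),
        " classes)\n", sep = "")
  invisible(x)
}

#' Read a long-format longitudinal CSV file
#'
#' Reads a CSV with one row per measurement and named columns for the
#' subject id, the time and the response. Rows are grouped by id preserving
#' the within-id file order.
#'
#' @param path path to a CSV file (UTF-8, header row, decimal point ".").
#' @param id_col,time_col,y_col column names.
#' @param label_col optional column name holding true cluster labels.
#'
#' @return A [longitudinal_data] object.
#' @export
read_long_csv <- function(path, id_col = "id", time_col = "time",
                          y_col = "y", label_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  need <- c(id_col, time_col, y_col, label_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  parse_num <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", what, " in column '", col, "' at data row ",
           bad[1], " (value '", df[[col]][bad[1]], "')")
    v
  }
  longitudinal_data(
    id = df[[id_col]],
    time = parse_num(time_col, "time"),
    y = parse_num(y_col, "response"),
    true_label = if (!is.null(label_col)) parse_num(label_col, "label")
  )
}

#' Write a longitudinal dataset as long-format CSV
#'
#' Inverse of [read_long_csv()]: columns `id`, `time`, `y` and, when true
#' labels are present, `true_label`.
#'
#' @param data a [longitudinal_data] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path) {
  stopifnot(inherits(data, "longitudinal_data"))
  df <- data.frame(id = data$id, time = data$time, y = data$y,
                   stringsAsFactors = FALSE)
  if (!is.null(data$true_labels))
    df$true_label <- data$true_labels[data$sidx]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Design specifications for trajectory mean curves
#'
#' A design specification maps measurement times to the rows of the
#' per-subject design matrices X_i of the mixture-of-regressions model
#' mu_ik = X_i theta_k. Three kinds are provided: polynomial bases
#' `[1, t, ..., t^d]`, the broken-stick basis `[1, t, (t - knot)+]`
#' (a continuous piecewise-linear curve whose slope changes at the knot),
#' and arbitrary user-supplied column builders.
#'
#' @param degree polynomial degree d >= 0; gives q = d + 1 columns.
#' @param knot broken-stick knot position on the time axis.
#' @param builder function mapping a numeric time vector to a numeric
#'   matrix with `q` columns; the first column must be the intercept.
#' @param q number of columns `builder` produces.
#' @param name label used in printing.
#'
#' @return An object of class `design_spec` with fields `kind`, `q` and a
#'   `builder` function.
#' @export
#' @examples
#' build_design(longitudinal_data("a", 30, 5), design_broken_stick(21))
design_polynomial <- function(degree) {
  degree <- as.integer(degree)
  if (degree < 0L) {
    warning("polynomial degree < 0; using degree 0 (intercept only)")
    degree <- 0L
  }
  structure(list(
    kind = "polynomial", q = degree + 1L, degree = degree,
    builder = function(time) {
      X <- outer(time, 0:degree, `^`)
      colnames(X) <- c("(Intercept)", if (degree > 0)
        paste0("t", if (degree > 1) c("", 2:degree) else ""))
      X
    }
  ), class = "design_spec")
}

#' @rdname design_polynomial
#' @export
design_broken_stick <- function(knot) {
  knot <- as.numeric(knot)
  structure(list(
    kind = "broken_stick", q = 3L, knot = knot,
    builder = function(time) {
      X <- cbind(1, time, pmax(time - knot, 0))
      colnames(X) <- c("(Intercept)", "t", paste0("(t-", knot, ")+"))
      X
    }
  ), class = "design_spec")
}

#' @rdname design_polynomial
#' @export
design_custom <- function(builder, q, name = "custom") {
  stopifnot(is.function(builder), q >= 1)
  structure(list(kind = name, q = as.integer(q), builder = builder),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design spec:", x$kind, "(", x$q, "columns )\n")
  invisible(x)
}

#' Build the stacked design matrix for a dataset
#'
#' Evaluates a [design_spec] at every measurement time. The result is the
#' row-stacked matrix of all per-subject design matrices X_i, aligned with
#' the dataset's rows; `data$sidx` recovers the per-subject blocks. Times
#' are used exactly as given (no centering or standardization).
#'
#' @param data a [longitudinal_data] object.
#' @param spec a [design_spec].
#' @return An N x q numeric matrix with the spec attached as attribute
#'   `"spec"`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "longitudinal_data"), inherits(spec, "design_spec"))
  if (identical(spec$kind, "broken_stick") &&
      (spec$knot <= min(data$time) || spec$knot >= max(data$time)))
    warning("broken-stick knot ", spec$knot,
            " lies outside the observed time range [", min(data$time), ", ",
            max(data$time), "]")
  X <- spec$builder(data$time)
  X <- as.matrix(X)
  if (ncol(X) != spec$q)
    stop("design builder produced ", ncol(X), " columns, expected ", spec$q)
  if (nrow(X) != data$N)
    stop("design builder must return one row per measurement")
  storage.mode(X) <- "double"
  attr(X, "spec") <- spec
  X
}
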