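# Population-level statistics: correlation tests and partial
# correlations computed from a labelled correlation matrix.

#' Labelled correlation matrix with sample size
#'
#' @param values Symmetric matrix with unit diagonal and entries in
#'   `[-1, 1]`.
#' @param labels Variable names (default from `dimnames`).
#' @param n Sample size; must exceed the number of variables.
#' @return An object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(values, labels = colnames(values), n) {
  values <- as.matrix(values)
  p <- ncol(values)
  if (is.null(labels) || length(labels) != p)
    stop("labels must name every variable")
  if (nrow(values) != p) stop("matrix must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("matrix must be symmetric")
  if (any(abs(diag(values) - 1) > 1e-10))
    stop("diagonal must be exactly 1")
  if (any(abs(values) > 1)) stop("entries must lie in [-1, 1]")
  if (n <= p) stop("sample size must exceed the number of variables")
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, n = as.integer(n)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Correlation matrix (n = %d)\n", x$n))
  print(round(x$values, digits))
  invisible(x)
}

#' Read a correlation matrix from CSV or JSON
#'
#' CSV: a square labelled table (first column = row labels).  JSON: an
#' object with fields `labels`, `values` (row-major matrix), `n`.
#'
#' @param path File path.
#' @param n Sample size (required for CSV; overrides JSON if given).
#' @return A [correlation_matrix()] object.
#' @export
read_correlation_matrix <- function(path, n = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$values) || is.null(obj$labels))
      stop("malformed correlation JSON: need fields labels, values")
    v <- matrix(unlist(obj$values), length(obj$labels), byrow = TRUE)
    if (is.null(n)) n <- obj$n
    return(correlation_matrix(v, obj$labels, n))
  }
  df <- tryCatch(utils::read.csv(path, row.names = 1, check.names = FALSE),
                 error = function(e)
                   stop("could not parse correlation CSV '", path, "': ",
                        conditionMessage(e)))
  v <- as.matrix(df)
  if (!is.numeric(v)) stop("correlation CSV contains non-numeric entries")
  if (is.null(n)) stop("sample size 'n' is required with a CSV matrix")
  correlation_matrix(v, colnames(v), n)
}

#' The bundled group correlation matrix
#'
#' Correlations between columnar width (1/c), retinotopic V1 surface
#' area, the deep-pyramidal-to-interneuron drive a23 and peak gamma
#' frequency f, over 32 hemisphere datasets; shipped as a plain-text
#' fixture.
#'
#' @return A [correlation_matrix()] object (n = 32, variables
#'   `width`, `v1_size`, `a23`, `f`).
#' @export
group_correlations <- function() {
  path <- system.file("extdata", "group_correlations.csv",
                      package = "cmcfield", mustWork = TRUE)
  read_correlation_matrix(path, n = 32)
}

#' Significance test of a Pearson correlation
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` referred to a t distribution with
#' `n - 2` degrees of freedom.  The one-tailed p-value is taken in the
#' direction of the observed sign.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Sample size, `n > 2`.
#' @param tails `"one"` or `"two"`.
#' @return List with `p.value`, `statistic`, `df`, `r`, `tails`.
#' @export
pearson_test <- function(r, n, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(abs(r) < 1, n > 2)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- stats::pt(-abs(t), df)
  if (tails == "two") p <- 2 * p
  list(p.value = p, statistic = t, df = df, r = r, tails = tails)
}

#' Partial correlation from a correlation matrix
#'
#' Precision-matrix normalisation on the sub-problem spanned by `x`,
#' `y` and the controls: `r = -P_xy / sqrt(P_xx P_yy)`.  The p-value
#' refers `t = r sqrt(df / (1 - r^2))` to a t distribution with
#' `df = n - 2 - #controls`; one-tailed (in the direction of the
#' observed sign) by default, for directional hypotheses.
#'
#' @param corr A [correlation_matrix()] object.
#' @param x,y Variable names.
#' @param controls Character vector of control variable names.
#' @param tails `"one"` or `"two"`.
#' @return List with `estimate`, `p.value`, `statistic`, `df`.
#' @export
partial_correlation <- function(corr, x, y, controls = character(),
                                tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(inherits(corr, "correlation_matrix"))
  vars <- c(x, y, controls)
  if (anyDuplicated(vars)) stop("x, y and controls must be distinct")
  if (!all(vars %in% corr$labels))
    stop("unknown variable(s): ",
         paste(setdiff(vars, corr$labels), collapse = ", "))
  S <- corr$values[vars, vars, drop = FALSE]
  P <- tryCatch(solve(S), error = function(e)
    stop("correlation submatrix is singular"))
  r <- -P[x, y] / sqrt(P[x, x] * P[y, y])
  df <- corr$n - 2 - length(controls)
  t <- r * sqrt(df / (1 - r^2))
  p <- stats::pt(-abs(t), df)
  if (tails == "two") p <- 2 * p
  list(estimate = unname(r), p.value = unname(p), statistic = unname(t),
       df = df, tails = tails)
}
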