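#' Semicontinuous dataset
#'
#' Bundles a nonnegative data matrix with group labels and derives the
#' quantities used by the two-part model: the presence indicators
#' \eqn{Y_{ij} = 1(X_{ij} > 0)}, the log-abundances \eqn{\tilde X_{ij} =
#' \log X_{ij}} of the present entries (`NA` where absent), and the
#' per-observation support sizes.  Zeros are treated as structural absences
#' of the Bernoulli part, not as missing values: `NA`/`NaN` entries are
#' rejected rather than coerced, since silently mapping them to zero would
#' corrupt the presence/absence model.
#'
#' @param X numeric matrix (or data frame coercible to one) with `n` rows
#'   (observations) and `p` columns (variables).  All entries must be
#'   finite and nonnegative; zeros encode absence.
#' @param groups vector of length `n` with the group label of each row.
#'   Coerced to a factor; every level must occur at least once.
#'
#' @return An object of class `"sc_dataset"`: a list with components `X`,
#'   `Xlog` (log-abundances, `NA` where absent), `Y` (0/1 presence matrix),
#'   `groups` (factor), `n`, `p`, `K`, `nk` (per-group sizes), `nik`
#'   (per-row number of present components) and `var_names`.
#'
#' @examples
#' X <- matrix(c(0, 2.5, 1.0,
#'               1.2, 0, 3.0), nrow = 2, byrow = TRUE)
#' d <- sc_dataset(X, groups = c("a", "b"))
#' d$Y
#' @export
sc_dataset <- function(X, groups) {
  X <- as.matrix(X)
  if (!is.numeric(X))
    stop_data("`X` must be a numeric matrix")
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop_data(sprintf(
      "missing value (NA/NaN) at row %d, column %d: zeros encode absence, missing values are not allowed",
      bad[1L], bad[2L]))
  }
  if (any(!is.finite(X)))
    stop_data("`X` contains non-finite entries")
  if (any(X < 0)) {
    bad <- which(X < 0, arr.ind = TRUE)[1L, ]
    stop_data(sprintf("negative value %g at row %d, column '%s'",
                      X[bad[1L], bad[2L]], bad[1L],
                      colname_or_index(X, bad[2L])))
  }
  n <- nrow(X)
  p <- ncol(X)
  if (length(groups) != n)
    stop_data(sprintf("`groups` has length %d but `X` has %d rows",
                      length(groups), n))
  g <- droplevels(as.factor(groups))
  if (is.null(colnames(X)))
    colnames(X) <- paste0("v", seq_len(p))

  Y <- (X > 0) * 1
  Xlog <- X
  Xlog[Y == 0] <- NA_real_
  Xlog <- log(Xlog)
  dimnames(Xlog) <- dimnames(X)

  structure(list(
    X = X, Xlog = Xlog, Y = Y,
    groups = g, n = n, p = p,
    K = nlevels(g), nk = as.integer(table(g)),
    nik = as.integer(rowSums(Y)),
    var_names = colnames(X)
  ), class = "sc_dataset")
}

colname_or_index <- function(X, j) {
  if (is.null(colnames(X))) as.character(j) else colnames(X)[j]
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("Semicontinuous dataset: n = %d, p = %d, K = %d group%s (%s)\n",
              x$n, x$p, x$K, if (x$K > 1) "s" else "",
              paste(sprintf("%s: %d", levels(x$groups), x$nk), collapse = ", ")))
  cat(sprintf("Zero fraction: %.3f\n", mean(x$Y == 0)))
  invisible(x)
}

# Column subset preserving the sc_dataset invariants.
sc_subset_cols <- function(data, keep) {
  out <- data
  out$X <- data$X[, keep, drop = FALSE]
  out$Xlog <- data$Xlog[, keep, drop = FALSE]
  out$Y <- data$Y[, keep, drop = FALSE]
  out$p <- ncol(out$X)
  out$nik <- as.integer(rowSums(out$Y))
  out$var_names <- colnames(out$X)
  out
}

# Internal: log-abundance matrix with zeros at absences (dense input for the
# compiled routines).
sc_zmat <- function(data) {
  Z <- data$Xlog
  Z[data$Y == 0] <- 0
  Z
}

assert_sc_dataset <- function(data) {
  if (!inherits(data, "sc_dataset"))
    stop_data("expected an object created by `sc_dataset()`")
  invisible(data)
}
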