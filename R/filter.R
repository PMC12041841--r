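#' Pairwise co-observation filter
#'
#' The entry-wise denominators of the covariance estimator require every
#' pair of retained variables to be simultaneously present in at least one
#' observation (pooled across groups).  Variables violating the condition
#' are removed greedily, starting from those with the largest number of
#' absent components; ties are broken by removing the largest column index,
#' so the result does not depend on row order.  Columns with no presence at
#' all are removed first.
#'
#' @param data an [sc_dataset()].
#' @return A list with components `data` (the filtered dataset) and
#'   `report` (class `"sc_filter_report"`): removed variable indices, names
#'   and reasons, and the retained dimension `p_star`.
#' @seealso [scmanova()], which applies this filter automatically.
#' @export
sc_filter <- function(data) {
  assert_sc_dataset(data)
  p <- data$p
  co <- crossprod(data$Y)            # co-observation counts, diag = presences
  absent <- data$n - diag(co)

  retained <- rep(TRUE, p)
  removed <- integer(0)
  reason <- character(0)

  never <- which(diag(co) == 0)
  if (length(never)) {
    retained[never] <- FALSE
    removed <- c(removed, never)
    reason <- c(reason, rep("never present", length(never)))
  }

  repeat {
    idx <- which(retained)
    if (length(idx) < 2L) break
    sub <- co[idx, idx, drop = FALSE]
    diag(sub) <- 1
    viol <- which(sub == 0, arr.ind = TRUE)
    if (nrow(viol) == 0L) break
    vcols <- idx[unique(c(viol[, 1L], viol[, 2L]))]
    # most absences first; ties -> largest column index
    drop_j <- vcols[order(-absent[vcols], -vcols)][1L]
    retained[drop_j] <- FALSE
    removed <- c(removed, drop_j)
    reason <- c(reason, "pairwise support")
  }

  if (sum(retained) < 2L)
    stop_degenerate(sprintf(
      "fewer than 2 variables survive the pairwise co-observation filter (%d of %d)",
      sum(retained), p))

  report <- structure(list(
    removed = data.frame(
      index = removed,
      name = data$var_names[removed],
      reason = reason,
      stringsAsFactors = FALSE),
    p_star = sum(retained),
    p = p
  ), class = "sc_filter_report")

  list(data = sc_subset_cols(data, which(retained)), report = report)
}

#' @export
print.sc_filter_report <- function(x, ...) {
  cat(sprintf("Pairwise-support filter: retained %d of %d variables (p* = %d)\n",
              x$p_star, x$p, x$p_star))
  if (nrow(x$removed)) {
    cat("Removed:\n")
    print(x$removed, row.names = FALSE)
  }
  invisible(x)
}

# Columns with at least one presence in every group; needed for the
# group-specific means of the alternative model.
group_present_cols <- function(data) {
  cnt <- rowsum(data$Y, data$groups)
  which(apply(cnt > 0, 2L, all))
}
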