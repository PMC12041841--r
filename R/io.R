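#' Read a semicontinuous dataset from a delimited text file
#'
#' Reads a CSV/TSV matrix (rows = observations, columns = variables, with
#' a header of variable names) and resolves group labels from a designated
#' column, a separate single-column file (one label per line, no header),
#' or a vector supplied directly.
#'
#' @param file path to the data file.
#' @param groups name of the label column in `file`, path to a separate
#'   label file, or a vector of labels of matching length.
#' @param sep field separator; when `NULL` it is sniffed from the first
#'   line (tab if present, comma otherwise).
#' @return an [sc_dataset()]; column names are preserved so removed
#'   variables can be reported by name.
#' @export
read_sc_dataset <- function(file, groups, sep = NULL) {
  if (!file.exists(file))
    stop_data(sprintf("input file '%s' does not exist", file))
  if (is.null(sep)) {
    first <- readLines(file, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (length(groups) == 1L && is.character(groups)) {
    if (groups %in% colnames(df)) {
      g <- df[[groups]]
      df <- df[, setdiff(colnames(df), groups), drop = FALSE]
    } else if (file.exists(groups)) {
      g <- readLines(groups)
      g <- g[nzchar(g)]
      if (length(g) != nrow(df))
        stop_data(sprintf(
          "label file '%s' has %d labels but the data has %d rows",
          groups, length(g), nrow(df)))
    } else {
      stop_data(sprintf(
        "`groups` ('%s') is neither a column of '%s' nor an existing file",
        groups, file))
    }
  } else {
    g <- groups
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      coerced <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(coerced) & !is.na(df[[j]]))[1L]
      stop_data(sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        df[[j]][bad], bad, colnames(df)[j]))
    }
  }
  sc_dataset(as.matrix(df), g)
}

#' Write a semicontinuous dataset to delimited text
#'
#' Inverse of [read_sc_dataset()]: the group labels go into a leading
#' `group` column.
#'
#' @param data an [sc_dataset()].
#' @param file output path.
#' @param sep field separator.
#' @export
write_sc_dataset <- function(data, file, sep = ",") {
  assert_sc_dataset(data)
  df <- data.frame(group = as.character(data$groups),
                   data$X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Schema-stable list representation of a test result (shared by the JSON
# writer and the CLI).
sc_result_json <- function(result) {
  stopifnot(inherits(result, "scmanova"))
  list(
    statistic = result$statistic,
    p_value = result$p_value,
    p_value_mode = result$p_value_mode,
    lambda_hat = result$lambda_hat,
    lambda0_hat = result$lambda0_hat,
    p_star = result$p_star,
    removed = if (nrow(result$removed)) lapply(seq_len(nrow(result$removed)),
      function(i) list(name = result$removed$name[i],
                       reason = result$removed$reason[i])) else list(),
    B = result$B,
    seed = result$seed,
    n = result$n,
    K = result$K,
    perm_failures = result$perm_failures,
    config = list(
      reselect = result$config$reselect,
      p_value = result$config$p_value,
      penalized_ratio = result$config$penalized_ratio,
      lambda_search = result$config$lambda_search,
      lambda_grid = result$config$lambda_grid,
      lambda0_grid = result$config$lambda0_grid)
  )
}

#' Write a test result as JSON
#'
#' Serializes a [scmanova()] result (statistic, p-value, selected
#' penalties, retained dimension, removed variables by name, and a full
#' configuration echo) to a machine-parseable JSON file.
#'
#' @param result a `"scmanova"` object.
#' @param file output path.
#' @export
write_sc_result <- function(result, file) {
  jsonlite::write_json(sc_result_json(result), file,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(file)
}
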