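# Plain-text import/export of the package's objects.

#' Read / write a response matrix CSV
#'
#' Header row of item ids, one row per examinee, `NA` token for missing
#' cells, 0/1 integers otherwise.
#'
#' @param path file path.
#' @param na token representing missingness (default "NA").
#' @return `read_response_matrix` returns a numeric matrix over
#'   \{0, 1, NA\}.
#' @export
read_response_matrix <- function(path, na = "NA") {
  m <- as.matrix(read.csv(path, na.strings = na, check.names = FALSE))
  check_response_matrix(m)
}

#' @param x response matrix.
#' @rdname read_response_matrix
#' @export
write_response_matrix <- function(x, path, na = "NA") {
  x <- check_response_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  write.csv(as.data.frame(x), path, row.names = FALSE, na = na)
  invisible(path)
}

#' Read a Q-matrix CSV
#'
#' J rows by K columns of 0/1, no row index column; a header row is
#' tolerated.
#'
#' @param path file path.
#' @param header whether the file has a header row (default FALSE).
#' @return A binary matrix.
#' @export
read_q_matrix <- function(path, header = FALSE) {
  q <- as.matrix(read.csv(path, header = header))
  dimnames(q) <- NULL
  check_q_matrix(q)
}

#' Export a DINA fit
#'
#' Writes the item parameters and class prior as JSON and, when `map_csv`
#' is given, the MAP profiles as CSV.
#'
#' @param fit a [fit_dina_em()] result.
#' @param json_path output path for the JSON summary.
#' @param map_csv optional output path for the MAP profile CSV.
#' @export
write_dina_fit <- function(fit, json_path, map_csv = NULL) {
  stopifnot(inherits(fit, "dina_fit"))
  jsonlite::write_json(
    list(s = fit$s, g = fit$g, prior = fit$prior,
         converged = fit$converged, n_iter = fit$n_iter),
    json_path, digits = NA, auto_unbox = TRUE)
  if (!is.null(map_csv)) {
    prof <- estimate_profiles_map(fit)
    colnames(prof) <- paste0("attr", seq_len(ncol(prof)))
    write.csv(as.data.frame(prof), map_csv, row.names = FALSE)
  }
  invisible(json_path)
}
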