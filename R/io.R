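#' Read droplet counts from a TSV or JSON file
#'
#' Two on-disk forms are accepted: a 2-column key/value TSV (no header; keys
#' `n_type1`, `n_type2`, `n_mixed`) or a JSON object with the same keys.
#' The format is chosen by extension (`.json` vs anything else).
#'
#' @param path File to read.
#' @return A [droplet_counts()].
#' @export
read_droplet_counts <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("no such file: ", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("key", "value"))
    stats::setNames(as.list(df$value), df$key)
  }
  need <- c("n_type1", "n_type2", "n_mixed")
  if (!all(need %in% names(vals)))
    stop_validation(paste0("counts file must provide keys ",
                           paste(need, collapse = ", "), "; missing: ",
                           paste(setdiff(need, names(vals)), collapse = ", ")))
  droplet_counts(as.numeric(vals$n_type1), as.numeric(vals$n_type2),
                 as.numeric(vals$n_mixed))
}

estimate_as_list <- function(est) {
  list(
    multiplet_frequency = est$multiplet_frequency,
    multiplet_frequency_display = sprintf("%.3f", est$multiplet_frequency),
    mu1 = est$load$mu1,
    mu2 = est$load$mu2,
    n_total_droplets = est$load$n_droplets,
    n_nonempty = est$counts$n_nonempty,
    n_type1 = est$counts$n_type1,
    n_type2 = est$counts$n_type2,
    n_mixed = est$counts$n_mixed,
    doublet_approximation = est$doublet_approximation,
    doublet_approximation_display = sprintf("%.3f", est$doublet_approximation))
}

#' Write a multiplet estimate to JSON and/or a TSV report
#'
#' The JSON object is the machine interface (full precision plus 3-decimal
#' display strings); the TSV is a human-readable key/value report. Files are
#' written to a temporary path and renamed into place, so no partial output
#' survives an error.
#'
#' @param est A `multiplet_estimate` from [estimate_from_counts()].
#' @param json,tsv Output paths; `NULL` to skip either.
#' @return Invisibly, `est`.
#' @export
write_estimate <- function(est, json = NULL, tsv = NULL) {
  stopifnot(inherits(est, "multiplet_estimate"))
  payload <- estimate_as_list(est)
  if (!is.null(json)) {
    write_atomically(json, function(tmp)
      jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA))
  }
  if (!is.null(tsv)) {
    write_atomically(tsv, function(tmp) {
      lines <- vapply(names(payload), function(k)
        paste(k, format(payload[[k]], digits = 15), sep = "\t"), character(1))
      writeLines(lines, tmp)
    })
  }
  invisible(est)
}

write_atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {  # cross-device fallback
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
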