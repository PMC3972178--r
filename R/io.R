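# Result tables on disk: deterministic column order, tab-separated, headers
# documented in the writers below.

PROBE_RESULT_COLS <- c("probe_id", "log2fc", "s2", "df", "posterior_var",
                       "moderated_t", "p_value", "probe_call")
PROMOTER_RESULT_COLS <- c("promoter_id", "gene_symbol", "n_probes", "p_up",
                          "p_down", "direction", "promoter_p", "fdr",
                          "n_called_probes", "dm_call", "strict_call",
                          "single_probe")

#' Write a result table as TSV
#'
#' Columns are reordered to the documented layout for probe and promoter
#' results (other tables keep their column order); an empty result set
#' produces a header-only file.
#'
#' @param results data.frame of results.
#' @param path Output path.
#' @param columns Optional explicit column order.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, columns = NULL) {
  stopifnot(is.data.frame(results))
  if (is.null(columns)) {
    columns <- if (all(PROBE_RESULT_COLS %in% names(results))) {
      PROBE_RESULT_COLS
    } else if (all(PROMOTER_RESULT_COLS %in% names(results))) {
      PROMOTER_RESULT_COLS
    } else {
      names(results)
    }
  }
  miss <- setdiff(columns, names(results))
  if (length(miss)) {
    stop("result table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.table(results[, columns, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write results to '", path, "': ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Read promoter results back from TSV
#'
#' Inverse of [write_results()] for promoter tables; call columns are
#' restored as logicals so re-read results reproduce calls exactly.
#'
#' @param path TSV written by [write_results()].
#' @return data.frame of promoter results.
#' @export
read_promoter_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(PROMOTER_RESULT_COLS, names(tab))
  if (length(miss)) {
    stop("not a promoter result table; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c("dm_call", "strict_call", "single_probe")) {
    tab[[col]] <- as.logical(tab[[col]])
  }
  tab
}
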