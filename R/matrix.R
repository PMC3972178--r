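# Methylation matrix: probes x samples of log2(MeDIP/input) ratios with a
# two-group design. Missing values are a hard error; imputation is out of
# scope because upstream array processing delivers complete matrices.

#' Construct a methylation matrix
#'
#' @param values Numeric matrix, probes in rows and samples in columns.
#' @param probe_ids Character vector aligned to rows.
#' @param sample_ids Character vector aligned to columns.
#' @param group_labels Character vector per sample, values `"CPA"` (case) or
#'   `"control"`.
#' @return A list of class `medip_matrix`.
#' @export
medip_matrix <- function(values, probe_ids, sample_ids, group_labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(probe_ids) != nrow(values)) {
    stop("probe_ids length does not match row count", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values) ||
      length(group_labels) != ncol(values)) {
    stop("sample_ids/group_labels length does not match column count",
         call. = FALSE)
  }
  if (anyNA(values)) {
    stop("methylation matrix contains missing values; imputation is not supported",
         call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicated probe_id in matrix", call. = FALSE)
  }
  if (!all(group_labels %in% c("CPA", "control"))) {
    stop("group labels must be 'CPA' or 'control' (map other labels via the design file)",
         call. = FALSE)
  }
  n_per <- table(factor(group_labels, levels = c("CPA", "control")))
  if (any(n_per < 2)) {
    stop("each group needs at least 2 samples (got CPA=", n_per["CPA"],
         ", control=", n_per["control"], ")", call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values,
                 probe_ids = as.character(probe_ids),
                 sample_ids = as.character(sample_ids),
                 group_labels = as.character(group_labels)),
            class = "medip_matrix")
}

#' Read a methylation matrix and its design
#'
#' @param matrix_tsv TSV whose first column is `probe_id` followed by one
#'   numeric column per sample (header row of sample ids).
#' @param design_tsv TSV with columns `sample_id` and `group`. Groups other
#'   than `CPA`/`control` are accepted when `case_label` names which level is
#'   the case group; the other level becomes `control`.
#' @param case_label Optional label in the design's `group` column to map to
#'   `CPA`.
#' @return A `medip_matrix` whose columns follow the design file order.
#' @export
read_matrix <- function(matrix_tsv, design_tsv, case_label = NULL) {
  for (p in c(matrix_tsv, design_tsv)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  tab <- utils::read.delim(matrix_tsv, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "probe_id") {
    stop("matrix TSV must start with a 'probe_id' column", call. = FALSE)
  }
  design <- utils::read.delim(design_tsv, header = TRUE,
                              stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design file needs columns 'sample_id' and 'group'", call. = FALSE)
  }
  missing_samples <- setdiff(design$sample_id, names(tab)[-1])
  if (length(missing_samples)) {
    stop("design sample(s) absent from matrix: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab)[-1], design$sample_id)
  if (length(extra)) {
    warning("matrix column(s) not in design dropped: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }

  groups <- design$group
  if (!all(groups %in% c("CPA", "control"))) {
    lv <- unique(groups)
    if (length(lv) != 2) {
      stop("design must define exactly two groups, found: ",
           paste(lv, collapse = ", "), call. = FALSE)
    }
    if (is.null(case_label) || !case_label %in% lv) {
      stop("non-standard group labels (", paste(lv, collapse = ", "),
           "); supply 'case_label' to name the case group", call. = FALSE)
    }
    groups <- ifelse(groups == case_label, "CPA", "control")
  }

  vals <- as.matrix(tab[, design$sample_id, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("matrix contains non-numeric cells", call. = FALSE)
  }
  medip_matrix(vals, tab$probe_id, design$sample_id, groups)
}

#' Write a methylation matrix and design to disk
#'
#' Writes `matrix.tsv` (probe_id + one column per sample) and `design.tsv`
#' (sample_id, group) into `dir`. Values round-trip through [read_matrix()]
#' to better than 1e-12.
#'
#' @param mat A `medip_matrix`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_matrix <- function(mat, dir) {
  stopifnot(inherits(mat, "medip_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             design = file.path(dir, "design.tsv"))
  tab <- data.frame(probe_id = mat$probe_ids,
                    format(mat$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  names(tab) <- c("probe_id", mat$sample_ids)
  utils::write.table(tab, paths["matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = mat$sample_ids,
                                group = mat$group_labels),
                     paths["design"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# column indices of the two groups, case first
group_indices <- function(mat) {
  list(cpa = which(mat$group_labels == "CPA"),
       control = which(mat$group_labels == "control"))
}
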