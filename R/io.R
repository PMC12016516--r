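#' Construct a spectral count table
#'
#' A spectral count table is a proteins x runs matrix of non-negative integer
#' spectral counts with unique protein identifiers as row names and unique
#' run identifiers as column names. Rows that are zero in every run are legal
#' observations and are retained.
#'
#' @param counts matrix (or data.frame) of non-negative integers; row names
#'   are protein identifiers, column names run identifiers.
#' @return An integer matrix of class `spectral_counts`.
#' @export
#' @examples
#' m <- matrix(c(4L, 0L, 0L, 0L, 7L, 2L), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("TK0001", "TK0002", "TK0003"), c("r1", "r2")))
#' spectral_counts(m)
spectral_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_validation("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("counts must carry protein row names and run column names")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop_validation("duplicated protein identifier: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop_validation("duplicated run identifier: ", dup)
  }
  if (anyNA(counts)) stop_validation("counts must not contain missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation(sprintf(
      "counts must be non-negative integers; offending cell: protein '%s', run '%s'",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]
    ))
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("spectral_counts", class(counts))
  counts
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat(sprintf("Spectral count table: %d proteins x %d runs\n", nrow(x), ncol(x)))
  cat(sprintf("  total counts %d, zero cells %.1f%%\n",
              sum(x), 100 * mean(x == 0)))
  invisible(x)
}

#' Construct a sample sheet
#'
#' Binds each MS run to its strain (tagged gene or `"PARENTAL"`), growth
#' condition (presence of elemental sulfur and of pyruvate), replicate index
#' and role. Control runs must come from the parental strain; experimental
#' runs must not.
#'
#' @param df data.frame with columns `run_id`, `strain`, `role`
#'   (`"experimental"` or `"control"`), `sulfur` (logical), `pyruvate`
#'   (logical), `replicate` (positive integer).
#' @return A data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  required <- c("run_id", "strain", "role", "sulfur", "pyruvate", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_validation("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  df$run_id <- as.character(df$run_id)
  df$strain <- as.character(df$strain)
  df$role <- as.character(df$role)
  df$sulfur <- parse_logical(df$sulfur, "sulfur")
  df$pyruvate <- parse_logical(df$pyruvate, "pyruvate")
  df$replicate <- as.integer(df$replicate)

  if (anyDuplicated(df$run_id)) {
    stop_validation("duplicated run_id: ", df$run_id[duplicated(df$run_id)][1L])
  }
  if (!all(df$role %in% c("experimental", "control"))) {
    stop_validation("role must be 'experimental' or 'control'")
  }
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    stop_validation("replicate must be a positive integer")
  }
  ctrl <- df$role == "control"
  if (any(df$strain[ctrl] != "PARENTAL")) {
    stop_validation("control runs must reference the PARENTAL strain")
  }
  if (any(df$strain[!ctrl] == "PARENTAL")) {
    stop_validation("experimental runs must not reference the PARENTAL strain")
  }
  key <- paste(df$strain, df$sulfur, df$pyruvate, df$replicate)
  if (anyDuplicated(key)) {
    stop_validation("duplicate (strain, sulfur, pyruvate, replicate): ",
                    key[duplicated(key)][1L])
  }
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

parse_logical <- function(x, name) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  xs <- tolower(trimws(as.character(x)))
  out[xs %in% c("true", "t", "1", "yes")] <- TRUE
  out[xs %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop_validation(name, " must be logical (TRUE/FALSE)")
  out
}

#' Read a spectral count table from TSV
#'
#' Expects a header row of run identifiers, a first column of protein
#' identifiers, and explicit integer counts (missing values are not allowed;
#' zeros must be written out). When a sample sheet is supplied, every run in
#' the table must appear in the sheet.
#'
#' @param path TSV file path.
#' @param sheet optional [sample_sheet()] used to cross-check run identifiers.
#' @param warn_ids warn when protein identifiers deviate from the TK-number
#'   convention (`TK` followed by digits). Identifiers are otherwise opaque.
#' @return A `spectral_counts` matrix.
#' @export
read_count_table <- function(path, sheet = NULL, warn_ids = TRUE) {
  check_file_exists(path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop_io("count table needs a protein column plus >=1 run column: ", path)
  ids <- df[[1L]]
  runs <- colnames(df)[-1L]
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_validation(sprintf(
      "non-integer or negative count in '%s': protein '%s', run '%s' (value '%s')",
      path, ids[bad[1L, 1L]], runs[bad[1L, 2L]], df[bad[1L, 1L], bad[1L, 2L] + 1L]
    ))
  }
  dimnames(num) <- list(ids, runs)
  tab <- spectral_counts(num)
  if (warn_ids && !all(grepl("^TK[0-9]+$", ids))) {
    warning("protein identifiers deviate from the TK-number convention (TK followed by digits)",
            call. = FALSE)
  }
  if (!is.null(sheet)) {
    missing_runs <- setdiff(runs, sheet$run_id)
    if (length(missing_runs)) {
      stop_validation("run(s) absent from the sample sheet: ",
                      paste(missing_runs, collapse = ", "))
    }
  }
  tab
}

#' Write a spectral count table to TSV
#' @param x `spectral_counts` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#' @param path TSV with columns run_id, strain, role, sulfur, pyruvate, replicate.
#' @return A `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  check_file_exists(path)
  sample_sheet(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = ""))
}

#' Write a sample sheet to TSV
#' @param x `sample_sheet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select experimental and control runs for a bait in one condition
#'
#' Resolves the bait's tagged purifications and the parental control
#' purifications matched to the same growth condition.
#'
#' @param table `spectral_counts` matrix (runs are checked for presence).
#' @param sheet `sample_sheet`.
#' @param bait tagged gene identifier.
#' @param sulfur,pyruvate growth condition flags.
#' @return A list with character vectors `experimental` and `control`.
#' @export
select_group <- function(table, sheet, bait, sulfur, pyruvate) {
  check_flag(sulfur, "sulfur"); check_flag(pyruvate, "pyruvate")
  cond <- sprintf("%sS/%sP", if (sulfur) "+" else "-", if (pyruvate) "+" else "-")
  exp_runs <- sheet$run_id[sheet$role == "experimental" & sheet$strain == bait &
                             sheet$sulfur == sulfur & sheet$pyruvate == pyruvate]
  if (!length(exp_runs)) {
    apms_stop(sprintf("no experimental runs for bait %s in %s", bait, cond),
              "apms_missing_group_error")
  }
  ctrl_runs <- sheet$run_id[sheet$role == "control" &
                              sheet$sulfur == sulfur & sheet$pyruvate == pyruvate]
  if (!length(ctrl_runs)) {
    apms_stop(sprintf("no parental control runs in %s for bait %s", cond, bait),
              "apms_missing_control_error")
  }
  absent <- setdiff(c(exp_runs, ctrl_runs), colnames(table))
  if (length(absent)) {
    stop_validation("run(s) in sample sheet but absent from count table: ",
                    paste(absent, collapse = ", "))
  }
  list(experimental = exp_runs, control = ctrl_runs)
}

#' Read a target-protein table from TSV
#'
#' @param path TSV with columns `gene_id`, `protein`, `complex_acronym`
#'   (semicolon-separated when a gene belongs to several complexes),
#'   `subunit`, `tag_terminus` (`C` or `N`).
#' @return A data.frame of class `target_table`.
#' @export
read_target_table <- function(path) {
  check_file_exists(path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  required <- c("gene_id", "protein", "complex_acronym", "subunit", "tag_terminus")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_validation("target table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop_validation("duplicated gene_id in target table: ",
                    df$gene_id[duplicated(df$gene_id)][1L])
  }
  if (!all(df$tag_terminus %in% c("C", "N"))) {
    stop_validation("tag_terminus must be 'C' or 'N'")
  }
  class(df) <- c("target_table", "data.frame")
  df
}
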