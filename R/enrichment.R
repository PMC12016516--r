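#' One-sided Fisher exact test for spectral-count enrichment
#'
#' Tests whether a protein's pooled spectral counts are enriched in
#' experimental over control purifications. The 2x2 table is
#' (this protein vs all other proteins) x (experimental vs control), with
#' counts pooled (summed) over replicate runs. Under the null the protein's
#' experimental count follows a hypergeometric distribution conditioned on
#' the table margins; the one-sided P value is the upper tail at the observed
#' count (enrichment in experimental).
#'
#' All four arguments are vectorized and recycled.
#'
#' @param a protein counts pooled over experimental runs.
#' @param b protein counts pooled over control runs.
#' @param c_other all-other-protein counts pooled over experimental runs.
#' @param d_other all-other-protein counts pooled over control runs.
#' @return P values in (0, 1].
#' @export
#' @examples
#' fisher_onesided(5, 0, 95, 100)
#' fisher_onesided(0, 0, 100, 100)  # no protein counts at all -> P = 1
fisher_onesided <- function(a, b, c_other, d_other) {
  n <- max(length(a), length(b), length(c_other), length(d_other))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c_other <- rep_len(c_other, n); d_other <- rep_len(d_other, n)
  cells <- cbind(a, b, c_other, d_other)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop_validation("contingency cells must be non-negative integers")
  }
  if (any(rowSums(cells) == 0)) {
    stop_validation("undefined test: all four contingency cells are zero")
  }
  # Upper tail P(X >= a) for X ~ Hypergeometric(m = a+b, n = c+d, k = a+c)
  p <- stats::phyper(a - 1, a + b, c_other + d_other, a + c_other,
                     lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; a validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`. Adjusted values are
#' order-preserving, at least as large as the raw values, and capped at 1.
#'
#' @param p vector of P values in (0, 1].
#' @return Adjusted P values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop_validation("empty P value vector")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop_validation("P values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_exp + pseudocount) / (mean_ctrl + pseudocount))`. The
#' pseudocount keeps the ratio finite for preys absent from controls, which
#' is the typical signature of a true partner.
#'
#' @param mean_exp,mean_ctrl mean spectral counts (>= 0), vectorized.
#' @param pseudocount positive offset added to both means (default 0.5).
#' @return log2 ratios.
#' @export
#' @examples
#' log2_fold_change(8, 0)          # log2(8.5 / 0.5) = log2(17)
#' log2_fold_change(400, 100)      # just under 2
log2_fold_change <- function(mean_exp, mean_ctrl, pseudocount = 0.5) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop_validation("pseudocount must be a single positive number")
  }
  if (anyNA(c(mean_exp, mean_ctrl)) || any(mean_exp < 0) || any(mean_ctrl < 0)) {
    stop_validation("means must be non-negative")
  }
  log2((mean_exp + pseudocount) / (mean_ctrl + pseudocount))
}

#' Score one bait in one condition
#'
#' For every protein detected in at least one experimental run, pools its
#' spectral counts across the bait's experimental runs and across the matched
#' parental control runs, tests enrichment with [fisher_onesided()], adjusts
#' P values across the tested proteins with [bh_adjust()], and computes the
#' pseudocounted log2 fold change of mean counts. A protein is significant
#' when its P value (adjusted or raw per `config$p_mode`) is below
#' `config$alpha` and its log2 fold change is at least `config$fc_min`.
#'
#' @param table `spectral_counts` matrix.
#' @param sheet `sample_sheet`.
#' @param bait tagged gene identifier.
#' @param sulfur,pyruvate growth condition flags.
#' @param config [pipeline_config()].
#' @return A data.frame of class `enrichment_records`, one row per tested
#'   protein, with columns `protein_id`, `bait_gene`, `sulfur`, `pyruvate`,
#'   `n_detected`, `n_replicates`, `mean_exp`, `mean_ctrl`, `log2fc`,
#'   `p_raw`, `p_adj`, `significant`, `rescued`, `rank` (NA until
#'   [assign_ranks()] is applied).
#' @export
score_bait <- function(table, sheet, bait, sulfur, pyruvate,
                       config = pipeline_config()) {
  stopifnot(inherits(config, "apms_config"))
  grp <- select_group(table, sheet, bait, sulfur, pyruvate)
  X <- unclass(table)[, grp$experimental, drop = FALSE]
  Y <- unclass(table)[, grp$control, drop = FALSE]

  n_detected <- rowSums(X >= config$detection_floor)
  tested <- n_detected >= 1L
  total_exp <- sum(X)
  total_ctrl <- sum(Y)

  if (!any(tested)) {
    return(empty_records())
  }

  a <- rowSums(X)[tested]
  b <- rowSums(Y)[tested]
  p_raw <- fisher_onesided(a, b, total_exp - a, total_ctrl - b)
  p_adj <- bh_adjust(p_raw)

  if (config$normalize) {
    X <- scale_to_mean_library(X)
    Y <- scale_to_mean_library(Y)
  }
  mean_exp <- rowMeans(X)[tested]
  mean_ctrl <- rowMeans(Y)[tested]
  log2fc <- log2_fold_change(mean_exp, mean_ctrl, config$pseudocount)

  p_used <- if (config$p_mode == "adjusted") p_adj else p_raw
  significant <- p_used < config$alpha & log2fc >= config$fc_min

  out <- data.frame(
    protein_id = rownames(X)[tested],
    bait_gene = bait,
    sulfur = sulfur,
    pyruvate = pyruvate,
    n_detected = as.integer(n_detected[tested]),
    n_replicates = ncol(X),
    mean_exp = unname(mean_exp),
    mean_ctrl = unname(mean_ctrl),
    log2fc = unname(log2fc),
    p_raw = unname(p_raw),
    p_adj = unname(p_adj),
    significant = unname(significant),
    rescued = FALSE,
    rank = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("enrichment_records", "data.frame")
  out
}

scale_to_mean_library <- function(m) {
  libs <- colSums(m)
  if (all(libs == 0)) return(m)
  sweep(m, 2L, mean(libs) / pmax(libs, 1), `*`)
}

empty_records <- function() {
  out <- data.frame(
    protein_id = character(), bait_gene = character(),
    sulfur = logical(), pyruvate = logical(),
    n_detected = integer(), n_replicates = integer(),
    mean_exp = numeric(), mean_ctrl = numeric(), log2fc = numeric(),
    p_raw = numeric(), p_adj = numeric(),
    significant = logical(), rescued = logical(), rank = integer(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Rescue a bait that narrowly misses the fold-change threshold
#'
#' When the tagged bait itself passes the P-value criterion but falls short
#' of the minimum log2 fold change, the fold-change threshold for that
#' bait/condition is lowered to the bait's own log2 fold change and
#' significance is recomputed: the bait and every other protein within the
#' adjusted range become significant and are flagged `rescued`. Rescue is
#' only attempted when the bait's log2 fold change is at least
#' `config$rescue_floor`, so a failed purification cannot drag the threshold
#' towards zero. Records are returned unchanged when the bait already passes
#' or fails the P criterion; if the bait was not detected at all, a warning
#' is raised and the records are returned unchanged.
#'
#' @param records `enrichment_records` for a single bait/condition.
#' @param config [pipeline_config()].
#' @return The (possibly updated) records; a rescue event is recorded in the
#'   `"rescue"` attribute.
#' @export
rescue_bait <- function(records, config = pipeline_config()) {
  stopifnot(inherits(records, "enrichment_records"))
  if (!nrow(records)) return(records)
  bait <- unique(records$bait_gene)
  if (length(bait) != 1L) {
    stop_validation("rescue_bait expects records from a single bait/condition")
  }
  i <- which(records$protein_id == bait)
  if (!length(i)) {
    warning(sprintf("bait %s not detected in its own purification; no rescue applied", bait),
            call. = FALSE)
    return(records)
  }
  p_used <- if (config$p_mode == "adjusted") records$p_adj else records$p_raw
  bait_fc <- records$log2fc[i]
  bait_passes_p <- p_used[i] < config$alpha

  if (records$significant[i] || !bait_passes_p || bait_fc < config$rescue_floor) {
    return(records)
  }
  newly <- !records$significant & p_used < config$alpha & records$log2fc >= bait_fc
  records$significant[newly] <- TRUE
  records$rescued[newly] <- TRUE
  attr(records, "rescue") <- list(bait = bait, threshold = bait_fc,
                                  n_rescued = sum(newly))
  message(sprintf("rescued bait %s: fold-change threshold lowered to %.3f (%d protein(s) added)",
                  bait, bait_fc, sum(newly)))
  records
}

#' Score every bait/condition in an experiment
#'
#' Runs [score_bait()], [rescue_bait()] and [assign_ranks()] for every
#' (bait, condition) combination present among the experimental runs of the
#' sample sheet, and concatenates the per-comparison records. BH adjustment
#' is performed within each bait/condition comparison, matching the
#' per-purification testing design.
#'
#' @param table `spectral_counts` matrix.
#' @param sheet `sample_sheet`.
#' @param baits optional subset of tagged gene identifiers (default: all).
#' @param config [pipeline_config()].
#' @param rescue apply bait rescue (default TRUE).
#' @return Combined `enrichment_records` with ranks assigned to significant
#'   rows; rescue events are collected in the `"rescues"` attribute.
#' @export
score_all <- function(table, sheet, baits = NULL, config = pipeline_config(),
                      rescue = TRUE) {
  exp_rows <- sheet[sheet$role == "experimental", , drop = FALSE]
  combos <- unique(exp_rows[c("strain", "sulfur", "pyruvate")])
  if (!is.null(baits)) {
    unknown <- setdiff(baits, combos$strain)
    if (length(unknown)) {
      stop_validation("bait(s) absent from sample sheet: ", paste(unknown, collapse = ", "))
    }
    combos <- combos[combos$strain %in% baits, , drop = FALSE]
  }
  combos <- combos[order(combos$strain, !combos$sulfur, !combos$pyruvate), , drop = FALSE]

  rescues <- list()
  pieces <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    rec <- score_bait(table, sheet, combos$strain[k],
                      combos$sulfur[k], combos$pyruvate[k], config)
    if (rescue) {
      rec <- suppressMessages(rescue_bait(rec, config))
      ev <- attr(rec, "rescue")
      if (!is.null(ev)) rescues[[length(rescues) + 1L]] <- c(ev, sulfur = combos$sulfur[k],
                                                             pyruvate = combos$pyruvate[k])
    }
    pieces[[k]] <- assign_ranks(rec, config)
  }
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out)) out <- empty_records()
  class(out) <- c("enrichment_records", "data.frame")
  attr(out, "rescues") <- rescues
  out
}
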