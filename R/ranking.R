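#' Five-tier confidence rank for a significant association
#'
#' A significant bait-prey association earns the top rank of 5 when it meets
#' all three stringency categories: detected in all required experimental
#' replicates (default 3), P value at or below the strict level (default
#' 0.01), and log2 fold change at or above the strict threshold (default 4).
#' The rank drops by one point for each category not met; the replicate
#' category costs one point per missing replicate (detected in 1 of 3 costs
#' two points), which is how associations reach rank 1. Ranks are floored
#' at 1.
#'
#' @param n_detected experimental replicates in which the prey was detected.
#' @param p P value compared against `p_strict` (use the same adjusted or raw
#'   P that defined significance).
#' @param log2fc log2 fold change.
#' @param significant logical; all records must be significant - ranking an
#'   association that failed the significance thresholds is a contract error.
#' @param replicates_required,p_strict,fc_strict rank criteria (defaults 3,
#'   0.01, 4).
#' @return Integer ranks in 1..5, vectorized over the record fields.
#' @export
#' @examples
#' rank_score(3, 0.005, 4.5)  # all categories met -> 5
#' rank_score(3, 0.03, 4.5)   # one category short -> 4
#' rank_score(1, 0.03, 2.5)   # two replicates missing + two lax categories -> 1
rank_score <- function(n_detected, p, log2fc, significant = TRUE,
                       replicates_required = 3L, p_strict = 0.01, fc_strict = 4) {
  n <- max(length(n_detected), length(p), length(log2fc))
  n_detected <- rep_len(n_detected, n)
  p <- rep_len(p, n)
  log2fc <- rep_len(log2fc, n)
  significant <- rep_len(significant, n)
  if (!all(significant)) {
    stop_validation("rank_score is only defined for significant associations")
  }
  if (anyNA(c(n_detected, p, log2fc))) {
    stop_validation("rank_score fields must not be missing")
  }
  deductions <- pmax(0L, replicates_required - as.integer(n_detected)) +
    (p > p_strict) + (log2fc < fc_strict)
  as.integer(pmax(1L, 5L - deductions))
}

#' Assign ranks to scored records
#'
#' Fills the `rank` column of an `enrichment_records` table: significant
#' rows get their [rank_score()] (computed from the adjusted or raw P value
#' per `config$p_mode`); non-significant rows keep `NA`.
#'
#' @param records `enrichment_records`.
#' @param config [pipeline_config()].
#' @return The records with the `rank` column populated.
#' @export
assign_ranks <- function(records, config = pipeline_config()) {
  stopifnot(inherits(records, "enrichment_records"))
  if (!nrow(records)) return(records)
  sig <- records$significant
  records$rank <- NA_integer_
  if (any(sig)) {
    p_used <- if (config$p_mode == "adjusted") records$p_adj else records$p_raw
    records$rank[sig] <- rank_score(
      records$n_detected[sig], p_used[sig], records$log2fc[sig],
      replicates_required = config$replicates_required,
      p_strict = config$strict_alpha, fc_strict = config$fc_strict
    )
  }
  records
}

#' Rank distribution of significant associations
#'
#' Tallies significant associations by rank within each growth condition.
#' Tallies sum to the number of significant records; percentages sum to 100
#' within each condition (up to rounding).
#'
#' @param records `enrichment_records` with ranks assigned.
#' @param by_condition split tallies by (sulfur, pyruvate); when `FALSE`, a
#'   single overall tally is returned.
#' @return data.frame with columns `sulfur`, `pyruvate` (when split),
#'   `rank`, `n`, `pct`.
#' @export
rank_distribution <- function(records, by_condition = TRUE) {
  sig <- records[!is.na(records$rank) & records$significant, , drop = FALSE]
  tally <- function(sub) {
    n <- vapply(5:1, function(r) sum(sub$rank == r), integer(1))
    data.frame(rank = 5:1, n = n,
               pct = if (sum(n)) 100 * n / sum(n) else rep(0, 5))
  }
  if (!by_condition || !nrow(sig)) {
    out <- tally(sig)
    if (by_condition) out <- cbind(sulfur = NA, pyruvate = NA, out)
    return(out)
  }
  combos <- unique(sig[c("sulfur", "pyruvate")])
  combos <- combos[order(!combos$sulfur, !combos$pyruvate), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    sub <- sig[sig$sulfur == combos$sulfur[k] & sig$pyruvate == combos$pyruvate[k], ]
    cbind(sulfur = combos$sulfur[k], pyruvate = combos$pyruvate[k], tally(sub))
  }))
  rownames(out) <- NULL
  out
}

#' Per-bait rank summary
#'
#' One row per (bait, condition): total significant partners (the bait's own
#' protein is excluded from the partner count) and the tally at each rank.
#'
#' @param records `enrichment_records` with ranks assigned.
#' @return data.frame with columns `bait`, `sulfur`, `pyruvate`, `total`,
#'   `rank5` .. `rank1`.
#' @export
rank_summary <- function(records) {
  sig <- records[records$significant & !is.na(records$rank), , drop = FALSE]
  sig <- sig[sig$protein_id != sig$bait_gene, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(bait = character(), sulfur = logical(), pyruvate = logical(),
                      total = integer(), rank5 = integer(), rank4 = integer(),
                      rank3 = integer(), rank2 = integer(), rank1 = integer()))
  }
  combos <- unique(sig[c("bait_gene", "sulfur", "pyruvate")])
  combos <- combos[order(combos$bait_gene, !combos$sulfur, !combos$pyruvate), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    sub <- sig[sig$bait_gene == combos$bait_gene[k] &
                 sig$sulfur == combos$sulfur[k] &
                 sig$pyruvate == combos$pyruvate[k], ]
    counts <- vapply(5:1, function(r) sum(sub$rank == r), integer(1))
    data.frame(bait = combos$bait_gene[k], sulfur = combos$sulfur[k],
               pyruvate = combos$pyruvate[k], total = nrow(sub),
               rank5 = counts[1], rank4 = counts[2], rank3 = counts[3],
               rank2 = counts[4], rank1 = counts[5])
  }))
  rownames(out) <- NULL
  out
}
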