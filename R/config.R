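#' Pipeline configuration
#'
#' Collects every tunable threshold of the scoring, ranking and rescue
#' procedure. Defaults reproduce the published workflow: a prey is significant
#' when its BH-adjusted one-sided Fisher P value is below `alpha` (0.05) and
#' its log2 fold change is at least `fc_min` (2); the stricter tier used by
#' the rank score requires P at or below `strict_alpha` (0.01) and log2 fold
#' change at least `fc_strict` (4).
#'
#' @param alpha significance level applied to the (adjusted) Fisher P value.
#' @param strict_alpha stricter P threshold earning the rank-score P category;
#'   must be below `alpha`.
#' @param fc_min minimum log2 fold change (experimental over control) for
#'   significance.
#' @param fc_strict stricter log2 fold-change threshold earning the rank-score
#'   fold-change category; must exceed `fc_min`.
#' @param pseudocount added to both means before taking the log2 ratio, so
#'   preys absent from controls (the typical true partner) get a finite fold
#'   change.
#' @param rescue_floor minimum log2 fold change the bait itself must reach for
#'   threshold rescue to be considered; prevents a failed purification from
#'   dragging the fold-change threshold towards zero.
#' @param p_mode `"adjusted"` (default) compares BH-adjusted P values to the
#'   thresholds; `"raw"` uses unadjusted P values.
#' @param normalize if `TRUE`, per-run counts are scaled to the mean library
#'   size before means and fold changes are computed (the Fisher test always
#'   uses raw pooled counts). Off by default: the published workflow applies
#'   no between-run normalization.
#' @param detection_floor spectral counts at or above this value count a
#'   protein as detected in a run (default 1, i.e. any identified peptide).
#' @param replicates_required experimental replicates expected by the
#'   reproducibility category of the rank score (default 3).
#' @param min_rank default minimum rank retained by network exports.
#'
#' @return An object of class `apms_config` (a validated named list).
#' @seealso [score_bait()], [rank_score()], [rescue_bait()]
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$alpha
pipeline_config <- function(alpha = 0.05,
                            strict_alpha = 0.01,
                            fc_min = 2,
                            fc_strict = 4,
                            pseudocount = 0.5,
                            rescue_floor = 1,
                            p_mode = c("adjusted", "raw"),
                            normalize = FALSE,
                            detection_floor = 1L,
                            replicates_required = 3L,
                            min_rank = 1L) {
  p_mode <- match.arg(p_mode)
  num1 <- function(x, name, lo = -Inf, strict_lo = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop_validation(name, " must be a single number")
    }
    if (if (strict_lo) x <= lo else x < lo) {
      stop_validation(name, " must be ", if (strict_lo) "> " else ">= ", lo)
    }
    as.numeric(x)
  }
  alpha <- num1(alpha, "alpha", 0, TRUE)
  strict_alpha <- num1(strict_alpha, "strict_alpha", 0, TRUE)
  if (alpha > 1 || strict_alpha > 1) stop_validation("alpha levels must be in (0, 1]")
  if (strict_alpha >= alpha) stop_validation("strict_alpha must be below alpha")
  fc_min <- num1(fc_min, "fc_min")
  fc_strict <- num1(fc_strict, "fc_strict")
  if (fc_strict <= fc_min) stop_validation("fc_strict must exceed fc_min")
  pseudocount <- num1(pseudocount, "pseudocount", 0, TRUE)
  rescue_floor <- num1(rescue_floor, "rescue_floor", 0)
  check_flag(normalize, "normalize")
  detection_floor <- num1(detection_floor, "detection_floor", 1)
  replicates_required <- as.integer(num1(replicates_required, "replicates_required", 1))
  min_rank <- as.integer(num1(min_rank, "min_rank", 1))
  if (min_rank > 5L) stop_validation("min_rank must be in 1..5")

  structure(
    list(
      alpha = alpha, strict_alpha = strict_alpha,
      fc_min = fc_min, fc_strict = fc_strict,
      pseudocount = pseudocount, rescue_floor = rescue_floor,
      p_mode = p_mode, normalize = normalize,
      detection_floor = detection_floor,
      replicates_required = replicates_required,
      min_rank = min_rank
    ),
    class = "apms_config"
  )
}

#' @export
print.apms_config <- function(x, ...) {
  cat("AP-MS scoring configuration\n")
  cat(sprintf("  significance: p_%s < %g and log2FC >= %g\n",
              x$p_mode, x$alpha, x$fc_min))
  cat(sprintf("  strict tier : p <= %g, log2FC >= %g\n", x$strict_alpha, x$fc_strict))
  cat(sprintf("  pseudocount %g | rescue floor %g | detection floor %g | normalize %s\n",
              x$pseudocount, x$rescue_floor, x$detection_floor, x$normalize))
  invisible(x)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return An `apms_config`.
#' @export
read_pipeline_config <- function(path) {
  check_file_exists(path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop_validation("unsupported config format: .", ext, " (use JSON or YAML)")
  )
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop_validation("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}
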