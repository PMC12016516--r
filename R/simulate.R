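#' Configuration for the synthetic AP-MS experiment generator
#'
#' Describes a tagged-bait purification study: a proteome, a set of baits
#' each purified in triplicate under one or more growth conditions, and up to
#' four parental control purifications per condition. Defaults mirror a
#' genome-reduced archaeal proteome of ~2,306 proteins with ~30 true partners
#' per bait.
#'
#' @param proteome_size number of proteins in the proteome (default 2306).
#' @param n_baits number of tagged bait proteins.
#' @param partners_per_bait true partners planted per bait (default 30).
#' @param effect_range planted log2 enrichment range, drawn uniformly
#'   (default `c(2, 6)`, spanning the fold-change decision boundaries at 2
#'   and 4).
#' @param background_mean mean spectral count of a typical detectable
#'   background binder (default 10).
#' @param dispersion negative-binomial dispersion of counts (variance =
#'   mean + dispersion * mean^2; default 0.25). Must be positive.
#' @param detectability probability that a protein yields usable tryptic
#'   signal; undetectable proteins emit zero counts everywhere.
#' @param undetectable_fraction fraction of the proteome forced to
#'   detectability zero regardless of `detectability` (proteins too small or
#'   refractory to produce peptides).
#' @param n_exp_reps experimental replicates per bait/condition (default 3).
#' @param n_ctrl_reps parental control replicates per condition (default 4).
#' @param sticky_fraction fraction of the proteome with elevated resin
#'   affinity in ALL purifications, experimental and control alike (default
#'   0.02); a correct pipeline must reject these.
#' @param sticky_boost abundance multiplier for sticky proteins (default 20).
#' @param baseline_shape gamma shape of per-protein baseline means; small
#'   values give the sparse, highly skewed background typical of AP-MS
#'   (default 0.3).
#' @param bait_log2fc log2 enrichment of the bait's own protein in its
#'   purifications (default 5).
#' @param library_jitter per-run library-size jitter as a fraction (default
#'   0, i.e. equal depth; 0.2 gives +/-20%).
#' @param conditions data.frame with logical columns `sulfur` and `pyruvate`,
#'   one row per growth condition (default: +S and -S, both with pyruvate).
#' @param seed master seed; all randomness is derived from it through
#'   per-purpose substreams so that adding baits does not perturb existing
#'   runs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(proteome_size = 2306L,
                       n_baits = 1L,
                       partners_per_bait = 30L,
                       effect_range = c(2, 6),
                       background_mean = 10,
                       dispersion = 0.25,
                       detectability = 1,
                       undetectable_fraction = 0,
                       n_exp_reps = 3L,
                       n_ctrl_reps = 4L,
                       sticky_fraction = 0.02,
                       sticky_boost = 20,
                       baseline_shape = 0.3,
                       bait_log2fc = 5,
                       library_jitter = 0,
                       conditions = data.frame(sulfur = c(TRUE, FALSE),
                                               pyruvate = TRUE),
                       seed = 1L) {
  pos_int <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
      stop_validation(name, " must be an integer >= ", min)
    }
    as.integer(x)
  }
  prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop_validation(name, " must be a probability in [0, 1]")
    }
    as.numeric(x)
  }
  proteome_size <- pos_int(proteome_size, "proteome_size", 2L)
  n_baits <- pos_int(n_baits, "n_baits")
  partners_per_bait <- pos_int(partners_per_bait, "partners_per_bait", 0L)
  if (partners_per_bait >= proteome_size) {
    stop_validation("partners_per_bait must be smaller than proteome_size")
  }
  if (!is.numeric(effect_range) || length(effect_range) != 2L ||
      anyNA(effect_range) || effect_range[1] > effect_range[2]) {
    stop_validation("effect_range must be an increasing pair of log2 effects")
  }
  if (!is.numeric(background_mean) || background_mean <= 0) {
    stop_validation("background_mean must be positive")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop_validation("dispersion must be positive")
  }
  detectability <- prob(detectability, "detectability")
  undetectable_fraction <- prob(undetectable_fraction, "undetectable_fraction")
  sticky_fraction <- prob(sticky_fraction, "sticky_fraction")
  if (!is.numeric(sticky_boost) || sticky_boost < 1) {
    stop_validation("sticky_boost must be >= 1")
  }
  if (!is.numeric(baseline_shape) || baseline_shape <= 0) {
    stop_validation("baseline_shape must be positive")
  }
  n_exp_reps <- pos_int(n_exp_reps, "n_exp_reps")
  n_ctrl_reps <- pos_int(n_ctrl_reps, "n_ctrl_reps")
  library_jitter <- prob(library_jitter, "library_jitter")
  if (library_jitter >= 1) stop_validation("library_jitter must be below 1")
  conditions <- as.data.frame(conditions)
  if (!all(c("sulfur", "pyruvate") %in% names(conditions)) || !nrow(conditions)) {
    stop_validation("conditions needs >=1 row with columns sulfur and pyruvate")
  }
  conditions$sulfur <- parse_logical(conditions$sulfur, "sulfur")
  conditions$pyruvate <- parse_logical(conditions$pyruvate, "pyruvate")
  if (anyDuplicated(paste(conditions$sulfur, conditions$pyruvate))) {
    stop_validation("duplicate growth condition")
  }
  seed <- pos_int(seed, "seed", 0L)

  structure(
    list(proteome_size = proteome_size, n_baits = n_baits,
         partners_per_bait = partners_per_bait, effect_range = as.numeric(effect_range),
         background_mean = background_mean, dispersion = dispersion,
         detectability = detectability, undetectable_fraction = undetectable_fraction,
         n_exp_reps = n_exp_reps, n_ctrl_reps = n_ctrl_reps,
         sticky_fraction = sticky_fraction, sticky_boost = sticky_boost,
         baseline_shape = baseline_shape, bait_log2fc = bait_log2fc,
         library_jitter = library_jitter, conditions = conditions, seed = seed),
    class = "sim_config"
  )
}

# Deterministic substream seed: fold integer labels into the master seed with
# an LCG-style hash, kept inside the 32-bit signed range.
sub_seed <- function(seed, ...) {
  s <- as.double(seed %% 2147483647L)
  for (k in c(...)) {
    s <- (s * 69069 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Simulate an AP-MS spectral-count experiment with known ground truth
#'
#' Generates per-protein baseline (resin background) abundances from a
#' skewed gamma distribution, plants `partners_per_bait` true partners per
#' bait whose experimental means are the control means scaled by
#' `2^effect`, elevates sticky proteins equally in experimental and control
#' runs, zeroes undetectable proteins everywhere, and draws counts from a
#' negative binomial with the configured dispersion. The bait's own protein
#' is enriched by `bait_log2fc` in its purifications.
#'
#' Randomness is hierarchical: baselines, bait identities, partner sets and
#' each run block have their own substream derived from the master seed, so
#' regenerating with more baits leaves all previously existing runs
#' byte-identical.
#'
#' @param config [sim_config()].
#' @return A list with `counts` ([spectral_counts()] matrix), `sheet`
#'   ([sample_sheet()]), and `truth` (data.frame bait_gene, prey_protein,
#'   sulfur, pyruvate, effect_log2fc, detectable).
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(proteome_size = 200, n_baits = 1,
#'                                       partners_per_bait = 5, seed = 7))
#' dim(sim$counts)
#' head(sim$truth)
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$proteome_size
  ids <- sprintf("TK%04d", seq_len(P))

  # --- substream 1: proteome-level draws ------------------------------------
  base <- withr::with_seed(sub_seed(config$seed, 1L), {
    mu <- stats::rgamma(P, shape = config$baseline_shape,
                        rate = config$baseline_shape / config$background_mean)
    n_sticky <- round(config$sticky_fraction * P)
    sticky <- if (n_sticky) sample.int(P, n_sticky) else integer(0)
    mu[sticky] <- pmax(mu[sticky], config$background_mean) * config$sticky_boost
    detectable <- stats::rbinom(P, 1L, config$detectability) == 1L
    n_undet <- round(config$undetectable_fraction * P)
    if (n_undet) detectable[sample.int(P, n_undet)] <- FALSE
    list(mu = mu, sticky = sticky, detectable = detectable)
  })
  mu <- base$mu
  detectable <- base$detectable

  # Partner pool: proteins with enough resin background that a planted
  # multiplicative enrichment is observable against the control runs.
  pool <- setdiff(which(mu >= config$background_mean / 2), base$sticky)
  bait_pool <- intersect(pool, which(detectable))

  # --- substream 2+k: bait identities (prefix-stable in k) ------------------
  baits <- integer(0)
  for (k in seq_len(config$n_baits)) {
    cand <- setdiff(bait_pool, baits)
    if (!length(cand)) stop_validation("proteome too small to host ", config$n_baits, " baits")
    baits[k] <- withr::with_seed(sub_seed(config$seed, 2L, k),
                                 cand[sample.int(length(cand), 1L)])
  }

  # --- substream 3+k: planted partner sets and effects ----------------------
  n_cond <- nrow(config$conditions)
  truth_rows <- list()
  partner_sets <- vector("list", config$n_baits)
  effect_sets <- vector("list", config$n_baits)
  for (k in seq_len(config$n_baits)) {
    # exclude only baits 1..k so partner draws stay prefix-stable in n_baits
    cand <- setdiff(pool, baits[seq_len(k)])
    if (length(cand) < config$partners_per_bait) {
      stop_validation("partner pool too small: ", length(cand), " candidates for ",
                      config$partners_per_bait, " partners (increase proteome_size)")
    }
    picks <- withr::with_seed(sub_seed(config$seed, 3L, k), {
      idx <- if (config$partners_per_bait) sample(cand, config$partners_per_bait) else integer(0)
      eff <- matrix(stats::runif(length(idx) * n_cond,
                                 config$effect_range[1], config$effect_range[2]),
                    nrow = length(idx))
      list(idx = idx, eff = eff)
    })
    partner_sets[[k]] <- picks$idx
    effect_sets[[k]] <- picks$eff
    for (ci in seq_len(n_cond)) {
      if (length(picks$idx)) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          bait_gene = ids[baits[k]], prey_protein = ids[picks$idx],
          sulfur = config$conditions$sulfur[ci],
          pyruvate = config$conditions$pyruvate[ci],
          effect_log2fc = picks$eff[, ci],
          detectable = detectable[picks$idx],
          stringsAsFactors = FALSE
        )
      }
    }
  }

  size <- 1 / config$dispersion
  draw_block <- function(seed, means, n_runs) {
    withr::with_seed(seed, {
      lib <- if (config$library_jitter > 0) {
        stats::runif(n_runs, 1 - config$library_jitter, 1 + config$library_jitter)
      } else rep(1, n_runs)
      m <- outer(means, lib)
      cnt <- matrix(stats::rnbinom(length(m), mu = m, size = size), nrow = length(means))
      cnt[!detectable, ] <- 0L
      cnt
    })
  }
  cond_label <- function(ci) {
    sprintf("%sS%sP",
            if (config$conditions$sulfur[ci]) "p" else "m",
            if (config$conditions$pyruvate[ci]) "p" else "m")
  }

  blocks <- list(); run_meta <- list()
  # --- substream 4+ci: parental control runs per condition ------------------
  for (ci in seq_len(n_cond)) {
    cnt <- draw_block(sub_seed(config$seed, 4L, ci), mu, config$n_ctrl_reps)
    runs <- sprintf("TS559_%s_C%d", cond_label(ci), seq_len(config$n_ctrl_reps))
    colnames(cnt) <- runs
    blocks[[length(blocks) + 1L]] <- cnt
    run_meta[[length(run_meta) + 1L]] <- data.frame(
      run_id = runs, strain = "PARENTAL", role = "control",
      sulfur = config$conditions$sulfur[ci], pyruvate = config$conditions$pyruvate[ci],
      replicate = seq_len(config$n_ctrl_reps), stringsAsFactors = FALSE
    )
  }
  # --- substream 5+(k,ci): experimental runs per bait and condition ---------
  for (k in seq_len(config$n_baits)) {
    for (ci in seq_len(n_cond)) {
      means <- mu
      idx <- partner_sets[[k]]
      if (length(idx)) means[idx] <- mu[idx] * 2^effect_sets[[k]][, ci]
      means[baits[k]] <- mu[baits[k]] * 2^config$bait_log2fc
      cnt <- draw_block(sub_seed(config$seed, 5L, k, ci), means, config$n_exp_reps)
      runs <- sprintf("%s_%s_E%d", ids[baits[k]], cond_label(ci),
                      seq_len(config$n_exp_reps))
      colnames(cnt) <- runs
      blocks[[length(blocks) + 1L]] <- cnt
      run_meta[[length(run_meta) + 1L]] <- data.frame(
        run_id = runs, strain = ids[baits[k]], role = "experimental",
        sulfur = config$conditions$sulfur[ci], pyruvate = config$conditions$pyruvate[ci],
        replicate = seq_len(config$n_exp_reps), stringsAsFactors = FALSE
      )
    }
  }

  counts <- do.call(cbind, blocks)
  rownames(counts) <- ids
  truth <- if (length(truth_rows)) {
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(bait_gene = character(), prey_protein = character(),
               sulfur = logical(), pyruvate = logical(),
               effect_log2fc = numeric(), detectable = logical(),
               stringsAsFactors = FALSE)
  }
  list(
    counts = spectral_counts(counts),
    sheet = sample_sheet(do.call(rbind, c(run_meta, list(make.row.names = FALSE)))),
    truth = truth
  )
}

#' Nucleotide insert encoding the HA epitope and His6 affinity tag
#'
#' Returns the 45-nt sequence appended at the tagged locus: 27 nt encoding
#' the nine-residue hemagglutinin (HA) epitope YPYDVPDYA followed by 18 nt
#' encoding six histidines.
#'
#' @param segment `"full"` (default, 45 nt), `"ha"` (27 nt) or `"his6"`
#'   (18 nt).
#' @return A nucleotide string.
#' @export
#' @examples
#' nchar(build_tag_insert())  # 45
build_tag_insert <- function(segment = c("full", "ha", "his6")) {
  segment <- match.arg(segment)
  ha <- "TACCCATACGACGTTCCGGACTACGCA"
  his6 <- "CATCACCATCACCATCAC"
  switch(segment, full = paste0(ha, his6), ha = ha, his6 = his6)
}
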