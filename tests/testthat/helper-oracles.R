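# Independent oracle for the one-sided enrichment test: explicit summation of
# the hypergeometric pmf (via log-binomial coefficients) over the upper tail.
# Kept free of phyper/fisher.test so it checks the implementation from a
# different route.
hyper_tail_oracle <- function(a, b, c_other, d_other) {
  m <- a + b
  n <- c_other + d_other
  k <- a + c_other
  x <- max(0, k - n):min(k, m)
  lp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  sum(exp(lp[x >= a]))
}

# Minimal enrichment_records builder for unit tests.
make_records <- function(protein_id, bait_gene = "TK0001",
                         sulfur = TRUE, pyruvate = TRUE,
                         n_detected = 3L, n_replicates = 3L,
                         mean_exp = 50, mean_ctrl = 0, log2fc = 5,
                         p_raw = 1e-6, p_adj = p_raw,
                         significant = TRUE, rescued = FALSE,
                         rank = NA_integer_) {
  n <- length(protein_id)
  for (arg in c("bait_gene", "sulfur", "pyruvate", "n_detected", "n_replicates",
                "mean_exp", "mean_ctrl", "log2fc", "p_raw", "p_adj",
                "significant", "rescued", "rank")) {
    assign(arg, rep_len(get(arg), n))
  }
  df <- data.frame(
    protein_id = protein_id, bait_gene = bait_gene,
    sulfur = sulfur, pyruvate = pyruvate,
    n_detected = as.integer(n_detected), n_replicates = as.integer(n_replicates),
    mean_exp = mean_exp, mean_ctrl = mean_ctrl, log2fc = log2fc,
    p_raw = p_raw, p_adj = p_adj,
    significant = significant, rescued = rescued, rank = as.integer(rank),
    stringsAsFactors = FALSE
  )
  class(df) <- c("enrichment_records", "data.frame")
  df
}

# Small hand-built experiment: one bait, one condition, 3 experimental and
# 4 control runs, with a planted prey, a flat background and a sticky binder.
make_toy_experiment <- function() {
  set.seed(101)
  proteins <- sprintf("TK%04d", 1:6)
  runs_e <- paste0("TK0001_pSpP_E", 1:3)
  runs_c <- paste0("TS559_pSpP_C", 1:4)
  counts <- matrix(5L, nrow = 6, ncol = 7,
                   dimnames = list(proteins, c(runs_e, runs_c)))
  counts["TK0002", runs_e] <- c(10L, 12L, 9L)   # planted prey
  counts["TK0002", runs_c] <- 0L
  counts["TK0001", runs_e] <- c(60L, 55L, 70L)  # the bait itself
  counts["TK0001", runs_c] <- 1L
  counts["TK0006", ] <- 40L                     # sticky in every run
  sheet <- sample_sheet(data.frame(
    run_id = c(runs_e, runs_c),
    strain = c(rep("TK0001", 3), rep("PARENTAL", 4)),
    role = c(rep("experimental", 3), rep("control", 4)),
    sulfur = TRUE, pyruvate = TRUE,
    replicate = c(1:3, 1:4)
  ))
  list(counts = spectral_counts(counts), sheet = sheet)
}
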