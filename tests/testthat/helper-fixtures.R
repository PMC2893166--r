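paper_treatments <- c("control", "wcr_untreated", "wcr_treated")

paper_design <- function() build_loop_design(paper_treatments, 3, dye_swap = TRUE)

fixture_path <- function(f) system.file("extdata", f, package = "loopmaa")

# simulate -> log -> stage 1 -> residuals, in one step
pipeline_residuals <- function(cfg, design, ...) {
  sim <- simulate_experiment(cfg, design)
  extract_residuals(fit_stage1(log_transform(sim$intensities), design, ...))
}

# independent exact Wilcoxon oracle: enumerate every rank assignment
wilcoxon_bruteforce_p <- function(a, b) {
  na <- length(a)
  N <- na + length(b)
  w <- sum(rank(c(a, b))[seq_len(na)])
  sums <- colSums(matrix(utils::combn(N, na), nrow = na))
  refl <- na * (N + 1) - w
  lo <- min(w, refl)
  hi <- max(w, refl)
  min(1, (sum(sums <= lo) + sum(sums >= hi)) / length(sums))
}
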