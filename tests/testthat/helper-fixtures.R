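# Shared fixtures built in code; kept tiny so the default run stays fast.

toy_genotypes <- function(n = 30, p = 12, seed = 11, n_chrom = 2) {
  simulate_genotypes(n, p, n_chrom = n_chrom, ld_rho = 0.3,
                     maf_range = c(0.2, 0.5), seed = seed)
}

# small architecture that fits in a few hundred markers
small_arch <- function(h2 = 0.5, k_large = 0.05) {
  architecture_config(k_large = k_large, n_medium = 30, k_small = 0.001,
                      h2 = h2)
}

# Monte-Carlo standard error of a chain mean via batch means
batch_se <- function(x, n_batches = 25) {
  b <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]), 1)
  stats::sd(means) / sqrt(n_batches)
}

# map with a single 5-marker chromosome (window-strategy toys)
five_marker_map <- function() {
  marker_map(paste0("m", 1:5), rep("1", 5), c(100, 200, 300, 400, 500))
}
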