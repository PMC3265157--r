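# small shared fixtures; everything is generated in code

small_grid <- function(n = 41L) activity_grid(-6, 6, n)

# truncated normal density values on a grid (unnormalised truncation error
# is negligible for sd <= 1 and |mean| <= 2 on [-6, 6])
normal_values <- function(grid, mean = 0, sd = 1) {
  stats::dnorm(grid$nodes, mean, sd)
}

# exact squared L2 distance between two normal densities with equal sd
normal_l2sq <- function(mean1, mean2, sd) {
  (1 / (2 * sd * sqrt(pi))) * 2 * (1 - exp(-(mean1 - mean2)^2 / (4 * sd^2)))
}
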