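# Small shared fixtures, built once per test run.

tiny_bench <- make_test_bench(p_high = 120, p_low = 30, n_elec = 24,
                              strip_width = 10)

# differential pieces under the Cz reference
tiny_scheme <- local({
  labels <- tiny_bench$layout$labels
  make_reference_scheme(length(labels), match("Cz", labels), labels)
})

tiny_At_high <- tiny_scheme$M %*% tiny_bench$leadfields$high$A
tiny_At_low <- tiny_scheme$M %*% tiny_bench$leadfields$low$A

# exact-statistics instance with a known silent patch on the fine grid
tiny_truth <- sample_contiguous_region(tiny_bench$grids$high, k = 8,
                                       seed = 42, depth_limit = 30)
tiny_model <- build_source_covariance(tiny_bench$grids$high, gamma = 0.12,
                                      sigma_s2 = 1,
                                      silent_set = tiny_truth)

# brute-force objective of the CSpeC program with a binary indicator
cspec_binary_objective <- function(beta, L, silent) {
  p <- length(beta)
  u <- rep(0, p)
  u[silent] <- 1                      # u = 1 - g
  sum(beta * u) + as.numeric(crossprod(u, L %*% u))
}

# all contiguous k-subsets of a path graph 1..p
path_contiguous_subsets <- function(p, k) {
  lapply(seq_len(p - k + 1), function(s) s:(s + k - 1))
}
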