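# Shared fixture builders (all data generated in code).

# symmetric nonnegative random weight matrix with zero diagonal
random_weight_matrix <- function(P, density = 0.6, seed = 1) {
  withr::with_seed(seed, {
    M <- matrix(0, P, P)
    up <- upper.tri(M)
    vals <- stats::runif(sum(up))
    vals[stats::runif(sum(up)) > density] <- 0
    M[up] <- vals
    M <- M + t(M)
    M
  })
}

# tiny synthetic study used by several suites
tiny_ground_truth <- function(seed = 5) {
  make_ground_truth(n_participants = 8L, n_nodes = 8L, n_windows = 4L,
                    poly_degree = 2L, seed = seed)
}

tiny_design <- function(seed = 5, rep_seed = 11) {
  generate_synthetic_study(tiny_ground_truth(seed), seed = rep_seed)
}
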