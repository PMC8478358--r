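# Independent oracles used across test files. These deliberately use the
# most naive formulation available (explicit matrix inversion, Monte-Carlo
# draws) so they stay independent of the package's implementation paths.

# GLS normal equations by explicit inversion: b = (X' V^-1 X)^-1 X' V^-1 y
gls_bruteforce <- function(X, y, V) {
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y)
}

# Monte-Carlo sample of the studentized range Q_{k, df}
mc_studentized_range <- function(n_draws, k, df, seed) {
  withr::with_seed(seed, {
    z <- matrix(rnorm(n_draws * k), ncol = k)
    rng <- apply(z, 1, max) - apply(z, 1, min)
    s <- sqrt(rchisq(n_draws, df) / df)
    rng / s
  })
}

# small fixed trees used in several files
toy_tree_3 <- function() read_newick(text = "((A:1,B:1):1,C:2);")
toy_tree_4 <- function() read_newick(text = "((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);")
star_tree <- function(n = 8) {
  read_newick(text = paste0(
    "(", paste0("t", seq_len(n), ":1", collapse = ","), ");"))
}
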