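# Shared fixtures, built in code at test time.

tiny_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_phantom_atlas(c(20, 20, 20), n_seeds = 4, n_networks = 3,
                                   rng_seed = 42)
    }
    cache
  }
})

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 4, n_timepoints = 96, tr = 2.5, rng_seed = 7),
    list(...))
  do.call(sim_config, args)
}

# a small random volume with given dims
random_volume <- function(dims = c(10, 10, 10, 40), tr = 2.5, seed = 1,
                          baseline = 0) {
  v <- rsdenoise:::with_seed(seed, array(rnorm(prod(dims)), dim = dims))
  volume4d(v + baseline, tr = tr)
}

full_mask <- function(dims) array(TRUE, dim = dims)

# independent normal-equations OLS oracle: residual of Y on [1, X]
oracle_residual <- function(Y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% Y)
  Y - X1 %*% beta
}
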