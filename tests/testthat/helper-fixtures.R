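# Shared fixtures, built in code at load time.

# A single marker profile row; markers default negative.
profile_row <- function(nanog = 0, foxa2 = 0, hex = 0, noggin = 0,
                        tbx6 = 0, ap2a = 0, sox3 = 0) {
  tibble::tibble(nanog = nanog, foxa2 = foxa2, hex = hex, noggin = noggin,
                 tbx6 = tbx6, ap2a = ap2a, sox3 = sox3)
}

# All 128 binary marker profiles.
all_profiles <- function() {
  do.call(tidyr::expand_grid,
          stats::setNames(rep(list(0:1), 7), marker_names()))
}

# Small mixed population reused across tests (deterministic).
fixture_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(population_config(n_cells = 2000,
                                                      seed = 20260926 %% 1000))
    }
    cache
  }
})

# Independent beta-binomial predictive by numerical quadrature:
# p(t) = C(m, t) * E[p^t (1-p)^(m-t)] with p ~ Beta(a + s, b + n - s).
quad_predictive <- function(alpha, beta, N, n, s) {
  m <- N - n
  sapply(0:m, function(t) {
    choose(m, t) * stats::integrate(
      function(p) stats::dbeta(p, alpha + s, beta + n - s) *
        p^t * (1 - p)^(m - t),
      0, 1, rel.tol = 1e-10
    )$value
  })
}
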