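# Shared fixtures, generated in code and cached per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

small_tube <- function(...)
  make_plug_tube(radius = 6, wall_width = 3, shape = c(6, 11, 11),
                 nt = 10, ...)

# a reproducible random velocity field (values have no physical meaning;
# used for interpolation-layout and periodicity checks)
random_field <- function(seed = 42, nt = 5, nz = 6, ny = 7, nx = 8,
                         spacing = c(2, 3, 4), origin = c(-1, 2, 0.5)) {
  set.seed(seed)
  velocity_field(array(rnorm(nt * nz * ny * nx * 3, sd = 20),
                       dim = c(nt, nz, ny, nx, 3)),
                 spacing, timeframe_duration = 40, venc = 100,
                 origin = origin)
}

# exhaustive sign-exchange oracle for the paired signed-rank test
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}
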