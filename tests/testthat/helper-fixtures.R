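# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

exemplar <- function(category, seed = 0L) {
  cached(sprintf("exemplar_%d_%d", category, seed),
         generate_exemplar(category, seed))
}

# A toy MLP with arbitrary layer sizes (the forward/gradient code is
# size-agnostic even though the pipeline architecture is fixed).
make_toy_model <- function(sizes, seed = 1L) {
  set.seed(seed)
  m <- list()
  for (l in 1:3) {
    m[[paste0("W", l)]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = 0.5),
                                  sizes[l], sizes[l + 1])
    m[[paste0("b", l)]] <- rnorm(sizes[l + 1], sd = 0.1)
  }
  m$config <- mlp_config(seed = seed)
  structure(m, class = "mlp_model")
}

# Numeric MSE loss of a model on (X, Y), used by the finite-difference check.
toy_loss <- function(model, X, Y) mean((mlp_forward(model, X) - Y)^2)

# A 34-point axis-aligned square outline (side `side`, centred), traced
# counter-clockwise in image coordinates.
square_outline <- function(side = 48, center = 48) {
  half <- side / 2
  t <- seq(0, 4, length.out = 35)[-35]
  pts <- t(vapply(t, function(u) {
    e <- floor(u); f <- u - e
    switch(e + 1,
           c(-half + side * f, -half),   # top edge, left -> right
           c(half, -half + side * f),    # right edge downward
           c(half - side * f, half),     # bottom edge right -> left
           c(-half, half - side * f))    # left edge upward
  }, numeric(2)))
  outline2d(cbind(center + pts[, 1], center + pts[, 2]), 1L)
}

# Tiny balanced record set shared across datastore / evaluation tests.
small_records <- function() cached("records_80", generate_dataset(80, seed = 11))
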