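# Internal numerical helpers.

# Inverse-gamma density, shape a, scale b (density ~ g^{-a-1} exp(-b/g)).
dinvgamma <- function(g, shape, scale, log = FALSE) {
  ld <- ifelse(g > 0,
               shape * log(scale) - lgamma(shape) - (shape + 1) * log(g) - scale / g,
               -Inf)
  if (log) ld else exp(ld)
}

rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

# Row-wise cumulative sums of a matrix (replicates in rows, observations in columns).
row_cumsum <- function(m) {
  if (ncol(m) == 1L) return(m)
  t(apply(m, 1L, cumsum))
}

# Derive independent substream seeds from one root seed.  Each replicate gets
# its own seed so results do not depend on the order in which replicates run.
substream_seeds <- function(root_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(root_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Composite Simpson rule on [a, b] with an odd number of nodes.
simpson <- function(f, a, b, n_nodes = 4001L) {
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  x <- seq(a, b, length.out = n_nodes)
  y <- f(x)
  h <- (b - a) / (n_nodes - 1L)
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1L] <- 1
  w[n_nodes] <- 1
  sum(w * y) * h / 3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
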