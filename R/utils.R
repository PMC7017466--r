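# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps phantom generation and pipeline
# runs reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Otsu's threshold on a numeric vector (maximizes between-class variance).
# Returns a value separating the two classes; n_bins trades speed for
# resolution and is ample for 16-bit CT histograms.
otsu_threshold <- function(x, n_bins = 512L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  bin[bin > n_bins] <- n_bins
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- mids * w
  omega0 <- cumsum(w)
  mu0 <- cumsum(mu)
  mu_t <- mu0[n_bins]
  omega1 <- 1 - omega0
  valid <- omega0 > 0 & omega1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * omega0[valid] - mu0[valid])^2 /
    (omega0[valid] * omega1[valid])
  k <- which.max(sigma_b)
  (edges[k] + edges[k + 1L]) / 2
}

# Deterministic, roughly uniform unit directions on the sphere
# (Fibonacci lattice); used for Feret-width estimation.
fibonacci_directions <- function(n = 128L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# World coordinate (mm) of the centre of voxel index i (1-based) at the
# given voxel size: first voxel centre sits at voxel_size/2.
voxel_centre_mm <- function(index, voxel_size_mm) {
  (index - 0.5) * voxel_size_mm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
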