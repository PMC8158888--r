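# Independent brute-force oracles and tiny fixtures used across the suite.

# Dice coefficient by explicit element loop.
dsc_loop <- function(a, b) {
  inter <- 0
  sa <- 0
  sb <- 0
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) inter <- inter + 1
    sa <- sa + a[i]
    sb <- sb + b[i]
  }
  if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
}

# Per-channel pooling by explicit loops.
channel_pool_loop <- function(x) {
  d <- dim(x)
  C <- d[length(d)]
  m <- matrix(x, prod(d[-length(d)]), C)
  gap <- numeric(C)
  gmp <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    mx <- -Inf
    for (i in seq_len(nrow(m))) {
      s <- s + m[i, c]
      if (m[i, c] > mx) mx <- m[i, c]
    }
    gap[c] <- s / nrow(m)
    gmp[c] <- mx
  }
  list(gap = gap, gmp = gmp)
}

# Count 6-connected foreground components with a flood fill (independent of
# the package's labelling kernel).
count_components_loop <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  ncomp <- 0
  idx_all <- which(mask > 0)
  for (start in idx_all) {
    if (seen[start]) next
    ncomp <- ncomp + 1
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pos <- arrayInd(cur, d)
      for (ax in 1:3) {
        for (dd in c(-1L, 1L)) {
          np <- pos
          np[ax] <- np[ax] + dd
          if (np[ax] < 1 || np[ax] > d[ax]) next
          flat <- np[1] + d[1] * (np[2] - 1L) + d[1] * d[2] * (np[3] - 1L)
          if (mask[flat] > 0 && !seen[flat]) {
            seen[flat] <- TRUE
            queue <- c(queue, flat)
          }
        }
      }
    }
  }
  ncomp
}

rand_volume <- function(shape, seed = 1) {
  set.seed(seed)
  volume(array(stats::rnorm(prod(shape)), shape))
}

rand_mask <- function(shape, p = 0.3, seed = 1) {
  set.seed(seed)
  volume(array((stats::runif(prod(shape)) < p) * 1, shape), is_mask = TRUE)
}

tiny_model_cfg <- function(...) {
  model_config(in_size = 16, n_blocks = 2, base_channels = 3,
               dense_layers = 2, growth = 3, n3d_blocks = 1, ...)
}

# Small phantoms (keep unit tests fast; the miniature study uses the default
# 64 x 64 x 48).
small_phantom_spec <- function(seed = 1) {
  phantom_spec(shape = c(24L, 24L, 16L), seed = seed)
}
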