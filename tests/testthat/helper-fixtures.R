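# Shared fixtures, all built in code.

# Digitized ball of radius r (mm) at isotropic spacing sp (mm).
digitize_ball <- function(r, sp = 1, pad = 2) {
  cds <- seq(-r - pad * sp, r + pad * sp, by = sp)
  n <- length(cds)
  g <- expand.grid(x = cds, y = cds, z = cds)
  array(with(g, x^2 + y^2 + z^2) <= r^2, dim = c(n, n, n))
}

# Axis-aligned cube of side L voxels inside a padded grid.
digitize_cube <- function(L, pad = 2) {
  n <- L + 2 * pad
  m <- array(FALSE, c(n, n, n))
  m[(pad + 1):(pad + L), (pad + 1):(pad + L), (pad + 1):(pad + L)] <- TRUE
  m
}

# Small default cohort config for fast end-to-end tests.
tiny_config <- function(n = 6, seed = 101, ...) {
  cohort_config(n_patients = n, rng_seed = seed, ...)
}

# A deterministic textured test volume + blob mask.
toy_volume_mask <- function(seed = 1, n = 16) {
  set.seed(seed)
  vol <- array(rnorm(n^3, 100, 15), c(n, n, n))
  mask <- digitize_ball(5, 1, pad = 2)
  stopifnot(all(dim(mask) <= n))
  m <- array(FALSE, c(n, n, n))
  m[seq_len(dim(mask)[1]), seq_len(dim(mask)[2]), seq_len(dim(mask)[3])] <-
    mask
  list(volume = vol, mask = m, spacing = c(1, 1, 1))
}

# Brute-force pair-counting AUC (O(n^2) oracle).
auc_bruteforce <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exact two-sided WMW p-value by enumerating all rank splits (no ties).
wmw_enumerate <- function(x, y) {
  n1 <- length(x)
  all <- c(x, y)
  r <- rank(all)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(all), n1)
  Us <- apply(splits, 2, function(idx)
    sum(rank(all)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(y)) / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}
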