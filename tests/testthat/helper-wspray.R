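# Shared fixtures and independent oracles.

# Independent brute-force Otsu oracle: naive per-k class statistics,
# no cumulative sums, explicit loop over all 256 candidates.
brute_force_bcv <- function(p, k) {
  lev <- 0:255
  P1 <- sum(p[lev <= k])
  P2 <- sum(p[lev > k])
  if (P1 <= 0 || P2 <= 0) return(0)
  m <- sum(lev[lev <= k] * p[lev <= k])
  mG <- sum(lev * p)
  (mG * P1 - m)^2 / (P1 * P2)
}

brute_force_otsu <- function(p) {
  s <- vapply(0:255, function(k) brute_force_bcv(p, k), numeric(1))
  kmax <- which(s == max(s)) - 1L
  list(threshold = as.integer(floor(mean(kmax))), sigma2_max = max(s),
       curve = s)
}

# Random bimodal count histogram (seeded by the caller).
random_histogram <- function() {
  n1 <- sample(50:300, 1)
  n2 <- sample(50:300, 1)
  m1 <- sample(20:110, 1)
  m2 <- sample(140:235, 1)
  v <- c(round(stats::rnorm(n1, m1, sample(3:25, 1))),
         round(stats::rnorm(n2, m2, sample(3:25, 1))))
  v <- pmin(pmax(v, 0), 255)
  gray_histogram(counts = tabulate(v + 1L, nbins = 256L))
}

# Two well-separated gray modes as an image.
two_mode_image <- function(lo = 50L, hi = 200L, n_each = 100L) {
  gray_image(matrix(c(rep(lo, n_each), rep(hi, n_each)), nrow = 10))
}

# Random sparse logical mask (seeded by the caller).
random_mask <- function(nr = 40, nc = 60, p = 0.2) {
  droplet_mask(matrix(stats::runif(nr * nc) < p, nr, nc))
}

# Write a solid-colour RGB PNG, return its path.
write_rgb_png <- function(rgb, path = tempfile(fileext = ".png"),
                          nr = 2, nc = 2, dpi = NULL) {
  arr <- array(rep(rgb, each = nr * nc), c(nr, nc, 3))
  png::writePNG(arr, path, dpi = dpi)
  path
}

noise_free_spec <- function(seed, n_droplets = 20, ...) {
  synthetic_spec(n_droplets = n_droplets, noise_sigma = 0,
                 glare_hole_prob = 0, seed = seed, ...)
}
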