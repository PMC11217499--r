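# Brute-force O(n^2) oracles and small fixture builders, independent of the
# package's C++ kernels.

# CSR localization table over [0, w) x [0, h)
csr_table <- function(n, w = 512, h = w, seed = NULL, unit = "pixel") {
  if (!is.null(seed)) set.seed(seed)
  loc_table(data.frame(x = runif(n, 0, w), y = runif(n, 0, h)),
            unit = unit, extent = c(0, w, 0, h))
}

# Pair correlation by explicit double loop, same band convention as the
# package ((r, r+dr], ties on the upper edge stay in the band).
pcf_oracle <- function(origins, targets, dr, r_max, guard,
                       same_set = FALSE) {
  ext <- attr(origins, "extent")
  keep <- origins$x >= ext["xmin"] + guard & origins$x < ext["xmax"] - guard &
          origins$y >= ext["ymin"] + guard & origins$y < ext["ymax"] - guard
  ox <- origins$x[keep]; oy <- origins$y[keep]
  oi <- if (same_set) which(keep) else rep(NA_integer_, sum(keep))
  nbands <- round(r_max / dr)
  counts <- integer(nbands)
  for (i in seq_along(ox)) {
    for (j in seq_len(nrow(targets))) {
      if (!is.na(oi[i]) && j == oi[i]) next
      d <- sqrt((targets$x[j] - ox[i])^2 + (targets$y[j] - oy[i])^2)
      if (d == 0 || d > r_max) next
      k <- ceiling(d / dr)
      counts[k] <- counts[k] + 1L
    }
  }
  area <- (ext["xmax"] - ext["xmin"]) * (ext["ymax"] - ext["ymin"])
  lambda <- nrow(targets) / area
  r_lo <- (seq_len(nbands) - 1) * dr
  band_area <- pi * ((r_lo + dr)^2 - r_lo^2)
  counts / (band_area * sum(keep) * lambda)
}

# Exact nearest neighbour by double loop.
nn_oracle <- function(origins, targets, guard, same_set = FALSE) {
  ext <- attr(origins, "extent")
  keep <- origins$x >= ext["xmin"] + guard & origins$x < ext["xmax"] - guard &
          origins$y >= ext["ymin"] + guard & origins$y < ext["ymax"] - guard
  ox <- origins$x[keep]; oy <- origins$y[keep]
  oi <- if (same_set) which(keep) else rep(NA_integer_, sum(keep))
  vapply(seq_along(ox), function(i) {
    d <- sqrt((targets$x - ox[i])^2 + (targets$y - oy[i])^2)
    if (!is.na(oi[i])) d[oi[i]] <- Inf
    min(d)
  }, numeric(1))
}

# Synthetic pcf_curve from explicit g values (for fit tests).
make_curve <- function(g, dr = 5, lambda = 1e-3) {
  nb <- length(g)
  r_lo <- (seq_len(nb) - 1) * dr
  tibble::new_tibble(
    tibble::tibble(r = r_lo, r_mid = r_lo + dr / 2, g = g,
                   count = rep(0L, nb)),
    n = 1000L, lambda = lambda, dr = dr, r_max = nb * dr, guard = 100,
    unit = "pixel", class = "pcf_curve")
}

# Blinking-only CSR localizations: molecules at CSR positions, each
# appearing Poisson(mean_blinks) times with Gaussian scatter sigma.
blinking_table <- function(n_mol, w, sigma, mean_blinks = 4, seed = 1) {
  set.seed(seed)
  mx <- runif(n_mol, 0, w); my <- runif(n_mol, 0, w)
  m <- rpois(n_mol, mean_blinks)
  x <- rep(mx, m) + rnorm(sum(m), 0, sigma)
  y <- rep(my, m) + rnorm(sum(m), 0, sigma)
  keep <- x >= 0 & x < w & y >= 0 & y < w
  loc_table(data.frame(x = x[keep], y = y[keep]), unit = "pixel",
            extent = c(0, w, 0, w))
}
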