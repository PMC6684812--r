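# shared fixtures and independent oracles used across the test files

no_harmonics <- function() {
  data.frame(omega = numeric(0), cos = numeric(0), sin = numeric(0))
}

# spec with only the stated components active; everything else off
flat_spec <- function(n_days = 100, a0 = 9.34, a1 = 0,
                      harmonics = no_harmonics(),
                      weekday_offsets = rep(0, 7),
                      ar = numeric(0), sd = 0.1, seed = 1,
                      count_mode = "round-lognormal") {
  simulation_spec(n_days = n_days, a0 = a0, a1 = a1,
                  harmonics = harmonics,
                  weekday_offsets = weekday_offsets,
                  ar_coefficients = ar, innovation_sd = sd,
                  count_mode = count_mode, seed = seed)
}

# hand-built periodogram object for direct tests of the g statistic
fake_periodogram <- function(ordinates, n = 2 * length(ordinates) + 1) {
  j <- seq_along(ordinates)
  structure(list(n = n, index = j, omega = 2 * pi * j / n,
                 ordinate = as.numeric(ordinates)),
            class = "periodogram")
}

# MVN density, plain implementation
mvn_density <- function(x, mean, cov) {
  d <- length(mean)
  R <- chol(cov)
  z <- backsolve(R, x - mean, transpose = TRUE)
  exp(-0.5 * sum(z^2)) / ((2 * pi)^(d / 2) * prod(diag(R)))
}

# independent oracle: P(lower <= X <= upper) by nested Gauss-Legendre
# quadrature of the MVN density (practical for dimension <= 3)
mvn_box_quadrature <- function(mean, cov, lower, upper, nodes = 48) {
  d <- length(mean)
  stopifnot(d <= 3)
  # Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch matrix
  k <- seq_len(nodes - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, nodes, nodes)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x01 <- e$values
  w01 <- 2 * e$vectors[1, ]^2
  node_list <- lapply(seq_len(d), function(i) {
    a <- lower[i]; b2 <- upper[i]
    list(x = (b2 - a) / 2 * x01 + (a + b2) / 2,
         w = (b2 - a) / 2 * w01)
  })
  grid <- expand.grid(lapply(node_list, `[[`, "x"))
  wgrid <- expand.grid(lapply(node_list, `[[`, "w"))
  total <- 0
  for (i in seq_len(nrow(grid))) {
    total <- total + prod(as.numeric(wgrid[i, ])) *
      mvn_density(as.numeric(grid[i, ]), mean, cov)
  }
  total
}

# exhaustive oracle for anthrome labelling: scan every cell rectangle
brute_force_assign <- function(grid, lat, lon) {
  ytop <- grid$yllcorner + grid$nrows * grid$cellsize
  out <- rep(NA_integer_, length(lat))
  for (i in seq_along(lat)) {
    for (r in seq_len(grid$nrows)) {
      yhi <- ytop - (r - 1) * grid$cellsize
      ylo <- ytop - r * grid$cellsize
      # half-open: [ylo, yhi) from below, i.e. lat in (ylo, yhi]
      if (!(lat[i] <= yhi && lat[i] > ylo)) next
      for (cc in seq_len(grid$ncols)) {
        xlo <- grid$xllcorner + (cc - 1) * grid$cellsize
        xhi <- grid$xllcorner + cc * grid$cellsize
        if (lon[i] >= xlo && lon[i] < xhi) {
          code <- grid$codes[r, cc]
          out[i] <- if (code == grid$nodata) NA_integer_ else code
          break
        }
      }
      break
    }
  }
  out
}

# minimal hand-built mean-function posterior / band for partition tests
fake_mfp <- function(mean, cov, start_date = as.Date("2002-07-08")) {
  structure(list(t = seq_along(mean), mean = mean, cov = as.matrix(cov),
                 start_date = start_date, label = "fake"),
            class = "mean_fn_posterior")
}

fake_band <- function(mfp, halfwidth) {
  structure(list(alpha = 0.05, gamma = NA, z = NA,
                 lower = mfp$mean - halfwidth,
                 upper = mfp$mean + halfwidth,
                 mean = mfp$mean, sds = rep(1, length(mfp$mean)),
                 coverage_estimate = NA, n_mc = 0L, seed = 0L,
                 t = mfp$t, start_date = mfp$start_date),
            class = "credible_band")
}
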