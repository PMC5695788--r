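# Independent oracles used to cross-check the implementation.

# Direct O(n^2) 2D convolution with a truncated, normalized Gaussian
# kernel and zero padding: the definition smooth_field() must match.
brute_force_smooth <- function(values, fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  radius <- ceiling(4 * sigma)
  w1 <- dnorm(seq(-radius, radius), sd = sigma)
  w1 <- w1 / sum(w1)
  kern <- outer(w1, w1)
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -radius:radius) {
        ii <- i + di
        if (ii < 1 || ii > nr) next
        for (dj in -radius:radius) {
          jj <- j + dj
          if (jj < 1 || jj > nc) next
          acc <- acc + kern[di + radius + 1, dj + radius + 1] * values[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Plain sum-of-products Pearson correlation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Monte-Carlo power of the two-sided correlation test: fraction of
# simulated bivariate-normal samples whose |r| clears the critical value.
mc_power_oracle <- function(rho, n, alpha, n_draws, seed = 1) {
  rc <- critical_r(alpha, n)
  set.seed(seed)
  block <- 10000L
  hits <- 0L
  done <- 0L
  while (done < n_draws) {
    b <- min(block, n_draws - done)
    y <- matrix(rnorm(n * b), n)
    x <- rho * y + sqrt(1 - rho^2) * matrix(rnorm(n * b), n)
    yc <- sweep(y, 2, colMeans(y)); xc <- sweep(x, 2, colMeans(x))
    r <- colSums(yc * xc) / sqrt(colSums(yc^2) * colSums(xc^2))
    hits <- hits + sum(abs(r) >= rc)
    done <- done + b
  }
  hits / n_draws
}

# Connected-component check under 4-neighborhood by flood fill.
is_connected_4 <- function(inside) {
  idx <- which(inside)
  if (length(idx) == 0L) return(FALSE)
  nr <- nrow(inside)
  visited <- matrix(FALSE, nr, ncol(inside))
  queue <- idx[1L]
  visited[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    i <- ((cur - 1L) %% nr) + 1L
    j <- ((cur - 1L) %/% nr) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1L]; jj <- j + d[2L]
      if (ii < 1L || ii > nr || jj < 1L || jj > ncol(inside)) next
      lin <- (jj - 1L) * nr + ii
      if (inside[lin] && !visited[lin]) {
        visited[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
  }
  all(visited[idx])
}
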