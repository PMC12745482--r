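# Independent oracles used across the suite. These deliberately use naive
# algorithms (scalar BFS, explicit moment sums, numerical optimization) so
# they share no code path with the implementation they check.

# Scalar breadth-first flood fill over the thresholded set.
bfs_flood_oracle <- function(values, seed, low, high, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  in_range <- values >= low & values <= high
  stopifnot(in_range[seed[1], seed[2]])
  offs <- if (connectivity == 8) {
    cbind(di = rep(-1:1, 3), dj = rep(-1:1, each = 3))[-5, ]
  } else {
    cbind(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  visited <- matrix(FALSE, nr, nc)
  qi <- integer(nr * nc); qj <- integer(nr * nc)
  qi[1] <- seed[1]; qj[1] <- seed[2]
  head <- 1L; tail <- 1L
  visited[seed[1], seed[2]] <- TRUE
  while (head <= tail) {
    pi <- qi[head]; pj <- qj[head]; head <- head + 1L
    for (k in seq_len(nrow(offs))) {
      i <- pi + offs[k, 1]; j <- pj + offs[k, 2]
      if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
          in_range[i, j] && !visited[i, j]) {
        visited[i, j] <- TRUE
        tail <- tail + 1L
        qi[tail] <- i; qj[tail] <- j
      }
    }
  }
  visited
}

# Deming fit by direct numerical minimization of the profiled loss
# sum((y - a - b x)^2) / (lambda + b^2), the generalized perpendicular
# residual; alpha is profiled out analytically.
deming_numeric_oracle <- function(x, y, lambda = 1) {
  loss <- function(beta) {
    alpha <- mean(y) - beta * mean(x)
    sum((y - alpha - beta * x)^2) / (lambda + beta^2)
  }
  opt <- stats::optimize(loss, interval = c(-50, 50), tol = 1e-12)
  beta <- opt$minimum
  list(alpha = mean(y) - beta * mean(x), beta = beta)
}

# Lin's concordance by explicit moment sums (population divisors).
ccc_moment_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Random BMD-like slice with in-range and out-of-range structure.
random_bmd_slice <- function(n = 64, seed = 1) {
  withr_seed <- function(s, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); force(code)
  }
  withr_seed(seed, {
    base <- matrix(stats::runif(n * n, 0, 600), n, n)
    # a few dense blobs so the thresholded set has non-trivial components
    for (k in 1:3) {
      ci <- sample(seq(8, n - 8), 2)
      rows <- matrix(seq_len(n), n, n)
      cols <- matrix(seq_len(n), n, n, byrow = TRUE)
      blob <- (rows - ci[1])^2 + (cols - ci[2])^2 <= stats::runif(1, 9, 49)
      base[blob] <- stats::runif(1, 500, 1500)
    }
    base
  })
}
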