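# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seeds (kept below 2^31) derived from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# round() with exact halves going to the LOWER integer (slice-index convention).
round_half_down <- function(x) as.integer(ceiling(x - 0.5))

# Population standard deviation (divisor n).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# out[i, j] = m[i + di, j + dj] where defined, `fill` elsewhere.
shift_mat <- function(m, di, dj, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  si <- max(1L, 1L - di); ei <- min(nr, nr - di)
  sj <- max(1L, 1L - dj); ej <- min(nc, nc - dj)
  if (si <= ei && sj <= ej) {
    out[si:ei, sj:ej] <- m[(si + di):(ei + di), (sj + dj):(ej + dj)]
  }
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else if (connectivity == 8) {
    o <- expand.grid(di = -1:1, dj = -1:1)
    o <- o[!(o$di == 0 & o$dj == 0), ]
    lapply(seq_len(nrow(o)), function(k) c(o$di[k], o$dj[k]))
  } else {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
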