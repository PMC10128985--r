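# Independent brute-force oracles used to cross-check the vectorised
# implementations. These deliberately use naive loops.

# flood fill with 4-connectivity; returns TRUE when all `pixels` (linear
# indices) form one connected component
flood_connected4 <- function(pixels, nr, nc) {
  if (length(pixels) <= 1L) return(TRUE)
  inset <- logical(nr * nc)
  inset[pixels] <- TRUE
  seen <- logical(nr * nc)
  queue <- pixels[1L]
  seen[queue] <- TRUE
  while (length(queue) > 0L) {
    p <- queue[[1L]]
    queue <- queue[-1L]
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r2 <- r + d[1L]; c2 <- cc + d[2L]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      q <- (c2 - 1L) * nr + r2
      if (inset[q] && !seen[q]) {
        seen[q] <- TRUE
        queue <- c(queue, q)
      }
    }
  }
  all(seen[pixels])
}

# dense two-loop diffusion oracle for new = evap*(own + diff*(nghAvg - own));
# sink boundary: off-grid neighbours contribute zero to the 8-neighbour mean
diffuse_oracle <- function(z, evap = 0.9, diff_const = 0.1) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i2 <- i + di; j2 <- j + dj
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) acc <- acc + z[i2, j2]
    }
    out[i, j] <- evap * (z[i, j] + diff_const * (acc / 8 - z[i, j]))
  }
  out
}

# mean nearest-neighbour distance of a pixel coordinate set
mean_nn_distance <- function(rc) {
  n <- nrow(rc)
  d <- as.matrix(stats::dist(rc))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

# run one diffusion step through the package on a single arbitrary layer
wrap_diffuse <- function(z, evap = 0.9, diff_const = 0.1,
                         boundary = "sink", neighbours = 8L) {
  f <- cytokine_field(nrow(z), ncol(z), evap = evap, diff_const = diff_const,
                      neighbours = neighbours, boundary = boundary)
  f$layers$IL10 <- z
  diffuse_step(f)$layers$IL10
}
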