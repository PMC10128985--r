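# Internal lattice helpers. Pixels are addressed by linear index into an
# nr x nc matrix in R's column-major order; (row, col) coordinates are 1-based
# in memory and converted to the 0-based on-disk convention at file boundaries.

# Moore neighbourhood offsets, fixed order: scanning the 3x3 block by rows with
# the centre removed. This order is what makes lexicographic tie-breaks
# ("smallest (row, col) first") fall out of a plain which.max/which.min.
.moore <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

.vonneumann <- cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))

idx_to_rc <- function(idx, nr) {
  cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
}

rc_to_idx <- function(row, col, nr) (col - 1L) * nr + row

# Neighbour linear indices for a vector of pixels: length(idx) x k matrix,
# NA where the neighbour falls off the grid.
neighbour_idx <- function(idx, nr, nc, offsets = .moore) {
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  k <- nrow(offsets)
  out <- matrix(NA_integer_, length(idx), k)
  for (j in seq_len(k)) {
    r <- row + offsets[j, 1L]
    cc <- col + offsets[j, 2L]
    ok <- r >= 1L & r <= nr & cc >= 1L & cc <= nc
    out[ok, j] <- rc_to_idx(r[ok], cc[ok], nr)
  }
  out
}

# Multi-source breadth-first Chebyshev distance map. `passable` (logical
# matrix/vector over the grid) restricts expansion; sources are always given
# distance 0 even if not passable themselves (agents stop on arrival).
# Implemented on a sentinel-padded grid so neighbour expansion is pure
# offset arithmetic with no bounds checks.
bfs_distance <- function(sources, nr, nc, passable = NULL) {
  d <- matrix(NA_integer_, nr, nc)
  sources <- unique(as.integer(sources))
  if (length(sources) == 0L) return(d)
  npr <- nr + 2L
  n_pad <- npr * (nc + 2L)
  allow <- logical(n_pad)
  cc <- rep(seq_len(nc), each = nr)
  interior <- cc * npr + rep(seq_len(nr), times = nc) + 1L
  allow[interior] <- if (is.null(passable)) TRUE else as.vector(passable)
  to_pad <- ((sources - 1L) %/% nr + 1L) * npr + ((sources - 1L) %% nr + 1L) + 1L
  offs <- c(-1L, 1L, -npr, npr, -npr - 1L, -npr + 1L, npr - 1L, npr + 1L)
  dist_p <- rep(NA_integer_, n_pad)
  dist_p[to_pad] <- 0L
  allow[to_pad] <- FALSE
  frontier <- to_pad
  dist <- 0L
  while (length(frontier) > 0L) {
    nb <- rep(frontier, each = 8L) + offs
    nb <- nb[allow[nb]]
    if (length(nb) == 0L) break
    allow[nb] <- FALSE
    nb <- unique(nb)
    dist <- dist + 1L
    dist_p[nb] <- dist
    frontier <- nb
  }
  d[] <- dist_p[interior]
  d
}

# Round-half-up, used for damage pixel counts (round() half-to-even would make
# e.g. 0.5% of an odd count ambiguous).
round_half_up <- function(x) as.integer(floor(x + 0.5))

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# One argmin/argmax per row with uniform random tie-breaking (draws from the
# current RNG stream, so runs stay reproducible under a fixed seed).
row_argmax_random <- function(m) max.col(m, ties.method = "random")
row_argmin_random <- function(m) max.col(-m, ties.method = "random")
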