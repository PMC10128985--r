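#' Tissue cross-section geometry
#'
#' A `tissue_geometry` holds the 2-D label grid that every other component of
#' the simulator operates on: muscle fibres as contiguous sets of fibril
#' pixels, an extracellular-matrix (ECM) band separating them, and empty
#' margin. Each pixel represents 3.61 um^2 of tissue and the cross-section
#' stands for a 50 um thick slice.
#'
#' Label coding (also the on-disk CSV coding, see [save_geometry()]):
#' `0` = EMPTY, `-1` = ECM, `k >= 1` = fibril pixel of fibre `k`.
#'
#' Alongside the labels the object carries per-pixel simulation state:
#' * `fib_state` / `ecm_state`: 0 = intact, 1 = damaged, 2 = removed;
#' * `collagen`: collagen density in \[0, 1\] on ECM pixels (`NA` elsewhere);
#' * `integrity`: structural integrity in \[0, 1\], chewed down by
#'   inflammatory cells before phagocytosis can complete.
#'
#' In-memory coordinates are 1-based `(row, col)` as usual for R matrices;
#' all file interfaces use 0-based coordinates.
#'
#' @param label integer matrix using the coding above.
#' @param pixel_area pixel area in um^2 (default 3.61).
#' @param slice_thickness slice thickness in um (default 50).
#' @return A `tissue_geometry` object.
#' @export
tissue_geometry <- function(label, pixel_area = 3.61, slice_thickness = 50) {
  label <- as.matrix(label)
  storage.mode(label) <- "integer"
  bad <- which(label < -1L)
  if (length(bad) > 0L) {
    rc <- idx_to_rc(bad[1L], nrow(label))
    stop(sprintf("unknown label code %d at row %d, col %d",
                 label[bad[1L]], rc[1L, 1L], rc[1L, 2L]))
  }
  fib <- label > 0L
  ecm <- label == -1L
  g <- structure(list(
    label = label,
    fib_state = matrix(ifelse(fib, 0L, NA_integer_), nrow(label), ncol(label)),
    ecm_state = matrix(ifelse(ecm, 0L, NA_integer_), nrow(label), ncol(label)),
    collagen = matrix(ifelse(ecm, 1, NA_real_), nrow(label), ncol(label)),
    integrity = matrix(ifelse(fib | ecm, 1, NA_real_), nrow(label), ncol(label)),
    pixel_area = pixel_area,
    slice_thickness = slice_thickness
  ), class = "tissue_geometry")
  g$fibre_ids <- sort(unique(label[fib]))
  g$initial_counts <- geometry_counts(g)
  g
}

#' Pixel counts of a geometry
#'
#' @param geom a [tissue_geometry()].
#' @return Named integer vector with `fibril`, `ecm` and `empty` pixel counts
#'   (by label, regardless of damage state).
#' @export
geometry_counts <- function(geom) {
  lab <- geom$label
  c(fibril = sum(lab > 0L), ecm = sum(lab == -1L), empty = sum(lab == 0L))
}

#' @export
print.tissue_geometry <- function(x, ...) {
  ct <- geometry_counts(x)
  cat(sprintf(
    "tissue_geometry: %d x %d grid, %d fibres, %d fibril / %d ECM / %d empty pixels\n",
    nrow(x$label), ncol(x$label), length(x$fibre_ids), ct[1L], ct[2L], ct[3L]))
  dmg <- sum(x$fib_state == 1L, na.rm = TRUE)
  rem <- sum(x$fib_state == 2L, na.rm = TRUE)
  if (dmg + rem > 0L)
    cat(sprintf("  fibril state: %d damaged, %d removed\n", dmg, rem))
  invisible(x)
}

# Lloyd iterations on the mask pixel coordinates; returns integer cluster
# assignment (1..k). Farthest-point initial centres keep clusters non-empty
# and well spread, giving rounded, convex-ish fibre territories.
.lloyd_assign <- function(coords, k, iters = 12L) {
  n <- nrow(coords)
  centres <- matrix(0, k, 2L)
  centres[1L, ] <- coords[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- (coords[, 1L] - centres[1L, 1L])^2 + (coords[, 2L] - centres[1L, 2L])^2
    for (j in 2L:k) {
      centres[j, ] <- coords[which.max(d2), ]
      d2 <- pmin(d2, (coords[, 1L] - centres[j, 1L])^2 +
                     (coords[, 2L] - centres[j, 2L])^2)
    }
  }
  assign <- rep(1L, n)
  for (it in seq_len(iters)) {
    dd <- matrix(0, n, k)
    for (j in seq_len(k)) {
      dd[, j] <- (coords[, 1L] - centres[j, 1L])^2 +
                 (coords[, 2L] - centres[j, 2L])^2
    }
    assign <- max.col(-dd, ties.method = "first")
    for (j in seq_len(k)) {
      inj <- assign == j
      if (!any(inj)) { # re-seed an empty cluster at the farthest pixel
        far <- which.max(dd[cbind(seq_len(n), assign)])
        assign[far] <- j
        inj <- assign == j
      }
      centres[j, ] <- colMeans(coords[inj, , drop = FALSE])
    }
  }
  assign
}

#' Generate a synthetic muscle cross-section
#'
#' Builds a label grid with exactly `n_fibres` contiguous fibres,
#' `target_fibrils` fibril pixels and `target_ecm` ECM pixels. The tissue
#' disc is tessellated into fibre territories (Lloyd/Voronoi-style around
#' well-spread seed points), territory boundaries are labelled ECM, and the
#' ECM band is then thickened or eroded pixel-by-pixel until the requested
#' counts are hit exactly. Fibres are 4-connected and no two fibres are ever
#' Moore-adjacent (the ECM band is at least one pixel wide), which the
#' generator verifies before returning.
#'
#' The default arguments reproduce the model's reference tissue: 30 fibres,
#' 25840 fibril and 4318 ECM pixels.
#'
#' @param n_fibres number of fibres (>= 1).
#' @param target_fibrils exact number of fibril pixels.
#' @param target_ecm exact number of ECM pixels.
#' @param seed RNG seed; the generator is deterministic given its arguments.
#' @return A [tissue_geometry()].
#' @export
#' @examples
#' g <- generate_cross_section(4, 400, 120, seed = 7)
#' geometry_counts(g)
generate_cross_section <- function(n_fibres = 30L, target_fibrils = 25840L,
                                   target_ecm = 4318L, seed = 1L) {
  n_fibres <- as.integer(n_fibres)
  target_fibrils <- as.integer(target_fibrils)
  target_ecm <- as.integer(target_ecm)
  if (n_fibres < 1L) stop("n_fibres must be >= 1")
  if (target_fibrils < n_fibres) stop("need at least one fibril pixel per fibre")
  if (target_ecm < 0L) stop("target_ecm must be >= 0")
  total <- target_fibrils + target_ecm
  with_seed(seed, {
    # square grid with ~15% empty margin around a tissue disc of exact size
    side <- ceiling(sqrt(total / 0.85))
    nr <- nc <- as.integer(side)
    ctr <- (side + 1) / 2
    rows <- rep(seq_len(nr), times = nc)
    cols <- rep(seq_len(nc), each = nr)
    d2 <- (rows - ctr)^2 + (cols - ctr)^2
    ord <- order(d2, rows, cols)
    mask_idx <- sort(ord[seq_len(total)])

    label <- matrix(0L, nr, nc)
    coords <- cbind(rows[mask_idx], cols[mask_idx])
    label[mask_idx] <- .lloyd_assign(coords, n_fibres)

    if (target_ecm > 0L) {
      label <- .fit_ecm_band(label, nr, nc, target_ecm)
    } else if (n_fibres > 1L) {
      stop("infeasible targets: ", n_fibres,
           " fibres cannot be separated with 0 ECM pixels")
    }
    .validate_generated(label, n_fibres, target_fibrils, target_ecm)
    tissue_geometry(label)
  })
}

# Label territory boundaries as ECM, then adjust the band to the exact count.
.fit_ecm_band <- function(label, nr, nc, target_ecm) {
  tissue <- which(label != 0L)
  nb <- neighbour_idx(tissue, nr, nc)
  nbl <- matrix(0L, nrow(nb), 8L)
  nbl[!is.na(nb)] <- label[nb[!is.na(nb)]]
  own <- label[tissue]
  # boundary: touching a different fibre or the empty margin / grid edge
  is_bnd <- rowSums(nbl != own & nbl != -1L, na.rm = FALSE) > 0L
  is_bnd <- is_bnd | rowSums(is.na(nb)) > 0L
  orig <- label # remember fibre ownership of every ECM-converted pixel
  label[tissue[is_bnd]] <- -1L

  added <- tissue[is_bnd] # conversion order, base band first
  # thicken: peel successive fibril layers adjacent to the ECM band
  while (sum(label == -1L) < target_ecm) {
    fib <- which(label > 0L)
    if (length(fib) == 0L) stop("infeasible targets: ECM band consumed all fibrils")
    nbf <- neighbour_idx(fib, nr, nc)
    touch <- rep(FALSE, length(fib))
    for (j in 1:8) {
      ok <- !is.na(nbf[, j])
      touch[ok] <- touch[ok] | label[nbf[ok, j]] == -1L
    }
    layer <- fib[touch]
    if (length(layer) == 0L) stop("infeasible targets: cannot grow ECM band")
    # do not erase a fibre completely
    sizes <- tabulate(label[label > 0L])
    keep <- sizes[label[layer]] > 1L
    take <- layer[keep]
    need <- target_ecm - sum(label == -1L)
    if (length(take) > need) take <- take[seq_len(need)]
    if (length(take) == 0L) stop("infeasible targets: cannot grow ECM band")
    added <- c(added, take)
    label[take] <- -1L
  }

  excess <- sum(label == -1L) - target_ecm
  if (excess > 0L) {
    # erode, preferring most-recently-added pixels; a conversion back to
    # fibre f is safe only when no *other* fibre is Moore-adjacent
    queue <- rev(added)
    for (p in queue) {
      if (excess == 0L) break
      if (label[p] != -1L) next
      nbp <- neighbour_idx(p, nr, nc)
      nbp <- nbp[!is.na(nbp)]
      fids <- unique(label[nbp])
      fids <- fids[fids > 0L]
      f <- orig[p]
      if (f <= 0L) f <- if (length(fids) == 1L) fids else 0L
      # safe restore: only fibre f in the Moore neighbourhood, and p attaches
      # to f through an edge (keeps fibres 4-connected)
      nbp4 <- neighbour_idx(p, nr, nc, offsets = .vonneumann)
      nbp4 <- nbp4[!is.na(nbp4)]
      if (f > 0L && all(fids == f) && any(label[nbp4] == f)) {
        label[p] <- f
        excess <- excess - 1L
      }
    }
    if (excess > 0L)
      stop("infeasible targets: ECM band cannot be eroded to ", target_ecm,
           " pixels without merging fibres")
  }
  label
}

.validate_generated <- function(label, n_fibres, target_fibrils, target_ecm) {
  nr <- nrow(label); nc <- ncol(label)
  ct <- c(sum(label > 0L), sum(label == -1L))
  if (ct[1L] != target_fibrils || ct[2L] != target_ecm)
    stop(sprintf("infeasible targets: achieved %d fibril / %d ECM pixels", ct[1L], ct[2L]))
  ids <- sort(unique(label[label > 0L]))
  if (length(ids) != n_fibres)
    stop("infeasible targets: fibre count collapsed to ", length(ids))
  # separation: no two different fibres Moore-adjacent
  fib <- which(label > 0L)
  nb <- neighbour_idx(fib, nr, nc)
  for (j in 1:8) {
    ok <- !is.na(nb[, j])
    l2 <- label[nb[ok, j]]
    if (any(l2 > 0L & l2 != label[fib[ok]]))
      stop("infeasible targets: fibres touch without an ECM band")
  }
  # 4-connectivity of each fibre
  for (f in ids) {
    px <- which(label == f)
    d <- bfs_distance_vn(px[1L], nr, nc, passable = label == f)
    if (any(is.na(d[px])))
      stop("infeasible targets: fibre ", f, " is not 4-connected")
  }
  invisible(TRUE)
}

# von Neumann BFS used for connectivity checks
bfs_distance_vn <- function(sources, nr, nc, passable) {
  d <- matrix(NA_integer_, nr, nc)
  d[sources] <- 0L
  frontier <- sources
  dist <- 0L
  while (length(frontier) > 0L) {
    nb <- neighbour_idx(frontier, nr, nc, offsets = .vonneumann)
    nb <- nb[!is.na(nb)]
    nb <- unique(nb)
    nb <- nb[is.na(d[nb]) & passable[nb]]
    if (length(nb) == 0L) break
    dist <- dist + 1L
    d[nb] <- dist
    frontier <- nb
  }
  d
}

#' Default reference geometry
#'
#' Convenience wrapper for [generate_cross_section()] at the reference tissue
#' scale: 30 fibres, 25840 fibril pixels and 4318 ECM pixels.
#'
#' @param seed RNG seed.
#' @return A [tissue_geometry()].
#' @export
default_geometry <- function(seed = 1L) {
  generate_cross_section(30L, 25840L, 4318L, seed = seed)
}

#' Fibre border pixels
#'
#' Every fibril pixel with at least one ECM pixel among its eight Moore
#' neighbours. These form the satellite-cell niche and the fibre outline that
#' fibroblasts remodel against.
#'
#' @param geom a [tissue_geometry()].
#' @return Integer matrix with columns `row`, `col` (1-based), one row per
#'   border pixel, ordered by (row, col).
#' @export
fibre_border_pixels <- function(geom) {
  idx <- border_pixel_idx(geom)
  rc <- idx_to_rc(idx, nrow(geom$label))
  rc[order(rc[, 1L], rc[, 2L]), , drop = FALSE]
}

# linear-index version used internally
border_pixel_idx <- function(geom) {
  lab <- geom$label
  nr <- nrow(lab); nc <- ncol(lab)
  fib <- which(lab > 0L)
  if (length(fib) == 0L) return(integer(0))
  nb <- neighbour_idx(fib, nr, nc)
  touch <- rep(FALSE, length(fib))
  for (j in 1:8) {
    ok <- !is.na(nb[, j])
    touch[ok] <- touch[ok] | lab[nb[ok, j]] == -1L
  }
  sort(fib[touch])
}

#' Fibre sizes
#'
#' Pixel count per fibre. Removed fibril pixels (phagocytosed and not yet
#' repaired) are excluded, so during a simulation the sizes track the tissue
#' that is actually present.
#'
#' @param geom a [tissue_geometry()].
#' @return Named integer vector, names are fibre ids.
#' @export
fibre_sizes <- function(geom) {
  lab <- geom$label
  present <- lab > 0L & geom$fib_state != 2L
  ids <- geom$fibre_ids
  sz <- tabulate(lab[present], nbins = max(ids))
  stats::setNames(sz[ids], ids)
}

#' Save / load a geometry label grid
#'
#' The on-disk format is a headerless CSV of integer label codes
#' (`0` = EMPTY, `-1` = ECM, `k >= 1` = fibre `k`) plus a JSON sidecar
#' (`<path>.json`) carrying `pixel_area` and `slice_thickness`. A `.png` path
#' writes/reads an 8-bit grayscale PNG with the same coding stored as
#' `code + 2` (so at most 253 fibres). Round-tripping reproduces the label
#' grid exactly.
#'
#' @param geom a [tissue_geometry()].
#' @param path file path (`.csv` or `.png`).
#' @return `load_geometry()` returns a [tissue_geometry()]; `save_geometry()`
#'   returns `path` invisibly.
#' @export
save_geometry <- function(geom, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(geom$label) > 253L)
      stop("PNG label export supports at most 253 fibres; use CSV")
    png::writePNG((geom$label + 2L) / 255, path)
  } else {
    utils::write.table(geom$label, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  meta <- list(pixel_area = geom$pixel_area,
               slice_thickness = geom$slice_thickness)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_geometry
#' @export
load_geometry <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    label <- matrix(as.integer(round(img * 255)) - 2L, nrow(img), ncol(img))
  } else {
    lines <- readLines(path)
    if (length(lines) == 0L) stop("parse error: empty geometry file ", path)
    parts <- strsplit(lines, ",", fixed = TRUE)
    ncol1 <- length(parts[[1L]])
    label <- matrix(0L, length(parts), ncol1)
    for (i in seq_along(parts)) {
      if (length(parts[[i]]) != ncol1)
        stop(sprintf("parse error: row %d has %d columns, expected %d",
                     i, length(parts[[i]]), ncol1))
      v <- suppressWarnings(as.integer(parts[[i]]))
      if (anyNA(v))
        stop(sprintf("parse error: non-integer label at row %d, col %d",
                     i, which(is.na(v))[1L]))
      label[i, ] <- v
    }
  }
  bad <- which(label < -1L)
  if (length(bad) > 0L) {
    rc <- idx_to_rc(bad[1L], nrow(label))
    stop(sprintf("parse error: unknown label code %d at row %d, col %d",
                 label[bad[1L]], rc[1L, 1L], rc[1L, 2L]))
  }
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    tissue_geometry(label, pixel_area = meta$pixel_area,
                    slice_thickness = meta$slice_thickness)
  } else {
    tissue_geometry(label)
  }
}
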