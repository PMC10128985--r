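#' Seed widespread (random) damage
#'
#' Marks `round_half_up(fraction * initial fibril count)` fibril pixels as
#' damaged, sampled uniformly without replacement across the whole
#' cross-section. This is the inflammatory-disease-like damage mode: no
#' mechanical signal, damage dispersed over the tissue.
#'
#' @param geom a [tissue_geometry()].
#' @param fraction damage fraction in \[0, 1\].
#' @param seed RNG seed (deterministic sampling).
#' @return Integer matrix of damaged pixel coordinates, columns `row`, `col`
#'   (1-based). The geometry itself is not modified; see [apply_damage()].
#' @export
seed_widespread <- function(geom, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  fib <- which(geom$label > 0L)
  m <- round_half_up(fraction * length(fib))
  if (m == 0L) return(cbind(row = integer(0), col = integer(0)))
  idx <- with_seed(seed, sort(sample(fib, m)))
  idx_to_rc(idx, nrow(geom$label))
}

#' Seed localised (strain-driven) damage
#'
#' Marks the `round_half_up(fraction * initial fibril count)` fibril pixels
#' carrying the highest strain as damaged, in a binary fashion. Ties at the
#' cutoff strain are broken by (row, col) lexicographic order. This is the
#' exercise-like damage mode: damage follows the mechanical strain field.
#'
#' @param geom a [tissue_geometry()].
#' @param strain a [strain_field()] covering at least the requested number of
#'   fibril pixels.
#' @param fraction damage fraction in \[0, 1\].
#' @return Integer matrix of damaged pixel coordinates (`row`, `col`).
#' @export
seed_localised <- function(geom, strain, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n_fib <- sum(geom$label > 0L)
  m <- round_half_up(fraction * n_fib)
  if (m == 0L) return(cbind(row = integer(0), col = integer(0)))
  cov <- strain$pixels
  if (length(cov) < m)
    stop(sprintf("strain field covers %d pixels but %d are required",
                 length(cov), m))
  nr <- nrow(geom$label)
  rc <- idx_to_rc(cov, nr)
  # highest strain first; ties by ascending (row, col)
  ord <- order(-strain$values[cov], rc[, 1L], rc[, 2L])
  idx <- sort(cov[ord[seq_len(m)]])
  idx_to_rc(idx, nr)
}

#' One-shot necrosis spread
#'
#' Applied once at seeding time: every fibril or ECM pixel inside the 3x3
#' block centred on a seeded damaged pixel also becomes damaged (ECM pixels
#' lose their collagen). The expansion is not recursive, so applying it twice
#' with the same seed set changes nothing.
#'
#' @param geom a [tissue_geometry()].
#' @param damaged seeded damage coordinates (matrix with `row`, `col`) as
#'   returned by [seed_widespread()] / [seed_localised()].
#' @return List with `fibril` and `ecm`: coordinate matrices of all pixels
#'   damaged after the spread (seeds included).
#' @export
propagate_necrosis <- function(geom, damaged) {
  nr <- nrow(geom$label)
  if (nrow(damaged) == 0L)
    return(list(fibril = cbind(row = integer(0), col = integer(0)),
                ecm = cbind(row = integer(0), col = integer(0))))
  seeds <- rc_to_idx(damaged[, 1L], damaged[, 2L], nr)
  block <- cbind(seeds, neighbour_idx(seeds, nr, ncol(geom$label)))
  block <- unique(block[!is.na(block)])
  fib <- sort(block[geom$label[block] > 0L])
  ecm <- sort(block[geom$label[block] == -1L])
  list(fibril = idx_to_rc(fib, nr), ecm = idx_to_rc(ecm, nr))
}

#' Apply a damage specification to a geometry
#'
#' Seeds damage in the requested mode, runs the one-shot necrosis spread
#' ([propagate_necrosis()]), and returns the mutated geometry: damaged fibril
#' pixels get `fib_state = 1`, damaged ECM pixels get `ecm_state = 1` and
#' collagen density 0.
#'
#' @param geom a [tissue_geometry()].
#' @param mode one of `"widespread"`, `"localised"`, `"none"`.
#' @param fraction damage fraction (must be 0 for mode `"none"`).
#' @param strain a [strain_field()], required for `"localised"`.
#' @param seed RNG seed for widespread sampling.
#' @param necrosis apply the 3x3 necrosis spread (default TRUE).
#' @return The modified [tissue_geometry()].
#' @export
apply_damage <- function(geom, mode = c("widespread", "localised", "none"),
                         fraction = 0, strain = NULL, seed = 1L,
                         necrosis = TRUE) {
  mode <- match.arg(mode)
  if (mode == "none") {
    if (fraction != 0) stop("mode 'none' requires fraction 0")
    return(geom)
  }
  seeds <- switch(mode,
    widespread = seed_widespread(geom, fraction, seed = seed),
    localised = {
      if (is.null(strain)) stop("localised damage requires a strain field")
      seed_localised(geom, strain, fraction)
    })
  nr <- nrow(geom$label)
  if (necrosis) {
    spread <- propagate_necrosis(geom, seeds)
    fib_idx <- rc_to_idx(spread$fibril[, 1L], spread$fibril[, 2L], nr)
    ecm_idx <- rc_to_idx(spread$ecm[, 1L], spread$ecm[, 2L], nr)
  } else {
    fib_idx <- rc_to_idx(seeds[, 1L], seeds[, 2L], nr)
    ecm_idx <- integer(0)
  }
  geom$fib_state[fib_idx] <- 1L
  if (length(ecm_idx) > 0L) {
    geom$ecm_state[ecm_idx] <- 1L
    geom$collagen[ecm_idx] <- 0
  }
  geom
}

#' Strain field over fibril pixels
#'
#' A non-negative scalar strain per covered fibril pixel, either imported
#' from a CSV (e.g. finite-element output registered to the grid) or
#' generated synthetically with [synth_strain_field()].
#'
#' @param geom a [tissue_geometry()].
#' @param values numeric matrix of strains (grid-shaped, `NA` off coverage).
#' @param provenance `"imported"` or `"synthetic"`.
#' @return A `strain_field` object with fields `values` (matrix), `pixels`
#'   (covered linear indices) and `provenance`.
#' @export
strain_field <- function(geom, values, provenance = "imported") {
  pixels <- which(!is.na(values))
  if (any(values[pixels] < 0)) stop("strain values must be >= 0")
  on_fib <- geom$label[pixels] > 0L
  if (!all(on_fib)) {
    rc <- idx_to_rc(pixels[!on_fib], nrow(values))
    stop("strain defined on non-fibril pixels at (row,col): ",
         paste(sprintf("(%d,%d)", rc[, 1L], rc[, 2L])[seq_len(min(5L, nrow(rc)))],
               collapse = " "))
  }
  structure(list(values = values, pixels = pixels, provenance = provenance),
            class = "strain_field")
}

#' Load a strain field from CSV
#'
#' Expected header `row,col,strain` with 0-based integer pixel coordinates
#' and non-negative strains; every covered pixel must be a fibril pixel of
#' `geom`.
#'
#' @param path CSV path.
#' @param geom a [tissue_geometry()] the field is registered to.
#' @return A [strain_field()] with provenance `"imported"`.
#' @export
load_strain <- function(path, geom) {
  df <- utils::read.csv(path)
  need <- c("row", "col", "strain")
  if (!all(need %in% names(df)))
    stop("strain CSV must have header row,col,strain")
  nr <- nrow(geom$label); nc <- ncol(geom$label)
  r <- as.integer(df$row) + 1L # 0-based on disk
  cc <- as.integer(df$col) + 1L
  off <- r < 1L | r > nr | cc < 1L | cc > nc
  if (any(off))
    stop("strain coordinates outside grid at CSV rows: ",
         paste(utils::head(which(off), 5L), collapse = ", "))
  vals <- matrix(NA_real_, nr, nc)
  vals[rc_to_idx(r, cc, nr)] <- df$strain
  strain_field(geom, vals, provenance = "imported")
}

#' Save a damage set to CSV
#'
#' Writes damaged pixel coordinates with the on-disk 0-based convention and
#' header `row,col`.
#'
#' @param damaged coordinate matrix (`row`, `col`, 1-based) from the seeding
#'   functions.
#' @param path output CSV path.
#' @export
save_damage_set <- function(damaged, path) {
  utils::write.csv(data.frame(row = damaged[, 1L] - 1L,
                              col = damaged[, 2L] - 1L),
                   path, row.names = FALSE)
  invisible(path)
}

#' Synthesise a strain field
#'
#' Generates a smooth, spatially correlated random field over the fibril
#' pixels (repeated box-blurred white noise, shifted to be non-negative) and
#' multiplicatively boosts it at fibre-border pixels with high local boundary
#' curvature and at fibrils adjacent to thin (< 2 px) ECM bands. This
#' emulates the finite-element observation that angular fibre geometry and
#' thin ECM concentrate strain, and makes the top strain percentiles form
#' spatial clusters the way mechanical hot-spots do.
#'
#' @param geom a [tissue_geometry()].
#' @param seed RNG seed (the field is deterministic given the seed).
#' @param smooth_passes number of 3x3 box-blur passes; the default gives a
#'   correlation length of roughly a fibre diameter, so the top strain
#'   percentiles form one or a few contiguous hot zones (as a mechanical
#'   strain concentration does) rather than scattered islets.
#' @param boost multiplicative boost applied at high-curvature border pixels
#'   and thin-ECM neighbours; mild by default so it biases which smooth hot
#'   zones reach the top percentiles without fragmenting them.
#' @return A [strain_field()] with provenance `"synthetic"`.
#' @export
synth_strain_field <- function(geom, seed = 1L, smooth_passes = 60L,
                               boost = 1.15) {
  lab <- geom$label
  nr <- nrow(lab); nc <- ncol(lab)
  with_seed(seed, {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    for (k in seq_len(smooth_passes)) z <- box_blur(z)
    z <- z - min(z)

    fib <- which(lab > 0L)
    nb <- neighbour_idx(fib, nr, nc)
    ecm_ngh <- matrix(FALSE, length(fib), 8L)
    ok <- !is.na(nb)
    ecm_ngh[ok] <- lab[nb[ok]] == -1L
    n_ecm <- rowSums(ecm_ngh)
    border <- fib[n_ecm > 0L]
    # curvature proxy: border pixels with many ECM neighbours sit at corners
    curved <- fib[n_ecm >= 3L]

    # thin ECM: an ECM pixel Moore-adjacent to two different fibres means the
    # band is < 2 px wide there; boost the fibrils touching such pixels
    ecm <- which(lab == -1L)
    nbe <- neighbour_idx(ecm, nr, nc)
    thin <- rep(FALSE, length(ecm))
    for (j in 1:8) {
      okj <- !is.na(nbe[, j])
      l2 <- ifelse(okj, lab[nbe[, j]], 0L)
      for (k in 1:8) {
        if (k <= j) next
        okk <- okj & !is.na(nbe[, k])
        l3 <- ifelse(okk, lab[nbe[, k]], 0L)
        thin <- thin | (okk & l2 > 0L & l3 > 0L & l2 != l3)
      }
    }
    thin_ecm <- ecm[thin]
    if (length(thin_ecm) > 0L) {
      nbt <- neighbour_idx(thin_ecm, nr, nc)
      nbt <- nbt[!is.na(nbt)]
      thin_fib <- unique(nbt[lab[nbt] > 0L])
    } else thin_fib <- integer(0)

    z[curved] <- z[curved] * boost
    z[thin_fib] <- z[thin_fib] * boost
    vals <- matrix(NA_real_, nr, nc)
    vals[fib] <- z[fib]
    strain_field(geom, vals, provenance = "synthetic")
  })
}

# 3x3 box blur with edge replication (internal)
box_blur <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  up <- z[c(1L, seq_len(nr - 1L)), ]
  dn <- z[c(seq_len(nr - 1L) + 1L, nr), ]
  acc <- z + up + dn
  lf <- acc[, c(1L, seq_len(nc - 1L))]
  rt <- acc[, c(seq_len(nc - 1L) + 1L, nc)]
  (acc + lf + rt) / 9
}
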