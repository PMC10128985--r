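#' Cytokine names
#'
#' The seven secreted factors carried as value layers, in the fixed internal
#' order used throughout the package.
#' @export
CYTOKINES <- c("IL10", "IL15", "TNF", "HGF", "IL6", "IGF1", "TGFb")

#' Default production coefficients
#'
#' The 31 named, non-negative coefficients of the seven signed linear
#' production equations, flattened in equation order (IL-10, IL-15, TNF-a,
#' HGF, IL-6, IGF-1, TGF-b). Signs live in the equation structure, not in
#' the coefficients; see [production_rates()].
#'
#' @return Named numeric vector of length 31.
#' @export
default_coefficients <- function() {
  c(il10_AM = 0.899, il10_IL6 = 0.827, il10_HGF = 0.670,
    il15_F = 0.004, il15_Mb = 0.558, il15_TNF = 0.377, il15_TGFb = 0.825,
    tnf_IM = 0.273, tnf_N = 0.456, tnf_Fb = 0.493, tnf_TGFb = 0.346,
    tnf_IL6 = 0.106, tnf_IL10 = 0.044, tnf_IGF1 = 0.485,
    hgf_F = 0.755, hgf_IL6 = 0.156,
    il6_N = 0.043, il6_IM = 0.395, il6_F = 0.077, il6_HGF = 0.077,
    il6_TGFb = 0.132, il6_TNF = 0.482,
    igf1_AM = 0.258, igf1_F = 0.009, igf1_TNF = 0.788, igf1_TGFb = 0.019,
    igf1_IL6 = 0.477, igf1_IL10 = 0.826,
    tgfb_F = 0.007, tgfb_AM = 0.211, tgfb_IL6 = 0.798)
}

#' Validate a coefficient set
#'
#' @param coeffs named numeric vector; must contain exactly the 31 names of
#'   [default_coefficients()], all non-negative.
#' @return The coefficients, reordered canonically.
#' @export
coefficient_set <- function(coeffs = default_coefficients()) {
  ref <- names(default_coefficients())
  if (length(coeffs) != 31L || !setequal(names(coeffs), ref))
    stop("a coefficient set needs exactly the 31 named coefficients")
  coeffs <- coeffs[ref]
  if (any(coeffs < 0)) stop("coefficients must be >= 0 (signs are structural)")
  coeffs
}

#' Population counts entering the production equations
#'
#' @param AM anti-inflammatory (M2) macrophage count.
#' @param IM pro-inflammatory (M1) macrophage count.
#' @param N neutrophil count.
#' @param Fb fibroblast count.
#' @param F fibre count (constant during a run).
#' @param Mb myoblast count.
#' @return Named numeric vector.
#' @export
population_counts <- function(AM = 0, IM = 0, N = 0, Fb = 0, F = 0, Mb = 0) {
  x <- c(AM = AM, IM = IM, N = N, Fb = Fb, F = F, Mb = Mb)
  if (any(x < 0)) stop("population counts must be non-negative")
  x
}

#' Cytokine production rates
#'
#' The seven time-derivatives of the secreted-factor levels, per the signed
#' linear combinations of cell counts and current cytokine levels:
#' \deqn{dIL10/dt = 0.899 AM + 0.827 IL6 + 0.670 HGF}
#' \deqn{dIL15/dt = 0.004 F + 0.558 Mb + 0.377 TNF - 0.825 TGFb}
#' \deqn{dTNF/dt  = 0.273 IM + 0.456 N + 0.493 Fb - 0.346 TGFb - 0.106 IL6
#'                 - 0.044 IL10 - 0.485 IGF1}
#' \deqn{dHGF/dt  = 0.755 F + 0.156 IL6}
#' \deqn{dIL6/dt  = 0.043 N + 0.395 IM + 0.077 F - 0.077 HGF - 0.132 TGFb
#'                 + 0.482 TNF}
#' \deqn{dIGF1/dt = 0.258 AM + 0.009 F - 0.788 TNF - 0.019 TGFb - 0.477 IL6
#'                 + 0.826 IL10}
#' \deqn{dTGFb/dt = 0.007 F + 0.211 AM + 0.798 IL6}
#' (coefficients shown at their defaults; any [coefficient_set()] may be
#' supplied, e.g. one produced by [ga_optimise()]).
#'
#' @param counts a [population_counts()] vector.
#' @param totals named numeric vector of current cytokine levels (arbitrary
#'   units), names as in [CYTOKINES]; missing entries are taken as 0.
#' @param coeffs a [coefficient_set()].
#' @return Named numeric vector of the seven derivatives.
#' @export
production_rates <- function(counts, totals = NULL,
                             coeffs = default_coefficients()) {
  counts <- population_counts(counts[["AM"]], counts[["IM"]], counts[["N"]],
                              counts[["Fb"]], counts[["F"]], counts[["Mb"]])
  tot <- stats::setNames(numeric(7L), CYTOKINES)
  if (!is.null(totals)) tot[names(totals)] <- totals
  k <- coefficient_set(coeffs)
  c(IL10 = k[["il10_AM"]] * counts[["AM"]] + k[["il10_IL6"]] * tot[["IL6"]] +
      k[["il10_HGF"]] * tot[["HGF"]],
    IL15 = k[["il15_F"]] * counts[["F"]] + k[["il15_Mb"]] * counts[["Mb"]] +
      k[["il15_TNF"]] * tot[["TNF"]] - k[["il15_TGFb"]] * tot[["TGFb"]],
    TNF = k[["tnf_IM"]] * counts[["IM"]] + k[["tnf_N"]] * counts[["N"]] +
      k[["tnf_Fb"]] * counts[["Fb"]] - k[["tnf_TGFb"]] * tot[["TGFb"]] -
      k[["tnf_IL6"]] * tot[["IL6"]] - k[["tnf_IL10"]] * tot[["IL10"]] -
      k[["tnf_IGF1"]] * tot[["IGF1"]],
    HGF = k[["hgf_F"]] * counts[["F"]] + k[["hgf_IL6"]] * tot[["IL6"]],
    IL6 = k[["il6_N"]] * counts[["N"]] + k[["il6_IM"]] * counts[["IM"]] +
      k[["il6_F"]] * counts[["F"]] - k[["il6_HGF"]] * tot[["HGF"]] -
      k[["il6_TGFb"]] * tot[["TGFb"]] + k[["il6_TNF"]] * tot[["TNF"]],
    IGF1 = k[["igf1_AM"]] * counts[["AM"]] + k[["igf1_F"]] * counts[["F"]] -
      k[["igf1_TNF"]] * tot[["TNF"]] - k[["igf1_TGFb"]] * tot[["TGFb"]] -
      k[["igf1_IL6"]] * tot[["IL6"]] + k[["igf1_IL10"]] * tot[["IL10"]],
    TGFb = k[["tgfb_F"]] * counts[["F"]] + k[["tgfb_AM"]] * counts[["AM"]] +
      k[["tgfb_IL6"]] * tot[["IL6"]])
}

#' Cytokine value layers
#'
#' Seven scalar grids co-registered with the tissue grid, holding secreted
#' factor levels in arbitrary units as deviations from the optimised baseline
#' (so a freshly created field is all zero). Diffusion follows the update
#' `new = evap * (own + diffConst * (nghAvg - own))` with the grid edge as a
#' value sink.
#'
#' @param nr,nc grid dimensions (or pass `geom` instead).
#' @param geom optional [tissue_geometry()] supplying the dimensions.
#' @param evap evaporation constant in \[0, 1\] (default 0.9).
#' @param diff_const diffusion constant in \[0, 1\] (default 0.1).
#' @param neighbours 8 (Moore, default) or 4 (von Neumann) for the
#'   neighbour average.
#' @param boundary `"sink"` (default: off-grid neighbours contribute zero and
#'   outflow is lost) or `"closed"` (reflective: with `evap = 1` total mass
#'   is conserved).
#' @return A `cytokine_field` object: list of layer matrices plus constants.
#' @export
cytokine_field <- function(nr = NULL, nc = NULL, geom = NULL, evap = 0.9,
                           diff_const = 0.1, neighbours = 8L,
                           boundary = c("sink", "closed")) {
  if (!is.null(geom)) { nr <- nrow(geom$label); nc <- ncol(geom$label) }
  stopifnot(evap >= 0, evap <= 1, diff_const >= 0, diff_const <= 1,
            neighbours %in% c(4L, 8L))
  boundary <- match.arg(boundary)
  layers <- stats::setNames(
    lapply(CYTOKINES, function(.) matrix(0, nr, nc)), CYTOKINES)
  structure(list(layers = layers, evap = evap, diff_const = diff_const,
                 neighbours = as.integer(neighbours), boundary = boundary),
            class = "cytokine_field")
}

#' @export
print.cytokine_field <- function(x, ...) {
  tot <- vapply(x$layers, sum, numeric(1))
  cat(sprintf("cytokine_field: %d x %d, evap=%g, diffConst=%g, %d-neighbour, %s boundary\n",
              nrow(x$layers[[1L]]), ncol(x$layers[[1L]]), x$evap,
              x$diff_const, x$neighbours, x$boundary))
  print(round(tot, 4))
  invisible(x)
}

#' Deposit production into a layer
#'
#' A positive delta is split equally over the cytokine's source pixels and
#' added there; with no source pixels it is spread uniformly over the layer.
#' A negative delta is applied uniformly over the layer and each pixel is
#' clamped at zero (levels are deviations and never go negative).
#'
#' @param field a [cytokine_field()].
#' @param cytokine layer name (one of [CYTOKINES]).
#' @param delta scalar production for this tick.
#' @param source_pixels integer vector of linear pixel indices (may be empty).
#' @return The modified field.
#' @export
deposit <- function(field, cytokine, delta, source_pixels = integer(0)) {
  layer <- field$layers[[cytokine]]
  if (delta > 0) {
    if (length(source_pixels) > 0L) {
      layer[source_pixels] <- layer[source_pixels] + delta / length(source_pixels)
    } else {
      layer <- layer + delta / length(layer)
    }
  } else if (delta < 0) {
    layer <- pmax(layer + delta / length(layer), 0)
  }
  field$layers[[cytokine]] <- layer
  field
}

# sum of the k shifted copies of z (neighbour sum) via one padded matrix;
# pad "zero" implements the value-sink boundary, "replicate" the closed one
.neighbour_sum <- function(z, offsets, pad = "zero") {
  nr <- nrow(z); nc <- ncol(z)
  w <- max(abs(offsets))
  zp <- matrix(0, nr + 2L * w, nc + 2L * w)
  zp[(w + 1L):(nr + w), (w + 1L):(nc + w)] <- z
  if (pad == "replicate") {
    for (k in seq_len(w)) {
      zp[w + 1L - k, ] <- zp[w + 2L - k, ]
      zp[nr + w + k, ] <- zp[nr + w + k - 1L, ]
      zp[, w + 1L - k] <- zp[, w + 2L - k]
      zp[, nc + w + k] <- zp[, nc + w + k - 1L]
    }
  }
  acc <- matrix(0, nr, nc)
  for (j in seq_len(nrow(offsets))) {
    acc <- acc + zp[(w + 1L + offsets[j, 1L]):(nr + w + offsets[j, 1L]),
                    (w + 1L + offsets[j, 2L]):(nc + w + offsets[j, 2L])]
  }
  acc
}

#' One diffusion/evaporation step
#'
#' Updates every pixel of every layer simultaneously by
#' `new = evap * (own + diffConst * (nghAvg - own))`, where `nghAvg` is the
#' equal-weight average over the configured neighbourhood. With the default
#' sink boundary, out-of-grid neighbours contribute zero to the average and
#' the corresponding outflow leaves the grid; with a closed boundary the
#' edge reflects (and `evap = 1` conserves total mass exactly).
#'
#' @param field a [cytokine_field()].
#' @return The updated field.
#' @export
diffuse_step <- function(field) {
  offs <- if (field$neighbours == 8L) .moore else .vonneumann
  pad <- if (field$boundary == "closed") "replicate" else "zero"
  ev <- field$evap
  dc <- field$diff_const
  for (nm in names(field$layers)) {
    z <- field$layers[[nm]]
    ngh_avg <- .neighbour_sum(z, offs, pad) / nrow(offs)
    field$layers[[nm]] <- ev * (z + dc * (ngh_avg - z))
  }
  field
}

#' Local sensing of a cytokine layer
#'
#' `sense()` reads the local level; `best_neighbour()` returns the Moore
#' neighbour with the maximal level, ties broken by lexicographic (row, col)
#' order; `temporal_gradient_positive()` compares the level at a pixel with
#' its value in the previous-tick layer.
#'
#' @param field a [cytokine_field()].
#' @param cytokine layer name.
#' @param pixel `c(row, col)` (1-based).
#' @return `sense()`: scalar; `best_neighbour()`: `c(row, col)` of the best
#'   neighbour; `temporal_gradient_positive()`: logical.
#' @export
sense <- function(field, cytokine, pixel) {
  field$layers[[cytokine]][pixel[1L], pixel[2L]]
}

#' @rdname sense
#' @export
best_neighbour <- function(field, cytokine, pixel) {
  layer <- field$layers[[cytokine]]
  pixel <- as.integer(pixel)
  nr <- nrow(layer); nc <- ncol(layer)
  nb <- neighbour_idx(rc_to_idx(pixel[1L], pixel[2L], nr), nr, nc)[1L, ]
  nb <- nb[!is.na(nb)] # .moore order is (row, col)-lexicographic
  best <- nb[which.max(layer[nb])]
  unname(idx_to_rc(best, nr)[1L, ])
}

#' @rdname sense
#' @param previous the previous-tick [cytokine_field()] (history).
#' @export
temporal_gradient_positive <- function(field, previous, cytokine, pixel) {
  sense(field, cytokine, pixel) > sense(previous, cytokine, pixel)
}

#' Layer totals
#'
#' @param field a [cytokine_field()].
#' @return Named numeric vector of per-layer sums (arbitrary units).
#' @export
field_totals <- function(field) {
  vapply(field$layers, sum, numeric(1))
}

#' Read / write a coefficient file
#'
#' JSON with the 31 named coefficients of [default_coefficients()].
#' @param path file path.
#' @param coeffs a [coefficient_set()].
#' @export
save_coefficients <- function(coeffs, path) {
  jsonlite::write_json(as.list(coefficient_set(coeffs)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_coefficients
#' @export
load_coefficients <- function(path) {
  coefficient_set(unlist(jsonlite::read_json(path)))
}
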