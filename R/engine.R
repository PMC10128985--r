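# Simulation engine: state initialisation, the tick loop, and ensemble
# orchestration. The state lives in an environment so the per-tick phase
# functions (agents.R) can mutate grids and agent tables in place.

new_sim_state <- function(geom, cfg, run_seed) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$nr <- nrow(geom$label)
  st$nc <- ncol(geom$label)
  st$lab <- geom$label
  st$fstate <- geom$fib_state
  st$estate <- geom$ecm_state
  st$coll <- geom$collagen
  st$integ <- geom$integrity
  st$n_fibres <- length(geom$fibre_ids)
  st$fibre_ids <- geom$fibre_ids
  st$pixel_area <- geom$pixel_area
  st$slice_thickness <- geom$slice_thickness
  st$claimed <- matrix(FALSE, st$nr, st$nc)
  st$removed_tick <- matrix(NA_integer_, st$nr, st$nc)
  st$fields <- cytokine_field(st$nr, st$nc, evap = cfg$evap,
                              diff_const = cfg$diff_const,
                              neighbours = cfg$neighbours,
                              boundary = cfg$boundary)
  st$prev <- st$fields$layers
  st$border <- border_pixel_idx(geom)
  st$border_rc <- idx_to_rc(st$border, st$nr)
  st$sc_moves <- moves_per_tick(cfg$sc_speed_um, cfg$pixel_area)
  st$fib_moves <- moves_per_tick(cfg$fibroblast_speed_um, cfg$pixel_area)

  ags <- init_agents(geom, seed = derive_seed(run_seed, 202L), config = cfg)
  st$neut <- ags$neutrophils[c("idx", "target", "timer", "idle")]
  st$mac <- ags$macrophages[c("idx", "target", "timer", "idle", "phen", "nphago")]
  st$sc <- ags$satellite_cells[c("idx", "stage", "timer", "dwell", "cool",
                                 "lowhgf", "site", "act_age")]
  st$n_sc_seeded <- nrow(st$sc)
  st$fibro <- data.frame(idx = ags$fibroblasts$idx, target = NA_integer_,
                         timer = NA_integer_)


  st$tick <- 0L
  st$cum_sc_activated <- 0L
  st$dmg_dirty <- TRUE
  st$fib_dirty <- TRUE
  st$border_dirty <- FALSE
  st$dmap_damage <- NULL
  st$dmap_repair <- NULL
  st$dmap_fib <- NULL
  st$dmap_border <- NULL
  st$fib_tgt_built <- -1L
  st$src_neut <- integer(0)
  st$src_mac <- integer(0)
  st$initial_fibril <- sum(geom$label > 0L)
  st$initial_ecm <- sum(geom$label == -1L)
  st
}

.refresh_masks <- (function() {
  function(st) {
    cfg <- st$cfg
    fs <- st$fstate
    # myoblasts fuse only where debris has been cleared (removed sites);
    # work_mask tracks any outstanding fibril injury
    st$repair_mask <- !is.na(fs) & fs == 2L
    st$work_mask <- !is.na(fs) & (fs == 1L | fs == 2L)
    age_ok <- !is.na(st$removed_tick) &
      (st$tick - st$removed_tick) >= cfg$fibrosis_delay
    es <- st$estate
    ecm_need <- !is.na(es) & (es != 0L | st$coll < 1)
    ecm_need[is.na(ecm_need)] <- FALSE
    gap <- !is.na(fs) & fs == 2L & !st$claimed & age_ok
    if (any(gap)) {
      # fibrosis is a response to dense chronic gap fields: a candidate must
      # sit in a neighbourhood of many unrepaired gaps (isolated lesions
      # awaiting repair are spared) and touch the current ECM network, so
      # it creeps in from the matrix
      gap_all <- (!is.na(fs) & fs == 2L) + 0
      offs24 <- as.matrix(expand.grid(dr = -2:2, dc = -2:2))
      offs24 <- offs24[!(offs24[, 1L] == 0L & offs24[, 2L] == 0L), , drop = FALSE]
      dens <- .neighbour_sum(gap_all, offs24) + gap_all
      gap <- gap & dens >= cfg$fibrosis_density
      gi <- which(gap)
      if (length(gi) > 0L) {
        nb <- neighbour_idx(gi, st$nr, st$nc)
        touch <- rep(FALSE, length(gi))
        for (j in 1:8) {
          okj <- !is.na(nb[, j])
          touch[okj] <- touch[okj] | st$lab[nb[okj, j]] == -1L
        }
        gap[gi[!touch]] <- FALSE
      }
    }
    st$fib_target_mask <- ecm_need | gap
    # effective collagen for neutrophil search: damage and debris read as 0
    ceff <- matrix(Inf, st$nr, st$nc)
    fib <- !is.na(fs)
    ceff[fib] <- ifelse(fs[fib] == 0L, 1, 0)
    ecm <- !is.na(es)
    ceff[ecm] <- ifelse(es[ecm] == 2L, 0, st$coll[ecm])
    st$ceff <- ceff
    invisible()
  }
})()

.refresh_maps <- function(st) {
  cfg <- st$cfg
  due <- st$tick %% cfg$map_refresh == 0L
  if (is.null(st$dmap_damage) || (due && st$dmg_dirty)) {
    dmg_idx <- which(.mask_damaged(st))
    st$dmap_damage <- bfs_distance(dmg_idx, st$nr, st$nc)
    st$dmg_dirty <- length(dmg_idx) > 0L # claims/removals keep it live
  }
  if (is.null(st$dmap_repair) || due) {
    rep_idx <- which(st$repair_mask & !st$claimed)
    st$dmap_repair <- bfs_distance(rep_idx, st$nr, st$nc,
                                   passable = st$lab != 0L)
  }
  n_fib_tgt <- sum(st$fib_target_mask)
  if (is.null(st$dmap_fib) ||
      (due && (st$fib_dirty || n_fib_tgt != st$fib_tgt_built))) {
    passable <- st$lab == -1L |
      (st$lab > 0L & !is.na(st$fstate) & st$fstate == 2L)
    st$dmap_fib <- bfs_distance(which(st$fib_target_mask), st$nr, st$nc,
                                passable = passable)
    st$fib_tgt_built <- n_fib_tgt
    st$fib_dirty <- FALSE
  }
  if (st$border_dirty || is.null(st$dmap_border)) {
    if (st$border_dirty) {
      g <- .state_geometry(st)
      st$border <- border_pixel_idx(g)
      st$border_rc <- idx_to_rc(st$border, st$nr)
      st$border_dirty <- FALSE
    }
    # hypertrophy targets: border pixels that actually have a convertible
    # neighbour (an ECM/EMPTY pixel touching exactly one fibre); narrow
    # inter-fibre bands never qualify, so myoblasts head straight for
    # expandable stretches of the outline instead of wandering
    viable <- .viable_border(st)
    if (length(viable) == 0L) viable <- st$border
    st$dmap_border <- bfs_distance(viable, st$nr, st$nc,
                                   passable = st$lab != 0L)
  }
  invisible()
}

.viable_border <- function(st) {
  conv <- which(st$lab <= 0L)
  if (length(conv) == 0L) return(integer(0))
  nb <- neighbour_idx(conv, st$nr, st$nc)
  lo <- matrix(Inf, length(conv), 8L)
  hi <- matrix(-Inf, length(conv), 8L)
  ok <- !is.na(nb)
  lv <- st$lab[nb[ok]]
  fib <- lv > 0L
  lo[ok][fib] <- lv[fib]
  hi[ok][fib] <- lv[fib]
  lo_min <- do.call(pmin, as.data.frame(lo))
  hi_max <- do.call(pmax, as.data.frame(hi))
  safe <- conv[is.finite(lo_min) & lo_min == hi_max]
  if (length(safe) == 0L) return(integer(0))
  # border fibrils Moore-adjacent to a safe convertible pixel
  nb2 <- neighbour_idx(safe, st$nr, st$nc)
  nb2 <- nb2[!is.na(nb2)]
  out <- unique(nb2[st$lab[nb2] > 0L])
  intersect(out, st$border)
}

# rebuild a tissue_geometry view of the current grid state
.state_geometry <- function(st) {
  g <- structure(list(
    label = st$lab, fib_state = st$fstate, ecm_state = st$estate,
    collagen = st$coll, integrity = st$integ,
    pixel_area = st$pixel_area, slice_thickness = st$slice_thickness
  ), class = "tissue_geometry")
  g$fibre_ids <- st$fibre_ids
  g$initial_counts <- c(fibril = st$initial_fibril, ecm = st$initial_ecm,
                        empty = sum(st$lab == 0L))
  g
}

# Term-wise spatial deposition of the production equations. Each
# population's production term lands on that population's pixels
# (inflammatory terms only where cells are in contact with damage, fibre
# terms along the fibre borders, HGF on damaged ECM), while the
# cytokine-cross terms act on the layer as a whole. The per-layer sums of
# all contributions equal production_rates() exactly; only the spatial
# placement is refined here.
.deposit_production <- function(field, coeffs, counts, totals, src) {
  k <- coeffs
  dep <- function(f, nm, amount, sources, fallback = integer(0)) {
    if (amount == 0) return(f)
    if (length(sources) == 0L) sources <- fallback
    deposit(f, nm, amount, sources)
  }
  AM <- counts[["AM"]]; IM <- counts[["IM"]]; N <- counts[["N"]]
  Fb <- counts[["Fb"]]; FF <- counts[["F"]]; Mb <- counts[["Mb"]]
  tt <- totals
  f <- field
  # IL-10: M2-driven, amplified by IL-6 and HGF
  f <- dep(f, "IL10", k[["il10_AM"]] * AM, src$m2)
  f <- dep(f, "IL10", k[["il10_IL6"]] * tt[["IL6"]] +
             k[["il10_HGF"]] * tt[["HGF"]], integer(0))
  # IL-15: fibre-derived, myoblast-derived, TNF up / TGF-b down
  f <- dep(f, "IL15", k[["il15_F"]] * FF, src$border)
  f <- dep(f, "IL15", k[["il15_Mb"]] * Mb, src$myoblasts, src$border)
  f <- dep(f, "IL15", k[["il15_TNF"]] * tt[["TNF"]] -
             k[["il15_TGFb"]] * tt[["TGFb"]], integer(0))
  # TNF-a: released by inflammatory cells in contact with damage and by
  # fibroblasts; suppressed by the anti-inflammatory milieu
  f <- dep(f, "TNF", k[["tnf_IM"]] * IM, src$m1_contact)
  f <- dep(f, "TNF", k[["tnf_N"]] * N, src$neut_contact)
  f <- dep(f, "TNF", k[["tnf_Fb"]] * Fb, src$fibroblasts, src$ecm)
  f <- dep(f, "TNF", -(k[["tnf_TGFb"]] * tt[["TGFb"]] +
                       k[["tnf_IL6"]] * tt[["IL6"]] +
                       k[["tnf_IL10"]] * tt[["IL10"]] +
                       k[["tnf_IGF1"]] * tt[["IGF1"]]), integer(0))
  # HGF: released from the ECM as a whole; the IL-6-stimulated component
  # raises it everywhere during inflammation (the satellite-cell niche senses
  # this elevation relative to its baseline)
  f <- dep(f, "HGF", k[["hgf_F"]] * FF + k[["hgf_IL6"]] * tt[["IL6"]],
           src$ecm)
  # IL-6
  f <- dep(f, "IL6", k[["il6_N"]] * N, src$neut_contact)
  f <- dep(f, "IL6", k[["il6_IM"]] * IM, src$m1_contact)
  f <- dep(f, "IL6", k[["il6_F"]] * FF, src$border)
  f <- dep(f, "IL6", k[["il6_TNF"]] * tt[["TNF"]] -
             k[["il6_HGF"]] * tt[["HGF"]] -
             k[["il6_TGFb"]] * tt[["TGFb"]], integer(0))
  # IGF-1
  f <- dep(f, "IGF1", k[["igf1_AM"]] * AM, src$m2)
  f <- dep(f, "IGF1", k[["igf1_F"]] * FF, src$border)
  f <- dep(f, "IGF1", k[["igf1_IL10"]] * tt[["IL10"]] -
             k[["igf1_TNF"]] * tt[["TNF"]] -
             k[["igf1_TGFb"]] * tt[["TGFb"]] -
             k[["igf1_IL6"]] * tt[["IL6"]], integer(0))
  # TGF-b
  f <- dep(f, "TGFb", k[["tgfb_AM"]] * AM, src$m2)
  f <- dep(f, "TGFb", k[["tgfb_F"]] * FF, src$border)
  f <- dep(f, "TGFb", k[["tgfb_IL6"]] * tt[["IL6"]], integer(0))
  f
}

.production_phase <- function(st) {
  cfg <- st$cfg
  counts <- population_counts(
    AM = sum(st$mac$phen == 2L), IM = sum(st$mac$phen == 1L),
    N = nrow(st$neut), Fb = nrow(st$fibro), F = st$n_fibres,
    Mb = sum(st$sc$stage %in% c(3L, 4L)))
  src <- list(
    m2 = st$mac$idx[st$mac$phen == 2L],
    m1_contact = unique(st$src_mac),
    neut_contact = unique(st$src_neut),
    fibroblasts = st$fibro$idx,
    border = st$border,
    myoblasts = st$sc$idx[st$sc$stage %in% c(3L, 4L)],
    dmg_ecm = which(!is.na(st$estate) & st$estate == 1L),
    ecm = which(st$lab == -1L))
  st$fields <- .deposit_production(st$fields, cfg$coefficients, counts,
                                   field_totals(st$fields), src)
  invisible()
}

.record_row <- function(st) {
  fs <- st$fstate
  es <- st$estate
  tot <- field_totals(st$fields)
  c(tick = st$tick,
    fibril = sum(fs == 0L, na.rm = TRUE),
    damaged_fibril = sum(fs == 1L, na.rm = TRUE),
    removed_fibril = sum(fs == 2L, na.rm = TRUE),
    ecm = sum(es != 2L, na.rm = TRUE),
    damaged_ecm = sum(es == 1L, na.rm = TRUE),
    neutrophils = nrow(st$neut),
    macrophages = nrow(st$mac),
    m1 = sum(st$mac$phen == 1L),
    m2 = sum(st$mac$phen == 2L),
    sc_quiescent = sum(st$sc$stage == 0L),
    sc_active = sum(st$sc$stage == 2L),
    myoblasts = sum(st$sc$stage %in% c(3L, 4L)),
    sc_total = nrow(st$sc),
    fibroblasts = nrow(st$fibro),
    cum_sc_activated = st$cum_sc_activated,
    tot)
}

.sim_tick <- function(st) {
  st$tick <- st$tick + 1L
  .refresh_masks(st)
  .refresh_maps(st)
  st$src_neut <- integer(0)
  st$src_mac <- integer(0)

  phases <- list(.step_neutrophils, .step_macrophages,
                 .step_satellite_cells, .step_fibroblasts)
  ord <- if (st$cfg$ordering == "shuffled") sample.int(4L) else 1:4
  for (k in ord) phases[[k]](st)

  # remodelled fibre outline once the satellite-cell response has wound down
  if (all(st$sc$stage %in% c(0L, 1L)) && st$border_dirty) {
    g <- .state_geometry(st)
    st$border <- border_pixel_idx(g)
    st$border_rc <- idx_to_rc(st$border, st$nr)
    st$border_dirty <- FALSE
    st$dmap_border <- NULL
  }

  st$prev <- st$fields$layers
  .production_phase(st)
  st$fields <- diffuse_step(st$fields)
  .record_row(st)
}

#' Steady-state cytokine field
#'
#' The production coefficients determine not only the dynamics but the
#' starting condition: the value layers are initialised at the steady state
#' of the undisturbed tissue (baseline populations, no damage, no
#' inflammatory contact so pro-inflammatory production is spread uniformly,
#' IL-15 released along the fibre borders). The steady state is found by
#' iterating the production/diffusion update to a fixed point; because
#' several production terms are negative and layers clamp at zero, the
#' pro-inflammatory layers settle at zero and the anti-inflammatory layers
#' at positive levels.
#'
#' @param geom a [tissue_geometry()].
#' @param config a [sim_config()].
#' @param tol convergence tolerance on the largest per-pixel change.
#' @param max_iter iteration cap.
#' @return A [cytokine_field()] at (numerical) steady state.
#' @export
steady_state_field <- function(geom, config = sim_config(), tol = 1e-10,
                               max_iter = 2000L) {
  cfg <- config
  field <- cytokine_field(geom = geom, evap = cfg$evap,
                          diff_const = cfg$diff_const,
                          neighbours = cfg$neighbours, boundary = cfg$boundary)
  counts <- population_counts(AM = 0, IM = cfg$baseline_macrophages,
                              N = cfg$baseline_neutrophils,
                              Fb = cfg$baseline_fibroblasts,
                              F = length(geom$fibre_ids), Mb = 0)
  # undisturbed-tissue sources: no inflammatory contact, no M2, resident
  # fibroblast output spread over the ECM, fibre terms along the borders
  src <- list(m2 = integer(0), m1_contact = integer(0),
              neut_contact = integer(0), fibroblasts = integer(0),
              border = border_pixel_idx(geom), myoblasts = integer(0),
              dmg_ecm = integer(0), ecm = which(geom$label == -1L))
  for (it in seq_len(max_iter)) {
    field <- .deposit_production(field, cfg$coefficients, counts,
                                 field_totals(field), src)
    new <- diffuse_step(field)
    delta <- max(vapply(CYTOKINES, function(nm)
      max(abs(new$layers[[nm]] - field$layers[[nm]])), numeric(1)))
    field <- new
    if (delta < tol) break
  }
  field
}

#' Run one simulation
#'
#' Seeds damage at tick 0 (with the one-shot necrosis spread), initialises
#' the agent populations and zeroed value layers, then advances the model
#' one hour per tick: agent phases in shuffled order, cytokine production
#' and deposition, one diffusion step, and recording. The run is fully
#' deterministic given `(config, seed, geometry)`.
#'
#' @param config a [sim_config()].
#' @param geom a [tissue_geometry()]; `NULL` builds the default reference
#'   geometry (30 fibres, 25840/4318 pixels, geometry seed 1).
#' @param run_seed RNG seed for this run; defaults to `config$seed`.
#' @param baseline optional [steady_state_field()] to start from (computed
#'   when `NULL`; ensembles share one).
#' @return A `muscle_sim` list: `series` (data frame, one row per tick
#'   including tick 0), `geometry` (final [tissue_geometry()]), `config`,
#'   `run_seed`, `initial` (initial fibril/ECM counts), `baseline_totals`
#'   (per-cytokine steady-state totals; cytokine series minus these are the
#'   deviations from baseline).
#' @export
run_simulation <- function(config = sim_config(), geom = NULL,
                           run_seed = NULL, baseline = NULL) {
  cfg <- config
  if (is.null(geom)) geom <- default_geometry(seed = 1L)
  if (is.null(run_seed)) run_seed <- cfg$seed
  if (is.null(baseline)) baseline <- steady_state_field(geom, cfg)

  strain <- cfg$strain
  if (cfg$damage_mode == "localised" && is.null(strain))
    strain <- synth_strain_field(geom, seed = 1L)
  geom <- apply_damage(geom, mode = cfg$damage_mode,
                       fraction = cfg$damage_fraction, strain = strain,
                       seed = derive_seed(run_seed, 101L),
                       necrosis = cfg$necrosis)
  # damage breaks elements down to the clearance gate
  dmgpix <- which((!is.na(geom$fib_state) & geom$fib_state == 1L) |
                  (!is.na(geom$ecm_state) & geom$ecm_state == 1L))
  geom$integrity[dmgpix] <- cfg$clearance_threshold

  st <- new_sim_state(geom, cfg, run_seed)
  st$fields$layers <- baseline$layers
  st$prev <- baseline$layers
  st$base_layers <- baseline$layers
  rows <- vector("list", cfg$duration + 1L)
  .refresh_masks(st)
  rows[[1L]] <- .record_row(st)
  with_seed(derive_seed(run_seed, 303L), {
    for (t in seq_len(cfg$duration)) rows[[t + 1L]] <- .sim_tick(st)
  })
  series <- as.data.frame(do.call(rbind, rows))
  structure(list(series = series, geometry = .state_geometry(st),
                 config = cfg, run_seed = run_seed,
                 initial = c(fibril = st$initial_fibril, ecm = st$initial_ecm),
                 baseline_totals = field_totals(baseline)),
            class = "muscle_sim")
}

#' @export
print.muscle_sim <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("muscle_sim: %d ticks, %s damage %.0f%%, seed %d\n", n - 1L,
              x$config$damage_mode, 100 * x$config$damage_fraction,
              x$run_seed))
  last <- x$series[n, ]
  cat(sprintf("  endpoint: %d fibrils (initial %d), %d ECM, %d fibroblasts\n",
              as.integer(last$fibril), as.integer(x$initial[["fibril"]]),
              as.integer(last$ecm), as.integer(last$fibroblasts)))
  invisible(x)
}

#' Run an ensemble of simulations
#'
#' `n_runs` independent runs with per-run seeds derived deterministically
#' from the master seed, plus per-tick mean and standard deviation of every
#' recorded series.
#'
#' @param config a [sim_config()] (`config$n_runs` used unless overridden).
#' @param geom shared [tissue_geometry()] (`NULL` = default reference).
#' @param n_runs override for the ensemble size.
#' @return A `muscle_ensemble` list: `runs` (list of `muscle_sim`), `mean`
#'   and `sd` (data frames over ticks), `seeds`, `config`, `initial`.
#' @export
run_ensemble <- function(config = sim_config(), geom = NULL, n_runs = NULL) {
  cfg <- config
  if (is.null(n_runs)) n_runs <- cfg$n_runs
  if (is.null(geom)) geom <- default_geometry(seed = 1L)
  seeds <- vapply(seq_len(n_runs), function(i) derive_seed(cfg$seed, i),
                  integer(1))
  baseline <- steady_state_field(geom, cfg)
  runs <- lapply(seeds, function(s)
    run_simulation(cfg, geom, run_seed = s, baseline = baseline))
  mats <- lapply(runs, function(r) as.matrix(r$series))
  arr <- simplify2array(mats)
  mu <- apply(arr, c(1L, 2L), mean)
  sdev <- if (n_runs > 1L) apply(arr, c(1L, 2L), stats::sd) else mu * 0
  mu <- as.data.frame(mu)
  sdev <- as.data.frame(sdev)
  mu$tick <- runs[[1L]]$series$tick
  sdev$tick <- runs[[1L]]$series$tick
  structure(list(runs = runs, mean = mu, sd = sdev, seeds = seeds,
                 config = cfg, initial = runs[[1L]]$initial),
            class = "muscle_ensemble")
}

#' @export
print.muscle_ensemble <- function(x, ...) {
  cat(sprintf("muscle_ensemble: %d runs, %s damage %.0f%%\n",
              length(x$runs), x$config$damage_mode,
              100 * x$config$damage_fraction))
  invisible(x)
}

#' Export a time series as long-format CSV
#'
#' One row per (tick, series) pair with columns `tick,series,value`.
#'
#' @param series the `series` data frame of a `muscle_sim` (or an ensemble
#'   mean).
#' @param path output path.
#' @export
export_timeseries <- function(series, path) {
  nm <- setdiff(names(series), "tick")
  long <- data.frame(
    tick = rep(series$tick, times = length(nm)),
    series = rep(nm, each = nrow(series)),
    value = unlist(series[nm], use.names = FALSE))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read back a long-format time-series CSV
#'
#' Inverse of [export_timeseries()].
#' @param path CSV path.
#' @return Wide data frame with a `tick` column.
#' @export
import_timeseries <- function(path) {
  long <- utils::read.csv(path)
  wide <- stats::reshape(long, idvar = "tick", timevar = "series",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[order(wide$tick), , drop = FALSE]
}
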