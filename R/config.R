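#' Simulation configuration
#'
#' Collects every tunable of a run. Defaults are the model's reference
#' conditions: 672 one-hour ticks (28 days), evaporation 0.9 and diffusion
#' constant 0.1 for the value layers, 30 + 30 seeded inflammatory cells,
#' 21 fibroblasts (hard cap 67), and satellite cells at 0.08 per fibre per
#' 10 um thickness scaled to the 50 um slice.
#'
#' Behavioural thresholds that the underlying biology leaves open are
#' config-exposed and documented in the package vignette:
#' `integrity_decrement`/`clearance_threshold` (phagocytosis gate),
#' `neut_prolif_threshold` (local TNF-a + IL-6 level, AU),
#' `mac_prolif_window` (ticks of persistent damage before M1 expansion),
#' `resolution_idle` (ticks without nearby damage before an inflammatory
#' agent is removed, floored at the seeded 30),
#' `hgf_activation_rel` and `hgf_division_dwell` (satellite-cell
#' activation/division relative to the local HGF baseline), `sc_pool_factor`
#' (niche ceiling on satellite-cell divisions), and `fibrosis_delay` (age in
#' ticks after which an unrepaired, ECM-adjacent removed fibril pixel becomes
#' a fibroblast remodelling target).
#'
#' @param damage_mode `"none"`, `"widespread"` or `"localised"`.
#' @param damage_fraction damage fraction (the study uses 0, 0.01, 0.02,
#'   0.05, 0.10; any value in \[0, 1\] is accepted).
#' @param duration number of one-hour ticks (default 672).
#' @param n_runs ensemble size for [run_ensemble()] (default 50).
#' @param seed master seed; each ensemble run derives its own seed from it.
#' @param strain optional [strain_field()] for localised damage; when `NULL`
#'   a synthetic field is generated from the run seed.
#' @param coefficients a [coefficient_set()].
#' @param evap,diff_const,neighbours,boundary value-layer constants, see
#'   [cytokine_field()].
#' @param ... overrides for the named behavioural parameters listed in
#'   Details (unknown names are an error).
#' @return A `sim_config` list.
#' @export
sim_config <- function(damage_mode = c("none", "widespread", "localised"),
                       damage_fraction = 0, duration = 672L, n_runs = 50L,
                       seed = 1L, strain = NULL,
                       coefficients = default_coefficients(),
                       evap = 0.9, diff_const = 0.1, neighbours = 8L,
                       boundary = "sink", ...) {
  cfg <- list(
    damage_mode = match.arg(damage_mode),
    damage_fraction = damage_fraction,
    duration = as.integer(duration),
    n_runs = as.integer(n_runs),
    seed = as.integer(seed),
    strain = strain,
    coefficients = coefficient_set(coefficients),
    evap = evap, diff_const = diff_const,
    neighbours = as.integer(neighbours), boundary = boundary,
    necrosis = TRUE,
    # tissue constants
    pixel_area = 3.61,
    # seeding
    baseline_neutrophils = 30L,
    baseline_macrophages = 30L,
    baseline_fibroblasts = 21L,
    sc_per_fibre = 0.08 * 5,
    # phagocytosis
    integrity_decrement = 0.25,
    clearance_threshold = 0.5,
    phago_ticks_fibril = 2L,
    phago_ticks_ecm = 4L,
    # inflammatory dynamics
    neut_prolif_threshold = 0.75,
    neut_prolif_prob = 0.5,
    mac_prolif_window = 24L,
    mac_prolif_prob = 0.25,
    mac_speed = 1L,
    crowding_cap = 3L, # max same-type agents on a pixel for proliferation
    sense_radius = 5L,
    resolution_idle = 24L,
    # satellite cells (HGF sensed relative to its local baseline level)
    sc_activation_delay = 72L,
    hgf_activation_rel = 1.25,
    sc_activation_gain = 2, # per-tick activation prob per unit HGF excess
    hgf_division_dwell = 6L,
    differentiation_delay = 24L, # min ticks in ACTIVE before differentiating
    sc_division_prob = 0.5,
    sc_division_cooldown = 8L,
    sc_speed_um = 40,
    requiescence_idle = 24L,
    fusion_min = 3L,
    fusion_max = 24L,
    sc_incorporation_prob = 0.02,
    sc_incorporation_hyper = 0.02, # incorporation prob for hypertrophy fusions
    sc_pool_factor = 8, # divisions shut off as pool nears factor x seeded SCs
    repair_patch = 3L, # Chebyshev radius healed around a fusion site
    hypertrophy_patch = 5L, # border pixels converted per hypertrophy fusion
    hypertrophy_limit = 0.01, # max fibril gain above initial (fraction)
    # fibroblasts
    fibroblast_speed_um = 52,
    fibroblast_cap = 67L,
    fib_division_prob = 0.5,
    fib_decay_prob = 0.05,
    fib_repair_ticks = 4L,
    fibrosis_delay = 240L,
    fibrosis_density = 10L, # min removed-gap pixels in the 5x5 block
    fibrosis_ticks = 8L, # collagen deposition time to convert a fibril gap
    # engine
    map_refresh = 4L,
    ordering = "shuffled",
    gradient_eps = 1e-9
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$duration < 1L) stop("duration must be >= 1")
  if (cfg$damage_fraction < 0 || cfg$damage_fraction > 1)
    stop("damage_fraction must be in [0, 1]")
  if (cfg$damage_mode == "none" && cfg$damage_fraction != 0)
    stop("damage_mode 'none' requires damage_fraction 0")
  class(cfg) <- "sim_config"
  cfg
}

# cell speed (um/h) to grid moves per tick via the pixel-area convention:
# 40 um/h over 3.61 um^2 pixels gives floor(40 / 3.61) = 11 moves per tick.
moves_per_tick <- function(speed_um, pixel_area) as.integer(speed_um %/% pixel_area)

# deterministic per-run seed derivation (kept below 2^31)
derive_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) %% 2147483647 * 48271 + i * 16807) %% 2147483647)
}
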