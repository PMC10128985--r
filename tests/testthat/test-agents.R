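# micro-scenario helper: a bare simulation state on a given geometry with
# flat (steady) fields, bypassing run_simulation
micro_state <- function(geom, seed = 1L, cfg = sim_config()) {
  st <- myoregen:::new_sim_state(geom, cfg, seed)
  base <- cytokine_field(geom = geom)
  st$fields$layers <- base$layers
  st$prev <- base$layers
  st$base_layers <- base$layers
  st$tick <- 1L
  myoregen:::.refresh_masks(st)
  myoregen:::.refresh_maps(st)
  st
}

test_that("init_agents seeds the published counts on the reference tissue", {
  g <- default_geometry_cached()
  ags <- init_agents(g, seed = 1)
  expect_identical(nrow(ags$neutrophils), 30L)
  expect_identical(nrow(ags$macrophages), 30L)
  expect_identical(nrow(ags$satellite_cells), 12L) # round(0.08 * 5 * 30)
  expect_identical(nrow(ags$fibroblasts), 21L)
  expect_true(all(ags$macrophages$phen == 1L))

  # placement rules: inflammatory cells and fibroblasts on ECM, SCs on
  # fibre borders
  expect_true(all(g$label[ags$neutrophils$idx] == -1L))
  expect_true(all(g$label[ags$fibroblasts$idx] == -1L))
  border <- myoregen:::border_pixel_idx(g)
  expect_true(all(ags$satellite_cells$idx %in% border))

  # SC density scales with fibre count: 45 fibres -> round(0.4 * 45) = 18
  g45 <- generate_cross_section(45, 2700, 950, seed = 2)
  expect_identical(nrow(init_agents(g45, seed = 1)$satellite_cells), 18L)

  # determinism
  expect_identical(init_agents(g, seed = 9), init_agents(g, seed = 9))
  expect_error(init_agents(tissue_geometry(matrix(1L, 4, 4))), "ECM")
})

test_that("a neutrophil phagocytoses an adjacent broken-down fibril in 2 ticks", {
  g <- ring_geometry()
  st <- micro_state(g)
  centre <- myoregen:::rc_to_idx(4L, 4L, 7L)
  st$fstate[centre] <- 1L
  st$integ[centre] <- 0.5 # damage leaves the element at the clearance gate
  st$neut <- data.frame(idx = myoregen:::rc_to_idx(4L, 3L, 7L),
                        target = NA_integer_, timer = NA_integer_, idle = 0L)
  st$mac <- st$mac[0, ]
  set.seed(1)
  myoregen:::.refresh_masks(st)
  myoregen:::.step_neutrophils(st)
  expect_identical(st$fstate[centre], 1L) # tick 1: engaged, not yet removed
  myoregen:::.step_neutrophils(st)
  expect_identical(st$fstate[centre], 2L) # tick 2: removed
})

test_that("damaged ECM requires 4 ticks of phagocytosis", {
  g <- ring_geometry()
  st <- micro_state(g)
  ecm <- myoregen:::rc_to_idx(2L, 2L, 7L)
  st$estate[ecm] <- 1L
  st$coll[ecm] <- 0
  st$integ[ecm] <- 0.5
  st$neut <- data.frame(idx = myoregen:::rc_to_idx(2L, 3L, 7L),
                        target = NA_integer_, timer = NA_integer_, idle = 0L)
  st$mac <- st$mac[0, ]
  set.seed(1)
  myoregen:::.refresh_masks(st)
  for (k in 1:3) {
    myoregen:::.step_neutrophils(st)
    expect_identical(st$estate[ecm], 1L)
  }
  myoregen:::.step_neutrophils(st)
  expect_identical(st$estate[ecm], 2L)
})

test_that("without damage inflammatory agents neither move nor proliferate", {
  g <- small_geometry()
  st <- micro_state(g)
  before_n <- st$neut
  before_m <- st$mac
  set.seed(2)
  for (k in 1:10) {
    myoregen:::.step_neutrophils(st)
    myoregen:::.step_macrophages(st)
  }
  expect_identical(st$neut, before_n)
  expect_identical(st$mac, before_m)
})

test_that("macrophages switch M1 to M2 after phagocytosis and never revert", {
  g <- ring_geometry()
  st <- micro_state(g)
  centre <- myoregen:::rc_to_idx(4L, 4L, 7L)
  st$fstate[centre] <- 1L
  st$integ[centre] <- 0.5
  st$neut <- st$neut[0, ]
  st$mac <- data.frame(idx = myoregen:::rc_to_idx(4L, 5L, 7L),
                       target = NA_integer_, timer = NA_integer_, idle = 0L,
                       phen = 1L, nphago = 0L)
  set.seed(1)
  myoregen:::.refresh_masks(st)
  myoregen:::.step_macrophages(st)
  expect_identical(st$mac$phen, 1L)
  myoregen:::.step_macrophages(st) # completes the 2-tick phagocytosis
  expect_identical(st$mac$phen, 2L)
  for (k in 1:20) myoregen:::.step_macrophages(st) # absorbing state
  expect_true(all(st$mac$phen == 2L))
})

test_that("fusion timers are uniform whole numbers on 3..24", {
  set.seed(123)
  draws <- rfusion_timer(1e5)
  expect_identical(min(draws), 3L)
  expect_identical(max(draws), 24L)
  expect_equal(mean(draws), 13.5, tolerance = 0.05)
  expect_true(all(draws == floor(draws)))
  # every value attained roughly uniformly
  tab <- table(draws)
  expect_identical(length(tab), 22L)
  expect_lt(diff(range(tab)) / mean(tab), 0.15)
})

test_that("satellite cells stay quiescent without an HGF signal", {
  g <- small_geometry()
  st <- micro_state(g)
  set.seed(3)
  for (k in 1:30) myoregen:::.step_satellite_cells(st)
  expect_true(all(st$sc$stage == 0L))
  expect_identical(st$cum_sc_activated, 0L)
})

test_that("a myoblast at a damaged fibril restores it after its fusion timer", {
  g <- ring_geometry()
  cfg <- sim_config(sc_incorporation_prob = 0)
  st <- micro_state(g, cfg = cfg)
  centre <- myoregen:::rc_to_idx(4L, 4L, 7L)
  st$fstate[centre] <- 1L
  st$sc <- data.frame(idx = centre, stage = 4L, timer = 3L, dwell = 0L,
                      cool = 0L, lowhgf = 0L, site = centre, act_age = 0L)
  st$claimed[centre] <- TRUE
  set.seed(1)
  for (k in 1:2) {
    myoregen:::.step_satellite_cells(st)
    expect_identical(st$fstate[centre], 1L)
  }
  myoregen:::.step_satellite_cells(st) # timer expires
  expect_identical(st$fstate[centre], 0L)
  expect_identical(st$integ[centre], 1)
})

test_that("fibroblast cap of 67 holds even under favourable gradients", {
  g <- small_geometry()
  st <- micro_state(g)
  ecm <- which(g$label == -1L)
  st$fibro <- data.frame(idx = ecm[seq_len(67)], target = NA_integer_,
                         timer = NA_integer_)
  # strongly positive temporal gradients of IL-15 and TGF-b everywhere
  st$fields$layers$IL15 <- st$fields$layers$IL15 + 10
  st$fields$layers$TGFb <- st$fields$layers$TGFb + 10
  set.seed(4)
  myoregen:::.refresh_masks(st)
  myoregen:::.step_fibroblasts(st)
  expect_lte(nrow(st$fibro), 67L) # never exceeds the cap

  # below the cap the same gradients do produce divisions
  st$fibro <- st$fibro[1:10, ]
  myoregen:::.step_fibroblasts(st)
  expect_gt(nrow(st$fibro), 10L)
  expect_lte(nrow(st$fibro), 67L)
})

test_that("fibroblasts stay on the ECM network throughout a damaged run", {
  g <- mid_geometry()
  cfg <- sim_config(damage_mode = "widespread", damage_fraction = 0.05,
                    duration = 1, seed = 8)
  geom <- apply_damage(g, "widespread", 0.05,
                       seed = myoregen:::derive_seed(8, 101L))
  dmg <- which((!is.na(geom$fib_state) & geom$fib_state == 1L) |
               (!is.na(geom$ecm_state) & geom$ecm_state == 1L))
  geom$integrity[dmg] <- cfg$clearance_threshold
  st <- myoregen:::new_sim_state(geom, cfg, 8L)
  base <- mid_baseline()
  st$fields$layers <- base$layers
  st$prev <- base$layers
  st$base_layers <- base$layers
  set.seed(99)
  ok <- TRUE
  for (t in 1:120) {
    myoregen:::.sim_tick(st)
    pos <- st$fibro$idx
    on_net <- st$lab[pos] == -1L |
      (st$lab[pos] > 0L & !is.na(st$fstate[pos]) & st$fstate[pos] == 2L)
    ok <- ok && all(on_net)
  }
  expect_true(ok)
})

test_that("the remodelled fibre outline follows current adjacency", {
  g <- small_geometry()
  initial <- fibre_border_pixels(g)
  # undamaged tissue: outline identical to the initial border set
  expect_identical(remodel_fibre_outline(g, 0L), initial)
  # active SCs present: no-op, previous outline returned
  fake_prev <- initial[1:5, , drop = FALSE]
  expect_identical(remodel_fibre_outline(g, 3L, previous = fake_prev),
                   fake_prev)
  # after losing a border fibril the outline changes
  b1 <- initial[1L, ]
  idx <- myoregen:::rc_to_idx(b1[1L], b1[2L], nrow(g$label))
  g$fib_state[idx] <- 2L
  g$label[idx] <- -1L # remodelled into ECM
  g$ecm_state[idx] <- 0L
  out <- remodel_fibre_outline(g, 0L)
  expect_false(identical(out, initial))
})
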