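test_that("widespread seeding takes exactly round-half-up(fraction * fibrils)", {
  g <- default_geometry_cached()
  d10 <- seed_widespread(g, 0.10, seed = 3)
  expect_identical(nrow(d10), 2584L) # 0.10 * 25840

  expect_identical(nrow(seed_widespread(g, 0, seed = 3)), 0L)

  d1a <- seed_widespread(g, 0.01, seed = 1)
  d1b <- seed_widespread(g, 0.01, seed = 2)
  expect_identical(nrow(d1a), 258L)
  expect_identical(nrow(d1b), 258L)
  expect_false(identical(d1a, d1b))
  # determinism and fibril-only sampling
  expect_identical(d1a, seed_widespread(g, 0.01, seed = 1))
  idx <- myoregen:::rc_to_idx(d1a[, 1L], d1a[, 2L], nrow(g$label))
  expect_true(all(g$label[idx] > 0L))
  expect_error(seed_widespread(g, 1.5, seed = 1), "fraction")
})

test_that("localised seeding takes the top strain pixels with lexicographic ties", {
  g <- small_geometry()
  sf <- synth_strain_field(g, seed = 5)
  m <- myoregen:::round_half_up(0.10 * 400)
  d <- seed_localised(g, sf, 0.10)
  expect_identical(nrow(d), m)
  # sort-and-slice oracle
  nr <- nrow(g$label)
  vals <- sf$values[sf$pixels]
  cutoff <- sort(vals, decreasing = TRUE)[m]
  idx <- myoregen:::rc_to_idx(d[, 1L], d[, 2L], nr)
  expect_true(all(sf$values[idx] >= cutoff))

  expect_identical(nrow(seed_localised(g, sf, 0)), 0L)

  # construct an exact tie at the cutoff: the lexicographically smaller
  # coordinate must win
  fib <- which(g$label > 0L)
  vals2 <- matrix(NA_real_, nr, ncol(g$label))
  vals2[fib] <- 0
  two <- sort(fib)[1:2]
  vals2[two] <- 1 # tie between the first two fibril pixels in (row,col) order
  sf2 <- strain_field(g, vals2)
  d2 <- seed_localised(g, sf2, 1 / 400) # exactly one pixel
  expect_identical(nrow(d2), 1L)
  expect_identical(unname(myoregen:::rc_to_idx(d2[1L, 1L], d2[1L, 2L], nr)),
                   min(two))

  # equal fractions give equal damage magnitudes in both modes
  dW <- seed_widespread(g, 0.05, seed = 9)
  dL <- seed_localised(g, sf, 0.05)
  expect_identical(nrow(dW), nrow(dL))

  # coverage error: more pixels requested than the field covers
  sparse <- matrix(NA_real_, nr, ncol(g$label))
  sparse[fib[1:3]] <- 1
  expect_error(seed_localised(g, strain_field(g, sparse), 0.5), "covers")
})

test_that("necrosis spreads one-shot over the 3x3 block and is idempotent", {
  g <- ring_geometry() # fibre 3:5 x 3:5, ECM ring around it
  centre <- cbind(row = 4L, col = 4L)
  sp <- propagate_necrosis(g, centre)
  expect_identical(nrow(sp$fibril), 9L) # whole 3x3 fibre
  expect_identical(nrow(sp$ecm), 0L)

  corner <- cbind(row = 3L, col = 3L) # fibre corner: block overlaps ECM
  sp2 <- propagate_necrosis(g, corner)
  expect_identical(nrow(sp2$fibril), 4L)
  expect_identical(nrow(sp2$ecm), 5L)
  expect_identical(nrow(sp2$fibril) + nrow(sp2$ecm), 9L)

  # two seeds one pixel apart: union of blocks, no double counting
  two <- rbind(c(4L, 3L), c(4L, 4L))
  sp3 <- propagate_necrosis(g, two)
  expect_identical(nrow(sp3$fibril) + nrow(sp3$ecm), 12L)

  # idempotence: expanding from the same seed set twice changes nothing
  sp4 <- propagate_necrosis(g, centre)
  expect_identical(sp, sp4)

  # grid-corner clipping on a bare 2x2 fibre at the origin
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L
  gc <- tissue_geometry(lab)
  spc <- propagate_necrosis(gc, cbind(row = 1L, col = 1L))
  expect_lte(nrow(spc$fibril) + nrow(spc$ecm), 4L)
})

test_that("localised damage is spatially clustered relative to widespread", {
  g <- mid_geometry()
  sf <- synth_strain_field(g, seed = 1)
  dL <- seed_localised(g, sf, 0.05)
  nn_local <- mean_nn_distance(dL)
  nn_wide <- vapply(1:10, function(s)
    mean_nn_distance(seed_widespread(g, 0.05, seed = s)), numeric(1))
  expect_true(all(nn_local < nn_wide))
})

test_that("synthetic strain fields are deterministic, non-negative, clustered", {
  g <- mid_geometry()
  s1 <- synth_strain_field(g, seed = 3)
  s2 <- synth_strain_field(g, seed = 3)
  expect_identical(s1$values, s2$values)
  expect_true(all(s1$values[s1$pixels] >= 0))
  expect_identical(sort(s1$pixels), sort(which(g$label > 0L)))

  # top-decile strain pixels cluster more tightly than uniform draws
  nr <- nrow(g$label)
  m <- myoregen:::round_half_up(0.10 * length(s1$pixels))
  top <- myoregen:::idx_to_rc(
    myoregen:::rc_to_idx(seed_localised(g, s1, 0.10)[, 1L],
                         seed_localised(g, s1, 0.10)[, 2L], nr), nr)
  nn_top <- mean_nn_distance(top)
  set.seed(42)
  nn_unif <- replicate(20, {
    pick <- sample(s1$pixels, m)
    mean_nn_distance(myoregen:::idx_to_rc(pick, nr))
  })
  expect_lt(nn_top, mean(nn_unif))
})

test_that("strain CSV import validates coordinates and round-trips", {
  g <- small_geometry()
  nr <- nrow(g$label)
  fib <- which(g$label > 0L)[1:3]
  rc <- myoregen:::idx_to_rc(fib, nr)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(row = rc[, 1L] - 1L, col = rc[, 2L] - 1L,
                       strain = c(0.5, 1.5, 2.5)), path, row.names = FALSE)
  sf <- load_strain(path, g)
  expect_identical(length(sf$pixels), 3L)
  expect_identical(sf$provenance, "imported")
  expect_equal(sf$values[fib], c(0.5, 1.5, 2.5))

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(row = 9999, col = 0, strain = 1), bad,
            row.names = FALSE)
  expect_error(load_strain(bad, g), "outside grid")

  # strain on a non-fibril pixel is rejected with its coordinates
  ecm <- which(g$label == -1L)[1L]
  rc2 <- myoregen:::idx_to_rc(ecm, nr)
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(row = rc2[, 1L] - 1L, col = rc2[, 2L] - 1L,
                       strain = 1), bad2, row.names = FALSE)
  expect_error(load_strain(bad2, g), "non-fibril")
})
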