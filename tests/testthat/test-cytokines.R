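test_that("production rates reproduce the printed signed linear combinations", {
  k <- default_coefficients()
  expect_identical(length(k), 31L)
  expect_true(all(k >= 0))

  # a lone anti-inflammatory macrophage drives IL-10 at its coefficient
  r <- production_rates(population_counts(AM = 1))
  expect_identical(unname(r["IL10"]), 0.899)

  # homogeneity: all-zero inputs give all-zero derivatives
  r0 <- production_rates(population_counts())
  expect_identical(unname(r0), rep(0, 7))

  # full TNF-a equation, hand-computed:
  # 0.273*10 + 0.456*5 + 0.493*2 - 0.346 - 0.106 - 0.044 - 0.485 = 5.015
  r2 <- production_rates(
    population_counts(IM = 10, N = 5, Fb = 2),
    c(TGFb = 1, IL6 = 1, IL10 = 1, IGF1 = 1))
  expect_equal(unname(r2["TNF"]),
               0.273 * 10 + 0.456 * 5 + 0.493 * 2 - 0.346 - 0.106 - 0.044 - 0.485)
  expect_equal(unname(r2["TNF"]), 5.015)

  # every equation against an independent matrix-form oracle
  A <- matrix(0, 7, 7, dimnames = list(CYTOKINES, CYTOKINES))
  A["IL10", c("IL6", "HGF")] <- c(0.827, 0.670)
  A["IL15", c("TNF", "TGFb")] <- c(0.377, -0.825)
  A["TNF", c("TGFb", "IL6", "IL10", "IGF1")] <- -c(0.346, 0.106, 0.044, 0.485)
  A["HGF", "IL6"] <- 0.156
  A["IL6", c("HGF", "TGFb", "TNF")] <- c(-0.077, -0.132, 0.482)
  A["IGF1", c("TNF", "TGFb", "IL6", "IL10")] <- c(-0.788, -0.019, -0.477, 0.826)
  A["TGFb", "IL6"] <- 0.798
  B <- matrix(0, 7, 6, dimnames = list(CYTOKINES,
                                       c("AM", "IM", "N", "Fb", "F", "Mb")))
  B["IL10", "AM"] <- 0.899
  B["IL15", c("F", "Mb")] <- c(0.004, 0.558)
  B["TNF", c("IM", "N", "Fb")] <- c(0.273, 0.456, 0.493)
  B["HGF", "F"] <- 0.755
  B["IL6", c("N", "IM", "F")] <- c(0.043, 0.395, 0.077)
  B["IGF1", c("AM", "F")] <- c(0.258, 0.009)
  B["TGFb", c("F", "AM")] <- c(0.007, 0.211)
  set.seed(11)
  for (i in 1:20) {
    cts <- population_counts(AM = sample(0:50, 1), IM = sample(0:50, 1),
                             N = sample(0:50, 1), Fb = sample(0:50, 1),
                             F = sample(0:50, 1), Mb = sample(0:50, 1))
    tot <- stats::setNames(runif(7, 0, 100), CYTOKINES)
    expect_equal(unname(production_rates(cts, tot)),
                 unname(drop(A %*% tot + B %*% cts)), tolerance = 1e-12)
  }

  expect_error(production_rates(population_counts(N = -1)), "non-negative")
})

test_that("deposition splits, clamps and conserves", {
  f <- cytokine_field(6, 6)
  f <- deposit(f, "TNF", 1.0, source_pixels = c(1L, 2L, 3L, 4L))
  expect_equal(f$layers$TNF[1:4], rep(0.25, 4))
  expect_equal(sum(f$layers$TNF), 1.0)

  # negative delta on an all-zero layer clamps at zero
  f <- deposit(f, "IL6", -5)
  expect_true(all(f$layers$IL6 == 0))

  # conservation of a point deposit
  f2 <- deposit(cytokine_field(6, 6), "IL10", 0.899, source_pixels = 17L)
  expect_equal(sum(f2$layers$IL10), 0.899)
  expect_equal(f2$layers$IL10[17L], 0.899)

  # positive delta with no sources spreads uniformly
  f3 <- deposit(cytokine_field(4, 4), "HGF", 1.6)
  expect_equal(unique(as.vector(f3$layers$HGF)), 0.1)
})

test_that("diffusion follows the evaporation/neighbour-average update", {
  # uniform interior: neighbour average equals own value, so new = 0.9 * v
  z <- matrix(2.5, 9, 9)
  out <- wrap_diffuse(z)
  expect_equal(out[5, 5], 0.9 * 2.5)

  # all-zero field is a fixed point
  expect_true(all(wrap_diffuse(matrix(0, 5, 5)) == 0))

  # single point mass: centre 0.9*(1 + 0.1*(0 - 1)) = 0.81, each Moore
  # neighbour 0.9*(0.1*(1/8)) = 0.01125
  z2 <- matrix(0, 7, 7)
  z2[4, 4] <- 1
  out2 <- wrap_diffuse(z2)
  expect_equal(out2[4, 4], 0.81)
  expect_equal(out2[3, 3], 0.01125)
  expect_equal(out2[4, 5], 0.01125)
  expect_equal(sum(out2 > 0), 9L)
})

test_that("diffusion matches the brute-force stencil oracle on random fields", {
  set.seed(99)
  for (i in 1:50) {
    z <- matrix(runif(100), 10, 10)
    expect_lt(max(abs(wrap_diffuse(z) - diffuse_oracle(z))), 1e-9)
  }
})

test_that("closed boundary with evap 1 conserves mass; evap < 1 loses mass", {
  set.seed(7)
  z <- matrix(runif(64), 8, 8)
  out <- wrap_diffuse(z, evap = 1, boundary = "closed")
  expect_lt(abs(sum(out) - sum(z)) / sum(z), 1e-9)

  f <- cytokine_field(8, 8, evap = 0.9)
  f$layers$TNF <- z
  tot <- sum(z)
  for (i in 1:5) {
    f <- diffuse_step(f)
    expect_lt(sum(f$layers$TNF), tot)
    tot <- sum(f$layers$TNF)
  }
  expect_true(all(vapply(f$layers, function(l) all(l >= 0), logical(1))))
})

test_that("sensing, best neighbour and temporal gradients behave", {
  f <- cytokine_field(5, 5)
  # flat layer: lexicographically first neighbour wins the tie
  expect_identical(best_neighbour(f, "HGF", c(3, 3)), c(2L, 2L))

  # single peak attracts from any adjacent pixel
  f$layers$HGF[2, 4] <- 5
  for (p in list(c(2, 3), c(3, 3), c(3, 4), c(1, 4), c(3, 5)))
    expect_identical(best_neighbour(f, "HGF", p), c(2L, 4L))

  expect_identical(sense(f, "HGF", c(2, 4)), 5)

  prev <- f
  expect_false(temporal_gradient_positive(f, prev, "HGF", c(2, 4)))
  f$layers$HGF[2, 4] <- 6
  expect_true(temporal_gradient_positive(f, prev, "HGF", c(2, 4)))
})

test_that("coefficient sets validate and round-trip through JSON", {
  expect_error(coefficient_set(c(a = 1)), "31")
  bad <- default_coefficients()
  bad[3] <- -0.1
  expect_error(coefficient_set(bad), ">= 0")

  path <- withr::local_tempfile(fileext = ".json")
  save_coefficients(default_coefficients(), path)
  expect_equal(load_coefficients(path), default_coefficients())
})
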