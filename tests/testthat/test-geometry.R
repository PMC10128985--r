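test_that("generator hits exact counts, including the reference tissue", {
  g <- default_geometry_cached()
  ct <- geometry_counts(g)
  expect_identical(unname(ct["fibril"]), 25840L)
  expect_identical(unname(ct["ecm"]), 4318L)
  expect_identical(length(g$fibre_ids), 30L)
  expect_identical(sum(ct), length(g$label))

  # exact-count contract over several seeds at small scale
  for (s in 1:5) {
    gg <- generate_cross_section(5, 600, 150, seed = s)
    expect_identical(unname(geometry_counts(gg)[c("fibril", "ecm")]),
                     c(600L, 150L))
    expect_identical(length(gg$fibre_ids), 5L)
  }
})

test_that("generator is deterministic and fibres are 4-connected", {
  g1 <- generate_cross_section(4, 400, 120, seed = 7)
  g2 <- generate_cross_section(4, 400, 120, seed = 7)
  expect_identical(g1$label, g2$label)
  g3 <- generate_cross_section(4, 400, 120, seed = 8)
  expect_false(identical(g1$label, g3$label))

  nr <- nrow(g1$label); nc <- ncol(g1$label)
  for (f in g1$fibre_ids)
    expect_true(flood_connected4(which(g1$label == f), nr, nc))
  # fibre separation: no two fibres Moore-adjacent
  fib <- which(g1$label > 0L)
  nb <- myoregen:::neighbour_idx(fib, nr, nc)
  for (j in 1:8) {
    ok <- !is.na(nb[, j])
    l2 <- g1$label[nb[ok, j]]
    expect_false(any(l2 > 0L & l2 != g1$label[fib[ok]]))
  }
})

test_that("degenerate single-fibre geometry works and infeasible targets fail", {
  g <- generate_cross_section(1, 100, 0, seed = 0)
  expect_identical(unname(geometry_counts(g)[c("fibril", "ecm")]), c(100L, 0L))
  expect_true(flood_connected4(which(g$label == 1L), nrow(g$label),
                               ncol(g$label)))
  # two fibres cannot be separated without any ECM
  expect_error(generate_cross_section(2, 100, 0, seed = 1), "infeasible")
})

test_that("save/load round-trips exactly, CSV and PNG", {
  g <- small_geometry()
  csv <- withr::local_tempfile(fileext = ".csv")
  save_geometry(g, csv)
  expect_identical(load_geometry(csv)$label, g$label)

  png <- withr::local_tempfile(fileext = ".png")
  save_geometry(g, png)
  expect_identical(load_geometry(png)$label, g$label)
})

test_that("label CSV parsing counts codes and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,1", "-1,-1,-1", "2,2,0"), path)
  g <- load_geometry(path)
  ct <- geometry_counts(g)
  expect_identical(unname(ct), c(4L, 3L, 2L))
  expect_identical(g$fibre_ids, c(1L, 2L))

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(load_geometry(empty), "parse error")

  ragged <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,1", "-1,-1"), ragged)
  expect_error(load_geometry(ragged), "row 2")

  badcode <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1", "-7,1"), badcode)
  expect_error(load_geometry(badcode), "unknown label code")
})

test_that("fibre border pixels follow Moore adjacency to ECM", {
  g <- ring_geometry() # 3x3 fibre wrapped in ECM
  b <- fibre_border_pixels(g)
  expect_identical(nrow(b), 8L) # perimeter only, centre excluded
  expect_false(any(b[, 1L] == 4 & b[, 2L] == 4))

  # no ECM anywhere -> no border
  g2 <- generate_cross_section(1, 100, 0, seed = 0)
  expect_identical(nrow(fibre_border_pixels(g2)), 0L)

  # sanity bound on the reference tissue
  g3 <- default_geometry_cached()
  nb <- nrow(fibre_border_pixels(g3))
  expect_gt(nb, 0L)
  expect_lt(nb, geometry_counts(g3)[["fibril"]])
})

test_that("fibre sizes sum to the fibril count and track mutations", {
  g <- default_geometry_cached()
  sz <- fibre_sizes(g)
  expect_identical(sum(sz), 25840L)
  expect_identical(length(sz), 30L)

  g2 <- generate_cross_section(1, 100, 0, seed = 0)
  expect_identical(fibre_sizes(g2), c("1" = 100L))

  # adding one fibril pixel to a fibre increments its size by exactly one
  g3 <- small_geometry()
  f <- g3$fibre_ids[[3L]]
  before <- fibre_sizes(g3)[[as.character(f)]]
  spot <- which(g3$label == -1L)[1L]
  g3$label[spot] <- f
  g3$fib_state[spot] <- 0L
  expect_identical(fibre_sizes(g3)[[as.character(f)]], before + 1L)
})
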