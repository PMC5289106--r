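test_that("equal sensitivity-plus-specificity threshold picks the balance point", {
  # separable scores: the minimum presence score gives sens = spec = 1
  expect_equal(equal_ss_threshold(c(0.8, 0.9, 0.7), c(0.1, 0.2)), 0.7)
  # worked enumeration: t = 0.6 balances at 0.5/0.5
  expect_equal(equal_ss_threshold(c(0.9, 0.4), c(0.6, 0.1)), 0.6)
  # identical distributions balance near 0.5/0.5 at an interior candidate
  sc <- seq(0.1, 0.9, by = 0.1)
  t <- equal_ss_threshold(sc, sc)
  sens <- mean(sc >= t); spec <- mean(sc < t)
  expect_lte(abs(sens - spec), 0.2)
  expect_error(equal_ss_threshold(numeric(0), c(0.1)), "non-empty")
})

test_that("binarisation respects the threshold, nodata and monotonicity", {
  m <- matrix(0.7, 4, 5)
  m[1, 1] <- NA
  g <- suitability_grid(m, cellsize = 2)
  expect_true(all(binarize(g, 0.5)$presence[-1]))
  expect_false(any(binarize(g, 0.9)$presence[-1]))
  expect_true(is.na(binarize(g, 0.5)$presence[1, 1]))
  # increasing t never increases the presence count
  set.seed(8)
  r <- suitability_grid(matrix(runif(200), 10, 20))
  counts <- vapply(seq(0, 1, by = 0.05), function(t)
    sum(binarize(r, t)$presence), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ensemble agreement is a cellwise model vote", {
  a <- binary_grid(matrix(TRUE, 2, 2))
  b <- binary_grid(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(ensemble_agreement(list(a, a))$values, matrix(1, 2, 2))
  ag <- ensemble_agreement(list(a, b))$values
  expect_equal(ag[2, 2], 0.5)
  expect_equal(ag[1, 1], 1)
  # invariant to grid ordering; values on the 1/n lattice
  grids <- lapply(1:8, function(i) {
    set.seed(i); binary_grid(matrix(runif(12) > 0.5, 3, 4))
  })
  g1 <- ensemble_agreement(grids)$values
  g2 <- ensemble_agreement(rev(grids))$values
  expect_equal(g1, g2)
  expect_true(all(abs(g1 * 8 - round(g1 * 8)) < 1e-12))
  expect_error(ensemble_agreement(list(a, binary_grid(matrix(TRUE, 3, 3)))),
               "mismatch")
})

test_that("patch cohesion reproduces the hand-computed landscapes", {
  full <- patch_metrics(binary_grid(matrix(TRUE, 3, 3)), matrix(TRUE, 3, 3))
  expect_equal(full$n_patches, 1L)
  expect_equal(full$area_cells, 9L)
  expect_equal(full$cohesion, 100)
  lone <- matrix(FALSE, 3, 3); lone[2, 2] <- TRUE
  single <- patch_metrics(binary_grid(lone), matrix(TRUE, 3, 3))
  expect_equal(single$cohesion, 0)
  empty <- patch_metrics(binary_grid(matrix(FALSE, 3, 3)), matrix(TRUE, 3, 3))
  expect_equal(empty$n_patches, 0L)
  expect_equal(empty$area_km2, 0)
  expect_true(is.na(empty$cohesion))
  expect_error(patch_metrics(binary_grid(matrix(TRUE, 1, 1)), matrix(TRUE, 1, 1)),
               "single-cell")
})

test_that("patches are 8-connected and bounded by the mask", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # diagonal touch: one patch
  m[4, 4] <- TRUE                    # isolated
  pm <- patch_metrics(binary_grid(m), matrix(TRUE, 4, 4))
  expect_equal(pm$n_patches, 2L)
  # restricting the mask splits the diagonal pair off
  mask <- matrix(TRUE, 4, 4); mask[2, 2] <- FALSE
  pm2 <- patch_metrics(binary_grid(m), mask)
  expect_equal(pm2$n_patches, 2L)
  expect_equal(pm2$area_cells, 2L)
})

test_that("area is additive over disjoint masks and scales with cell size", {
  set.seed(3)
  pres <- matrix(runif(48) > 0.4, 6, 8)
  b <- binary_grid(pres, cellsize = 5)
  left <- matrix(FALSE, 6, 8); left[, 1:4] <- TRUE
  right <- !left
  whole <- patch_metrics(b, matrix(TRUE, 6, 8))
  pl <- patch_metrics(b, left)
  pr <- patch_metrics(b, right)
  expect_equal(pl$area_cells + pr$area_cells, whole$area_cells)
  expect_equal(whole$area_km2, whole$area_cells * 25)
})

test_that("scaling a solid patch with its landscape never reduces cohesion", {
  pres <- matrix(FALSE, 4, 4); pres[2:3, 2:3] <- TRUE
  c1 <- patch_metrics(binary_grid(pres), matrix(TRUE, 4, 4))$cohesion
  # doubled landscape with the solid patch scaled 2x in both dimensions
  big <- matrix(FALSE, 8, 8); big[3:6, 3:6] <- TRUE
  c2 <- patch_metrics(binary_grid(big), matrix(TRUE, 8, 8))$cohesion
  expect_gte(c2, c1 - 1e-9)
})

test_that("scenario change reports contraction and fragmentation", {
  cur <- data.frame(catchment = c("A", "B"), scenario = "current",
                    n_patches = c(1L, 1L), area_cells = c(30L, 20L),
                    area_km2 = c(30, 20), cohesion = c(95, 90))
  lgm <- data.frame(catchment = c("B", "A"), scenario = "LGM",
                    n_patches = c(3L, 1L), area_cells = c(8L, 15L),
                    area_km2 = c(8, 15), cohesion = c(70, 91))
  chg <- scenario_change(cur, lgm)
  expect_equal(chg$catchment, c("A", "B"))
  expect_equal(chg$d_area_km2, c(-15, -12))
  expect_equal(chg$fragmentation, c(FALSE, TRUE))
  expect_equal(scenario_change(cur, cur[2:1, ])$d_area_km2, c(0, 0))
  expect_error(scenario_change(cur, lgm[1, ]), "labels")
})

test_that("ESRI ASCII grids round trip with nodata preserved", {
  set.seed(4)
  m <- matrix(round(runif(30), 3), 5, 6)
  m[2, 3] <- NA
  g <- suitability_grid(m, cellsize = 2.5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_equal(g2$values, m)
  expect_equal(g2$cellsize, 2.5, ignore_attr = TRUE)
  # binary grids are written as 0/1
  b <- binary_grid(m > 0.5, cellsize = 2.5)
  write_ascii_grid(b, path)
  expect_equal(read_ascii_grid(path)$values > 0.5, m > 0.5)
})
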