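test_that("integer allocation rounds half-up and caps at n_cell", {
  expect_identical(unname(integer_allocation(c(0.5, 0.5), 20)), c(10L, 10L))
  expect_identical(unname(integer_allocation(c(0.12, 0.88), 20)), c(2L, 18L))
  expect_identical(unname(integer_allocation(c(0.03, 0.97), 20)), c(1L, 19L))
  # everything rounding to zero: largest proportion gets one cell
  expect_identical(unname(integer_allocation(c(0.02, 0.01, 0.01), 10)),
                   c(1L, 0L, 0L))
  expect_error(integer_allocation(c(-0.1, 1.1), 10), "nonnegative")

  withr::with_seed(40, {
    for (rep in 1:1000) {
      k <- sample(2:6, 1)
      beta <- runif(k); beta <- beta / sum(beta)
      n_cell <- sample(1:20, 1)
      omega <- integer_allocation(beta, n_cell)
      expect_lte(sum(omega), n_cell)
      expect_true(all(abs(omega - n_cell * beta) <= 1))
    }
  })
})

test_that("choose_cell_subset finds exact decompositions exhaustively", {
  genes <- paste0("g", 1:4)
  prof <- matrix(c(1, 0, 0, 0,
                   0, 2, 0, 0,
                   0, 0, 3, 0,
                   0, 0, 0, 4), 4, 4,
                 dimnames = list(genes, paste0("c", 1:4)))
  y <- setNames(c(1, 2, 0, 4), genes)  # = c1 + c2 + c4
  res <- choose_cell_subset(y, list(T = paste0("c", 1:4)), c(T = 3L), prof,
                            budget = 10, seed = 1)
  expect_setequal(res$cells, c("c1", "c2", "c4"))
  expect_equal(res$objective, 0)

  # omega = 1: equals the brute-force argmin
  y2 <- setNames(c(0, 2.2, 0, 0), genes)
  res2 <- choose_cell_subset(y2, list(T = paste0("c", 1:4)), c(T = 1L), prof,
                             budget = 100, seed = 1)
  objs <- apply(prof, 2, function(p) sum((y2 - p)^2))
  expect_identical(res2$cells, names(which.min(objs)))

  # budget 1 on a large pool is seed-reproducible
  big_pool <- list(T = paste0("c", 1:4))
  r1 <- choose_cell_subset(y, big_pool, c(T = 2L), prof, budget = 1, seed = 9)
  r2 <- choose_cell_subset(y, big_pool, c(T = 2L), prof, budget = 1, seed = 9)
  expect_identical(r1, r2)

  expect_error(choose_cell_subset(y, list(T = "c1"), c(T = 2L), prof),
               "pool smaller")
})

test_that("spot geometry finds d_min and quadrant neighbors", {
  coords <- data.frame(unit = c("a", "b", "c", "d"),
                       x = c(0, 100, 0, 100), y = c(0, 0, 100, 100))
  geo <- spot_geometry(coords)
  expect_equal(geo$a$d_min, 100)
  # from a: c sits at 90 degrees (quadrant 1), b at 360 (quadrant 4)
  expect_identical(geo$a$quadrant_neighbor[1], "c")
  expect_identical(geo$a$quadrant_neighbor[4], "b")
  # from d: c at 180 (quadrant 2), b at 270 nearer than a in quadrant 3
  expect_identical(geo$d$quadrant_neighbor[2], "c")
  expect_identical(geo$d$quadrant_neighbor[3], "b")
  # single spot falls back to the default d_min
  expect_equal(spot_geometry(coords[1, ], default_d_min = 42)$a$d_min, 42)
})

test_that("placed cells stay within half the neighbor distance", {
  geo <- list(center = c(x = 10, y = -5), d_min = 100,
              quadrant_neighbor = c("n1", "n2", "n3", "n4"))
  withr::with_seed(41, {
    for (i in 1:500) {
      pc <- place_cell(geo, r_center = 0.4, r_neighbors = runif(4))
      r <- sqrt((pc$x - 10)^2 + (pc$y + 5)^2)
      expect_lte(r, 50 + 1e-9)
      expect_gt(pc$alpha, 0); expect_lte(pc$alpha, 1)
      expect_gt(pc$theta, 0); expect_lte(pc$theta, 360)
      # theta lies inside the drawn quadrant's arc
      expect_lte(pc$theta, 90 * pc$quadrant)
      expect_gt(pc$theta, 90 * pc$quadrant - 90)
    }
  })
  expect_error(place_cell(list(center = c(x = 0, y = 0), d_min = 0,
                               quadrant_neighbor = rep(NA, 4)), 0.1), "positive")
})

test_that("placement coordinates follow the polar formula", {
  # alpha = 1, theta = 90, d_min = 100, center (0,0) -> (0, 50)
  geo <- list(center = c(x = 0, y = 0), d_min = 100,
              quadrant_neighbor = c("n1", NA, NA, NA))
  found <- withr::with_seed(42, {
    ok <- FALSE
    for (i in 1:2000) {
      pc <- place_cell(geo, 0, c(0, 0, 0, 0))
      expect_equal(pc$x, pc$alpha * 100 * cospi(pc$theta / 180) / 2,
                   tolerance = 1e-12)
      expect_equal(pc$y, pc$alpha * 100 * sinpi(pc$theta / 180) / 2,
                   tolerance = 1e-12)
    }
    TRUE
  })
  expect_true(found)
})

test_that("empty quadrants are excluded and ratios bias the draw", {
  geo <- list(center = c(x = 0, y = 0), d_min = 100,
              quadrant_neighbor = c("n1", NA, "n3", NA))
  qs <- withr::with_seed(43, {
    vapply(1:2000, function(i) place_cell(geo, 0.5, c(1, NA, 1, NA))$quadrant,
           numeric(1))
  })
  expect_setequal(unique(qs), c(1, 3))
})

test_that("reconstruction places capped, in-range, reproducible cells", {
  paired <- simulate_paired_datasets(sim_config(cells_per_type = 60, seed = 5))
  grid <- simulate_grid_spots(paired$map$dataset, paired$map$annotation, 200)
  st <- spatial_dataset(normalize_counts(grid$dataset$expr), grid$dataset$coords,
                        "spot", cells_per_spot = grid$dataset$cells_per_spot)
  sc <- normalize_counts(paired$sc$expr)
  rec1 <- reconstruct_single_cell_map(st, grid$proportions, sc,
                                      paired$sc$annotation, budget = 20, seed = 2)
  rec2 <- reconstruct_single_cell_map(st, grid$proportions, sc,
                                      paired$sc$annotation, budget = 20, seed = 2)
  expect_identical(rec1$placements, rec2$placements)

  geo <- spot_geometry(st$coords)
  for (i in seq_len(nrow(rec1$placements))) {
    p <- rec1$placements[i, ]
    g <- geo[[p$spot]]
    expect_lte(sqrt((p$x - g$center[["x"]])^2 + (p$y - g$center[["y"]])^2),
               g$d_min / 2 + 1e-9)
  }
  per_spot <- table(rec1$placements$spot)
  caps <- st$cells_per_spot[names(per_spot)]
  expect_true(all(as.integer(per_spot) <= caps))

  # single spot, one type, one cell
  one <- expression_matrix(matrix(5L, 1, 1, dimnames = list("g1", "s1")),
                           layer = "raw")
  st1 <- spatial_dataset(one, data.frame(unit = "s1", x = 0, y = 0), "spot")
  scm <- expression_matrix(matrix(c(4L, 6L), 1, 2,
                                  dimnames = list("g1", c("c1", "c2"))),
                           layer = "raw")
  ann <- cell_type_annotation(setNames(c("T", "T"), c("c1", "c2")))
  props <- matrix(1, 1, 1, dimnames = list("s1", "T"))
  r <- reconstruct_single_cell_map(st1, props, scm, ann, n_cell = 1, seed = 3)
  expect_equal(nrow(r$placements), 1)
  expect_lte(sqrt(r$placements$x^2 + r$placements$y^2), 50)
})
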