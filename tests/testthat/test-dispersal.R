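bin <- function(values, cell = 1000) {
  g <- tiny_grid(values, cell)
  class(g) <- c("rs_binary", class(g))
  g
}

strip <- function(n = 20, occupied = 1) {
  v <- matrix(0, 1, n); v[1, occupied] <- 1
  bin(v)
}

test_that("clipping the initial range is a cellwise AND", {
  set.seed(1)
  cur <- bin(matrix(rbinom(100, 1, 0.5), 10, 10))
  ones <- tiny_grid(matrix(1, 10, 10))
  zeros <- tiny_grid(matrix(0, 10, 10))
  expect_equal(clip_initial_range(cur, ones)$values, cur$values)
  expect_true(all(clip_initial_range(cur, zeros)$values == 0))
  mask <- tiny_grid(matrix(rbinom(100, 1, 0.5), 10, 10))
  expect_equal(clip_initial_range(cur, mask)$values,
               (cur$values == 1 & mask$values == 1) * 1)
  expect_error(clip_initial_range(cur, tiny_grid(matrix(1, 9, 10))),
               "not aligned")
})

test_that("zero-range dispersal reduces to intersection with suitability", {
  set.seed(2)
  init <- bin(matrix(rbinom(64, 1, 0.5), 8, 8))
  suit <- bin(matrix(rbinom(64, 1, 0.7), 8, 8))
  cfg <- dispersal_config(500, n_steps = 3)   # below the 1000 m cell size
  out <- disperse(init, suit, cfg)
  expect_equal(out$final$values, (init$values == 1 & suit$values == 1) * 1)
  expect_true(all(out$counts$colonized == 0))
})

test_that("a mature front advances one dispersal radius per year", {
  # 1 x 20 strip, all suitable, source at the west end
  out <- disperse(strip(), bin(matrix(1, 1, 20)),
                  dispersal_config(1000, maturity_steps = 1, n_steps = 5))
  expect_equal(which(out$final$values == 1), 1:6)   # cells 0..5
  expect_equal(out$counts$colonized, rep(1, 5))
  # maturity 2 halves the front speed (explicit age-tracking oracle: a new
  # cell waits one extra year before seeding its neighbour)
  out2 <- disperse(strip(), bin(matrix(1, 1, 20)),
                   dispersal_config(1000, maturity_steps = 2, n_steps = 5))
  expect_equal(which(out2$final$values == 1), 1:4)  # ceil(5/2) colonized
  # a 2-cell radius doubles it
  out3 <- disperse(strip(), bin(matrix(1, 1, 20)),
                   dispersal_config(2000, maturity_steps = 1, n_steps = 5))
  expect_equal(which(out3$final$values == 1), 1:11)
})

test_that("basin boundaries block colonization unless a dam-free river
           path connects the cells", {
  n <- 20
  basin <- tiny_grid(matrix(rep(c(1, 2), c(10, 10)), 1, n, byrow = TRUE))
  nodam <- tiny_grid(matrix(0, 1, n))
  noriver <- tiny_grid(matrix(0, 1, n))
  cfg <- dispersal_config(1000, n_steps = 15,
                          barrier_mode = "basins_and_dams")
  # no river crossing: occupancy never leaves basin 1 (cells 1..10)
  out <- disperse(strip(), bin(matrix(1, 1, n)), cfg,
                  basin_id = basin, dam_mask = nodam, river_mask = noriver)
  expect_equal(which(out$final$values == 1), 1:10)
  # the strip itself is a river: the path exception opens the boundary
  river <- tiny_grid(matrix(1, 1, n))
  out2 <- disperse(strip(), bin(matrix(1, 1, n)), cfg,
                   basin_id = basin, dam_mask = nodam, river_mask = river)
  expect_equal(which(out2$final$values == 1), 1:16)
  # a dam on the river at cell 10 severs the path again
  dam <- tiny_grid(matrix(0, 1, n)); dam$values[1, 10] <- 1
  out3 <- disperse(strip(), bin(matrix(1, 1, n)), cfg,
                   basin_id = basin, dam_mask = dam, river_mask = river)
  expect_true(all(which(out3$final$values == 1) <= 10))
})

test_that("cells_block stops straight segments crossing a barrier cell", {
  v <- matrix(0, 5, 9); v[3, 1] <- 1
  suit <- bin(matrix(1, 5, 9))
  wall <- tiny_grid(matrix(0, 5, 9)); wall$values[, 5] <- 1
  wall$values[1, 5] <- 0    # gap at the southern end
  cfg <- dispersal_config(1500, n_steps = 12, barrier_mode = "cells_block")
  out <- disperse(bin(v), suit, cfg, dam_mask = wall)
  # east of the wall is reachable only via the gap row
  east <- out$final$values[, 6:9]
  expect_true(any(east == 1))
  expect_true(all(out$final$values[wall$values == 1] %in% 0))
  # with the gap closed the east side stays empty
  wall2 <- tiny_grid(matrix(0, 5, 9)); wall2$values[, 5] <- 1
  out2 <- disperse(bin(v), suit, cfg, dam_mask = wall2)
  expect_true(all(out2$final$values[, 5:9] == 0))
})

test_that("the automaton equals BFS reachability for maturity 1", {
  for (s in 1:5) {
    set.seed(s)
    init <- matrix(0, 10, 10)
    init[sample.int(100, 3)] <- 1
    suit <- matrix(rbinom(100, 1, 0.6), 10, 10)
    radius <- sample(1:2, 1)
    steps <- sample(2:4, 1)
    out <- disperse(bin(init), bin(suit),
                    dispersal_config(radius * 1000, 1, steps))
    want <- oracle_bfs_reach(init == 1, suit == 1, radius, steps)
    expect_equal(out$final$values == 1, want)
  }
})

test_that("occupancy grows with dispersal and shrinks with maturity", {
  set.seed(7)
  init <- matrix(0, 12, 12); init[sample.int(144, 2)] <- 1
  suit <- matrix(rbinom(144, 1, 0.55), 12, 12)
  counts <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    out <- disperse(bin(init), bin(suit),
                    dispersal_config(c(1000, 2000, 3000)[i],
                                     maturity_steps = j, n_steps = 6))
    counts[i, j] <- sum(out$final$values == 1)
  }
  for (j in 1:3) expect_true(all(diff(counts[, j]) >= 0))  # radius up
  for (i in 1:3) expect_true(all(diff(counts[i, ]) <= 0))  # maturity up
})

test_that("the automaton is deterministic and the pass-through comparator
           bounds it", {
  set.seed(8)
  init <- bin(matrix(rbinom(100, 1, 0.2), 10, 10))
  suit <- bin(matrix(rbinom(100, 1, 0.7), 10, 10))
  cfg <- dispersal_config(1500, 1, 4)
  a <- disperse(init, suit, cfg)
  b <- disperse(init, suit, cfg)
  expect_identical(a, b)
  # final occupancy is inside the final suitability and inside the
  # unlimited projection
  unl <- unlimited_projection(suit)
  expect_true(all(suit$values[a$final$values == 1] == 1))
  expect_true(all(unl$values[a$final$values == 1] == 1))
  expect_gte(sum(unl$values == 1), sum(a$final$values == 1))
  expect_error(disperse(init, list(), cfg), "at least one")
})
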