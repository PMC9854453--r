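test_that("threshold rules match their examples and the scan oracle", {
  # perfect separation: every rule lands between the clusters and the
  # resulting maps coincide
  sp <- rep(0.9, 10); sb <- rep(0.1, 40)
  # every rule lands in (0.1, 0.9] (MEAN_OCC_PROB returns exactly 0.9 when
  # every presence scores 0.9); with the >=-inclusive binarization all
  # four maps coincide
  maps <- lapply(threshold_methods(), function(m) {
    t <- find_threshold(sp, sb, m)
    expect_gt(t, 0.1); expect_lte(t, 0.9)
    as.numeric(c(sp, sb) >= t)
  })
  for (m in maps[-1]) expect_identical(m, maps[[1]])
  # mean occurrence probability is the arithmetic presence mean
  expect_equal(find_threshold(c(0.2, 0.4, 0.9), c(0.1), "MEAN_OCC_PROB"),
               0.5)
  # mixed instances: each rule equals the exhaustive candidate scan
  for (s in 1:10) {
    set.seed(s)
    spx <- round(runif(sample(3:25, 1)), 2)
    sbx <- round(runif(sample(3:25, 1)), 2)
    for (m in threshold_methods())
      expect_equal(find_threshold(spx, sbx, m), oracle_threshold(spx, sbx, m),
                   info = paste(m, s))
  }
  expect_error(find_threshold(numeric(0), 1, "MAX_TSS"), "required")
})

test_that("binarization is threshold-inclusive and nodata-propagating", {
  set.seed(1)
  v <- matrix(runif(100), 10, 10); v[1, 1] <- NA
  g <- tiny_grid(v)
  expect_true(all(binarize(g, 0)$values == 1, na.rm = TRUE))
  expect_true(all(binarize(g, 1.01)$values == 0, na.rm = TRUE))
  bz <- binarize(g, 0.5, "MAX_TSS")
  expect_equal(bz$values, ifelse(is.na(v), NA, (v >= 0.5) * 1))
  expect_identical(bz$method, "MAX_TSS")
  expect_true(is.na(bz$values[1, 1]))
  expect_error(binarize(g, NA), "finite")
})

test_that("net change, shift and overlap match hand-built set arithmetic", {
  full <- function(idx, n = 12) {
    v <- matrix(0, n, n); v[idx] <- 1
    g <- tiny_grid(v); class(g) <- c("rs_binary", class(g)); g
  }
  cur <- full(1:100)
  expect_equal(net_change(cur, cur)$net_change_pct, 0)
  expect_equal(range_shift(cur, cur), 0, ignore_attr = TRUE)
  # lose 20 of 100, gain 10 new: net change -10%
  fut <- full(c(21:100, 101:110))
  nc <- net_change(cur, fut)
  expect_equal(nc$loss_cells, 20); expect_equal(nc$gain_cells, 10)
  expect_equal(nc$net_change_pct, -10)
  # pure expansion by a quarter: +25%
  expect_equal(net_change(cur, full(1:125))$net_change_pct, 25)
  # future of 40 cells sharing 30: shift 25%
  cur2 <- full(1:30)
  fut2 <- full(c(1:30, 31:40))
  expect_equal(as.numeric(range_shift(cur2, fut2)), 25)
  # disjoint maps shift completely
  expect_equal(as.numeric(range_shift(full(1:10), full(11:30))), 100)
  # overlap percentages
  expect_equal(species_overlap(cur, cur), 100)
  expect_equal(species_overlap(full(1:10), full(11:30)), 0)
  expect_equal(species_overlap(full(1:50), full(16:80)), 70)  # 35 of 50
  expect_error(net_change(full(integer(0)), cur), "empty")
  expect_error(range_shift(cur, full(integer(0))), "empty")
  expect_error(species_overlap(full(integer(0)), cur), "empty")
})

test_that("summary identities hold on randomized map pairs", {
  set.seed(42)
  for (rep in 1:60) {
    pr <- random_binary_pair(sample(5:50, 1))
    a <- pr$a; b <- pr$b
    if (!sum(a$values == 1, na.rm = TRUE)) next
    nc <- net_change(a, b)
    expect_identical(nc$current_cells, nc$stable_cells + nc$loss_cells)
    expect_identical(nc$future_cells, nc$stable_cells + nc$gain_cells)
    if (nc$future_cells > 0) {
      sh <- as.numeric(range_shift(a, b))
      expect_true(sh >= 0 && sh <= 100)
      fut_in_cur <- nc$gain_cells == 0
      expect_identical(sh == 0, fut_in_cur)   # shift 0 iff future subset
    }
    expect_equal(species_overlap(a, a), 100)
  }
})

test_that("the change map uses the 4-class legend", {
  cur <- tiny_grid(matrix(c(1, 1, 0, 0), 2, 2))
  fut <- tiny_grid(matrix(c(1, 0, 1, 0), 2, 2))
  cm <- change_map(cur, fut)
  expect_equal(as.vector(cm$values), c(2, 1, 3, 0))  # stable/loss/gain/none
})

test_that("factorial summaries report medians, SDs and group sizes", {
  one <- data.frame(species = "a", scenario = "s1", metric = "m",
                    value = 42)
  s1 <- summarize_across(one)
  expect_equal(s1$median, 42); expect_equal(s1$sd, 0)
  three <- data.frame(species = "a", scenario = "s1", metric = "m",
                      value = c(60, 70, 80))
  expect_equal(summarize_across(three)$median, 70)
  # full 3 GCM x 4 threshold factorial: 12 values per scenario cell
  set.seed(2)
  fact <- expand.grid(gcm = paste0("g", 1:3), threshold = paste0("t", 1:4),
                      scenario = c("s1", "s2"), species = "a",
                      metric = "m", stringsAsFactors = FALSE)
  fact$value <- rnorm(nrow(fact))
  sm <- summarize_across(fact)
  expect_identical(nrow(sm), 2L)
  expect_true(all(sm$n == 12))
  for (sc in c("s1", "s2")) {
    v <- fact$value[fact$scenario == sc]
    expect_equal(sm$median[sm$scenario == sc], median(v))
    expect_equal(sm$sd[sm$scenario == sc], sd(v))
  }
})
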