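test_that("polygon morphometrics match closed forms", {
  sq <- measure_polygon(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sq$area, 1)
  expect_equal(sq$perimeter, 4)
  expect_equal(sq$circularity, pi / 4, tolerance = 1e-12)
  expect_equal(sq$solidity, 1, tolerance = 1e-12)

  # regular n-gons: circularity increases monotonically towards 1
  circs <- sapply(c(3, 5, 8, 16, 64, 256), function(n)
    measure_polygon(regular_ngon(n))$circularity)
  expect_true(all(diff(circs) > 0))
  expect_lt(max(circs), 1 + 1e-12)
  expect_gt(circs[6], 0.999)

  # any convex polygon has solidity exactly 1
  expect_equal(measure_polygon(regular_ngon(7))$solidity, 1,
               tolerance = 1e-12)

  expect_error(measure_polygon(cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))),
               "self-intersecting")
  expect_error(measure_polygon(cbind(0:1, 0:1)), "3 vertices")
})

test_that("polygon area/perimeter/solidity agree with naive loop oracles", {
  for (k in 1:12) {
    set.seed(500 + k)
    nv <- sample(5:40, 1)
    th <- sort(runif(nv, 0, 2 * pi))
    r <- runif(nv, 0.5, 1.5)
    v <- cbind(r * cos(th), r * sin(th))   # star-shaped, hence simple
    m <- measure_polygon(v)
    expect_equal(m$area, naive_polygon_area(v), tolerance = 1e-10)
    expect_equal(m$perimeter, naive_polygon_perimeter(v), tolerance = 1e-10)
    hull <- naive_convex_hull(v)
    expect_equal(m$solidity, naive_polygon_area(v) / naive_polygon_area(hull),
                 tolerance = 1e-10)
  }
})

test_that("Crofton perimeter reproduces frozen reference values", {
  # values computed once with an independent integral-geometry
  # implementation of the same 4-direction estimator
  set.seed(42)
  m1 <- matrix(rbinom(400, 1, 0.4), 20)
  m2 <- matrix(rbinom(400, 1, 0.4), 20)
  expect_equal(actomorph:::crofton_perimeter(m1), 262.9792415608,
               tolerance = 1e-9)
  expect_equal(actomorph:::crofton_perimeter(m2), 256.8702775208,
               tolerance = 1e-9)
  disc <- outer(1:201, 1:201, function(r, c) (r - 101)^2 + (c - 101)^2 <= 100^2)
  expect_equal(actomorph:::crofton_perimeter(disc), 630.0640295605,
               tolerance = 1e-9)
  expect_lt(abs(actomorph:::crofton_perimeter(disc) - 2 * pi * 100) /
            (2 * pi * 100), 0.005)
})

test_that("raster discs and squares agree with analytic shape values", {
  disc <- matrix(0L, 220, 220)
  disc[outer(1:220, 1:220, function(r, c)
    (r - 110)^2 + (c - 110)^2 <= 100^2)] <- 1L
  sr <- measure_cells(disc, 1)
  expect_gte(sr$circularity, 0.98)
  expect_gte(sr$solidity, 0.98)

  sq <- matrix(0L, 80, 80); sq[21:60, 21:60] <- 1L
  ss <- measure_cells(sq, 1)
  expect_lt(abs(ss$circularity - pi / 4), 0.03)
  expect_gt(ss$solidity, 0.98)
  expect_equal(ss$area_um2, 1600)
})

test_that("lobes reduce raster circularity and solidity in lockstep with truth", {
  d0 <- generate_lobed_cells(lobed_cell_params(n_cells = 4, lobe_amplitude = 0,
                                               seed = 8))
  d3 <- generate_lobed_cells(lobed_cell_params(n_cells = 4, lobe_amplitude = 0.3,
                                               seed = 8))
  s0 <- suppressMessages(measure_cells(d0$mask, 0.3))
  s3 <- suppressMessages(measure_cells(d3$mask, 0.3))
  expect_true(all(s3$circularity < s0$circularity))
  expect_true(all(s3$solidity < s0$solidity))
})

test_that("raster metrics converge to the polygon oracle as pixels shrink", {
  err <- sapply(c(0.6, 0.3, 0.15), function(ps) {
    mos <- generate_lobed_cells(lobed_cell_params(n_cells = 4,
                                                  lobe_amplitude = 0.3,
                                                  pixel_size_um = ps,
                                                  seed = 11))
    sr <- suppressMessages(measure_cells(mos$mask, ps))
    po <- t(sapply(mos$truth$polygons, function(v)
      unlist(measure_polygon(v), use.names = FALSE)[3:4]))
    c(mean(abs(sr$circularity - po[, 1])), mean(abs(sr$solidity - po[, 2])))
  })
  expect_true(all(diff(err[1, ]) < 0))    # circularity error shrinks
  expect_true(all(diff(err[2, ]) < 0))    # solidity error shrinks
})

test_that("small labels are excluded and border cells flagged", {
  m <- matrix(0L, 40, 40)
  m[5:20, 5:20] <- 1L           # proper cell
  m[30, 30] <- 2L               # below min_px
  m[1:10, 35:40] <- 3L          # touches border
  expect_message(measure_cells(m, 1), "excluded 1 label")
  sr <- suppressMessages(measure_cells(m, 1))
  expect_setequal(sr$cell_id, c(1L, 3L))
  expect_false(sr$touches_border[sr$cell_id == 1])
  expect_true(sr$touches_border[sr$cell_id == 3])
  expect_error(measure_cells(matrix(0L, 5, 5), 1), "no cells")
})

test_that("group comparison letters: identical groups share, shifts separate", {
  mk <- function(group, mu, plants = 4, cells = 12, seed = 1) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(plants), function(p)
      data.frame(cell_id = seq_len(cells), plant_id = p, replicate_id = 1,
                 group = group,
                 area_um2 = 100, perimeter_um = 40,
                 circularity = pmin(pmax(rnorm(cells, mu, 0.03), 0.01), 1),
                 solidity = 0.9, touches_border = FALSE)))
  }
  same <- rbind(mk("a", 0.6, seed = 1), mk("b", 0.6, seed = 2))
  cs <- compare_shape_groups(same, "circularity")
  expect_identical(unname(cs$letters["a"]), unname(cs$letters["b"]))
  expect_identical(cs$unit, "plant")

  three <- rbind(mk("a", 0.6, seed = 1), mk("b", 0.6, seed = 2),
                 mk("c", 0.6, seed = 3))
  ct <- compare_shape_groups(three, "circularity")
  expect_identical(length(unique(unname(ct$letters))), 1L)

  diffg <- rbind(mk("a", 0.45, seed = 1), mk("b", 0.8, seed = 2))
  cd <- compare_shape_groups(diffg, "circularity", alpha = 0.01)
  expect_false(cd$letters["a"] == cd$letters["b"])
  expect_lt(cd$pairs$p_bh[1], 0.01)
})

test_that("relabelling cells leaves group statistics unchanged", {
  d <- generate_lobed_cells(lobed_cell_params(n_cells = 9, seed = 3))
  s1 <- suppressMessages(measure_cells(d$mask, 0.3, plant_id = 1, group = "g"))
  perm <- sample(nrow(s1))
  s2 <- s1[perm, ]; s2$cell_id <- seq_len(nrow(s2))
  other <- s1; other$group <- "h"; other$plant_id <- 2
  c1 <- suppressWarnings(compare_shape_groups(rbind(s1, other), "solidity"))
  c2 <- suppressWarnings(compare_shape_groups(rbind(s2, other), "solidity"))
  expect_equal(c1$pairs$p_raw, c2$pairs$p_raw)
  expect_equal(c1$group_means, c2$group_means)
})

test_that("single-plant groups fall back to per-cell units with a warning", {
  d <- generate_lobed_cells(lobed_cell_params(n_cells = 9, seed = 3))
  a <- suppressMessages(measure_cells(d$mask, 0.3, plant_id = 1, group = "a"))
  b <- suppressMessages(measure_cells(d$mask, 0.3, plant_id = 1, group = "b"))
  expect_warning(cp <- compare_shape_groups(rbind(a, b), "circularity"),
                 "per-cell")
  expect_identical(cp$unit, "cell")
})
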