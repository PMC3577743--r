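test_that("daily deduplication keeps the earliest record per school-day", {
  s <- data.frame(id = c("A", "A", "A", "B", "B"),
                  date = as.Date(c("2020-01-01", "2020-01-01", "2020-01-02",
                                   "2020-01-01", "2020-01-01")),
                  time = c(2, 1, 1, 1, 2),
                  x = 1:5, y = 1:5)
  out <- dedupe_daily(s)
  expect_equal(nrow(out), 3L)
  # earliest record of A on day 1 is the one with time 1 (x = 2)
  expect_equal(out$x[out$id == "A" & out$date == as.Date("2020-01-01")], 2)
  # distinct days unchanged
  s2 <- data.frame(id = "A", date = as.Date("2020-01-01") + 0:9, x = 1:10, y = 1:10)
  expect_equal(nrow(dedupe_daily(s2)), 10L)
  # brute-force group count on a random set
  set.seed(1)
  s3 <- data.frame(id = sample(LETTERS[1:4], 30, TRUE),
                   date = as.Date("2020-01-01") + sample(0:5, 30, TRUE),
                   x = runif(30), y = runif(30))
  expect_equal(nrow(dedupe_daily(s3)),
               nrow(unique(s3[, c("id", "date")])))
})

test_that("LSCV bandwidth minimizes the score and is scale-equivariant", {
  set.seed(42)
  pts <- cbind(rnorm(200), rnorm(200))
  h <- lscv_bandwidth(pts)
  # independent recomputation of the score at every grid candidate
  n <- nrow(pts)
  d2 <- as.vector(dist(pts))^2
  score <- vapply(attr(h, "grid"), function(hh) {
    (n + 2 * sum(exp(-d2 / (4 * hh^2)))) / (4 * pi * hh^2 * n^2) -
      2 * sum(exp(-d2 / (2 * hh^2))) / (pi * hh^2 * n * (n - 1))
  }, numeric(1))
  expect_equal(as.numeric(h), attr(h, "grid")[which.min(score)])
  # scale equivariance within grid resolution
  h2 <- lscv_bandwidth(pts * 1000)
  expect_equal(as.numeric(h2) / as.numeric(h), 1000, tolerance = 0.05)
  # two tight separated clusters want less smoothing than the reference rule
  cl <- rbind(cbind(rnorm(100, 0, 0.5), rnorm(100, 0, 0.5)),
              cbind(rnorm(100, 10, 0.5), rnorm(100, 10, 0.5)))
  hc <- lscv_bandwidth(cl)
  expect_lt(as.numeric(hc), attr(hc, "h_ref"))
  expect_error(lscv_bandwidth(matrix(1, 20, 2)), "degenerate")
})

test_that("kernel UD integrates to one and matches the Gaussian convolution", {
  set.seed(7)
  pts <- cbind(rnorm(3000, 0, 1000), rnorm(3000, 0, 1000))
  ud <- kernel_ud(pts, 300, cell_size = 100)
  expect_equal(sum(ud$density) * ud$grid$cell_size^2, 1, tolerance = 1e-9)
  # density at the origin vs the N(0, (sigma^2 + h^2) I) closed form
  ctr <- grid_centers(ud$grid)
  f0 <- ud$density[which.min(abs(ctr$x)), which.min(abs(ctr$y))]
  expect_equal(f0, 1 / (2 * pi * (1000^2 + 300^2)), tolerance = 0.05)
  # single point: density peaks at the nearest cell
  ud1 <- kernel_ud(cbind(520, 480), 100, cell_size = 50)
  peak <- which(ud1$density == max(ud1$density), arr.ind = TRUE)
  c1 <- grid_centers(ud1$grid)
  expect_lt(abs(c1$x[peak[1]] - 520), 50)
  expect_lt(abs(c1$y[peak[2]] - 480), 50)
  expect_error(kernel_ud(pts, 300, grid = grid_spec(0, 0, 10, 10, 100)),
               "cover")
})

test_that("isopleths nest, match analytic areas, and support multipolygons", {
  set.seed(7)
  pts <- cbind(rnorm(3000, 0, 1000), rnorm(3000, 0, 1000))
  ud <- kernel_ud(pts, 300, cell_size = 100)
  iso95 <- isopleth(ud, 0.95)
  iso50 <- isopleth(ud, 0.50)
  expect_lte(iso50$area_km2, iso95$area_km2)
  expect_gte(iso95$mass, 0.95)
  analytic <- pi * qchisq(0.95, 2) * (1000^2 + 300^2) / 1e6
  expect_equal(iso95$area_km2, analytic, tolerance = 0.05)
  # the 50% cells are a subset of the 95% cells
  expect_true(all(iso95$mask[iso50$mask]))
  # two separated clusters give a disconnected representative range
  cl <- rbind(cbind(rnorm(300, 0, 300), rnorm(300, 0, 300)),
              cbind(rnorm(100, 8000, 300), rnorm(100, 8000, 300)))
  iso_cl <- isopleth(kernel_ud(cl, 300, cell_size = 100), 0.95)
  expect_gte(length(iso_cl$polygons), 2L)
  # uniform-density surface: level 0.5 takes about half the cells
  g <- grid_spec(0, 0, 20, 10, 100)
  unif <- structure(list(grid = g,
                         density = matrix(1 / (200 * 100^2), 20, 10)),
                    class = "ud_surface")
  iso_u <- isopleth(unif, 0.5)
  expect_lte(abs(sum(iso_u$mask) - 100), 20)  # half the cells, within a row
})

test_that("MCP equals an independent gift-wrapping hull and ignores interior points", {
  sq_km <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  expect_equal(mcp_area(sq_km)$area_km2, 1)
  set.seed(3)
  pts <- cbind(runif(50, 0, 5000), runif(50, 0, 5000))
  expect_equal(mcp_area(pts)$area_km2, oracle_hull_area(pts) / 1e6)
  # interior point changes nothing; hull of hull is the hull
  hull <- mcp_area(pts)
  expect_equal(mcp_area(rbind(pts, c(2500, 2500)))$area_km2, hull$area_km2)
  expect_equal(mcp_area(hull$polygon)$area_km2, hull$area_km2)
  # vagrant exclusion shrinks the hull
  vag <- c(rep(FALSE, 50), TRUE)
  far <- rbind(pts, c(50000, 50000))
  expect_equal(mcp_area(far, vagrant = vag, exclude_outliers = TRUE)$area_km2,
               hull$area_km2)
  expect_gt(mcp_area(far)$area_km2, hull$area_km2)
  expect_error(mcp_area(cbind(1:5, 1:5)), "collinear")
})

test_that("overlay fractions are exact on analytic cases", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  expect_equal(overlay_fraction(sq, sq)$fraction, 1)
  far <- sq + 5000
  expect_equal(overlay_fraction(sq, far)$fraction, 0)
  strip <- rbind(c(500, -100), c(2000, -100), c(2000, 1100), c(500, 1100))
  ov <- overlay_fraction(sq, strip)
  expect_equal(ov$fraction, 0.5)
  expect_equal(ov$area_km2, 0.5)
  # cell-based range against a half-plane strip: exact too
  g <- grid_spec(0, 0, 10, 10, 100)
  rng <- structure(list(level = 0.95, grid = g,
                        mask = matrix(TRUE, 10, 10),
                        polygons = list(sq), area_km2 = 1, mass = 1),
                   class = "range_estimate")
  expect_equal(overlay_fraction(rng, strip)$fraction, 0.5)
})

test_that("erasing avoided habitat removes exactly the avoided cells", {
  # range of 2x2 cells at 200 m over a 100 m habitat grid (nested 2:1)
  rg <- grid_spec(0, 0, 2, 2, 200)
  rng <- structure(list(level = 0.95, grid = rg, mask = matrix(TRUE, 2, 2),
                        polygons = list(), area_km2 = 0.16, mass = 1),
                   class = "range_estimate")
  # habitat grid: left half depth 1 (class 1), right half depth 3 (class 2)
  dg <- make_depth_grid(rep(c(1, 1, 3, 3), times = 4), 4, 4, cell = 100)
  hab <- classify_depth(dg, breaks = c(0, 2, 5))$grid
  none <- erase_avoided(rng, hab, integer(0))
  expect_equal(none$area_km2, 0.16)
  all_avoided <- erase_avoided(rng, hab, c(1, 2))
  expect_equal(all_avoided$area_km2, 0)
  expect_length(all_avoided$polygons, 0L)
  half <- erase_avoided(rng, hab, 1)
  expect_equal(half$area_km2, 0.08)
})
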