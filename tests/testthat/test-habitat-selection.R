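test_that("IDW interpolation is exact at soundings and matches the direct formula", {
  # constant field
  s_const <- data.frame(x = runif(20, 0, 500), y = runif(20, 0, 500), depth = 7)
  g <- grid_spec(0, 0, 10, 10, 50)
  expect_equal(as.vector(idw_depth_grid(s_const, g)$depth), rep(7, 100))
  # exactness at a sounding on a cell center
  s <- data.frame(x = c(125, 300, 40, 470, 210),
                  y = c(125, 80, 350, 400, 260),
                  depth = c(2, 5, 9, 14, 11))
  dg <- idw_depth_grid(s, g, power = 2, n_neighbors = 5)
  expect_equal(dg$depth[3, 3], 2)  # cell center (125, 125) coincides
  # brute-force check at an arbitrary cell: w = d^-2
  ctr <- grid_centers(g)
  cx <- ctr$x[8]; cy <- ctr$y[2]
  d2 <- (s$x - cx)^2 + (s$y - cy)^2
  w <- d2^(-1)
  expect_equal(dg$depth[8, 2], sum(w * s$depth) / sum(w))
  expect_error(idw_depth_grid(data.frame(x = 1, y = 1, depth = 1), g), "at least 3")
})

test_that("depth classification uses left-closed intervals and Table-2-style availability", {
  dg <- make_depth_grid(c(1.9, 2.0, 5.0, 19.9, 20.0, -0.5, 10, 14.9, 15),
                        3, 3, cell = 50)
  cl <- classify_depth(dg)
  # 2.0 m belongs to the shallow class, not intertidal; 20 m unclassified
  expect_equal(cl$grid$class[1, 1], 1L)   # 1.9
  expect_equal(cl$grid$class[2, 1], 2L)   # 2.0 boundary goes up
  expect_equal(cl$grid$class[3, 1], 3L)   # 5.0
  expect_equal(cl$grid$class[1, 2], 5L)   # 19.9
  expect_true(is.na(cl$grid$class[2, 2])) # 20.0 outside
  expect_true(is.na(cl$grid$class[3, 2])) # negative depth outside
  expect_equal(cl$grid$class[3, 3], 5L)   # 15 boundary goes up
  expect_equal(sum(cl$availability$g), 1)
  expect_error(classify_depth(dg, breaks = c(0, 5, 2)), "increasing")
  # fractional covers from published-style areas, to 4 dp
  av <- habitat_availability(table2_areas)
  expect_equal(round(av$g, 4), c(0.1736, 0.4643, 0.2538, 0.0913, 0.0169))
  # linear ramp over a rectangle: class areas proportional to break widths
  n <- 40L
  ramp <- make_depth_grid(rep(seq(0, 20 - 20 / n, length.out = n) + 10 / n,
                              times = n), n, n, cell = 50)
  av_ramp <- classify_depth(ramp)$availability
  expect_equal(av_ramp$g, c(2, 3, 5, 5, 5) / 20, tolerance = 1e-9)
})

test_that("use counts match a brute-force point-in-cell lookup", {
  set.seed(2)
  dg <- make_depth_grid(runif(100, 0, 20), 10, 10, cell = 50)
  cl <- classify_depth(dg)
  s <- data.frame(x = runif(100, 0, 500), y = runif(100, 0, 500))
  f <- count_use(s, cl$grid)
  # brute force: locate each point's cell by scanning
  brute <- integer(5)
  for (i in seq_len(100)) {
    ix <- floor(s$x[i] / 50) + 1; iy <- floor(s$y[i] / 50) + 1
    k <- cl$grid$class[ix, iy]
    if (!is.na(k)) brute[k] <- brute[k] + 1L
  }
  expect_equal(as.integer(f), brute)
  expect_equal(sum(f) + attr(f, "excluded"), 100L)
  # out-of-grid sightings are excluded with a warning
  expect_warning(count_use(data.frame(x = -10, y = -10), cl$grid), "excluded")
  # no sightings -> zeros
  expect_equal(as.integer(suppressWarnings(
    count_use(data.frame(x = numeric(0), y = numeric(0)), cl$grid))), rep(0L, 5))
})

test_that("Manly's alpha matches the published worked example and its limits", {
  a <- manly_alpha(table2_counts, habitat_availability(table2_areas))
  expect_equal(round(a, 2), c(0.07, 0.26, 0.29, 0.32, 0.05))
  expect_equal(sum(a), 1)
  # proportional use -> all equal
  g <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(manly_alpha(g * 1000, g), rep(0.25, 4))
  # absolute preference
  expect_equal(manly_alpha(c(0, 0, 0, 0, 10), rep(0.2, 5)), c(0, 0, 0, 0, 1))
  expect_error(manly_alpha(c(1, 1), c(0, 1)), "zero availability")
})

test_that("Bray-Curtis dissimilarity has its endpoints and worked value", {
  g <- table2_areas / sum(table2_areas)
  bcd <- bray_curtis(table2_counts, sum(table2_counts) * g)
  expect_equal(bcd, 0.135110, tolerance = 1e-5)  # frozen from direct arithmetic
  # agrees with the published 0.13 at truncation to 2 decimals
  expect_equal(floor(bcd * 100) / 100, 0.13)
  expect_equal(bray_curtis(c(3, 4), c(3, 4)), 0)
  expect_equal(bray_curtis(c(10, 0), c(0, 10)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("global randomization reproduces the null moments and p-values", {
  av <- habitat_availability(table2_areas)
  res <- randomization_global(table2_counts, av, n_iter = 10000, seed = 11)
  expect_equal(res$bcd_exp_mean, 0.03, tolerance = 0.2)
  expect_lt(max(abs(unname(res$bcd_exp_ci) - c(0.01, 0.05))), 0.015)
  expect_equal(res$p_global, 0)
  # observed equal to the null center -> large p
  e_round <- round(sum(table2_counts) * av$g)
  res_null <- randomization_global(e_round, habitat_availability(table2_areas),
                                   n_iter = 2000, seed = 3)
  expect_gt(res_null$p_global, 0.5)
  # two classes, g = (.5, .5), F = 100: closed-form E|Bin - 50|/100
  k <- 0:100
  exact <- sum(abs(k - 50) * dbinom(k, 100, 0.5)) / 100
  res2 <- randomization_global(c(50, 50), c(0.5, 0.5), n_iter = 20000, seed = 5)
  mc_se <- sd(abs(rbinom(20000, 100, 0.5) - 50) / 100) / sqrt(20000)
  expect_lt(abs(res2$bcd_exp_mean - exact), 3 * mc_se)
  # seeded reproducibility
  expect_identical(randomization_global(table2_counts, av, 500, seed = 9),
                   randomization_global(table2_counts, av, 500, seed = 9))
})

test_that("per-habitat D_r tests match the worked example and a centred null", {
  av <- habitat_availability(table2_areas)
  dr <- randomization_dr(table2_counts, av, n_iter = 10000, seed = 13)
  expect_equal(round(dr$dr_obs, 2), c(-0.13, 0.06, 0.09, 0.12, -0.15))
  # every class keeps its significance after Bonferroni; the three strongest
  # deviations never occur under the null in 10,000 draws
  expect_true(all(dr$p_adj < 0.05))
  expect_equal(dr$p_adj[c(1, 3, 4)], rep(0, 3))
  expect_equal(sum(dr$dr_obs), 0, tolerance = 1e-12)
  # null pseudo-D centred at zero within Monte-Carlo error (alpha is a ratio
  # estimator, so allow a small-sample bias margin on top of 3 SEs)
  expect_true(all(abs(dr$e_dr) < 3 * 0.5 / sqrt(10000) + 0.003))
  # proportional use: all deviations exactly zero
  av0 <- habitat_availability(c(10, 20, 30, 40))
  dr0 <- randomization_dr(c(100, 200, 300, 400), av0, n_iter = 200, seed = 1)
  expect_equal(dr0$dr_obs, rep(0, 4))
  # p-values are invariant to relabeling classes
  perm <- c(3, 1, 5, 2, 4)
  dr_p <- randomization_dr(table2_counts[perm],
                           habitat_availability(table2_areas[perm]),
                           n_iter = 10000, seed = 13)
  expect_equal(dr_p$alpha, dr$alpha[perm])
  expect_equal(dr_p$dr_obs, dr$dr_obs[perm])
  # p-values are relabeling-invariant in distribution (fresh draws differ)
  expect_equal(dr_p$p_adj, dr$p_adj[perm], tolerance = 0.02)
})

test_that("the electivity wrapper assembles a publishable table", {
  av <- habitat_availability(table2_areas)
  el <- electivity(table2_counts, av, n_iter = 2000, seed = 21)
  expect_s3_class(el, "electivity_result")
  expect_named(el$table,
               c("class", "label", "area_km2", "g", "n", "alpha", "dr_obs",
                 "e_dr", "e_dr_lo", "e_dr_hi", "p", "p_adj"))
  expect_equal(el$table$n, table2_counts)
  expect_output(print(el), "BCD_obs")
})
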