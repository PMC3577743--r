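# Depth-habitat electivity: IDW bathymetry interpolation, depth classes,
# Manly's alpha, and Bray-Curtis / D_r randomization tests.

#' Interpolate a depth grid from soundings by inverse distance weighting
#'
#' Each cell takes the inverse-distance-power weighted mean of its `n_neighbors`
#' nearest soundings. A cell whose center coincides with a sounding takes
#' that sounding's depth exactly.
#'
#' @param soundings data frame with columns `x`, `y` (projected m) and
#'   `depth` (m at lowest astronomical tide).
#' @param grid a [grid_spec()]; cell size 50 m in the reference analysis.
#' @param power inverse-distance exponent (default 2).
#' @param n_neighbors number of nearest soundings per cell (default 12).
#' @return An object of class `depth_grid`: list with `grid` and `depth`
#'   (`nx` by `ny` matrix, m).
#' @export
idw_depth_grid <- function(soundings, grid, power = 2, n_neighbors = 12L) {
  stopifnot(is.data.frame(soundings), all(c("x", "y", "depth") %in% names(soundings)))
  n <- nrow(soundings)
  if (n < 3L) stop("need at least 3 soundings")
  k <- min(n_neighbors, n)
  ctr <- grid_centers(grid)
  cx <- rep(ctr$x, times = grid$ny)
  cy <- rep(ctr$y, each = grid$nx)
  sx <- soundings$x; sy <- soundings$y; sz <- soundings$depth
  ncell <- length(cx)
  out <- numeric(ncell)
  chunk <- max(1L, floor(2e6 / n))
  for (from in seq(1L, ncell, by = chunk)) {
    to <- min(from + chunk - 1L, ncell)
    d2 <- outer(cx[from:to], sx, "-")^2 + outer(cy[from:to], sy, "-")^2
    out[from:to] <- vapply(seq_len(to - from + 1L), function(r) {
      dr <- d2[r, ]
      nb <- if (k < n) order(dr)[seq_len(k)] else seq_len(n)
      dnb <- dr[nb]
      if (dnb[1] < 1e-12) return(sz[nb[1]])    # exact at a sounding
      w <- dnb^(-power / 2)                    # d2 is squared distance
      sum(w * sz[nb]) / sum(w)
    }, numeric(1))
  }
  structure(list(grid = grid, depth = matrix(out, grid$nx, grid$ny)),
            class = "depth_grid")
}

#' Classify a depth grid into habitat classes and compute availability
#'
#' Depth classes are left-closed, right-open intervals `[break_r, break_{r+1})`
#' (a 2.0 m cell is "shallow", not "intertidal"). Cells outside the break
#' span are unclassified and excluded from availability. When a range is
#' supplied, availability is computed over the classified cells whose
#' centers fall inside it.
#'
#' @param dgrid a `depth_grid` from [idw_depth_grid()].
#' @param breaks strictly increasing depth breaks (m); the default gives the
#'   five classes intertidal (0-2), shallow (2-5), subtidal (5-10),
#'   moderate (10-15) and deeper water (15-20).
#' @param range optional `range_estimate` restricting availability.
#' @return List with `grid` (a `habitat_grid`: class-index matrix, breaks,
#'   labels) and `availability` (a `habitat_availability` data frame with
#'   columns `class`, `label`, `area_km2`, `g`).
#' @export
classify_depth <- function(dgrid, breaks = c(0, 2, 5, 10, 15, 20), range = NULL) {
  stopifnot(inherits(dgrid, "depth_grid"))
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  n_r <- length(breaks) - 1L
  labels <- sprintf("%g-%g m", breaks[-length(breaks)], breaks[-1])
  cls <- findInterval(as.vector(dgrid$depth), breaks)  # [b_r, b_{r+1}) -> r
  cls[cls < 1L | cls > n_r] <- NA_integer_
  cls <- matrix(as.integer(cls), dgrid$grid$nx, dgrid$grid$ny)
  hgrid <- structure(list(grid = dgrid$grid, class = cls,
                          breaks = breaks, labels = labels),
                     class = "habitat_grid")
  sel <- !is.na(cls)
  if (!is.null(range)) {
    stopifnot(inherits(range, "range_estimate"))
    ctr <- grid_centers(dgrid$grid)
    cx <- rep(ctr$x, times = dgrid$grid$ny)
    cy <- rep(ctr$y, each = dgrid$grid$nx)
    ci <- cell_index(range$grid, cx, cy)
    inr <- !is.na(ci[, 1]) & range$mask[cbind(ci[, 1], ci[, 2])]
    sel <- sel & matrix(inr, dgrid$grid$nx, dgrid$grid$ny)
  }
  counts <- tabulate(cls[sel], nbins = n_r)
  areas <- counts * dgrid$grid$cell_size^2 / 1e6
  list(grid = hgrid, availability = habitat_availability(areas, labels))
}

#' Habitat availability from class areas
#'
#' @param area_km2 nonnegative vector of per-class areas (km2).
#' @param labels optional class labels.
#' @return A `habitat_availability` data frame with columns `class`, `label`,
#'   `area_km2` and `g` (fractional cover, summing to 1).
#' @export
habitat_availability <- function(area_km2, labels = NULL) {
  stopifnot(all(area_km2 >= 0), sum(area_km2) > 0)
  n_r <- length(area_km2)
  if (is.null(labels)) labels <- paste("class", seq_len(n_r))
  structure(data.frame(class = seq_len(n_r), label = labels,
                       area_km2 = area_km2, g = area_km2 / sum(area_km2)),
            class = c("habitat_availability", "data.frame"))
}

#' Count habitat use by sightings
#'
#' `f_r` is the number of sightings whose containing grid cell carries class
#' `r`. Sightings outside the grid, or in unclassified cells, are excluded
#' with a warning (and reported in the `excluded` attribute).
#'
#' @param sightings data frame with columns `x`, `y` (projected m).
#' @param habitat a `habitat_grid` from [classify_depth()].
#' @return A `habitat_use` object: integer vector `f` with attribute
#'   `excluded`.
#' @export
count_use <- function(sightings, habitat) {
  stopifnot(inherits(habitat, "habitat_grid"))
  n_r <- length(habitat$labels)
  ci <- cell_index(habitat$grid, sightings$x, sightings$y)
  cls <- rep(NA_integer_, nrow(ci))
  ok <- !is.na(ci[, 1])
  cls[ok] <- habitat$class[cbind(ci[ok, 1], ci[ok, 2])]
  excluded <- sum(is.na(cls))
  if (excluded > 0)
    warning(sprintf("%d sighting(s) outside the classified grid were excluded", excluded))
  f <- tabulate(cls[!is.na(cls)], nbins = n_r)
  structure(as.integer(f), excluded = excluded, class = "habitat_use")
}

use_counts <- function(use) {
  if (inherits(use, "habitat_use")) as.integer(unclass(use)) else as.integer(use)
}

#' Manly's alpha electivity score
#'
#' `alpha_r = (f_r / g_r) / sum_s (f_s / g_s)`: 0 where a habitat is never
#' used, 1 for absolute preference, all equal to `1/n_R` when use is
#' proportional to availability.
#'
#' @param use per-class use counts (`habitat_use` or integer vector).
#' @param avail a `habitat_availability`, or a numeric vector of fractional
#'   covers `g`.
#' @return Numeric vector of electivity scores summing to 1.
#' @export
manly_alpha <- function(use, avail) {
  f <- use_counts(use)
  g <- if (is.data.frame(avail)) avail$g else as.numeric(avail)
  if (length(f) != length(g)) stop("use and availability lengths differ")
  if (any(g <= 0 & f > 0)) stop("positive use in a habitat with zero availability")
  ratio <- ifelse(f == 0, 0, f / g)
  ratio / sum(ratio)
}

#' Bray-Curtis dissimilarity between use and expected-use vectors
#'
#' `BCD = sum |f_r - E_r| / sum (f_r + E_r)`, in `[0, 1]`: 0 for identical
#' vectors, 1 for the most extreme dissimilarity.
#'
#' @param f,e equal-length nonnegative vectors.
#' @return Scalar dissimilarity.
#' @export
bray_curtis <- function(f, e) {
  f <- as.numeric(f); e <- as.numeric(e)
  if (length(f) != length(e)) stop("vectors must have equal length")
  if (any(f < 0) || any(e < 0)) stop("vectors must be nonnegative")
  tot <- sum(f + e)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(f - e)) / tot
}

#' Global randomization test of habitat selection (Bray-Curtis statistic)
#'
#' Under the null of selection proportional to availability the `F` schools
#' fall into classes as Multinomial(`g`); each draw's Bray-Curtis distance
#' from the expected counts `E(f_r) = F g_r` forms the null distribution.
#' `p = #\{pseudo-BCD >= BCD_obs\} / n_iter` (the raw proportion, which can
#' be exactly 0; set `conservative = TRUE` for the `(k+1)/(n+1)` estimator).
#'
#' @param use per-class use counts.
#' @param avail habitat availability (see [manly_alpha()]).
#' @param n_iter number of multinomial draws (default 10000).
#' @param seed optional integer seed.
#' @param conservative use the add-one p-value estimator.
#' @return List with `bcd_obs`, `bcd_exp_mean`, `bcd_exp_ci` (empirical
#'   2.5/97.5 percentiles), `p_global`, `n_iter`, `seed`.
#' @export
randomization_global <- function(use, avail, n_iter = 10000L, seed = NULL,
                                 conservative = FALSE) {
  f <- use_counts(use)
  g <- if (is.data.frame(avail)) avail$g else as.numeric(avail)
  F_tot <- sum(f)
  if (F_tot < 1) stop("need at least one sighting")
  if (!is.null(seed)) set.seed(seed)
  e <- F_tot * g
  bcd_obs <- bray_curtis(f, e)
  draws <- rmultinom(n_iter, F_tot, g)                  # n_R x n_iter
  pseudo <- colSums(abs(draws - e)) / (2 * F_tot)       # sum(draw + e) = 2F
  k <- sum(pseudo >= bcd_obs)
  p <- if (conservative) (k + 1) / (n_iter + 1) else k / n_iter
  list(bcd_obs = bcd_obs,
       bcd_exp_mean = mean(pseudo),
       bcd_exp_ci = unname(quantile(pseudo, c(0.025, 0.975))),
       p_global = p, n_iter = n_iter, seed = seed)
}

#' Per-habitat randomization tests on Manly's alpha deviations
#'
#' `D_r = alpha_r - 1/n_R`; positive values indicate preference, negative
#' avoidance. For each multinomial null draw the pseudo `D_r` are recomputed;
#' the two-sided p-value is the proportion of pseudo values at least as far
#' from 0 as the observed one, Bonferroni-adjusted as `min(1, n_R p)`.
#'
#' @inheritParams randomization_global
#' @return Data frame with per-class `alpha`, `dr_obs`, `e_dr` (null mean of
#'   the signed pseudo-deviations), `e_dr_lo`/`e_dr_hi` (2.5/97.5
#'   percentiles), `p` and `p_adj`; attributes `n_iter`, `seed`.
#' @export
randomization_dr <- function(use, avail, n_iter = 10000L, seed = NULL,
                             conservative = FALSE) {
  f <- use_counts(use)
  g <- if (is.data.frame(avail)) avail$g else as.numeric(avail)
  n_r <- length(g)
  F_tot <- sum(f)
  if (F_tot < 1) stop("need at least one sighting")
  if (!is.null(seed)) set.seed(seed)
  alpha_obs <- manly_alpha(f, g)
  dr_obs <- alpha_obs - 1 / n_r
  pos <- g > 0                  # zero-availability classes carry no test
  draws <- rmultinom(n_iter, F_tot, g)
  ratio <- draws[pos, , drop = FALSE] / g[pos]         # recycles g down columns
  pseudo_alpha <- sweep(ratio, 2, colSums(ratio), "/")
  pseudo_dr <- matrix(NA_real_, n_r, n_iter)
  pseudo_dr[pos, ] <- pseudo_alpha - 1 / n_r
  k <- rowSums(abs(pseudo_dr) >= matrix(abs(dr_obs), n_r, n_iter))
  p <- ifelse(pos, if (conservative) (k + 1) / (n_iter + 1) else k / n_iter,
              NA_real_)
  q_dr <- function(prob) apply(pseudo_dr, 1, function(z)
    if (all(is.na(z))) NA_real_ else quantile(z, prob))
  res <- data.frame(class = seq_len(n_r),
                    alpha = alpha_obs,
                    dr_obs = dr_obs,
                    e_dr = rowMeans(pseudo_dr),
                    e_dr_lo = q_dr(0.025),
                    e_dr_hi = q_dr(0.975),
                    p = p,
                    p_adj = pmin(1, n_r * p))
  attr(res, "n_iter") <- n_iter
  attr(res, "seed") <- seed
  res
}

#' Full electivity analysis
#'
#' Convenience wrapper combining [manly_alpha()], the global Bray-Curtis
#' randomization test and the per-habitat `D_r` tests into one result, the
#' per-class table mirroring the usual electivity report (class, area, g,
#' n, alpha, D_r, null expectation with CI, adjusted p).
#'
#' @inheritParams randomization_global
#' @return An `electivity_result`: list with `table` (per-class data frame),
#'   `global` (the [randomization_global()] result), `n_iter`, `seed`.
#' @export
electivity <- function(use, avail, n_iter = 10000L, seed = NULL) {
  f <- use_counts(use)
  av <- if (is.data.frame(avail)) avail else habitat_availability(as.numeric(avail))
  glob <- randomization_global(f, av, n_iter = n_iter, seed = seed)
  dr <- randomization_dr(f, av, n_iter = n_iter,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  tab <- data.frame(class = av$class, label = av$label,
                    area_km2 = av$area_km2, g = av$g, n = f,
                    dr[, c("alpha", "dr_obs", "e_dr", "e_dr_lo", "e_dr_hi",
                           "p", "p_adj")])
  structure(list(table = tab, global = glob, n_iter = n_iter, seed = seed),
            class = "electivity_result")
}

#' @export
print.electivity_result <- function(x, ...) {
  g <- x$global
  cat(sprintf("Habitat electivity (%d randomizations)\n", x$n_iter))
  cat(sprintf("  BCD_obs = %.3f, null mean %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              g$bcd_obs, g$bcd_exp_mean, g$bcd_exp_ci[1], g$bcd_exp_ci[2],
              g$p_global))
  print(format(x$table, digits = 3), ...)
  invisible(x)
}
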