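# IUCN regional Red List criteria B1, B2 and D as a transparent rules
# engine. Thresholds live in a versioned config, not in the logic.

iucn_levels <- c("CR", "EN", "VU", "NT", "not_met")

#' Default IUCN v3.1 threshold configuration
#'
#' Full CR/EN/VU ladders for criterion B1 (extent of occurrence, km2),
#' B2 (area of occupancy, km2) and D (mature individuals).
#'
#' @return Nested list of thresholds, with a `version` field.
#' @export
iucn_thresholds <- function() {
  list(version = "IUCN Red List Categories and Criteria v3.1",
       B1 = list(CR = 100, EN = 5000, VU = 20000),
       B2 = list(CR = 10, EN = 500, VU = 2000),
       D = list(CR = 50, EN = 250, VU = 1000))
}

#' Read an IUCN threshold configuration from a YAML key-value file
#'
#' The file must carry the same structure as [iucn_thresholds()]; missing
#' entries fall back to the defaults.
#'
#' @param path YAML file path.
#' @return Threshold list.
#' @export
read_iucn_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- iucn_thresholds()
  for (crit in c("B1", "B2", "D"))
    for (lev in c("CR", "EN", "VU"))
      if (!is.null(cfg[[crit]][[lev]])) out[[crit]][[lev]] <- cfg[[crit]][[lev]]
  if (!is.null(cfg$version)) out$version <- cfg$version
  out
}

#' Mature population size
#'
#' Mature individuals as a fixed fraction of total abundance, rounded down
#' to whole animals.
#'
#' @param N_total total population size.
#' @param mature_fraction fraction mature, in (0, 1] (0.5-0.6 is typical
#'   for inshore dolphins).
#' @return Integer count.
#' @export
mature_population <- function(N_total, mature_fraction) {
  if (mature_fraction <= 0 || mature_fraction > 1)
    stop("mature_fraction must be in (0, 1]")
  as.integer(floor(N_total * mature_fraction))
}

area_category <- function(area, ladder) {
  if (area < ladder$CR) "CR"
  else if (area < ladder$EN) "EN"
  else if (area < ladder$VU) "VU"
  else "not_met"
}

#' Assess IUCN criterion B (geographic range)
#'
#' B1 uses extent of occurrence (MCP area); B2 uses area of occupancy (the
#' 95% UD area serves as its proxy). The area sets a provisional category,
#' confirmed only when at least two of the three subcriteria hold:
#' single location / severe fragmentation, continuing decline, extreme
#' fluctuations.
#'
#' @param eoo_km2 extent of occurrence (km2), or `NULL` to skip B1.
#' @param aoo_km2 area of occupancy (km2), or `NULL` to skip B2.
#' @param single_location,continuing_decline,extreme_fluctuations logical
#'   subcriteria flags.
#' @param thresholds threshold config (default [iucn_thresholds()]).
#' @return Named character vector with entries `B1` and/or `B2`, each one of
#'   `"CR"`, `"EN"`, `"VU"`, `"not_met"`.
#' @export
assess_criterion_b <- function(eoo_km2 = NULL, aoo_km2 = NULL,
                               single_location = FALSE,
                               continuing_decline = FALSE,
                               extreme_fluctuations = FALSE,
                               thresholds = iucn_thresholds()) {
  if (is.null(eoo_km2) && is.null(aoo_km2))
    stop("provide at least one of eoo_km2, aoo_km2")
  n_sub <- sum(single_location, continuing_decline, extreme_fluctuations)
  out <- character(0)
  if (!is.null(eoo_km2)) {
    stopifnot(eoo_km2 >= 0)
    cat_b1 <- area_category(eoo_km2, thresholds$B1)
    out["B1"] <- if (n_sub >= 2) cat_b1 else "not_met"
  }
  if (!is.null(aoo_km2)) {
    stopifnot(aoo_km2 >= 0)
    cat_b2 <- area_category(aoo_km2, thresholds$B2)
    out["B2"] <- if (n_sub >= 2) cat_b2 else "not_met"
  }
  out
}

#' Assess IUCN criterion D (small population size)
#'
#' CR below 50 mature individuals, EN below 250, VU below 1000 (D1). No
#' subcriteria are required.
#'
#' @param n_mature number of mature individuals.
#' @param thresholds threshold config.
#' @return One of `"CR"`, `"EN"`, `"VU"`, `"not_met"`.
#' @export
assess_criterion_d <- function(n_mature, thresholds = iucn_thresholds()) {
  stopifnot(n_mature >= 0)
  area_category(n_mature, thresholds$D)
}

#' Combine per-criterion categories into an overall assessment
#'
#' The overall category is the highest-risk category met by any criterion.
#' With `downgrade = TRUE` (regional assessment with a plausible rescue
#' effect from conspecific populations outside the region) the category is
#' shifted one step down: CR to EN, EN to VU, VU to NT.
#'
#' @param categories named character vector of per-criterion categories.
#' @param downgrade apply the regional one-step downgrade.
#' @return An `iucn_result`: list with `per_criterion`, `overall`,
#'   `downgraded`.
#' @export
overall_assessment <- function(categories, downgrade = FALSE) {
  if (length(categories) == 0L) stop("no criteria evaluated")
  lev <- factor(categories, levels = iucn_levels, ordered = FALSE)
  if (anyNA(lev)) stop("unknown category in input")
  overall <- iucn_levels[min(match(categories, iucn_levels))]
  downgraded <- overall
  if (downgrade && overall %in% c("CR", "EN", "VU"))
    downgraded <- iucn_levels[match(overall, iucn_levels) + 1L]
  structure(list(per_criterion = categories, overall = overall,
                 downgraded = if (downgrade) downgraded else NULL),
            class = "iucn_result")
}

#' @export
print.iucn_result <- function(x, ...) {
  cat("IUCN regional assessment\n")
  for (k in names(x$per_criterion))
    cat(sprintf("  %-3s: %s\n", k, x$per_criterion[[k]]))
  cat("  overall:", x$overall, "\n")
  if (!is.null(x$downgraded))
    cat("  after regional downgrade:", x$downgraded, "\n")
  invisible(x)
}

#' One-call IUCN assessment from pipeline outputs
#'
#' Evaluates B1 (from the MCP extent of occurrence), B2 (from the 95% UD
#' area as area-of-occupancy proxy) and D (from mature population size),
#' then combines them.
#'
#' @param eoo_km2 MCP area (km2).
#' @param aoo_km2 95% UD area (km2).
#' @param N_total total abundance.
#' @param mature_fraction fraction of mature individuals (default 0.5).
#' @param single_location,continuing_decline,extreme_fluctuations criterion
#'   B subcriteria flags.
#' @param downgrade apply the regional one-step downgrade.
#' @param thresholds threshold config.
#' @return An `iucn_result` with an `inputs` element recording what was
#'   assessed.
#' @export
iucn_assess <- function(eoo_km2, aoo_km2, N_total, mature_fraction = 0.5,
                        single_location = FALSE, continuing_decline = FALSE,
                        extreme_fluctuations = FALSE, downgrade = FALSE,
                        thresholds = iucn_thresholds()) {
  n_mat <- mature_population(N_total, mature_fraction)
  cats <- c(assess_criterion_b(eoo_km2, aoo_km2,
                               single_location = single_location,
                               continuing_decline = continuing_decline,
                               extreme_fluctuations = extreme_fluctuations,
                               thresholds = thresholds),
            D = assess_criterion_d(n_mat, thresholds))
  res <- overall_assessment(cats, downgrade = downgrade)
  res$inputs <- list(eoo_km2 = eoo_km2, aoo_km2 = aoo_km2, N_total = N_total,
                     mature_fraction = mature_fraction, n_mature = n_mat,
                     subcriteria = c(single_location = single_location,
                                     continuing_decline = continuing_decline,
                                     extreme_fluctuations = extreme_fluctuations),
                     thresholds_version = thresholds$version)
  res
}
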