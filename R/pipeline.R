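# End-to-end orchestration: synthetic inputs (or files) -> dedupe -> kernel
# ranges -> depth-habitat electivity -> POPAN abundance -> PBR -> IUCN.
# Every stage writes plain CSV/GeoJSON so it can be re-run independently.

#' Pipeline configuration
#'
#' All tunables of the five analysis stages in one list. With the input
#' paths left `NULL` the synthetic-data module generates the inputs from
#' `scenario`.
#'
#' @param scenario a [synthetic_scenario()] used when no input files are
#'   given (its seed drives every stage's randomness).
#' @param sightings,soundings,histories optional CSV paths overriding the
#'   synthetic inputs.
#' @param ud_levels isopleth levels (default representative range 0.95 and
#'   core area 0.50).
#' @param kde_cell KDE grid resolution (m).
#' @param depth_cell depth grid resolution (m).
#' @param depth_breaks depth class breaks (m).
#' @param bandwidth `"lscv"` or a bandwidth in meters.
#' @param n_iter randomization iterations for the electivity tests.
#' @param models POPAN model labels (string for [parse_popan_models()]).
#' @param chat `"auto"`, or a fixed overdispersion factor.
#' @param n_boot bootstrap replicates when `chat = "auto"`.
#' @param theta proportion marked (defaults to the scenario's).
#' @param rmax maximum annual growth rate for PBR.
#' @param fr recovery factors for the PBR table.
#' @param n_sim PBR Monte Carlo draws.
#' @param mature_fractions fractions of mature individuals to report.
#' @param subcriteria named logical vector of criterion-B subcriteria flags.
#' @param downgrade apply the regional one-step downgrade in the IUCN stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = synthetic_scenario(),
                            sightings = NULL, soundings = NULL, histories = NULL,
                            ud_levels = c(0.95, 0.50),
                            kde_cell = 250, depth_cell = 50,
                            depth_breaks = c(0, 2, 5, 10, 15, 20),
                            bandwidth = "lscv",
                            n_iter = 10000L,
                            models = "phi(.)p(t)pent(.)N, phi(.)p(.)pent(.)N",
                            chat = 1, n_boot = 100L,
                            theta = NULL,
                            rmax = 0.04, fr = c(0.1, 0.3, 0.5, 1),
                            n_sim = 5000L,
                            mature_fractions = c(0.5, 0.6),
                            subcriteria = c(single_location = TRUE,
                                            continuing_decline = TRUE,
                                            extreme_fluctuations = FALSE),
                            downgrade = FALSE) {
  structure(list(scenario = scenario, sightings = sightings,
                 soundings = soundings, histories = histories,
                 ud_levels = sort(ud_levels, decreasing = TRUE),
                 kde_cell = kde_cell, depth_cell = depth_cell,
                 depth_breaks = depth_breaks, bandwidth = bandwidth,
                 n_iter = as.integer(n_iter), models = models, chat = chat,
                 n_boot = as.integer(n_boot),
                 theta = if (is.null(theta)) scenario$theta else theta,
                 rmax = rmax, fr = fr, n_sim = as.integer(n_sim),
                 mature_fractions = mature_fractions,
                 subcriteria = subcriteria, downgrade = downgrade),
            class = "pipeline_config")
}

stage_msg <- function(...) message(sprintf(...))

#' Run the full assessment pipeline
#'
#' Executes dedupe, range estimation, habitat electivity, POPAN abundance,
#' PBR and the IUCN assessment; writes per-stage CSV/GeoJSON outputs, a
#' manifest (package version, seeds, parameters) and a plain-text summary
#' into `out_dir`. Reruns with an identical config produce byte-identical
#' tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config$scenario
  t0 <- proc.time()[3]
  run_stage <- function(name, expr) {
    t <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stage_msg("[%s] done in %.1fs", name, proc.time()[3] - t)
    res
  }

  ## inputs
  inputs <- run_stage("inputs", {
    ext <- sc$domain_extent
    dgrid_spec <- grid_spec(ext[1], ext[3],
                            nx = ceiling((ext[2] - ext[1]) / config$depth_cell),
                            ny = ceiling((ext[4] - ext[3]) / config$depth_cell),
                            cell_size = config$depth_cell)
    soundings <- if (is.null(config$soundings)) generate_bathymetry(sc)
                 else read_soundings(config$soundings)
    dgrid <- idw_depth_grid(soundings, dgrid_spec)
    sightings <- if (is.null(config$sightings)) generate_sightings(sc, dgrid)
                 else read_sightings(config$sightings)
    histories <- if (is.null(config$histories)) generate_capture_histories(sc)
                 else read_capture_histories(config$histories)
    write_sightings(sightings, file.path(out_dir, "sightings.csv"))
    write.csv(soundings, file.path(out_dir, "soundings.csv"), row.names = FALSE)
    write_capture_histories(histories, file.path(out_dir, "capture_histories.csv"))
    list(soundings = soundings, dgrid = dgrid, sightings = sightings,
         histories = histories)
  })

  ## spatial range
  range_res <- run_stage("range", {
    s <- dedupe_daily(inputs$sightings)
    pts <- cbind(s$x, s$y)
    h <- if (identical(config$bandwidth, "lscv")) lscv_bandwidth(pts)
         else as.numeric(config$bandwidth)
    ud <- kernel_ud(pts, h, cell_size = config$kde_cell)
    ranges <- lapply(config$ud_levels, function(lv) isopleth(ud, lv))
    names(ranges) <- sprintf("ud%g", 100 * config$ud_levels)
    mcp <- mcp_area(pts)
    tab <- data.frame(
      layer = c(sprintf("%g%% UD", 100 * config$ud_levels), "MCP"),
      area_km2 = c(vapply(ranges, `[[`, numeric(1), "area_km2"), mcp$area_km2),
      bandwidth_m = as.numeric(h))
    write.csv(tab, file.path(out_dir, "range_areas.csv"), row.names = FALSE)
    for (nm in names(ranges))
      write_polygons_geojson(ranges[[nm]]$polygons,
                             file.path(out_dir, paste0("range_", nm, ".geojson")))
    write_polygons_geojson(mcp$polygon, file.path(out_dir, "mcp.geojson"))
    write_ascii_grid(ud, file.path(out_dir, "ud_surface.asc"))
    list(sightings = s, bandwidth = as.numeric(h), ud = ud, ranges = ranges,
         mcp = mcp, table = tab)
  })

  ## habitat electivity, per UD level
  elect_res <- run_stage("electivity", {
    out <- list()
    rows <- list()
    for (i in seq_along(config$ud_levels)) {
      lv <- config$ud_levels[i]
      rng <- range_res$ranges[[i]]
      cl <- classify_depth(inputs$dgrid, breaks = config$depth_breaks, range = rng)
      s <- range_res$sightings
      ci <- cell_index(rng$grid, s$x, s$y)
      inside <- !is.na(ci[, 1]) & rng$mask[cbind(ci[, 1], ci[, 2])]
      use <- suppressWarnings(count_use(s[inside, , drop = FALSE], cl$grid))
      el <- electivity(use, cl$availability, n_iter = config$n_iter,
                       seed = sc$seed + 10L + i)
      out[[sprintf("ud%g", 100 * lv)]] <- list(classified = cl, electivity = el)
      rows[[i]] <- cbind(ud = 100 * lv, el$table,
                         bcd_obs = el$global$bcd_obs,
                         bcd_exp = el$global$bcd_exp_mean,
                         p_global = el$global$p_global)
    }
    tab <- do.call(rbind, rows)
    write.csv(format(tab, digits = 6), file.path(out_dir, "electivity.csv"),
              row.names = FALSE)
    out
  })

  ## POPAN abundance
  abund_res <- run_stage("popan", {
    ms <- rank_popan_models(inputs$histories, config$models,
                            chat = config$chat, n_boot = config$n_boot,
                            seed = sc$seed + 20L)
    write.csv(format(ms$table, digits = 6),
              file.path(out_dir, "popan_models.csv"), row.names = FALSE)
    best <- ms$fits[[which(ms$table$converged)[1L]]]
    D <- nrow(inputs$histories)
    tot <- total_abundance(best$N_m, best$se$N_m, config$theta, n = D)
    write.csv(data.frame(model = best$label, N_m = best$N_m,
                         se_N_m = best$se$N_m, theta = tot$theta,
                         N_total = tot$N, N_rounded = tot$N_rounded,
                         se = tot$se, cv = tot$cv,
                         lo = tot$ci[1], hi = tot$ci[2]),
              file.path(out_dir, "abundance.csv"), row.names = FALSE)
    list(models = ms, best = best, total = tot)
  })

  ## PBR
  pbr_res <- run_stage("pbr", {
    set.seed(sc$seed + 30L)
    tab <- pbr_table(abund_res$total$N, abund_res$total$se, rmax = config$rmax,
                     fr = config$fr, n_sim = config$n_sim,
                     seed = sc$seed + 30L)
    write.csv(format(tab, digits = 6), file.path(out_dir, "pbr.csv"),
              row.names = FALSE)
    tab
  })

  ## IUCN
  iucn_res <- run_stage("iucn", {
    sub <- config$subcriteria
    res <- lapply(config$mature_fractions, function(mf)
      iucn_assess(eoo_km2 = range_res$mcp$area_km2,
                  aoo_km2 = range_res$ranges[[1L]]$area_km2,
                  N_total = abund_res$total$N_rounded,
                  mature_fraction = mf,
                  single_location = isTRUE(unname(sub["single_location"])),
                  continuing_decline = isTRUE(unname(sub["continuing_decline"])),
                  extreme_fluctuations = isTRUE(unname(sub["extreme_fluctuations"])),
                  downgrade = config$downgrade))
    tab <- do.call(rbind, lapply(res, function(r)
      data.frame(mature_fraction = r$inputs$mature_fraction,
                 n_mature = r$inputs$n_mature,
                 eoo_km2 = r$inputs$eoo_km2, aoo_km2 = r$inputs$aoo_km2,
                 B1 = r$per_criterion[["B1"]], B2 = r$per_criterion[["B2"]],
                 D = r$per_criterion[["D"]], overall = r$overall)))
    write.csv(tab, file.path(out_dir, "iucn.csv"), row.names = FALSE)
    list(results = res, table = tab)
  })

  manifest <- list(
    package = "coastcete",
    version = as.character(utils::packageVersion("coastcete")),
    seed = sc$seed,
    stage_seeds = list(sightings = sc$seed + 1L, histories = sc$seed + 2L,
                       electivity = sc$seed + 11L, popan = sc$seed + 20L,
                       pbr = sc$seed + 30L),
    parameters = config[setdiff(names(config), "scenario")],
    scenario = unclass(sc))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  summary_lines <- c(
    "coastcete pipeline summary",
    sprintf("sightings: %d (%d after daily dedupe)",
            nrow(inputs$sightings), nrow(range_res$sightings)),
    sprintf("bandwidth: %.0f m", range_res$bandwidth),
    sprintf("%s", paste(sprintf("%s = %.1f km2", range_res$table$layer,
                                range_res$table$area_km2), collapse = "; ")),
    sprintf("best POPAN model: %s, N_m = %.1f, N_total = %d (95%% CI %.0f-%.0f)",
            abund_res$best$label, abund_res$best$N_m,
            abund_res$total$N_rounded, abund_res$total$ci[1],
            abund_res$total$ci[2]),
    sprintf("PBR at Fr=%.1f: %.2f /yr", pbr_res$fr, pbr_res$pbr),
    sprintf("IUCN overall (mature fraction %.2f): %s",
            iucn_res$table$mature_fraction, iucn_res$table$overall))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  stage_msg("pipeline complete in %.1fs", proc.time()[3] - t0)

  invisible(list(inputs = inputs, range = range_res, electivity = elect_res,
                 abundance = abund_res, pbr = pbr_res, iucn = iucn_res,
                 manifest = manifest))
}
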