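#' Run the full simulate/analyze pipeline from a configuration
#'
#' Executes the requested stages of the analysis from a single configuration
#' (a nested list, or the path of a YAML file with the same structure) and
#' returns a machine-readable report. Supported top-level blocks:
#'
#' * `spt`: either `tracks` (a CSV path) or `simulate` (arguments to
#'   [simulate_tracks()]), optional `filter` (`min_length`,
#'   `bleach_cutoff_frame`), and `analysis` (`lag`, `k_max`, `alpha`,
#'   `bic_drop`, `msd_max_lag`, `cluster` flag). Runs
#'   filter -> MSD -> linear fit -> SQD -> model selection -> jump-distance
#'   check -> TAMSD clustering.
#' * `bli`: `sensorgram` (CSV path) + `analyte_conc`, or `simulate`
#'   (arguments to [simulate_sensorgram()]). Runs the 1:1 kinetic fits.
#' * `atpase`: `rates` (CSV path with `substrate_mM,rate`) or `simulate`
#'   (arguments to [simulate_rate_curve()]). Fits the Hill model.
#' * `qpcr`: `ct` (CSV path) or `simulate` (arguments to [simulate_qpcr()]),
#'   optional `efficiency_target`, `efficiency_ref`. Computes copy ratios.
#'
#' A top-level `seed` seeds every simulation block (offset per stage so the
#' streams are independent); identical config + seed gives identical results.
#' A failing stage is recorded and aborts only its own downstream steps.
#'
#' @param config Nested list or YAML file path.
#' @param out_dir Optional directory; when given, per-stage JSON results and
#'   TSV summary tables are written there.
#' @return An object of class `run_report`: list with `results` (per-stage),
#'   `warnings`, `errors`, `provenance` (package version, config hash, seed).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  seed <- config$seed %||% 1L
  results <- list(); errors <- list(); warnings_log <- character()

  collect <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        errors[[stage]] <<- conditionMessage(e)
        NULL
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  if (!is.null(config$spt)) {
    cfg <- config$spt
    ts <- collect("spt.input", {
      if (!is.null(cfg$tracks)) {
        do.call(read_tracks_csv, c(list(path = cfg$tracks),
                                   cfg$read %||% list()))
      } else if (!is.null(cfg$simulate)) {
        sim <- cfg$simulate
        sim$seed <- sim$seed %||% seed
        do.call(simulate_tracks, sim)
      } else abort("spt block needs `tracks` or `simulate`")
    })
    if (!is.null(ts)) {
      fl <- cfg$filter %||% list()
      ts <- collect("spt.filter", {
        filter_tracks(ts,
                      min_length = fl$min_length %||% 5,
                      bleach_cutoff_frame = fl$bleach_cutoff_frame %||% 500)
      })
    }
    if (!is.null(ts)) {
      an <- cfg$analysis %||% list()
      msd <- collect("spt.msd", compute_msd(ts, max_lag = an$msd_max_lag %||% 4))
      msd_fit <- if (!is.null(msd)) collect("spt.msd_fit", fit_msd_linear(msd))
      sel <- collect("spt.sqd", {
        sqd <- compute_sqd(ts, lag = an$lag %||% 1)
        select_model(sqd, k_max = an$k_max %||% 3,
                     alpha = an$alpha %||% 0.05,
                     bic_drop = an$bic_drop %||% 0.05,
                     seed = seed + 101L)
      })
      jd <- if (!is.null(sel)) {
        collect("spt.jump_distance",
                fit_jump_distance(ts, selected_fit(sel), lag = an$lag %||% 1))
      }
      clus <- if (!is.null(sel) && isTRUE(an$cluster %||% TRUE)) {
        collect("spt.cluster",
                cluster_tamsd(ts, k = sel$selected_k, seed = seed + 202L))
      }
      results$spt <- list(
        n_tracks = length(unique(ts$track_id)),
        msd = if (!is.null(msd)) as_tibble(msd),
        msd_fit = if (!is.null(msd_fit)) tidy(msd_fit),
        msd_d = if (!is.null(msd_fit)) msd_fit$d,
        selection = if (!is.null(sel)) {
          list(selected_k = sel$selected_k,
               comparisons = tidy(sel),
               components = tidy(selected_fit(sel)))
        },
        jump_distance = if (!is.null(jd)) {
          list(chi2 = jd$chi2, r_squared = jd$r_squared)
        },
        clusters = if (!is.null(clus)) tidy(clus))
    }
  }

  if (!is.null(config$bli)) {
    cfg <- config$bli
    results$bli <- collect("bli", {
      sg <- if (!is.null(cfg$sensorgram)) {
        read_sensorgram_csv(cfg$sensorgram, analyte_conc = cfg$analyte_conc,
                            t_assoc = cfg$t_assoc)
      } else if (!is.null(cfg$simulate)) {
        sim <- cfg$simulate
        sim$seed <- sim$seed %||% (seed + 303L)
        do.call(simulate_sensorgram, sim)
      } else abort("bli block needs `sensorgram` or `simulate`")
      fit <- fit_sensorgram(sg)
      list(estimates = tidy(fit), summary = glance(fit))
    })
  }

  if (!is.null(config$atpase)) {
    cfg <- config$atpase
    results$atpase <- collect("atpase", {
      rt <- if (!is.null(cfg$rates)) {
        df <- readr::read_csv(cfg$rates, show_col_types = FALSE, progress = FALSE)
        structure(as_tibble(df), class = c("rate_table", class(as_tibble(df))))
      } else if (!is.null(cfg$simulate)) {
        sim <- cfg$simulate
        sim$seed <- sim$seed %||% (seed + 404L)
        do.call(simulate_rate_curve, sim)
      } else abort("atpase block needs `rates` or `simulate`")
      fit <- fit_hill(rt, fix_nh = cfg$fix_nh)
      list(estimates = tidy(fit), summary = glance(fit))
    })
  }

  if (!is.null(config$qpcr)) {
    cfg <- config$qpcr
    results$qpcr <- collect("qpcr", {
      ct <- if (!is.null(cfg$ct)) {
        df <- readr::read_csv(cfg$ct, show_col_types = FALSE, progress = FALSE)
        structure(as_tibble(df), class = c("ct_table", class(as_tibble(df))))
      } else if (!is.null(cfg$simulate)) {
        sim <- cfg$simulate
        sim$seed <- sim$seed %||% (seed + 505L)
        do.call(simulate_qpcr, sim)
      } else abort("qpcr block needs `ct` or `simulate`")
      as_tibble(relative_copy_number(
        ct,
        efficiency_target = cfg$efficiency_target %||% 2,
        efficiency_ref = cfg$efficiency_ref %||% 2))
    })
  }

  report <- structure(list(
    results = results,
    errors = errors,
    warnings = warnings_log,
    provenance = list(
      package = as.character(utils::packageVersion("sptmix")),
      seed = seed,
      config_hash = rlang::hash(config))),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    for (nm in names(results)) {
      tabs <- extract_tables(results[[nm]], nm)
      for (tn in names(tabs)) {
        readr::write_tsv(tabs[[tn]], file.path(out_dir, paste0(tn, ".tsv")),
                         progress = FALSE)
      }
    }
  }
  report
}

report_to_json <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "data.frame")) return(as.data.frame(x))
    if (is.list(x)) return(purrr::map(x, simplify))
    x
  }
  simplify(unclass(report))
}

extract_tables <- function(x, prefix) {
  out <- list()
  walk <- function(x, name) {
    if (inherits(x, "data.frame")) {
      out[[name]] <<- as_tibble(x)
    } else if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste(name, nm, sep = "_"))
    }
  }
  walk(x, prefix)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run report (seed %s, config %s)\n",
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8)))
  cat("Stages:", paste(names(x$results), collapse = ", "), "\n")
  if (length(x$errors) > 0) {
    cat("Errors:\n")
    for (nm in names(x$errors)) cat(sprintf("  [%s] %s\n", nm, x$errors[[nm]]))
  }
  if (length(x$warnings) > 0) cat(length(x$warnings), "warning(s) recorded\n")
  invisible(x)
}

#' Write the synthetic fixture set used by the test suite
#'
#' Generates one small instance of every input format the package reads —
#' a track CSV, a TrackMate-style XML of the same tracks, a sensorgram CSV,
#' an ATPase rate CSV and a qPCR Ct CSV — together with a
#' `manifest.json` recording every ground-truth parameter. Regeneration with
#' the same seed is byte-identical.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed)

  tr_par <- list(n_tracks = 60, d = c(0.5, 0.02), fractions = c(0.6, 0.4),
                 frame_interval = 0.024, localization_sigma = 0)
  ts <- do.call(simulate_tracks, c(tr_par, list(seed = seed)))
  write_tracks_csv(ts, file.path(out_dir, "tracks.csv"))
  write_trackmate_xml(ts, file.path(out_dir, "tracks.xml"))
  manifest$tracks <- c(tr_par, list(
    n_tracks_after_default_filter =
      length(unique(filter_tracks(ts)$track_id))))

  bli_par <- list(ka = 7.42e4, kd = 0.16, analyte_conc = 2e-6, rmax = 1,
                  noise_sd = 0)
  sg <- do.call(simulate_sensorgram, c(bli_par, list(seed = seed + 1L)))
  readr::write_csv(as_tibble(sg), file.path(out_dir, "sensorgram.csv"),
                   progress = FALSE)
  manifest$sensorgram <- bli_par

  hill_par <- list(vmax = 0.023, k_half = 0.5, n_h = 0.97, noise_sd = 0)
  rt <- do.call(simulate_rate_curve, c(hill_par, list(seed = seed + 2L)))
  readr::write_csv(as_tibble(rt), file.path(out_dir, "rates.csv"),
                   progress = FALSE)
  manifest$rates <- hill_par

  qpcr_par <- list(true_copy_ratio = 5, efficiency_target = 1.9,
                   efficiency_ref = 2, noise_sd = 0, replicates = 3)
  ct <- do.call(simulate_qpcr, c(qpcr_par, list(seed = seed + 3L)))
  readr::write_csv(as_tibble(ct), file.path(out_dir, "ct.csv"),
                   progress = FALSE)
  manifest$qpcr <- qpcr_par

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tracks = file.path(out_dir, "tracks.csv"),
              trackmate = file.path(out_dir, "tracks.xml"),
              sensorgram = file.path(out_dir, "sensorgram.csv"),
              rates = file.path(out_dir, "rates.csv"),
              ct = file.path(out_dir, "ct.csv"),
              manifest = file.path(out_dir, "manifest.json")))
}

# minimal TrackMate-dialect writer used for fixtures and reader equivalence
write_trackmate_xml <- function(ts, path) {
  df <- as_tibble(ts)
  df$spot_id <- seq_len(nrow(df)) - 1L
  doc <- xml2::xml_new_root("TrackMate", version = "6.0.1")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "um",
                               timeunits = "s")
  all_spots <- xml2::xml_add_child(model, "AllSpots")
  for (fr in sort(unique(df$frame))) {
    sif <- xml2::xml_add_child(all_spots, "SpotsInFrame", frame = fr)
    sub <- df[df$frame == fr, ]
    for (i in seq_len(nrow(sub))) {
      xml2::xml_add_child(sif, "Spot",
                          ID = sub$spot_id[i],
                          FRAME = sub$frame[i],
                          POSITION_X = format(sub$x_um[i], digits = 17),
                          POSITION_Y = format(sub$y_um[i], digits = 17))
    }
  }
  all_tracks <- xml2::xml_add_child(model, "AllTracks")
  ids <- unique(df$track_id)
  for (j in seq_along(ids)) {
    sub <- df[df$track_id == ids[j], ]
    sub <- sub[order(sub$frame), ]
    tr <- xml2::xml_add_child(all_tracks, "Track", TRACK_ID = j - 1L,
                              name = ids[j])
    for (i in seq_len(nrow(sub) - 1)) {
      xml2::xml_add_child(tr, "Edge",
                          SPOT_SOURCE_ID = sub$spot_id[i],
                          SPOT_TARGET_ID = sub$spot_id[i + 1])
    }
  }
  settings <- xml2::xml_add_child(doc, "Settings")
  xml2::xml_add_child(settings, "TrackerSettings",
                      LINKING_MAX_DISTANCE = "0.5",
                      MAX_FRAME_GAP = "2",
                      GAP_CLOSING_MAX_DISTANCE = "0.8")
  xml2::write_xml(doc, path)
  invisible(path)
}
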