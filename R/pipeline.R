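write_stage_csv <- function(df, path, seed) {
  body <- readr::format_csv(as_tibble(df))
  writeLines(c(paste0("# querypulse seed=", seed),
               sub("\n+$", "", body)), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> classify -> analyze -> trend on one
#' seed: writes the raw log (JSONL), the classified records (CSV), one
#' cross-tabulation per query category, the advocacy table, the
#' control contrasts, daily trend series by TLD and advocacy, and a JSON
#' run manifest tying everything together. Every output CSV carries the
#' seed in a header comment and the whole run is deterministic for a fixed
#' seed.
#'
#' @param config A [generator_config()]; ignored when `log` is supplied.
#' @param out_dir Output directory (created if missing).
#' @param taxonomy A `qp_taxonomy`.
#' @param registry A `qp_registry`.
#' @param seed Integer seed overriding `config$seed`.
#' @param log Optional pre-existing log tibble (`day, query, clicked_url`)
#'   to analyse instead of generating one.
#' @param window A [event_window()]; defaults to the config's geometry.
#' @param top_k Named class rows per cross-tabulation.
#' @return The run manifest (list of class `qp_manifest`), invisibly:
#'   seed, config hash, per-stage record counts and timings,
#'   unclassified-query and unparseable-URL tallies, output file list.
#' @export
run_pipeline <- function(config = default_generator_config(), out_dir,
                         taxonomy = default_taxonomy(),
                         registry = default_registry(),
                         seed = NULL, log = NULL, window = NULL, top_k = 4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% config$seed)
  window <- window %||% event_window(config$event_day, config$window_days)
  outputs <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  log <- stage("generate", log %||% generate_log(config, seed = seed))
  log_path <- file.path(out_dir, "log.jsonl")
  write_search_log(log, log_path)
  outputs <- c(outputs, log_path)

  classified <- stage("classify", classify_log(log, taxonomy, registry))
  cls_path <- file.path(out_dir, "classified.csv")
  write_stage_csv(classified, cls_path, seed)
  outputs <- c(outputs, cls_path)

  control_cat <- config$control_name %||% "control"
  cats <- sort(unique(stats::na.omit(classified$category)))
  tabs <- stage("analyze", {
    tabs <- purrr::map(setNames(cats, cats), function(cat)
      build_crosstab(classified, cat, window, top_k = top_k))
    for (cat in cats) {
      p <- file.path(out_dir, paste0("crosstab_", cat, ".csv"))
      write_stage_csv(tabs[[cat]], p, seed)
      outputs <- c(outputs, p)
    }
    adv <- advocacy_crosstab(classified, window)
    p <- file.path(out_dir, "advocacy.csv")
    write_stage_csv(adv, p, seed)
    outputs <- c(outputs, p)
    if (control_cat %in% cats) {
      contrasts <- purrr::map_dfr(setdiff(cats, control_cat), function(cat) {
        ct <- control_contrast(tabs[[cat]], tabs[[control_cat]], warn = FALSE)
        dplyr::mutate(as_tibble(ct), group = cat, .before = 1)
      })
      p <- file.path(out_dir, "control_contrast.csv")
      write_stage_csv(contrasts, p, seed)
      outputs <- c(outputs, p)
    }
    tabs
  })

  stage("trend", {
    for (gb in c("tld_category", "advocacy")) {
      tr <- daily_series(classified, gb, window)
      p <- file.path(out_dir, paste0("trend_", gb, ".csv"))
      write_stage_csv(tr, p, seed)
      outputs <- c(outputs, p)
    }
  })

  manifest <- structure(list(
    seed = seed,
    config_hash = rlang::hash(config),
    n_records = nrow(log),
    n_classified = sum(!is.na(classified$category)),
    n_unclassified_queries = sum(is.na(classified$category)),
    n_unparseable_urls = sum(classified$url_error),
    crosstab_totals = purrr::map_int(tabs, function(t)
      as.integer(t$n[t$class_label == "total"])),
    timings = timings,
    outputs = basename(outputs)
  ), class = "qp_manifest")
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), manifest_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @export
print.qp_manifest <- function(x, ...) {
  cat("<qp_manifest> seed=", x$seed, " records=", x$n_records,
      " unclassified=", x$n_unclassified_queries,
      " url_errors=", x$n_unparseable_urls, "\n", sep = "")
  invisible(x)
}
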