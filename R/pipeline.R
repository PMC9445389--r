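#' Pipeline run configuration
#'
#' Bundles every stage's settings for an end-to-end run. Two modes:
#' *ingest* (`input_dir` points at an existing fixture/dataset in the
#' external file formats) or *simulate* (`sim` is a [sim_config()]; a
#' fixture is generated under `out_dir/fixture` first).
#'
#' @param out_dir output directory for run artifacts.
#' @param input_dir dataset directory (ingest mode); `NULL` to simulate.
#' @param sim a [sim_config()] (simulate mode); `NULL` to ingest.
#' @param priors a [bird_priors()] for simulate mode.
#' @param max_age upper age (days, inclusive) of the analysis window
#'   (default 15: the first two weeks of life).
#' @param light_period analysis light period clock times.
#' @param gap_threshold_s group-gap silence threshold, seconds.
#' @param grid_cols,grid_rows,pen_w,pen_l antenna grid geometry used for
#'   ingesting logs (must match the recording pen).
#' @param min_days,min_pairs,entropy_m,entropy_r_factor,class_bounds,outlier_k
#'   descriptor settings, see [compute_descriptors()].
#' @param ent_exclude_rounds rounds whose entropy is set missing
#'   wholesale (systemic recording problems).
#' @param include_rounds rounds entering the ADG model (`NULL` = all;
#'   rows with missing descriptors drop out listwise regardless).
#' @param bootstrap_B,alpha,selection_criterion statistical settings.
#' @param seed seed for the statistical layer (bootstrap CIs).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, input_dir = NULL, sim = NULL,
                       priors = bird_priors(),
                       max_age = 15, light_period = c("07:00", "23:00"),
                       gap_threshold_s = 300,
                       grid_cols = 5, grid_rows = 6,
                       pen_w = 1.8, pen_l = 2.6,
                       min_days = 3, min_pairs = 3,
                       entropy_m = 2, entropy_r_factor = 0.2,
                       class_bounds = c(2, 4, 7), outlier_k = 4,
                       ent_exclude_rounds = integer(),
                       include_rounds = NULL,
                       bootstrap_B = 1000, alpha = 0.05,
                       selection_criterion = "F", seed = 1L) {
  if (is.null(input_dir) && is.null(sim))
    stop("either input_dir (ingest) or sim (simulate) must be given")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  stopifnot(max_age >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys map to [run_config()] arguments; an optional `sim`
#' block maps to [sim_config()] and `priors` to [bird_priors()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$priors)) raw$priors <- do.call(bird_priors, raw$priors)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> log ingest -> group-gap and
#' light-period filtering -> daily distances -> activity descriptors ->
#' growth -> statistics, with the filtering order: scripted bird
#' removals first, then row-wise ADG outlier removal, then cell-wise
#' descriptor outlier masking. Writes all result tables, a model
#' summary, and a manifest with the seed, a config hash and per-stage
#' bird counts.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of class `broileract_run` with elements
#'   `daily`, `descriptors`, `growth`, `merged`, `correlations`,
#'   `quartile_comparison`, `model`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  input_dir <- config$input_dir
  if (is.null(input_dir)) {
    input_dir <- file.path(out_dir, "fixture")
    generate_dataset(config$sim, config$priors, input_dir)
  }

  meta <- jsonlite::read_json(file.path(input_dir, "rounds.json"),
                              simplifyVector = TRUE)
  rounds <- meta$rounds
  removed_birds <- unlist(meta$removed_birds)
  grid <- build_antenna_grid(config$grid_cols, config$grid_rows,
                             config$pen_w, config$pen_l)

  win_path <- file.path(input_dir, "windows.csv")
  handling <- if (file.exists(win_path)) {
    w <- data.table::fread(win_path)
    if (nrow(w) > 0) {
      w[, `:=`(start = as.POSIXct(start, tz = "UTC",
                                  format = "%Y-%m-%dT%H:%M:%S"),
               end = as.POSIXct(end, tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%S"))]
    }
    w
  } else NULL

  daily_list <- list(); class_list <- list()
  for (r in rounds$round_id) {
    log_path <- file.path(input_dir, sprintf("rfid_round%d.csv", r))
    if (!file.exists(log_path)) stop("stage ingest: missing log ", log_path)
    rec <- read_rfid_log(log_path, grid = grid)
    gaps <- find_group_gaps(rec, threshold_s = config$gap_threshold_s)
    win <- gaps
    if (!is.null(handling) && nrow(handling) > 0) {
      hw <- handling[handling$round_id == r, c("start", "end", "reason")]
      if (nrow(hw) > 0) win <- rbind(win, as.data.frame(hw))
    }
    streams <- clip_to_light_period(rec, win, rounds[rounds$round_id == r, ],
                                    light_period = config$light_period)
    daily_list[[length(daily_list) + 1L]] <-
      daily_activity_series(streams, grid)
    cls <- streams$events[age_days <= config$max_age,
      minute_activity_classes(.SD,
        effective_seconds = streams$bird_days[
          bird_id == .BY$bird_id & age_days == .BY$age_days,
          effective_seconds],
        light_period = config$light_period,
        class_bounds = config$class_bounds),
      by = .(bird_id, age_days)]
    if (nrow(cls) > 0) class_list[[length(class_list) + 1L]] <- cls
  }
  daily <- rbindlist(daily_list)
  class_days <- if (length(class_list)) rbindlist(class_list) else NULL

  # growth from the weight table
  weights <- data.table::fread(file.path(input_dir, "weights.csv"))
  growth_all <- growth_records(weights, rounds)

  # Fig-style filtering order with per-stage bird counts
  n_initial <- length(unique(growth_all$bird_id))
  growth1 <- growth_all[!bird_id %in% removed_birds]
  daily <- daily[!bird_id %in% removed_birds]
  n_after_removals <- length(unique(growth1$bird_id))
  filt <- adg_outlier_filter(growth1, k = config$outlier_k)
  growth2 <- filt$kept
  n_after_adg <- length(unique(growth2$bird_id))
  daily <- daily[bird_id %in% growth2$bird_id]
  if (!is.null(class_days))
    class_days <- class_days[bird_id %in% growth2$bird_id]

  descriptors <- compute_descriptors(
    daily, class_days, max_age = config$max_age,
    min_days = config$min_days, min_pairs = config$min_pairs,
    entropy_m = config$entropy_m,
    entropy_r_factor = config$entropy_r_factor,
    ent_exclude_rounds = config$ent_exclude_rounds,
    outlier_k = config$outlier_k)

  growth3 <- adg_quartile_groups(growth2)
  merged <- merge(growth3, descriptors[, !"round_id"], by = "bird_id")
  setorder(merged, round_id, bird_id)

  correlations <- descriptor_adg_correlations(
    merged, B = config$bootstrap_B, seed = config$seed)
  quartiles <- compare_quartile_groups(merged)
  model <- tryCatch(
    fit_adg_model(merged, include_rounds = config$include_rounds,
                  alpha = config$alpha,
                  criterion = config$selection_criterion),
    error = function(e) {
      warning("stage model: ", conditionMessage(e))
      NULL
    })

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    stage_counts = data.frame(
      stage = c("initial", "after_scripted_removals", "after_adg_outliers"),
      n_birds = c(n_initial, n_after_removals, n_after_adg)),
    adg_outliers_removed = filt$removed$bird_id,
    descriptor_quartile_thresholds = c(low = attr(growth3, "q_low"),
                                       high = attr(growth3, "q_high"))
  )

  paths <- list(
    descriptors = file.path(out_dir, "descriptors.csv"),
    growth = file.path(out_dir, "growth.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    quartiles = file.path(out_dir, "quartile_comparison.csv"),
    model = file.path(out_dir, "model_summary.txt"),
    manifest = file.path(out_dir, "manifest.json")
  )
  fwrite(descriptors, paths$descriptors)
  fwrite(growth3, paths$growth)
  fwrite(as.data.table(correlations), paths$correlations)
  fwrite(as.data.table(quartiles), paths$quartiles)
  writeLines(if (is.null(model)) "model not fitted" else
    utils::capture.output(print(model)), paths$model)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(structure(list(
    daily = daily, descriptors = descriptors, growth = growth3,
    merged = merged, correlations = correlations,
    quartile_comparison = quartiles, model = model,
    manifest = manifest, paths = paths
  ), class = "broileract_run"))
}

# md5 of the canonical JSON serialisation of the analysis-relevant
# config (paths excluded, so runs into different directories hash alike)
config_hash <- function(config) {
  x <- config
  x$out_dir <- NULL
  x$input_dir <- NULL
  x$sim <- if (!is.null(x$sim)) unclass(x$sim)
  if (!is.null(x$sim)) {
    x$sim$dark_periods <- as.vector(x$sim$dark_periods)
    x$sim$round_start_dates <- as.character(x$sim$round_start_dates)
  }
  x$priors <- if (!is.null(x$priors)) unclass(x$priors)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}
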