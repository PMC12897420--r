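#' Run the full ecohydrological-memory pipeline
#'
#' Orchestrates the analysis end to end: obtain rainfall, an abundance
#' table and a trait matrix (either synthesised from a scenario block or
#' loaded from CSV paths), simulate discharge, tabulate antecedent
#' descriptors, compute diversity, run the Spearman screen and the
#' [flow_memory()] fit, and write every stage as CSV plus a JSON run
#' report. Deterministic for a fixed seed.
#'
#' @param config A configuration list, or the path of a YAML/JSON file
#'   holding one. Recognised blocks: `catchment` (arguments of
#'   [catchment_config()]), `windows`, `seed`, `output_dir`, and either
#'   `scenario` (arguments of [memory_scenario()] plus optional `n_years`)
#'   or `inputs` (paths `rainfall`, `events`, `abundance`, `traits`).
#' @return Invisibly, a list with the stage outputs and the report
#'   (also written to `output_dir`).
#' @examples
#' \donttest{
#' out <- run_pipeline(list(scenario = list(n_events = 12), seed = 7,
#'                          output_dir = tempfile("hydromem")))
#' out$report$best_window
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  windows <- cfg$windows
  catchment <- do.call(catchment_config, cfg$catchment)

  if (!is.null(cfg$scenario)) {
    n_years <- cfg$scenario$n_years %||% 10
    cfg$scenario$n_years <- NULL
    scenario <- do.call(memory_scenario, cfg$scenario)
    st <- synth_memory_study(scenario, n_years = n_years,
                             catchment = catchment, windows = windows,
                             seed = cfg$seed)
    rain <- st$rainfall; q <- st$discharge; events <- st$event_dates
    desc <- st$descriptors; tm <- st$traits; ab <- st$abundance
    div <- st$diversity
  } else {
    io <- cfg$inputs
    rain <- read_rainfall(io$rainfall)
    events <- as.Date(utils::read.csv(io$events)$event_date)
    ab <- read_abundance(io$abundance)
    tm <- read_traits(io$traits)
    q <- simulate_discharge(rain, catchment)
    desc <- descriptor_table(q, events, windows)
    div <- diversity_table(ab, tm)
  }

  sp <- spearman_screen(desc, div)
  fm <- flow_memory(div, desc, windows = windows, ar1 = cfg$ar1 %||% TRUE)

  # doubles are written at full (round-tripping) precision so downstream
  # stages recomputed from the CSVs reproduce in-memory results exactly
  wr <- function(x, f) {
    num <- vapply(x, is.double, logical(1))
    x[num] <- lapply(x[num], function(v) sprintf("%.17g", v))
    utils::write.csv(x, file.path(cfg$output_dir, f), row.names = FALSE,
                     quote = FALSE)
  }
  wr(data.frame(date = rain$date, precip_mm = rain$precip_mm), "rainfall.csv")
  wr(q, "discharge.csv")
  wr(desc, "descriptors.csv")
  wr(div, "diversity.csv")
  wr(sp, "spearman_matrix.csv")
  wr(fm$comparison, "window_comparison.csv")
  wr(fm$importance, "importance_table.csv")

  report <- list(
    best_window = fm$best_window,
    excluded_responses = as.list(fm$excluded),
    window_summary = fm$window_summary,
    n_events = length(events),
    seed = cfg$seed,
    config_hash = config_hash(cfg)
  )
  jsonlite::write_json(report, file.path(cfg$output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("pipeline complete: ", length(events), " events, best window ",
          fm$best_window, " days -> ", cfg$output_dir)
  invisible(list(rainfall = rain, discharge = q, event_dates = events,
                 descriptors = desc, abundance = ab, traits = tm,
                 diversity = div, spearman = sp, fit = fm, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config$windows <- as.integer(config$windows %||% c(3L, 6L, 9L))
  if (length(config$windows) == 0 || any(config$windows < 2)) {
    stop("windows must be a non-empty set of lengths >= 2")
  }
  config$seed <- config$seed %||% 1L
  config$catchment <- config$catchment %||% list()
  config$output_dir <- config$output_dir %||% "hydromem_out"
  if (is.null(config$scenario) == is.null(config$inputs)) {
    stop("config must contain exactly one of 'scenario' or 'inputs'")
  }
  config
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[sort(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

#' Validate pipeline input files
#'
#' Schema and consistency checks over the CSV inputs of [run_pipeline()]:
#' rainfall column names, non-negativity and calendar-day continuity;
#' sufficient antecedent history for every event; abundance counts
#' non-negative integers with at least one individual per event; trait
#' scores within \[0, 3\]. Issues are reported, not raised.
#'
#' @param paths Named list with any of `rainfall`, `events`, `abundance`,
#'   `traits`; `max_window` is the largest antecedent window to check
#'   history for (default 9).
#' @param max_window Largest antecedent window, days.
#' @return Data frame `file`, `issue` (zero rows when everything is clean).
#' @export
validate_inputs <- function(paths, max_window = 9) {
  issues <- list()
  add <- function(file, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(file = file, issue = issue)
  }
  rain <- NULL
  if (!is.null(paths$rainfall)) {
    rain <- tryCatch(utils::read.csv(paths$rainfall), error = function(e) NULL)
    if (is.null(rain)) {
      add(paths$rainfall, "unreadable file")
    } else if (!all(c("date", "precip_mm") %in% names(rain))) {
      add(paths$rainfall, "missing columns date, precip_mm")
      rain <- NULL
    } else {
      if (anyNA(rain$precip_mm)) add(paths$rainfall, "missing depths")
      if (any(rain$precip_mm < 0, na.rm = TRUE)) {
        add(paths$rainfall, "negative depths")
      }
      dd <- diff(as.integer(as.Date(rain$date)))
      if (any(dd != 1L)) {
        add(paths$rainfall, sprintf("calendar gap after %s",
                                    rain$date[which(dd != 1L)[1]]))
      }
    }
  }
  if (!is.null(paths$events)) {
    ev <- tryCatch(utils::read.csv(paths$events), error = function(e) NULL)
    if (is.null(ev) || !"event_date" %in% names(ev)) {
      add(paths$events, "missing column event_date")
    } else if (!is.null(rain)) {
      first <- min(as.Date(rain$date))
      short <- as.Date(ev$event_date) - max_window < first
      if (any(short)) {
        add(paths$events, sprintf("%d event(s) lack %d days of history",
                                  sum(short), max_window))
      }
    }
  }
  if (!is.null(paths$abundance)) {
    ab <- tryCatch(utils::read.csv(paths$abundance), error = function(e) NULL)
    if (is.null(ab) || !all(c("event", "family", "count") %in% names(ab))) {
      add(paths$abundance, "missing columns event, family, count")
    } else {
      if (any(ab$count < 0)) add(paths$abundance, "negative counts")
      if (any(ab$count != round(ab$count))) {
        add(paths$abundance, "non-integer counts")
      }
      tot <- tapply(ab$count, ab$event, sum)
      if (any(tot <= 0)) add(paths$abundance, "event with zero individuals")
    }
  }
  if (!is.null(paths$traits)) {
    tr <- tryCatch(utils::read.csv(paths$traits), error = function(e) NULL)
    if (is.null(tr) ||
        !all(c("family", "trait", "category", "score") %in% names(tr))) {
      add(paths$traits, "missing columns family, trait, category, score")
    } else if (any(tr$score < 0 | tr$score > 3)) {
      add(paths$traits, "affinity scores outside [0, 3]")
    }
  }
  if (length(issues) == 0) {
    return(data.frame(file = character(), issue = character()))
  }
  do.call(rbind, issues)
}

#' Read a rainfall CSV (`date,precip_mm`)
#' @param path File path.
#' @return Validated rainfall data frame.
#' @export
read_rainfall <- function(path) {
  rain <- utils::read.csv(path)
  rain$date <- as.Date(rain$date)
  validate_rainfall(rain)
  rain
}

#' Read a long abundance CSV (`event,family,count`) into a counts matrix
#' @param path File path.
#' @return Integer matrix, families x events.
#' @export
read_abundance <- function(path) {
  ab <- utils::read.csv(path)
  stopifnot(all(c("event", "family", "count") %in% names(ab)))
  tab <- tapply(ab$count, list(ab$family, ab$event), sum, default = 0)
  storage.mode(tab) <- "integer"
  tab
}

#' Read a long trait CSV (`family,trait,category,score`) into a matrix
#'
#' Categories are aligned to the schema's column order; combinations absent
#' from the file score 0.
#'
#' @param path File path.
#' @param schema Trait schema data frame.
#' @return Numeric matrix, families x categories.
#' @export
read_traits <- function(path, schema = default_trait_schema()) {
  tr <- utils::read.csv(path)
  stopifnot(all(c("family", "trait", "category", "score") %in% names(tr)))
  fams <- sort(unique(tr$family))
  labs <- schema_labels(schema)
  tm <- matrix(0, length(fams), length(labs),
               dimnames = list(fams, labs))
  key <- paste(tr$trait, tr$category, sep = "|")
  unknown <- !key %in% labs
  if (any(unknown)) {
    stop("trait/category not in schema: ",
         paste(unique(key[unknown]), collapse = ", "))
  }
  tm[cbind(match(tr$family, fams), match(key, labs))] <- tr$score
  validate_trait_matrix(tm, schema)
  tm
}

#' Write a counts matrix as a long abundance CSV
#' @param abundance Families x events counts matrix.
#' @param path Output path.
#' @export
write_abundance <- function(abundance, path) {
  long <- data.frame(event = rep(colnames(abundance), each = nrow(abundance)),
                     family = rep(rownames(abundance), ncol(abundance)),
                     count = as.integer(abundance))
  utils::write.csv(long, path, row.names = FALSE)
}
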