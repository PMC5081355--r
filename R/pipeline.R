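# Pipeline orchestration: simulate -> cohort -> panel -> run-algorithm ->
# validate -> summarize, as composable stages over a single structured
# config. Every stage writes delimited tables plus a JSON manifest so reruns
# with the same config and seed reproduce outputs exactly.

#' Default pipeline configuration
#'
#' @return a list understood by [run_pipeline()]: `seed`, `out`, `codesets`
#'   (`"default"` or a YAML path), `algorithms` (built-in names or spec
#'   paths), `reference_population` (`"mm-dx"` or `"all"`), and optional
#'   `generator` overrides (`n` per stratum).
#' @export
pipeline_config <- function() {
  list(seed = 20160224L, out = "mmclaims-run", codesets = "default",
       algorithms = c("baseline", "algorithm2"),
       reference_population = "mm-dx", generator = list())
}

load_pipeline_config <- function(path) {
  cfg <- pipeline_config()
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg[names(user)] <- user
  cfg
}

resolve_codesets <- function(x) {
  if (is.null(x) || identical(x, "default")) return(default_codesets())
  if (inherits(x, "codeset_config")) return(x)
  load_codesets(x)
}

resolve_generator_config <- function(cfg) {
  gc <- default_config_from_tables()
  ov <- cfg$generator %||% list()
  if (!is.null(ov$n)) {
    n <- unlist(ov$n)
    gc$n[names(n)] <- as.integer(n)
  }
  for (nm in intersect(names(ov), c("enrollment_days", "chemo_cycle_days"))) {
    gc[[nm]] <- ov[[nm]]
  }
  gc
}

write_stage <- function(df, out_dir, file) {
  out <- df
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
  }
  write.csv(out, file.path(out_dir, file), row.names = FALSE, na = "")
}

write_manifest <- function(out_dir, command, cfg, inputs = character(0),
                           outputs = character(0)) {
  manifest <- list(
    command = command,
    config_hash = digest_config(cfg),
    seed = cfg$seed,
    inputs = inputs, outputs = outputs,
    tool_version = as.character(packageVersion("mmclaims")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# Cheap structural hash (no external digest dependency).
digest_config <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% .Machine$integer.max)
}

#' Run the full pipeline
#'
#' Simulates a calibrated population, builds the gold standard and the
#' development/validation split, constructs the index panel with features,
#' flags every patient under each configured algorithm, computes performance
#' metrics per algorithm and sample half, and writes the descriptive
#' summaries. All outputs are delimited tables under `out`; reruns with the
#' same config are identical.
#'
#' @param config a config list (see [pipeline_config()]) or a path to a
#'   YAML/JSON config file.
#' @param out optional output directory override.
#' @param seed optional seed override.
#' @return invisibly, a list with the in-memory stage outputs (`bundle`,
#'   `labels`, `panel`, `features`, `flags`, `metrics`, `table1`, `table2`).
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL, seed = NULL) {
  cfg <- if (is.character(config)) load_pipeline_config(config) else config
  if (!is.null(out)) cfg$out <- out
  if (!is.null(seed)) cfg$seed <- seed
  codesets <- resolve_codesets(cfg$codesets)
  out_dir <- cfg$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # simulate
  gen <- generate_population(resolve_generator_config(cfg), seed = cfg$seed,
                             codesets = codesets)
  write_bundle(gen$bundle, file.path(out_dir, "claims"))
  write_stage(gen$labels, out_dir, "labels_truth.csv")

  # cohort: re-derive the gold standard from the claims/EMR tables
  labels <- build_gold_standard(gen$bundle, codesets)
  assignment <- split_sample(labels, seed = cfg$seed)
  labels <- merge(labels, assignment, by = "patient_id", sort = TRUE)
  write_stage(labels, out_dir, "labels.csv")

  # panel + features
  panel <- build_panel(gen$bundle, codesets)
  events <- precompute_events(gen$bundle, codesets)
  features <- extract_features(panel, gen$bundle, codesets, events = events)
  write_stage(features, out_dir, "panel.csv")

  # run algorithms
  flags_list <- lapply(cfg$algorithms, function(a) {
    flag_population(resolve_algorithm(a), gen$bundle, codesets,
                    panel = panel, events = events)
  })
  flags <- do.call(rbind, flags_list)
  write_stage(flags, out_dir, "flags.csv")

  # validate per algorithm x sample half
  ref <- if (identical(cfg$reference_population, "all")) {
    gen$bundle$persons$patient_id
  } else {
    mm_reference_population(gen$bundle, codesets)
  }
  metrics <- list()
  for (fl in flags_list) {
    for (half in c("development", "validation")) {
      lab <- labels[labels$sample == half, , drop = FALSE]
      m <- performance_metrics(fl, lab, reference_population = ref)
      metrics[[length(metrics) + 1L]] <- cbind(data.frame(sample = half), m)
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[, c("algorithm_id", setdiff(names(metrics), "algorithm_id"))]
  write_stage(metrics, out_dir, "metrics.csv")

  # summarize
  table1 <- annualized_rates(labels, gen$bundle, codesets)
  strata <- assign_diagnosis_strata(features, labels, gen$bundle, codesets)
  table2 <- window_summaries(features, strata)
  write_stage(table1, out_dir, "table1.csv")
  write_stage(table2, out_dir, "table2.csv")

  write_manifest(out_dir, "pipeline", cfg,
                 outputs = c("claims", "labels.csv", "panel.csv", "flags.csv",
                             "metrics.csv", "table1.csv", "table2.csv"))
  invisible(list(bundle = gen$bundle, labels = labels, panel = panel,
                 features = features, flags = flags, metrics = metrics,
                 table1 = table1, table2 = table2))
}

parse_cli_args <- function(args) {
  out <- list(command = NULL, options = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        out$options[[key]] <- TRUE; i <- i + 1L
      } else {
        out$options[[key]] <- args[[i + 1L]]; i <- i + 2L
      }
    } else {
      if (is.null(out$command)) out$command <- a else {
        stop("unexpected argument '", a, "'", call. = FALSE)
      }
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `cohort`, `panel`, `run-algorithm`, `validate`,
#' `summarize`, `pipeline`. Global flags: `--config`, `--seed`, `--out`;
#' stage flags: `--in` (a directory written by `simulate`), `--algorithm`
#' (built-in name or spec path), `--reference-population` (`mm-dx`|`all`).
#' An executable wrapper ships in `inst/cli/mmclaims.R`.
#'
#' @param args character vector (defaults to `commandArgs(trailingOnly =
#'   TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
mm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(args)
  cmd <- parsed$command %||% "pipeline"
  opt <- parsed$options
  cfg <- if (!is.null(opt$config)) load_pipeline_config(opt$config) else pipeline_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out <- opt$out
  if (!is.null(opt$algorithm)) cfg$algorithms <- opt$algorithm
  if (!is.null(opt$`reference-population`)) {
    cfg$reference_population <- opt$`reference-population`
  }
  codesets <- resolve_codesets(cfg$codesets)
  out_dir <- cfg$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  load_input <- function() {
    dir_in <- opt$`in` %||% out_dir
    list(bundle = read_bundle(file.path(dir_in, "claims")),
         dir = dir_in)
  }
  read_labels <- function(dir_in) {
    lab <- read.csv(file.path(dir_in, "labels.csv"), colClasses = "character")
    lab$anchor_date <- as.Date(lab$anchor_date)
    lab$observation_start <- as.Date(lab$observation_start)
    lab$observation_end <- as.Date(lab$observation_end)
    lab$incident <- as.logical(lab$incident)
    lab
  }

  status <- tryCatch({
    switch(cmd,
      simulate = {
        gen <- generate_population(resolve_generator_config(cfg),
                                   seed = cfg$seed, codesets = codesets)
        write_bundle(gen$bundle, file.path(out_dir, "claims"))
        write_stage(gen$labels, out_dir, "labels_truth.csv")
        write_manifest(out_dir, "simulate", cfg, outputs = "claims")
      },
      cohort = {
        x <- load_input()
        labels <- build_gold_standard(x$bundle, codesets)
        labels <- merge(labels, split_sample(labels, cfg$seed),
                        by = "patient_id", sort = TRUE)
        write_stage(labels, out_dir, "labels.csv")
        write_manifest(out_dir, "cohort", cfg, inputs = x$dir,
                       outputs = "labels.csv")
      },
      panel = {
        x <- load_input()
        panel <- build_panel(x$bundle, codesets)
        features <- extract_features(panel, x$bundle, codesets)
        write_stage(features, out_dir, "panel.csv")
        write_manifest(out_dir, "panel", cfg, inputs = x$dir,
                       outputs = "panel.csv")
      },
      `run-algorithm` = {
        x <- load_input()
        flags <- do.call(rbind, lapply(cfg$algorithms, function(a) {
          flag_population(resolve_algorithm(a), x$bundle, codesets)
        }))
        write_stage(flags, out_dir, "flags.csv")
        write_manifest(out_dir, "run-algorithm", cfg, inputs = x$dir,
                       outputs = "flags.csv")
      },
      validate = {
        x <- load_input()
        labels <- read_labels(x$dir)
        flags <- read.csv(file.path(x$dir, "flags.csv"),
                          colClasses = "character")
        flags$flagged <- as.logical(flags$flagged)
        ref <- if (identical(cfg$reference_population, "all")) {
          x$bundle$persons$patient_id
        } else mm_reference_population(x$bundle, codesets)
        metrics <- do.call(rbind, lapply(split(flags, flags$algorithm_id),
          function(fl) {
            do.call(rbind, lapply(c("development", "validation"), function(h) {
              cbind(data.frame(sample = h),
                    performance_metrics(fl, labels[labels$sample == h, ], ref))
            }))
          }))
        write_stage(metrics, out_dir, "metrics.csv")
        write_manifest(out_dir, "validate", cfg, inputs = x$dir,
                       outputs = "metrics.csv")
      },
      summarize = {
        x <- load_input()
        labels <- read_labels(x$dir)
        panel <- build_panel(x$bundle, codesets)
        features <- extract_features(panel, x$bundle, codesets)
        write_stage(annualized_rates(labels, x$bundle, codesets),
                    out_dir, "table1.csv")
        strata <- assign_diagnosis_strata(features, labels, x$bundle, codesets)
        write_stage(window_summaries(features, strata), out_dir, "table2.csv")
        write_manifest(out_dir, "summarize", cfg, inputs = x$dir,
                       outputs = c("table1.csv", "table2.csv"))
      },
      pipeline = run_pipeline(cfg),
      stop("unknown command '", cmd, "'", call. = FALSE))
    0L
  }, error = function(e) {
    message("error [", cmd, "]: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
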