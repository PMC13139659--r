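# Pipeline orchestration: simulate (or read) -> validate -> phenology ->
# partition -> stability -> ANOVA -> phenospace, from one configuration,
# with per-stage statuses and a hashed output manifest. A stage failure
# stops its dependents but independent stages still run.

#' Build a pipeline run configuration
#'
#' Exactly one of `sim` (simulator settings) or `input` (paths to existing
#' CSVs) must be given.
#'
#' @param outdir Output directory (created if absent).
#' @param sim `NULL`, or a [sim_config()] / list of arguments for one.
#' @param input `NULL`, or a list with `trial_csv` (required) and optional
#'   `pools_csv`, `canopy_csv`; the canopy CSV needs columns `genotype`,
#'   `year`, `tt`, `gca`, `tt_anthesis`.
#' @param traits Traits for the stability and phenospace stages.
#' @param perspectives Stability perspectives to compute.
#' @param slope_traits Length-2 character vector (x, y) for the per-group
#'   slope screen.
#' @param alpha Significance level used throughout.
#' @param seed Root seed; overrides the seed inside `sim`.
#' @param years Optional year subset applied to the trial table.
#' @return Object of class `run_config`.
#' @export
run_config <- function(outdir, sim = NULL, input = NULL,
                       traits = c("GY", "GN", "TGW", "SN", "GpS",
                                  "GL", "GW"),
                       perspectives = c("genotype", "management"),
                       slope_traits = c("TGW", "GY"),
                       alpha = 0.05, seed = 1L, years = NULL) {
  if (is.null(sim) == is.null(input)) {
    stop("exactly one of `sim` and `input` must be given", call. = FALSE)
  }
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    sim <- do.call(sim_config, sim)
  }
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  if (!is.null(input) && is.null(input$trial_csv)) {
    stop("input mode needs `trial_csv`", call. = FALSE)
  }
  stopifnot(length(slope_traits) == 2)
  cfg <- list(outdir = outdir, sim = sim, input = input, traits = traits,
              perspectives = match.arg(perspectives,
                                       c("genotype", "management"),
                                       several.ok = TRUE),
              slope_traits = slope_traits,
              alpha = alpha, seed = as.integer(seed), years = years)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `sim` is a
#' mapping of [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(seed)) y$seed <- seed
  do.call(run_config, y)
}

write_stage_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order. Each stage's
#' outputs are written as CSV under `outdir`; a stage error is recorded
#' and its dependents are skipped, while independent stages complete.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: `stages` (stage, status,
#'   message), `balance` (the design balance report), `manifest` (file,
#'   md5), `seed`, `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  status <- data.frame(stage = character(0), status = character(0),
                       message = character(0), stringsAsFactors = FALSE)
  ok <- function(stage) {
    s <- status$status[status$stage == stage]
    length(s) == 1 && s == "ok"
  }
  note <- function(stage, st, msg = "") {
    status <<- rbind(status, data.frame(stage = stage, status = st,
                                        message = msg,
                                        stringsAsFactors = FALSE))
  }
  run_stage <- function(stage, deps, fun) {
    if (!all(vapply(deps, ok, TRUE))) {
      note(stage, "skipped", paste("dependency failed:",
                                   paste(deps[!vapply(deps, ok, TRUE)],
                                         collapse = ", ")))
      return(invisible(NULL))
    }
    tryCatch({
      fun()
      note(stage, "ok")
    }, error = function(e) note(stage, "error", conditionMessage(e)))
  }

  env <- new.env()
  balance <- NULL

  run_stage("data", character(0), function() {
    if (!is.null(config$sim)) {
      sim <- config$sim
      ycr <- simulate_yield_components(sim)
      env$table <- ycr$table
      env$truth <- ycr$truth
      env$spec <- sim_design_spec(sim)
      # weather + canopy series per year and genotype
      wseed <- stage_seed(sim$seed, "weather")
      cseed <- stage_seed(sim$seed, "canopy")
      sseed <- stage_seed(sim$seed, "source_sink")
      canopy_rows <- list()
      for (yi in seq_along(sim$years)) {
        yr <- sim$years[yi]
        w <- simulate_weather(paste0(yr - 1, "-10-15"),
                              paste0(yr, "-07-31"),
                              seed = wseed + yi)
        written <<- c(written,
                      write_stage_csv(w, config$outdir,
                                      paste0("weather_", yr, ".csv")))
        for (gi in seq_along(sim$genotypes)) {
          cp <- sim$canopy[gi, ]
          cs <- simulate_canopy(cp$tt50, cp$k, cp$tt_anthesis, w,
                                gca_max = cp$gca_max, noise_sd = 0.02,
                                seed = cseed + 100 * yi + gi)
          cs$genotype <- cp$genotype
          cs$year <- yr
          cs$tt_anthesis <- cp$tt_anthesis
          canopy_rows[[length(canopy_rows) + 1]] <- cs
        }
      }
      env$canopy <- do.call(rbind, canopy_rows)
      pools <- list()
      for (gi in seq_along(sim$genotypes)) {
        g <- sim$genotypes[gi]
        for (yi in seq_along(sim$years)) {
          p <- simulate_source_sink(sim$archetype[[g]], n = 8,
                                    seed = sseed + 100 * gi + yi)
          p$genotype <- g
          p$year <- sim$years[yi]
          pools[[length(pools) + 1]] <- p
        }
      }
      env$pools <- do.call(rbind, pools)
      written <<- c(written,
                    write_stage_csv(env$canopy, config$outdir, "canopy.csv"),
                    write_stage_csv(env$pools, config$outdir, "pools.csv"))
    } else {
      env$table <- read_trial_table(config$input$trial_csv)
      lev <- function(col) sort(unique(env$table[[col]]))
      env$spec <- design_spec(
        genotypes = lev("genotype"), years = lev("year"),
        blocks = lev("block"), nitrogen_levels = lev("nitrogen_level"),
        application_times = lev("application_time"),
        sowing_dates = lev("sowing_date"))
      if (!is.null(config$input$canopy_csv)) {
        env$canopy <- read.csv(config$input$canopy_csv,
                               stringsAsFactors = FALSE)
      }
      if (!is.null(config$input$pools_csv)) {
        env$pools <- read.csv(config$input$pools_csv,
                              stringsAsFactors = FALSE)
      }
    }
    if (!is.null(config$years)) {
      env$table <- env$table[env$table$year %in% config$years, ]
      class(env$table) <- c("trial_table", "data.frame")
      env$spec$years <- as.integer(config$years)
    }
    written <<- c(written,
                  write_stage_csv(as.data.frame(env$table), config$outdir,
                                  "trial.csv"))
  })

  run_stage("validate", "data", function() {
    balance <<- validate_design(env$table, env$spec)
    written <<- c(written,
                  write_stage_csv(
                    data.frame(balanced = balance$balanced,
                               expected = balance$expected,
                               deficient_cells = nrow(balance$deficient)),
                    config$outdir, "balance.csv"))
  })

  run_stage("phenology", "data", function() {
    if (is.null(env$canopy)) stop("no canopy series available")
    key <- interaction(env$canopy$genotype, env$canopy$year, drop = TRUE)
    rows <- lapply(split(env$canopy, key), function(s) {
      fit <- fit_senescence(s[c("tt", "gca")])
      data.frame(genotype = s$genotype[1], year = s$year[1],
                 gca_max = fit$gca_max, tt50 = fit$tt50, k = fit$k,
                 sse = fit$sse,
                 tt_anthesis = s$tt_anthesis[1],
                 gcd = green_canopy_duration(fit, s$tt_anthesis[1]),
                 stringsAsFactors = FALSE)
    })
    env$gcd <- do.call(rbind, rows)
    rownames(env$gcd) <- NULL
    written <<- c(written,
                  write_stage_csv(env$gcd, config$outdir, "gcd.csv"))
  })

  run_stage("partition", "data", function() {
    if (is.null(env$pools)) stop("no pool table available")
    part <- partition_spike(env$pools)
    env$partition <- part
    contrib <- contribution_summary(part, "substance")
    env$contributions <- contrib
    written <<- c(written,
                  write_stage_csv(part, config$outdir, "partition.csv"),
                  write_stage_csv(contrib, config$outdir,
                                  "contributions.csv"))
  })

  run_stage("stability", c("data", "validate"), function() {
    stab <- do.call(rbind, lapply(config$perspectives, function(p) {
      stability_table(env$table, config$traits, p)
    }))
    env$stability <- stab
    written <<- c(written,
                  write_stage_csv(stab, config$outdir, "stability.csv"))
    for (p in config$perspectives) {
      rc <- rank_correlation_matrix(stab[stab$perspective == p, ],
                                    index = "superiority",
                                    alpha = config$alpha)
      written <<- c(written,
                    write_stage_csv(as.data.frame(rc$rho), config$outdir,
                                    paste0("rankcorr_", p, ".csv")))
    }
  })

  run_stage("anova", c("data", "validate"), function() {
    for (yr in env$spec$years) {
      at <- fit_split3(env$table, config$traits[1], year = yr)
      written <<- c(written,
                    write_stage_csv(as.data.frame(at), config$outdir,
                                    paste0("anova_", yr, ".csv")))
      cl <- cld_letters(at, env$table, "genotype", alpha = config$alpha)
      written <<- c(written,
                    write_stage_csv(as.data.frame(cl), config$outdir,
                                    paste0("letters_", yr, ".csv")))
    }
  })

  run_stage("phenospace", c("data", "validate"), function() {
    df <- as.data.frame(env$table)
    df <- df[df$trait %in% config$traits, ]
    df$entity <- paste(df$genotype, df$year, sep = "|")
    agg <- aggregate(value ~ entity + trait, df, mean)
    m <- matrix(NA_real_,
                length(unique(agg$entity)), length(config$traits),
                dimnames = list(sort(unique(agg$entity)), config$traits))
    m[cbind(agg$entity, agg$trait)] <- agg$value
    space <- pca_scaled(m)
    env$space <- space
    scores <- project_phenospace(space, m)
    written <<- c(written,
                  write_stage_csv(
                    data.frame(trait = rownames(space$loadings),
                               space$loadings),
                    config$outdir, "pca_loadings.csv"),
                  write_stage_csv(
                    data.frame(entity = rownames(m), scores),
                    config$outdir, "pca_scores.csv"),
                  write_stage_csv(
                    data.frame(pc = seq_along(space$var_explained),
                               var_explained = space$var_explained),
                    config$outdir, "pca_variance.csv"))
    sl <- slope_screen(env$table, config$slope_traits[1],
                       config$slope_traits[2], alpha = config$alpha)
    env$slopes <- sl
    written <<- c(written,
                  write_stage_csv(as.data.frame(sl), config$outdir,
                                  "slopes.csv"))
  })

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  report <- list(stages = status, balance = balance, manifest = manifest,
                 seed = config$seed, outdir = config$outdir,
                 results = env)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ", outdir ", x$outdir, ")\n", sep = "")
  print.data.frame(x$stages, row.names = FALSE)
  cat(nrow(x$manifest), "file(s) written\n")
  invisible(x)
}

#' Did every pipeline stage succeed?
#' @param report A `run_report`.
#' @return TRUE iff all stages report "ok".
#' @export
pipeline_ok <- function(report) {
  all(report$stages$status == "ok")
}
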