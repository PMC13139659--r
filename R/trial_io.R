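# Data model and I/O for long-format plot-level trial tables.
#
# A trial table is tidy/long: one row per (year, block, nitrogen_level,
# application_time, sowing_date, genotype, trait) with a numeric value.
# Stability indices and the split-plot ANOVA both start from this table.

KEY_COLUMNS <- c("year", "block", "nitrogen_level", "application_time",
                 "sowing_date", "genotype", "trait")

#' Describe a split-split-split-plot trial design
#'
#' The design has four nested randomization strata below the block:
#' nitrogen level on the main plot, fertilizer application time on the
#' split plot, sowing date on the split-split plot and genotype on the
#' split-split-split plot. Blocks are the replicates.
#'
#' @param genotypes Character vector of genotype (cultivar) labels.
#' @param years Integer vector of trial years.
#' @param blocks Vector of block labels (default three replicates).
#' @param nitrogen_levels Total nitrogen levels, kg N per ha, as labels.
#'   Defaults to the optimal/sub-optimal pair 220 and 176.
#' @param application_times Heading-fertilizer application strategies.
#' @param sowing_dates Sowing-date treatments.
#'
#' @return An object of class `design_spec`: a list with one element per
#'   factor plus `replicates`, the expected number of plots per treatment
#'   cell (the number of blocks).
#' @export
#' @examples
#' design_spec(genotypes = c("A", "B"), years = 2020:2021)
design_spec <- function(genotypes,
                        years,
                        blocks = 1:3,
                        nitrogen_levels = c("220", "176"),
                        application_times = c("split", "combined"),
                        sowing_dates = c("early", "late")) {
  stopifnot(length(genotypes) >= 1, length(years) >= 1, length(blocks) >= 1)
  spec <- list(
    years = as.integer(years),
    blocks = as.character(blocks),
    nitrogen_levels = as.character(nitrogen_levels),
    application_times = as.character(application_times),
    sowing_dates = as.character(sowing_dates),
    genotypes = as.character(genotypes),
    replicates = length(blocks)
  )
  class(spec) <- "design_spec"
  spec
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Split-split-split-plot design spec\n")
  cat("  years:            ", paste(x$years, collapse = ", "), "\n")
  cat("  blocks:           ", paste(x$blocks, collapse = ", "), "\n")
  cat("  nitrogen (main):  ", paste(x$nitrogen_levels, collapse = ", "), "\n")
  cat("  application:      ", paste(x$application_times, collapse = ", "), "\n")
  cat("  sowing date:      ", paste(x$sowing_dates, collapse = ", "), "\n")
  cat("  genotypes:        ", paste(x$genotypes, collapse = ", "), "\n")
  invisible(x)
}

#' Construct and validate a trial table
#'
#' @param df A data.frame with the key columns `year`, `block`,
#'   `nitrogen_level`, `application_time`, `sowing_date`, `genotype`,
#'   `trait` plus numeric `value` and optional `unit`.
#' @param spec Optional [design_spec()]; when given, factor levels outside
#'   the design are rejected.
#'
#' @return The validated data.frame with class `trial_table`.
#' @export
trial_table <- function(df, spec = NULL) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(c(KEY_COLUMNS, "value"), names(df))
  if (length(missing_cols) > 0) {
    stop("trial table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!("unit" %in% names(df))) df$unit <- ""
  df$year <- as.integer(df$year)
  for (col in setdiff(KEY_COLUMNS, "year")) df[[col]] <- as.character(df[[col]])
  df$value <- as.numeric(df$value)

  key_na <- !complete.cases(df[KEY_COLUMNS])
  if (any(key_na)) {
    stop("trial table integrity error: NA in key columns on ",
         sum(key_na), " row(s)", call. = FALSE)
  }
  key <- do.call(paste, c(df[KEY_COLUMNS], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), KEY_COLUMNS, drop = FALSE][1, ]
    stop("trial table integrity error: duplicated key, first duplicate: ",
         paste(names(dup), unlist(dup), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  # units must be consistent within a trait
  units_by_trait <- tapply(df$unit, df$trait, function(u) length(unique(u)))
  if (any(units_by_trait > 1)) {
    stop("trial table integrity error: inconsistent units for trait(s) ",
         paste(names(units_by_trait)[units_by_trait > 1], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(spec)) {
    check_levels <- function(col, levels) {
      bad <- setdiff(unique(df[[col]]), as.character(levels))
      if (length(bad) > 0) {
        stop("trial table schema error: unknown ", col, " level(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
    check_levels("year", spec$years)
    check_levels("block", spec$blocks)
    check_levels("nitrogen_level", spec$nitrogen_levels)
    check_levels("application_time", spec$application_times)
    check_levels("sowing_date", spec$sowing_dates)
    check_levels("genotype", spec$genotypes)
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read a trial table from CSV
#'
#' CSV dialect: comma separated, UTF-8, `.` decimal, mandatory header.
#'
#' @param path Path to the CSV file.
#' @param spec Optional [design_spec()] used to reject unknown factor levels.
#' @return A `trial_table`.
#' @export
read_trial_table <- function(path, spec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  trial_table(df, spec)
}

#' Write a trial table to CSV
#'
#' Values are written as decimal text with 10 significant digits so that a
#' write/read/write cycle is byte-stable.
#'
#' @param table A `trial_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  out <- as.data.frame(table)
  out$value <- sprintf("%.10g", out$value)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check replicate balance of a trial table against its design
#'
#' Counts the plots present in every (year, nitrogen, application time,
#' sowing date, genotype, trait) treatment cell and compares with the
#' expected replicate number (the block count). Report-only: an unbalanced
#' table is not an error here, but downstream aggregation refuses it.
#'
#' @param table A `trial_table` (may be empty).
#' @param spec A [design_spec()].
#' @param traits Traits to check; defaults to the traits present in the
#'   table (for an empty table, checking is against a single unnamed trait).
#' @return A `balance_report`: list with `balanced` flag, `expected`
#'   replicate count, and `deficient`, a data.frame of cells whose plot
#'   count differs from the expected count.
#' @export
validate_design <- function(table, spec, traits = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  table <- as.data.frame(table)
  if (is.null(traits)) {
    traits <- if (nrow(table) > 0) sort(unique(table$trait)) else "(none)"
  }
  cells <- expand.grid(
    year = spec$years,
    nitrogen_level = spec$nitrogen_levels,
    application_time = spec$application_times,
    sowing_date = spec$sowing_dates,
    genotype = spec$genotypes,
    trait = traits,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cell_key <- function(d) {
    paste(d$year, d$nitrogen_level, d$application_time, d$sowing_date,
          d$genotype, d$trait, sep = "\r")
  }
  counts <- if (nrow(table) > 0) table(cell_key(table)) else table(character(0))
  n <- as.integer(counts[cell_key(cells)])
  n[is.na(n)] <- 0L
  cells$count <- n
  cells$expected <- spec$replicates
  deficient <- cells[cells$count != cells$expected, , drop = FALSE]
  rownames(deficient) <- NULL
  report <- list(balanced = nrow(deficient) == 0,
                 expected = spec$replicates,
                 n_cells = nrow(cells),
                 deficient = deficient)
  class(report) <- "balance_report"
  report
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report: ", if (x$balanced) "balanced" else "NOT balanced",
      " (", x$n_cells - nrow(x$deficient), "/", x$n_cells,
      " cells complete, expected ", x$expected, " replicate(s)/cell)\n",
      sep = "")
  if (!x$balanced) {
    cat("Deficient cells (first 10):\n")
    print(head(x$deficient, 10))
  }
  invisible(x)
}

management_label <- function(df) {
  paste(df$nitrogen_level, df$application_time, df$sowing_date, sep = ".")
}

#' Aggregate plot observations into an entity-by-environment matrix
#'
#' Block replicates are averaged; stability indices are computed on these
#' means, one value per entity and environment. Under the genotype
#' perspective the entities are genotypes and an environment is one year
#' by management combination; under the management perspective the entities
#' are the management combinations (nitrogen.applicationTime.sowingDate) and
#' an environment is one year by genotype combination.
#'
#' @param table A `trial_table`.
#' @param trait Trait to aggregate.
#' @param perspective `"genotype"` or `"management"`.
#' @return A numeric matrix of class `two_way_matrix` (entities in rows,
#'   environments in columns) with attributes `perspective` and `trait`.
#' @export
env_means <- function(table, trait, perspective = c("genotype", "management")) {
  perspective <- match.arg(perspective)
  df <- as.data.frame(table)
  df <- df[df$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for trait '", trait, "'", call. = FALSE)
  df$management <- management_label(df)

  if (perspective == "genotype") {
    df$entity <- df$genotype
    df$env <- paste(df$year, df$management, sep = "|")
  } else {
    df$entity <- df$management
    df$env <- paste(df$year, df$genotype, sep = "|")
  }
  # average over blocks within each entity x environment cell; every cell
  # must carry the same replicate count (stability needs a balanced table)
  cnt <- aggregate(value ~ entity + env, data = df, FUN = length)
  if (length(unique(cnt$value)) > 1) {
    short <- cnt[cnt$value < max(cnt$value), ][1, ]
    stop("missing cell: entity '", short$entity, "' in environment '",
         short$env, "' has ", short$value, " replicate(s), others have ",
         max(cnt$value), call. = FALSE)
  }
  agg <- aggregate(value ~ entity + env, data = df, FUN = mean)
  entities <- sort(unique(df$entity))
  envs <- sort(unique(df$env))
  m <- matrix(NA_real_, length(entities), length(envs),
              dimnames = list(entities, envs))
  m[cbind(match(agg$entity, entities), match(agg$env, envs))] <- agg$value
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing cell: entity '", entities[idx[1]], "' in environment '",
         envs[idx[2]], "' has no observation for trait '", trait, "'",
         call. = FALSE)
  }
  structure(m, class = c("two_way_matrix", "matrix", "array"),
            perspective = perspective, trait = trait)
}
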