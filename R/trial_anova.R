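# Split-split-split-plot analysis of variance with expected-mean-square
# based F tests.
#
# The design nests four randomization strata below the (random) block:
# nitrogen on the main plot, application time on the split plot, sowing
# date on the split-split plot and genotype on the split-split-split plot.
# Each stratum has its own error term -- the pooled block-by-treatment
# interactions of that stratum -- and every fixed effect is tested against
# the error of the deepest stratum it touches, as dictated by the expected
# mean squares of the mixed model. With one observation per plot the
# residual of the deepest (genotype) stratum is the pooled block-by-
# genotype interaction sum of squares.

STRATUM_FACTORS <- c(nitrogen_level = 1L, application_time = 2L,
                     sowing_date = 3L, genotype = 4L)

active_strata <- function(spec) {
  lv <- list(nitrogen_level = spec$nitrogen_levels,
             application_time = spec$application_times,
             sowing_date = spec$sowing_dates,
             genotype = spec$genotypes)
  names(lv)[vapply(lv, length, 1L) >= 2]
}

stratum_error_labels <- function(active) {
  depths <- STRATUM_FACTORS[active]
  labs <- paste0("Error(block:", active, ")")
  labs[length(labs)] <- "Residual"
  setNames(labs, active)
}

#' Expected-mean-square denominator mapping for a nested split-plot design
#'
#' For every fixed-effect source (main effects and all interactions of the
#' active treatment factors) gives the error stratum whose mean square is
#' the F denominator: a source is tested against the error of the deepest
#' stratum among its factors, the deepest stratum's error being the
#' residual. With a single active stratum (no splits) every effect is
#' tested against the residual.
#'
#' @param spec A [design_spec()]; factors with a single level are
#'   inactive.
#' @return Data.frame with columns `source`, `stratum` (the deepest factor)
#'   and `denominator` (the error-stratum label), one row per source.
#' @export
ems_denominators <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  active <- active_strata(spec)
  if (length(active) == 0) {
    stop("design has no treatment factor with 2+ levels", call. = FALSE)
  }
  labs <- stratum_error_labels(active)
  subsets <- unlist(lapply(seq_along(active), function(k) {
    utils::combn(active, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(subsets, function(fs) {
    deepest <- fs[which.max(STRATUM_FACTORS[fs])]
    data.frame(source = paste(fs, collapse = ":"),
               stratum = deepest,
               denominator = labs[[deepest]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Fit the split-split-split-plot ANOVA for one trait and year
#'
#' Sequential sums of squares from the saturated block-by-treatment model
#' (exact on balanced data, where all terms are orthogonal), with F ratios
#' formed per [ems_denominators()]: each fixed source over the pooled
#' block-interaction mean square of its stratum. The ANOVA is per year;
#' pass `year` when the table spans several.
#'
#' @param table A `trial_table` with one observation per plot.
#' @param trait Trait to analyse.
#' @param year Year to analyse (required if the table has several).
#' @return Data.frame of class `anova_table`: `source`, `df`, `sumsq`,
#'   `meansq`, `f_value`, `p_value`, `denominator`. Error strata appear as
#'   their own rows with no F. Attributes: `trait`, `year`,
#'   `denominators` (per-stratum MS and df), `total_ss`.
#' @export
fit_split3 <- function(table, trait, year = NULL) {
  df <- as.data.frame(table)
  df <- df[df$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for trait '", trait, "'", call. = FALSE)
  if (is.null(year)) {
    yrs <- unique(df$year)
    if (length(yrs) > 1) {
      stop("table spans years ", paste(yrs, collapse = ", "),
           "; the ANOVA is per year -- pass `year`", call. = FALSE)
    }
    year <- yrs
  }
  df <- df[df$year == year, , drop = FALSE]
  if (nrow(df) == 0) stop("no rows for year ", year, call. = FALSE)

  fac_cols <- c("block", names(STRATUM_FACTORS))
  for (col in fac_cols) df[[col]] <- factor(df[[col]])
  active <- names(STRATUM_FACTORS)[
    vapply(df[names(STRATUM_FACTORS)], nlevels, 1L) >= 2]
  if (length(active) == 0) stop("no active treatment factor", call. = FALSE)

  counts <- table(df[c("block", active)])
  if (!all(counts == 1)) {
    stop("unbalanced data for trait '", trait, "', year ", year,
         ": run validate_design() to locate the deficient cells",
         call. = FALSE)
  }

  fml <- stats::as.formula(paste("value ~",
                                 paste(c("block", active), collapse = " * ")))
  # the block-by-treatment model is saturated by design (one observation
  # per plot); anova.lm warns about the perfect fit, which is expected
  at <- withCallingHandlers(
    anova(lm(fml, data = df)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  terms <- rownames(at)
  keep <- terms != "Residuals"
  terms <- terms[keep]
  tdf <- at$Df[keep]
  tss <- at$`Sum Sq`[keep]

  has_block <- vapply(terms, function(t) "block" %in% term_factors(t), TRUE)
  depth_of <- function(t) {
    fs <- setdiff(term_factors(t), "block")
    if (length(fs) == 0) 0L else max(STRATUM_FACTORS[fs])
  }
  depths <- vapply(terms, depth_of, 1L)

  labs <- stratum_error_labels(active)
  deepest_active <- max(STRATUM_FACTORS[active])
  # pool the block-interaction terms of each stratum into its error
  pool <- lapply(active, function(f) {
    d <- STRATUM_FACTORS[[f]]
    sel <- has_block & depths == d
    list(label = labs[[f]], df = sum(tdf[sel]), ss = sum(tss[sel]))
  })
  names(pool) <- active
  denom_for_depth <- function(d) {
    pool[[names(STRATUM_FACTORS)[STRATUM_FACTORS == d]]]
  }

  rows <- list()
  block_sel <- has_block & depths == 0L
  rows[[1]] <- data.frame(source = "block", df = sum(tdf[block_sel]),
                          sumsq = sum(tss[block_sel]),
                          f_value = NA_real_, p_value = NA_real_,
                          denominator = NA_character_,
                          stringsAsFactors = FALSE)
  for (f in active) {
    d <- STRATUM_FACTORS[[f]]
    err <- pool[[f]]
    fixed_sel <- which(!has_block & depths == d)
    for (i in fixed_sel) {
      ms <- tss[i] / tdf[i]
      ems <- err$ss / err$df
      rows[[length(rows) + 1]] <- data.frame(
        source = terms[i], df = tdf[i], sumsq = tss[i],
        f_value = ms / ems,
        p_value = pf(ms / ems, tdf[i], err$df, lower.tail = FALSE),
        denominator = err$label, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      source = err$label, df = err$df, sumsq = err$ss,
      f_value = NA_real_, p_value = NA_real_,
      denominator = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$meansq <- out$sumsq / out$df
  out <- out[c("source", "df", "sumsq", "meansq", "f_value", "p_value",
               "denominator")]
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  attr(out, "trait") <- trait
  attr(out, "year") <- year
  attr(out, "denominators") <- lapply(pool, function(p) {
    list(label = p$label, ms = p$ss / p$df, df = p$df)
  })
  attr(out, "total_ss") <- sum(at$`Sum Sq`)
  attr(out, "n_obs") <- nrow(df)
  out
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Split-plot ANOVA, trait", attr(x, "trait"), "year",
      attr(x, "year"), "\n")
  print.data.frame(
    data.frame(x[1], lapply(x[2:6], function(v) signif(v, 5)), x[7]),
    row.names = FALSE)
  invisible(x)
}

# Insert-and-absorb letter assignment (Piepho-style): start from one
# group holding all levels; every significant pair splits each group
# containing both; subset groups are absorbed.
insert_absorb <- function(levels_ordered, sig_pairs) {
  cols <- list(levels_ordered)
  for (p in sig_pairs) {
    i <- p[1]; j <- p[2]
    new_cols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, i), setdiff(col, j)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop groups contained in another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by their best-ranked member, letter them a, b, c, ...
  first_pos <- vapply(cols, function(col) {
    min(match(col, levels_ordered))
  }, 1L)
  cols <- cols[order(first_pos)]
  letters_of <- setNames(rep("", length(levels_ordered)), levels_ordered)
  for (k in seq_along(cols)) {
    for (lv in cols[[k]]) {
      letters_of[lv] <- paste0(letters_of[lv], letters[k])
    }
  }
  letters_of
}

#' Compact letter display for a factor of the split-plot ANOVA
#'
#' Pairwise comparisons of the factor's level means use the factor's EMS
#' denominator mean square and degrees of freedom (an LSD test at `alpha`;
#' Bonferroni adjustment optional). Levels that share a letter are not
#' significantly different.
#'
#' @param anova An `anova_table` from [fit_split3()].
#' @param table The trial table the ANOVA was fit on.
#' @param factor_name One of the treatment factor columns, e.g.
#'   `"genotype"`.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (LSD) or `"bonferroni"`.
#' @return Object of class `letter_display`: data.frame `level`, `mean`,
#'   `letters`, plus attributes `alpha` and `p_matrix`.
#' @export
cld_letters <- function(anova, table, factor_name, alpha = 0.05,
                        adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(anova, "anova_table"))
  if (!factor_name %in% names(STRATUM_FACTORS)) {
    stop("unknown factor '", factor_name, "'", call. = FALSE)
  }
  dens <- attr(anova, "denominators")
  if (!factor_name %in% names(dens)) {
    stop("factor '", factor_name, "' was not tested in this ANOVA",
         call. = FALSE)
  }
  df <- as.data.frame(table)
  df <- df[df$trait == attr(anova, "trait") &
             df$year == attr(anova, "year"), , drop = FALSE]
  means <- tapply(df$value, df[[factor_name]], mean)
  r <- tapply(df$value, df[[factor_name]], length)
  if (length(unique(r)) != 1) {
    stop("unequal replication per level; refusing LSD comparison",
         call. = FALSE)
  }
  r <- r[[1]]
  err <- dens[[factor_name]]
  sed <- sqrt(2 * err$ms / r)

  lv <- names(sort(means, decreasing = TRUE))
  k <- length(lv)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  n_pairs <- k * (k - 1) / 2
  sig_pairs <- list()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      tval <- abs(means[[lv[a]]] - means[[lv[b]]]) / sed
      p <- 2 * pt(-tval, df = err$df)
      if (adjust == "bonferroni") p <- min(1, p * n_pairs)
      pmat[a, b] <- pmat[b, a] <- p
      if (p < alpha) sig_pairs[[length(sig_pairs) + 1]] <- c(lv[a], lv[b])
    }
  }
  lets <- insert_absorb(lv, sig_pairs)
  out <- data.frame(level = lv, mean = as.numeric(means[lv]),
                    letters = unname(lets[lv]), stringsAsFactors = FALSE)
  class(out) <- c("letter_display", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "p_matrix") <- pmat
  attr(out, "factor") <- factor_name
  out
}
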