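# Partition of the spike pool at maturity (BBCH87) into its three grain
# filling sources: the pre-anthesis reserve already in the spike at
# anthesis (BBCH61), net remobilization from the straw between anthesis
# and maturity, and post-anthesis assimilation. The same arithmetic
# applies to dry matter (t/ha), nitrogen and water-soluble carbohydrates
# (kg/ha): only the substance changes.

#' Net remobilization from straw between anthesis and maturity
#'
#' The straw pool's decline from anthesis to maturity, clipped at zero:
#' when the straw gains mass after anthesis (the straw acting as a sink),
#' remobilization is set to zero rather than negative.
#'
#' @param pool_61_straw Straw pool at anthesis (>= 0), vectorized.
#' @param pool_87_straw Straw pool at maturity (>= 0), same units.
#' @return `pmax(0, pool_61_straw - pool_87_straw)`.
#' @export
#' @examples
#' remobilized(10, 7)  # 3
#' remobilized(7, 10)  # 0: straw gained mass
remobilized <- function(pool_61_straw, pool_87_straw) {
  if (any(pool_61_straw < 0, na.rm = TRUE) ||
      any(pool_87_straw < 0, na.rm = TRUE)) {
    stop("pools must be non-negative", call. = FALSE)
  }
  pmax(0, pool_61_straw - pool_87_straw)
}

#' Partition the spike pool at maturity into its three sources
#'
#' Decomposes `pool_87_spike` as
#' pre-anthesis spike reserve (`pool_61_spike`) + net straw remobilization
#' (clipped at zero, see [remobilized()]) + post-anthesis assimilation
#' (the residual term, which may be negative under measurement noise and
#' is then flagged). The identity
#' `pre + remobilized + post == pool_87_spike` holds to machine precision
#' for every input. Fractions of the maturity spike pool are attached;
#' they are `NA` when `pool_87_spike` is zero.
#'
#' @param quartets A data.frame (or list) with numeric columns
#'   `pool_61_spike`, `pool_61_straw`, `pool_87_spike`, `pool_87_straw`,
#'   all non-negative, one row per observation. Extra columns (plot keys)
#'   are carried through.
#' @return A data.frame of class `partition_result` with the carried key
#'   columns plus `pre_anthesis_spike`, `remobilized_straw`,
#'   `post_anthesis`, `frac_pre`, `frac_remobilized`, `frac_post` and the
#'   logical `negative_post` flag.
#' @export
#' @examples
#' partition_spike(data.frame(pool_61_spike = 2, pool_61_straw = 10,
#'                            pool_87_spike = 12, pool_87_straw = 7))
partition_spike <- function(quartets) {
  q <- as.data.frame(quartets)
  need <- c("pool_61_spike", "pool_61_straw", "pool_87_spike", "pool_87_straw")
  missing_cols <- setdiff(need, names(q))
  if (length(missing_cols) > 0) {
    stop("missing pool column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in need) {
    if (any(q[[col]] < 0, na.rm = TRUE)) {
      stop("pools must be non-negative (", col, ")", call. = FALSE)
    }
  }
  pre <- q$pool_61_spike
  remob <- remobilized(q$pool_61_straw, q$pool_87_straw)
  post <- q$pool_87_spike - (pre + remob)

  total <- q$pool_87_spike
  frac_den <- ifelse(total > 0, total, NA_real_)
  out <- q
  out$pre_anthesis_spike <- pre
  out$remobilized_straw <- remob
  out$post_anthesis <- post
  out$frac_pre <- pre / frac_den
  out$frac_remobilized <- remob / frac_den
  out$frac_post <- post / frac_den
  out$negative_post <- post < 0
  class(out) <- c("partition_result", "data.frame")
  out
}

#' Mean source contributions per group
#'
#' Averages the per-observation contribution fractions of
#' [partition_spike()] within groups (e.g. per year, per genotype, or
#' overall). The mean of per-observation fractions is used, not the ratio
#' of pooled means.
#'
#' @param results A `partition_result`.
#' @param grouping Character vector of grouping column names in
#'   `results`, or `NULL` for one overall summary.
#' @return Data.frame with the grouping columns, `n`, and mean
#'   `frac_pre`, `frac_remobilized`, `frac_post`. Groups in which every
#'   fraction is missing yield `NA` with a warning.
#' @export
contribution_summary <- function(results, grouping = NULL) {
  res <- as.data.frame(results)
  if (nrow(res) == 0) stop("empty partition results", call. = FALSE)
  fcols <- c("frac_pre", "frac_remobilized", "frac_post")
  if (is.null(grouping)) {
    res$.all <- "overall"
    grouping_eff <- ".all"
  } else {
    missing_cols <- setdiff(grouping, names(res))
    if (length(missing_cols) > 0) {
      stop("unknown grouping column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    grouping_eff <- grouping
  }
  key <- interaction(res[grouping_eff], drop = TRUE, lex.order = TRUE)
  groups <- split(res, key)
  rows <- lapply(groups, function(g) {
    means <- vapply(fcols, function(col) {
      v <- g[[col]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    cbind(g[1, grouping_eff, drop = FALSE],
          data.frame(n = nrow(g), as.list(means)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(grouping)) out$.all <- NULL
  if (any(is.na(out[fcols]))) {
    warning("group(s) with all-missing fractions produced NA means")
  }
  out
}
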