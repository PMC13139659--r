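# Scaled-PCA phenotypic space over entity x trait summaries, projection
# of new entities, and per-group linear slope screening (e.g. straw WSC
# concentration at maturity against green canopy duration per genotype
# and year).

#' Principal component analysis with unit scaling
#'
#' Centers every trait and scales it to unit SD, then eigen-decomposes the
#' resulting correlation structure. Loading signs are fixed by convention:
#' the largest-magnitude element of every loading vector is positive, so
#' the output is deterministic across platforms.
#'
#' @param x Numeric matrix or data.frame, entities in rows, traits in
#'   columns; no missing values, at least 2 traits.
#' @return Object of class `pheno_space`: `loadings` (traits x PCs),
#'   `scores` (entities x PCs), `var_explained` (fractions summing to 1
#'   over the returned PCs), `center`, `scale`, `traits`.
#' @export
pca_scaled <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("trait matrix must be numeric", call. = FALSE)
  if (ncol(m) < 2) stop("need at least 2 traits", call. = FALSE)
  if (anyNA(m)) stop("trait matrix has missing values", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance trait(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, TRUE)
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  out <- list(
    loadings = pc$rotation,
    scores = pc$x,
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center,
    scale = pc$scale,
    traits = colnames(m)
  )
  class(out) <- "pheno_space"
  out
}

#' @export
print.pheno_space <- function(x, ...) {
  ve <- round(100 * x$var_explained, 1)
  cat("Phenotypic space over", length(x$traits), "traits;",
      "variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}

quadrant_of <- function(pc1, pc2) {
  # Cartesian convention, counterclockwise from (+, +)
  ifelse(pc1 >= 0 & pc2 >= 0, "I",
         ifelse(pc1 < 0 & pc2 >= 0, "II",
                ifelse(pc1 < 0 & pc2 < 0, "III", "IV")))
}

#' Project entities onto a fitted phenotypic space
#'
#' Applies the stored centering/scaling and multiplies onto the loadings.
#' Quadrant labels (PC1/PC2 sign pattern, Roman numerals counterclockwise
#' from +,+) are attached when at least two PCs exist.
#'
#' @param space A `pheno_space`.
#' @param rows Entity x trait matrix/data.frame with exactly the fitted
#'   traits.
#' @return Data.frame of PC scores with a `quadrant` column.
#' @export
project_phenospace <- function(space, rows) {
  stopifnot(inherits(space, "pheno_space"))
  m <- as.matrix(rows)
  if (is.null(colnames(m)) || !setequal(colnames(m), space$traits)) {
    stop("trait mismatch: projection needs exactly the fitted traits (",
         paste(space$traits, collapse = ", "), ")", call. = FALSE)
  }
  m <- m[, space$traits, drop = FALSE]
  z <- sweep(sweep(m, 2, space$center), 2, space$scale, "/")
  sc <- z %*% space$loadings
  out <- as.data.frame(sc)
  if (ncol(sc) >= 2) out$quadrant <- quadrant_of(sc[, 1], sc[, 2])
  out
}

#' Screen trait-versus-trait regressions per group
#'
#' For each group (e.g. genotype x year), regresses the y-trait on the
#' x-trait by ordinary least squares over the group's points -- by default
#' the means per management combination, so with the full design each
#' group contributes 8 equally weighted points -- and flags groups whose
#' slope differs from zero at `alpha` (two-sided t test).
#'
#' @param table A `trial_table` containing both traits.
#' @param x_trait,y_trait Trait names.
#' @param group_by Grouping columns (default genotype and year).
#' @param point_by Columns defining one point within a group (default the
#'   management factors; block replicates are averaged per point).
#' @param alpha Significance level for the flag.
#' @return Data.frame of class `slope_result`: grouping columns, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `significant`. Groups with
#'   fewer than 3 points or degenerate x variance are skipped with a
#'   warning.
#' @export
slope_screen <- function(table, x_trait, y_trait,
                         group_by = c("genotype", "year"),
                         point_by = c("nitrogen_level", "application_time",
                                      "sowing_date"),
                         alpha = 0.05) {
  df <- as.data.frame(table)
  pick <- function(tr) {
    sub <- df[df$trait == tr, , drop = FALSE]
    if (nrow(sub) == 0) stop("no rows for trait '", tr, "'", call. = FALSE)
    aggregate(sub["value"], by = sub[c(group_by, point_by)], FUN = mean)
  }
  x <- pick(x_trait)
  y <- pick(y_trait)
  names(x)[names(x) == "value"] <- ".x"
  names(y)[names(y) == "value"] <- ".y"
  xy <- merge(x, y, by = c(group_by, point_by))
  key <- interaction(xy[group_by], drop = TRUE, lex.order = TRUE)
  groups <- split(xy, key)
  skipped <- character(0)
  rows <- lapply(groups, function(g) {
    id <- g[1, group_by, drop = FALSE]
    label <- paste(unlist(id), collapse = "/")
    if (nrow(g) < 3 || var(g$.x) == 0) {
      skipped <<- c(skipped, label)
      return(NULL)
    }
    fit <- lm(.y ~ .x, data = g)
    sm <- summary(fit)
    cbind(id, data.frame(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = sm$coefficients[2, 4],
      n = nrow(g),
      stringsAsFactors = FALSE
    ))
  })
  if (length(skipped) > 0) {
    warning("skipped group(s) with < 3 points or constant x: ",
            paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no group had enough points", call. = FALSE)
  rownames(out) <- NULL
  out$significant <- out$p_value < alpha
  class(out) <- c("slope_result", "data.frame")
  attr(out, "x_trait") <- x_trait
  attr(out, "y_trait") <- y_trait
  attr(out, "alpha") <- alpha
  out
}
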