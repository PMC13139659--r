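# Trait-stability indices on an entity-by-environment mean matrix.
#
# Two complementary indices are implemented:
#   * the genotypic superiority measure P_i (Lin & Binns), the mean squared
#     distance of an entity from the best performer in each environment,
#     halved -- low P_i means stable AND high performing;
#   * Wricke's ecovalence W_i, the entity's share of the G-by-E interaction
#     sum of squares via double-centred residuals -- low W_i means
#     dynamically stable, irrespective of mean level.

as_two_way <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("two-way matrix must be numeric", call. = FALSE)
  if (anyNA(m)) stop("two-way matrix has missing cells", call. = FALSE)
  m
}

#' Genotypic superiority measure
#'
#' For entity i across n environments,
#' \deqn{P_i = \sum_j (X_{ij} - M_j)^2 / (2n)}
#' where \eqn{M_j} is the maximum observation in environment j. An entity
#' that achieves the environment maximum everywhere has \eqn{P_i = 0}.
#' Units are squared trait units.
#'
#' @param m Entity-by-environment matrix (e.g. from [env_means()]); no
#'   missing cells, at least one column.
#' @return Named numeric vector of P_i per entity (row).
#' @export
#' @examples
#' m <- rbind(a = c(1, 2), b = c(3, 4))
#' superiority(m)  # a: 2, b: 0
superiority <- function(m) {
  m <- as_two_way(m)
  if (ncol(m) < 1) stop("need at least one environment", call. = FALSE)
  mj <- apply(m, 2, max)
  rowSums(sweep(m, 2, mj)^2) / (2 * ncol(m))
}

#' Wricke's ecovalence
#'
#' For entity i,
#' \deqn{W_i = \sum_j (X_{ij} - \bar X_{i.} - \bar X_{.j} + \bar X_{..})^2,}
#' the squared double-centred residuals of the two-way table. Summed over
#' entities this equals the interaction sum of squares of the table.
#' Units are squared trait units.
#'
#' @param m Entity-by-environment matrix; no missing cells, at least two
#'   rows and two columns.
#' @return Named numeric vector of W_i per entity (row).
#' @export
#' @examples
#' ecovalence(rbind(a = c(1, 2), b = c(4, 3)))  # 0.5, 0.5
ecovalence <- function(m) {
  m <- as_two_way(m)
  if (nrow(m) < 2) {
    stop("ecovalence is degenerate with a single entity", call. = FALSE)
  }
  if (ncol(m) < 2) stop("need at least two environments", call. = FALSE)
  resid <- m - outer(rowMeans(m), colMeans(m), "+") + mean(m)
  rowSums(resid^2)
}

#' Stability table for one or more traits
#'
#' Aggregates a balanced trial table into entity-by-environment means per
#' trait and perspective, then computes both stability indices, the entity
#' mean and the stability ranks (rank 1 = most stable, i.e. lowest index;
#' ties get average ranks).
#'
#' @param table A `trial_table`, balanced for the requested traits.
#' @param traits Character vector of traits.
#' @param perspective `"genotype"` (entities are genotypes, environments
#'   are year-by-management combinations) or `"management"` (roles
#'   swapped).
#' @return A data.frame of class `stability_result` with columns `entity`,
#'   `trait`, `perspective`, `mean`, `superiority`, `ecovalence`,
#'   `n_environments`, `rank_superiority`, `rank_ecovalence`.
#' @export
stability_table <- function(table, traits,
                            perspective = c("genotype", "management")) {
  perspective <- match.arg(perspective)
  out <- lapply(traits, function(tr) {
    m <- env_means(table, tr, perspective)
    p <- superiority(m)
    w <- ecovalence(m)
    data.frame(
      entity = rownames(m),
      trait = tr,
      perspective = perspective,
      mean = rowMeans(m),
      superiority = p,
      ecovalence = w,
      n_environments = ncol(m),
      rank_superiority = rank(p, ties.method = "average"),
      rank_ecovalence = rank(w, ties.method = "average"),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  class(res) <- c("stability_result", "data.frame")
  res
}

# Null distribution of Spearman's rho over all permutations of 1..n,
# cached per n (feasible up to n = 8: 40320 permutations).
perm_rho_null <- local({
  cache <- list()
  all_perms <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- all_perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
      rest <- seq_len(n)[-k]
      cbind(k, matrix(rest[sub], nrow(sub)))
    }))
  }
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      p <- all_perms(n)
      ref <- seq_len(n)
      d2 <- rowSums((p - matrix(ref, nrow(p), n, byrow = TRUE))^2)
      cache[[key]] <<- 1 - 6 * d2 / (n^3 - n)
    }
    cache[[key]]
  }
})

spearman_test <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (method == "exact" && n <= 8 && !ties) {
    null <- perm_rho_null(n)
    p <- mean(abs(null) >= abs(rho) - 1e-12)
  } else {
    # two-sided t approximation on n - 2 df
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = p)
}

#' Spearman correlation matrix of stability ranks across traits
#'
#' Builds the trait-by-trait Spearman correlation of one stability index
#' across entities, to compare how entities rank in stability from trait to
#' trait. P-values are two-sided; with few entities (n <= 8) an exact
#' permutation p-value is available.
#'
#' @param results A `stability_result` covering several traits with the
#'   same entities (from [stability_table()]).
#' @param index `"superiority"` or `"ecovalence"`.
#' @param alpha Significance level for the mask (default 0.05).
#' @param method `"t"` for the t-distribution approximation, `"exact"` for
#'   the permutation null (n <= 8, no ties; falls back to t otherwise).
#' @return A list of class `rank_corr_matrix`: `rho`, `p` (symmetric
#'   matrices), `significant` (logical mask at `alpha`, diagonal `NA`),
#'   `alpha`, `method`, `n_entities`.
#' @export
rank_correlation_matrix <- function(results,
                                    index = c("superiority", "ecovalence"),
                                    alpha = 0.05,
                                    method = c("t", "exact")) {
  index <- match.arg(index)
  method <- match.arg(method)
  results <- as.data.frame(results)
  traits <- sort(unique(results$trait))
  entities <- sort(unique(results$entity))
  if (length(entities) < 3) {
    stop("need at least 3 entities for a rank correlation", call. = FALSE)
  }
  vals <- matrix(NA_real_, length(entities), length(traits),
                 dimnames = list(entities, traits))
  for (tr in traits) {
    sub <- results[results$trait == tr, , drop = FALSE]
    if (!setequal(sub$entity, entities)) {
      stop("trait '", tr, "' does not cover the same entities", call. = FALSE)
    }
    vals[sub$entity, tr] <- sub[[index]]
  }
  k <- length(traits)
  rho <- diag(1, k)
  p <- matrix(0, k, k)
  dimnames(rho) <- dimnames(p) <- list(traits, traits)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      st <- spearman_test(vals[, i], vals[, j], method)
      rho[i, j] <- rho[j, i] <- st$rho
      p[i, j] <- p[j, i] <- st$p
    }
  }
  sig <- p < alpha
  diag(sig) <- NA
  out <- list(rho = rho, p = p, significant = sig, alpha = alpha,
              method = method, index = index, n_entities = length(entities))
  class(out) <- "rank_corr_matrix"
  out
}

#' @export
print.rank_corr_matrix <- function(x, digits = 2, ...) {
  cat("Spearman rank-correlation matrix of", x$index, "across",
      ncol(x$rho), "traits (", x$n_entities, "entities, ",
      x$method, "p-values )\n")
  print(round(x$rho, digits))
  invisible(x)
}
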