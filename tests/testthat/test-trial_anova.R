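full_spec <- design_spec(genotypes = paste0("G", 1:8), years = 2020)

test_that("EMS denominator mapping follows the nested strata", {
  map <- ems_denominators(full_spec)
  # each fixed source has exactly one denominator
  expect_equal(anyDuplicated(map$source), 0)
  expect_equal(nrow(map), 2^4 - 1)
  den <- setNames(map$denominator, map$source)
  expect_equal(unname(den["nitrogen_level"]),
               "Error(block:nitrogen_level)")
  expect_equal(unname(den["application_time"]),
               "Error(block:application_time)")
  expect_equal(unname(den["nitrogen_level:application_time"]),
               "Error(block:application_time)")
  expect_equal(unname(den["sowing_date"]), "Error(block:sowing_date)")
  expect_equal(unname(den["nitrogen_level:application_time:sowing_date"]),
               "Error(block:sowing_date)")
  expect_equal(unname(den["genotype"]), "Residual")
  expect_true(all(den[grepl("genotype", names(den))] == "Residual"))

  # single-stratum design: everything against the residual
  solo <- design_spec(genotypes = paste0("G", 1:4), years = 2020,
                      nitrogen_levels = "220", application_times = "split",
                      sowing_dates = "early")
  map2 <- ems_denominators(solo)
  expect_equal(map2$denominator, "Residual")
})

test_that("fit_split3 agrees with the aov error-stratum oracle", {
  set.seed(14)
  sk <- plot_skeleton()
  sk$value <- 7 + 0.4 * (sk$nitrogen_level == "220") +
    0.3 * (sk$genotype %in% c("G1", "G2")) + rnorm(nrow(sk), 0, 0.3)
  at <- fit_split3(trial_table(sk), "GY")

  d <- sk
  for (col in c("block", "nitrogen_level", "application_time",
                "sowing_date", "genotype")) d[[col]] <- factor(d[[col]])
  oracle <- summary(aov(value ~ nitrogen_level * application_time *
                          sowing_date * genotype +
                          Error(block / nitrogen_level / application_time /
                                  sowing_date), data = d))
  # flatten the aov strata into a named table
  orows <- do.call(rbind, lapply(oracle, function(s) {
    tab <- s[[1]]
    data.frame(source = trimws(rownames(tab)), df = tab$Df,
               sumsq = tab$`Sum Sq`, f = tab$`F value`, p = tab$`Pr(>F)`,
               stringsAsFactors = FALSE)
  }))
  for (src in c("nitrogen_level", "application_time", "sowing_date",
                "genotype", "nitrogen_level:application_time",
                "nitrogen_level:sowing_date:genotype")) {
    mine <- at[at$source == src, ]
    ref <- orows[orows$source == src, ]
    expect_equal(mine$sumsq, ref$sumsq, tolerance = 1e-9)
    expect_equal(mine$f_value, ref$f, tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p, tolerance = 1e-9)
  }
  # pooled error strata agree with aov residuals
  for (err in c("Error(block:nitrogen_level)",
                "Error(block:application_time)",
                "Error(block:sowing_date)", "Residual")) {
    mine <- at[at$source == err, ]
    ref <- orows[orows$source == "Residuals", ]
    expect_true(any(abs(ref$sumsq - mine$sumsq) < 1e-9 &
                      ref$df == mine$df))
  }
})

test_that("the SS decomposition is exact and order-invariant", {
  set.seed(15)
  sk <- plot_skeleton()
  sk$value <- rnorm(nrow(sk), 7, 0.5)
  at <- fit_split3(trial_table(sk), "GY")
  expect_equal(sum(at$sumsq), attr(at, "total_ss"), tolerance = 1e-9)
  expect_equal(sum(at$df), nrow(sk) - 1)
  # balanced orthogonality: shuffling the rows changes nothing
  at2 <- fit_split3(trial_table(sk[sample(nrow(sk)), ]), "GY")
  expect_equal(at2$sumsq, at$sumsq, tolerance = 1e-9)
})

test_that("a large injected genotype effect is detected", {
  set.seed(16)
  sk <- plot_skeleton()
  sk$value <- 7 + 2 * (sk$genotype %in% paste0("G", 1:4)) +
    rnorm(nrow(sk), 0, 0.2)
  at <- fit_split3(trial_table(sk), "GY")
  expect_lt(at$p_value[at$source == "genotype"], 1e-6)
})

test_that("unbalanced tables are rejected with guidance", {
  sk <- plot_skeleton()
  sk$value <- rnorm(nrow(sk), 7)
  expect_error(fit_split3(trial_table(sk[-5, ]), "GY"), "validate_design")
  # multiple years need an explicit year
  sk2 <- rbind(sk, transform(sk, year = 2021))
  expect_error(fit_split3(trial_table(sk2), "GY"), "per year")
})

test_that("compact letters separate means consistently with the LSD tests", {
  set.seed(17)
  sk <- plot_skeleton(genotypes = c("A", "B", "C"))
  eff <- c(A = 0, B = 0.02, C = 3)   # A ~ B, both far from C
  sk$value <- 7 + eff[sk$genotype] + rnorm(nrow(sk), 0, 0.05)
  at <- fit_split3(trial_table(sk), "GY")
  cl <- cld_letters(at, trial_table(sk), "genotype")
  lets <- setNames(cl$letters, cl$level)
  expect_equal(unname(lets["C"]), "a")       # highest mean gets "a"
  expect_identical(lets[["A"]], lets[["B"]]) # A and B share a letter
  expect_false(lets[["C"]] == lets[["A"]])

  # consistency: sharing a letter <=> pairwise p >= alpha, random configs
  for (s in 1:5) {
    set.seed(100 + s)
    sk$value <- 7 + rnorm(3, 0, 0.5)[match(sk$genotype, c("A", "B", "C"))] +
      rnorm(nrow(sk), 0, 0.4)
    at <- fit_split3(trial_table(sk), "GY")
    cl <- cld_letters(at, trial_table(sk), "genotype")
    pm <- attr(cl, "p_matrix")
    lets <- setNames(strsplit(cl$letters, ""), cl$level)
    for (a in cl$level) for (b in cl$level) {
      if (a == b) next
      shared <- length(intersect(lets[[a]], lets[[b]])) > 0
      expect_identical(shared, pm[a, b] >= attr(cl, "alpha"))
    }
  }
  expect_error(cld_letters(at, trial_table(sk), "flavour"),
               "unknown factor")
})
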