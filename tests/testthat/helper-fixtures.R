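# In-code fixtures shared across the suite. Everything is generated; no
# files are shipped.

# toy trial table: g genotypes x e "environments" (year x management
# collapsed onto sowing_date levels when e = 2) x b blocks, one trait
toy_table <- function(values, genotypes, blocks = 1:3, year = 2020,
                      trait = "GY") {
  # values: array-like indexed [genotype, env, block]
  envs <- c("early", "late")
  rows <- expand.grid(genotype = genotypes, sowing_date = envs,
                      block = as.character(blocks),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$year <- year
  rows$nitrogen_level <- "220"
  rows$application_time <- "split"
  rows$trait <- trait
  rows$unit <- "t/ha"
  rows$value <- values[cbind(match(rows$genotype, genotypes),
                             match(rows$sowing_date, envs),
                             match(rows$block, as.character(blocks)))]
  trial_table(rows)
}

# full-design plot skeleton for one year (8 genotypes x 8 managements x
# 3 blocks); caller fills $value
plot_skeleton <- function(year = 2020, genotypes = paste0("G", 1:8),
                          trait = "GY") {
  sk <- expand.grid(block = as.character(1:3),
                    nitrogen_level = c("220", "176"),
                    application_time = c("split", "combined"),
                    sowing_date = c("early", "late"),
                    genotype = genotypes,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sk$year <- year
  sk$trait <- trait
  sk$unit <- "t/ha"
  sk
}

# independent oracle: interaction SS of a two-way mean table via the
# additive linear-model residual
interaction_ss_oracle <- function(m) {
  d <- data.frame(value = as.vector(m),
                  row = factor(rep(rownames(m), ncol(m))),
                  col = factor(rep(colnames(m), each = nrow(m))))
  sum(resid(lm(value ~ row + col, data = d))^2)
}

# constant-temperature weather series (tmin, tmax each day)
flat_weather <- function(n_days, tmin, tmax, start = "2020-03-01") {
  data.frame(date = seq(as.Date(start), by = "day", length.out = n_days),
             tmin_C = rep(tmin, n_days), tmax_C = rep(tmax, n_days))
}

# random two-way matrix with dimnames
rand_matrix <- function(nr, nc, mean = 5, sd = 2) {
  matrix(rnorm(nr * nc, mean, sd), nr, nc,
         dimnames = list(paste0("g", seq_len(nr)),
                         paste0("e", seq_len(nc))))
}
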