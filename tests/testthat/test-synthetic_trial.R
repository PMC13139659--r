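test_that("weather generator honours profile, seed and tmax >= tmin", {
  w <- simulate_weather("2020-03-01", "2020-03-10", tmin_mean = 5,
                        tmax_mean = 15, amplitude = 0, noise_sd = 0,
                        precip_rate = 0, seed = 1)
  expect_equal(w$tmin_C, rep(5, 10))
  expect_equal(w$tmax_C, rep(15, 10))
  w1 <- simulate_weather("2019-10-01", "2020-07-31", seed = 4)
  w2 <- simulate_weather("2019-10-01", "2020-07-31", seed = 4)
  expect_identical(w1, w2)
  # order constraint under heavy noise, ~10^4 days
  wn <- simulate_weather("2000-01-01", "2027-05-18", noise_sd = 6, seed = 2)
  expect_gte(nrow(wn), 10000)
  expect_true(all(wn$tmax_C >= wn$tmin_C))
  expect_true(all(wn$precip_mm >= 0))
})

test_that("yield generator is exact in the noise-free additive case", {
  cfg <- sim_config(sensitivity = rep(1, 8), sigma_ge = rep(0, 8),
                    block_sd = 0, residual_sd = 0,
                    trait_params = within(yieldstab:::default_trait_params(),
                                          res_sd <- 0 * res_sd),
                    seed = 2)
  sim <- simulate_yield_components(cfg)
  gy <- sim$table[sim$table$trait == "GY", ]
  env <- paste(gy$year, gy$nitrogen_level, gy$application_time,
               gy$sowing_date, sep = "|")
  expect_equal(gy$value,
               unname(cfg$mu + cfg$genotype_effects[gy$genotype] +
                        sim$truth$env_index[env]))
  # downstream ecovalence of the additive table is numerically zero
  expect_lt(max(ecovalence(env_means(sim$table, "GY", "genotype"))), 1e-10)
})

test_that("yield generator is deterministic and validates its config", {
  cfg <- sim_config(seed = 8)
  s1 <- simulate_yield_components(cfg)
  s2 <- simulate_yield_components(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth$eta, s2$truth$eta)

  expect_error(sim_config(sigma_ge = c(rep(0.1, 7), -0.1)), "config error")
  bad_cor <- yieldstab:::default_trait_cor()
  bad_cor["GY", "GN"] <- bad_cor["GN", "GY"] <- 0.999
  bad_cor["GY", "TGW"] <- bad_cor["TGW", "GY"] <- 0.999
  bad_cor["GN", "TGW"] <- bad_cor["TGW", "GN"] <- -0.999
  expect_error(sim_config(trait_cor = bad_cor), "positive definite")
})

test_that("a quiet genotype beats a noisy one in ecovalence almost always", {
  tp <- yieldstab:::default_trait_params()[1, ]  # GY only, for speed
  tc <- matrix(1, 1, 1, dimnames = list("GY", "GY"))
  wins <- 0L
  for (s in 1:100) {
    cfg <- sim_config(genotypes = paste0("G", 1:4),
                      genotype_effects = rep(0, 4),
                      sensitivity = rep(1, 4),
                      sigma_ge = c(0, 0.1, 0.1, 0.6),
                      trait_params = tp, trait_cor = tc,
                      archetype = rep("PS1", 4), seed = s)
    w <- ecovalence(env_means(simulate_yield_components(cfg)$table,
                              "GY", "genotype"))
    if (w[["G1"]] < w[["G4"]]) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("per-trial ecovalence ranking tracks the configured sigma spread", {
  sig <- 0.15 * 4^((0:7) / 7)
  rhos <- vapply(1:10, function(s) {
    cfg <- sim_config(sensitivity = rep(1, 8), sigma_ge = sig, seed = s)
    w <- ecovalence(env_means(simulate_yield_components(cfg)$table,
                              "GY", "genotype"))
    cor(rank(w), rank(sig), method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.75)
  expect_true(all(rhos > 0.5))
})

test_that("canopy simulator evaluates the logistic and validates params", {
  w <- flat_weather(40, 5, 15)  # 10 degCd per day
  s <- simulate_canopy(tt50 = 170, k = 0.05, tt_anthesis = 100, w,
                       gca_max = 0.9)
  expect_equal(s$tt, c(100, 170, 240, 310, 380))
  expect_equal(s$gca[2], 0.9 / 2)       # at TT50 exactly half the asymptote
  expect_equal(s$gca[1], 0.9 / (1 + exp(0.05 * (100 - 170))))
  s_early <- simulate_canopy(tt50 = 5000, k = 0.05, tt_anthesis = 10, w)
  expect_true(all(s_early$gca > 0.999))  # far before TT50: near asymptote

  expect_error(simulate_canopy(170, -1, 100, w), "k must be > 0")
  expect_error(simulate_canopy(90, 0.05, 100, w), "exceed")

  # round trip through the fitting code
  w2 <- flat_weather(300, 5, 15)
  s2 <- simulate_canopy(tt50 = 2000, k = 0.012, tt_anthesis = 1400, w2)
  fit <- fit_senescence(s2[c("tt", "gca")])
  expect_equal(fit$tt50, 2000, tolerance = 1e-6)
})

test_that("source-sink draws obey archetypes and the partition identity", {
  # deterministic preset: PS2 straw loses WSC, PS1 gains
  d2 <- simulate_source_sink("PS2", n = 1, noise_cv = 0, seed = 1)
  wsc2 <- d2[d2$substance == "WSC", ]
  expect_lt(wsc2$pool_87_straw, wsc2$pool_61_straw)
  d1 <- simulate_source_sink("PS1", n = 1, noise_cv = 0, seed = 1)
  wsc1 <- d1[d1$substance == "WSC", ]
  expect_gt(wsc1$pool_87_straw, wsc1$pool_61_straw)

  # identity holds for every draw
  many <- simulate_source_sink("PS1", n = 500, seed = 3)
  p <- partition_spike(many)
  resid <- many$pool_87_spike -
    (p$pre_anthesis_spike + p$remobilized_straw + p$post_anthesis)
  expect_true(all(abs(resid) <=
                    .Machine$double.eps * pmax(many$pool_87_spike, 1)))

  # configured gain probability is respected (PS1, default 0.8)
  big <- simulate_source_sink("PS1", n = 1000, seed = 17)
  wsc <- big[big$substance == "WSC", ]
  gain_rate <- mean(wsc$pool_87_straw > wsc$pool_61_straw)
  expect_lt(abs(gain_rate - 0.8), 0.05)

  expect_identical(simulate_source_sink("PS2", n = 5, seed = 9),
                   simulate_source_sink("PS2", n = 5, seed = 9))
})

test_that("stage seed derivation separates the simulation streams", {
  seeds <- vapply(c("weather", "yield", "canopy", "source_sink", "pipeline"),
                  function(st) stage_seed(42, st), integer(1))
  expect_equal(length(unique(seeds)), 5)
  expect_identical(stage_seed(42, "yield"), stage_seed(42, "yield"))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
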