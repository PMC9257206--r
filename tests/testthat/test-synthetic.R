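test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 123)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
  cfg2 <- sim_config(seed = 124)
  expect_false(identical(
    simulate_phenology(cfg)$first_flower_day,
    simulate_phenology(cfg2)$first_flower_day
  ))
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(), class = "ri_input_error")
  expect_error(
    sim_config(seed = 1, foraging = list(
      n_bouts = 10, length_mean = 3, kappa = 1.2, abundance = 0.5
    )),
    class = "ri_input_error"
  )
  bad_cr <- sim_config(seed = 1)$crosses
  bad_cr$embryo_intra <- c(0.5, 0.5, 0.5, -0.5)
  expect_error(sim_config(seed = 1, crosses = bad_cr),
    class = "ri_input_error"
  )
})

test_that("simulated phenology matches its generating windows", {
  # zero variance: every individual shares one window, RI in closed form
  cfg <- sim_config(
    seed = 2,
    phenology = list(
      n = c(10, 10), start_mean = c(100, 114), start_sd = c(0, 0),
      duration_mean = c(30, 30), duration_sd = c(0, 0)
    )
  )
  rec <- simulate_phenology(cfg)
  out <- phenology_ri_pair(rec, "A", "B")
  # windows 100..129 and 114..143 share 16 of 30 days
  expect_equal(out$S, c(16 / 30, 16 / 30))
  expect_equal(out$ri_pheno, c(14 / 30, 14 / 30))
  # n = 0 gives an empty table and downstream empty-input errors
  cfg0 <- sim_config(seed = 3, phenology = list(
    n = c(0, 0), start_mean = c(100, 100), start_sd = c(1, 1),
    duration_mean = c(10, 10), duration_sd = c(1, 1)
  ))
  rec0 <- simulate_phenology(cfg0)
  expect_equal(nrow(rec0), 0)
  expect_error(build_window(rec0, "A"), class = "ri_input_error")
})

test_that("noisy simulated schedules track the analytic overlap", {
  # with tight start SDs the species windows approximate the generating
  # intervals; computed S should sit within ~1 day discretisation of the
  # analytic interval overlap expanded by the observed start spread
  cfg <- sim_config(
    seed = 4,
    phenology = list(
      n = c(30, 30), start_mean = c(200, 214), start_sd = c(1, 1),
      duration_mean = c(30, 30), duration_sd = c(0, 0)
    )
  )
  rec <- simulate_phenology(cfg)
  wa <- build_window(rec, "A")
  wb <- build_window(rec, "B")
  ov <- overlap_proportions(wa, wb)
  analytic_S <- length(intersect(
    min(wa$days):max(wa$days),
    min(wb$days):max(wb$days)
  )) / length(min(wa$days):max(wa$days))
  expect_lt(abs(ov$S - analytic_S), 2 / length(wa$days))
})

test_that("perfect constancy forages without interspecific transitions", {
  cfg <- sim_config(seed = 7, foraging = list(
    n_bouts = 60, length_mean = 4, kappa = 1, abundance = 0.5
  ))
  bouts <- simulate_bouts(cfg)
  tab <- count_transitions(bouts, species = c("A", "B"))
  expect_equal(tab["A", "B"] + tab["B", "A"], 0L)
  expect_identical(ethological_ri(tab, "A"), 1)
  ci <- vapply(bouts, bout_constancy, numeric(1), species = c("A", "B"))
  expect_true(all(ci[!is.na(ci)] == 1))
})

test_that("abundance-random foraging gives RI centred on zero", {
  ri <- vapply(1:500, function(i) {
    cfg <- sim_config(seed = 1000 + i, foraging = list(
      n_bouts = 20, length_mean = 4, kappa = 0, abundance = 0.5
    ))
    tab <- count_transitions(simulate_bouts(cfg), species = c("A", "B"))
    tryCatch(ethological_ri(tab, "A"), ri_undefined_error = function(e) NA_real_)
  }, numeric(1))
  ri <- ri[!is.na(ri)]
  mc_se <- sd(ri) / sqrt(length(ri))
  expect_lt(abs(mean(ri)), 3 * mc_se)
})

test_that("simulated bout transition totals equal a brute-force recount", {
  cfg <- sim_config(seed = 8, foraging = list(
    n_bouts = 50, length_mean = 3, kappa = 0.9, abundance = 0.5
  ))
  bouts <- simulate_bouts(cfg)
  tab <- count_transitions(bouts, species = c("A", "B"))
  expect_equal(
    sum(tab),
    sum(vapply(bouts, function(b) length(b$visits) - 1L, integer(1)))
  )
})

test_that("simulated crosses respect invariants and recover their parameters", {
  cfg <- sim_config(seed = 9, crosses = list(
    n_pistils = 40, n_flowers = 60, n_fruits = 20,
    tube_load_mean = 10,
    p_style = c(intra = 0.8, inter = 0.8),
    p_ovary = c(intra = 0.6, inter = 0.6),
    p_fruit = c(intra = 0.9, inter = 0.9),
    seeds_per_fruit = 300,
    embryo_intra = c(large = 0.8, small = 0.1, aborted = 0.05, empty = 0.05),
    embryo_inter = c(large = 0.8, small = 0.1, aborted = 0.05, empty = 0.05)
  ))
  cr <- simulate_crosses(cfg)
  expect_silent(pistil_assays(cr$pistils))
  expect_silent(fruit_records(cr$fruits))
  expect_silent(seed_assays(cr$seeds))
  expect_true(all(cr$pistils$tubes_on_stigma >= 1))
  tot <- with(cr$seeds, n_large + n_small + n_aborted + n_empty)
  expect_true(all(tot == 300))
  s <- stage_success(
    pistils = cr$pistils, stage = "style",
    direction = c("A", "B")
  )
  se <- sqrt(0.8 * 0.2 / (10 * 40))
  expect_lt(abs(s$conspecific - 0.8), 3 * se)
  ov <- stage_success(
    pistils = cr$pistils, stage = "ovary",
    direction = c("A", "B")
  )
  se_ov <- sqrt(0.6 * 0.4 / (8 * 40))
  expect_lt(abs(ov$conspecific - 0.6), 3 * se_ov)
})

test_that("a zero interspecific fruit probability yields fruit RI exactly 1", {
  cr_cfg <- sim_config(seed = 10)$crosses
  cr_cfg$p_fruit <- c(intra = 0.95, inter = 0)
  cfg <- sim_config(seed = 10, crosses = cr_cfg)
  cr <- simulate_crosses(cfg)
  s <- stage_success(fruits = cr$fruits, stage = "fruit", direction = c("A", "B"))
  expect_identical(stage_ri(s), 1)
})

test_that("null simulations with equal arms centre every stage RI on zero", {
  base <- sim_config(seed = 1)$crosses
  base$n_pistils <- 15
  base$n_flowers <- 30
  base$n_fruits <- 8
  base$seeds_per_fruit <- 60
  base$p_style <- c(intra = 0.8, inter = 0.8)
  base$p_ovary <- c(intra = 0.6, inter = 0.6)
  base$p_fruit <- c(intra = 0.9, inter = 0.9)
  base$embryo_inter <- base$embryo_intra
  stages <- c("style", "ovary", "fruit", "seed")
  draws <- t(vapply(1:500, function(i) {
    cfg <- sim_config(seed = 2000 + i, crosses = base)
    cr <- simulate_crosses(cfg)
    vapply(stages, function(st) {
      s <- stage_success(
        pistils = cr$pistils, fruits = cr$fruits, seeds = cr$seeds,
        stage = st, direction = c("A", "B")
      )
      stage_ri(s)
    }, numeric(1))
  }, numeric(4)))
  for (st in stages) {
    mc_se <- sd(draws[, st]) / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, st])), 3 * mc_se)
  }
})
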