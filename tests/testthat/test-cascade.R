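test_that("ladders keep canonical order and flag missing barriers", {
  lad <- assemble_ladder(
    direction = c("a", "b"),
    phenology = 0.1, ethological = NA, style = 0.2,
    ovary = NULL, fruit = 0.3, seed = 0.4
  )
  expect_equal(lad$barrier, c(
    "phenology", "ethological", "style", "ovary", "fruit", "seed"
  ))
  expect_equal(lad$estimable, c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_error(assemble_ladder(direction = c("a", "b")),
    class = "ri_input_error"
  )
  expect_error(
    assemble_ladder(direction = c("a", "b"), phenology = 1.5),
    class = "ri_input_error"
  )
})

test_that("the cascade reproduces the published complete-isolation directions", {
  lad <- habenaria_ri_ladders()
  for (d in list(c("lim", "del"), c("del", "lim"), c("dav", "del"), c("del", "dav"))) {
    r <- subset(lad, maternal == d[1] & paternal == d[2])
    ladder <- assemble_ladder(
      direction = d,
      phenology = r$ri[r$barrier == "phenology"],
      ethological = r$ri[r$barrier == "ethological"],
      style = r$ri[r$barrier == "style"],
      ovary = r$ri[r$barrier == "ovary"],
      fruit = r$ri[r$barrier == "fruit"],
      seed = r$ri[r$barrier == "seed"]
    )
    res <- run_cascade(ladder)
    expect_identical(res$total, 1) # exact, not approximate
    # downstream of a complete barrier every contribution is 0
    tab <- res$table[res$table$estimable, ]
    after <- which(tab$ri == 1)[1]
    if (after < nrow(tab)) {
      expect_equal(tab$contribution[(after + 1):nrow(tab)],
        rep(0, nrow(tab) - after)
      )
    }
  }
})

test_that("the recurrence total approximates the published incomplete totals", {
  lad <- habenaria_ri_ladders()
  dav_lim <- subset(lad, maternal == "dav" & paternal == "lim" & !is.na(ri))$ri
  expect_equal(round(tail(ri_cumulative(dav_lim), 1), 3), 0.657)
  lim_dav <- subset(lad, maternal == "lim" & paternal == "dav" & !is.na(ri))$ri
  expect_equal(round(tail(ri_cumulative(lim_dav), 1), 3), 0.889)
})

test_that("for non-negative ladders the total equals 1 - prod(1 - RI)", {
  set.seed(51)
  for (i in 1:200) {
    ri <- runif(sample(2:6, 1))
    res <- ri_cumulative(ri)
    expect_equal(tail(res, 1), 1 - prod(1 - ri))
  }
  # zero ladder
  zero <- assemble_ladder(c("a", "b"),
    phenology = 0, ethological = 0,
    style = 0, ovary = 0, fruit = 0, seed = 0
  )
  out <- run_cascade(zero)
  expect_equal(out$total, 0)
  expect_equal(out$table$contribution, rep(0, 6))
})

test_that("weighted total degenerates to the stage RI when U = 0", {
  ov <- structure(
    list(S = 1, U = 0, focal_species = "a", partner_species = "b"),
    class = "phenology_overlap"
  )
  lad <- assemble_ladder(c("a", "b"),
    phenology = 0, fruit = 0.37,
    overlap = ov
  )
  expect_equal(ri_total_weighted(lad), 0.37)
  # two stages: matches direct evaluation of the weighted formula
  ov2 <- structure(
    list(S = 0.6, U = 0.4, focal_species = "a", partner_species = "b"),
    class = "phenology_overlap"
  )
  lad2 <- assemble_ladder(c("a", "b"),
    phenology = 0.4, ovary = 0.5, fruit = 0.2,
    overlap = ov2
  )
  h <- (1 - c(0.5, 0.2)) / 2
  cc <- (1 + c(0.5, 0.2)) / 2
  Hs <- prod(h)
  Cs <- prod(cc)
  het <- 0.6 * Hs
  con <- 0.6 * Cs + 0.4 * Cs
  expect_equal(ri_total_weighted(lad2), 1 - 2 * het / (het + con))
  # a complete stage blocks everything regardless of weighting
  lad3 <- assemble_ladder(c("a", "b"),
    phenology = 0.4, fruit = 1,
    overlap = ov2
  )
  expect_equal(ri_total_weighted(lad3), 1)
})

test_that("ri_isolation integrates all modules over both directions", {
  cfg <- sim_config(seed = 5)
  dat <- simulate_dataset(cfg)
  fit <- ri_isolation(
    phenology = dat$phenology, bouts = dat$bouts,
    pistils = dat$pistils, fruits = dat$fruits, seeds = dat$seeds,
    pair = c("A", "B")
  )
  expect_s3_class(fit, "ri_isolation")
  expect_named(fit$cascades, c("A x B", "B x A"))
  cm <- coef(fit)
  expect_equal(dim(cm), c(6, 2))
  expect_true(all(cm >= -1 & cm <= 1))
  for (cascade in fit$cascades) {
    tab <- cascade$table
    expect_equal(
      sum(tab$contribution[tab$estimable]), cascade$total
    )
  }
  expect_equal(
    fit$asymmetry$asymmetry,
    abs(fit$asymmetry$ri_forward - fit$asymmetry$ri_reverse)
  )
  # missing bout data degrades to a non-estimable ethological barrier
  fit2 <- ri_isolation(
    phenology = dat$phenology, pistils = dat$pistils,
    fruits = dat$fruits, seeds = dat$seeds, pair = c("A", "B")
  )
  expect_false(fit2$cascades[["A x B"]]$table$estimable[2])
})

test_that("bootstrap intervals are reproducible and degenerate correctly", {
  cfg <- sim_config(seed = 6)
  dat <- simulate_dataset(cfg)
  b1 <- ri_bootstrap(
    pistils = dat$pistils, fruits = dat$fruits, seeds = dat$seeds,
    direction = c("A", "B"), B = 100, seed = 99
  )
  b2 <- ri_bootstrap(
    pistils = dat$pistils, fruits = dat$fruits, seeds = dat$seeds,
    direction = c("A", "B"), B = 100, seed = 99
  )
  expect_identical(b1, b2) # bit-for-bit under a fixed seed
  expect_true(all(b1$lower <= b1$upper))
  # an always-blocked fruit barrier has interval exactly [1, 1]
  fr <- make_fruits(c("A", "B"), 40, 38, 40, 0)
  b3 <- ri_bootstrap(
    fruits = fr, direction = c("A", "B"), B = 50, seed = 1
  )
  fruit_row <- b3[b3$quantity == "fruit", ]
  expect_equal(fruit_row$lower, 1)
  expect_equal(fruit_row$upper, 1)
  expect_error(
    ri_bootstrap(fruits = fr, direction = c("A", "B"), B = 10),
    class = "ri_input_error"
  ) # seed is mandatory
})
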