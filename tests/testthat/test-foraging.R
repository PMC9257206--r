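test_that("transition counting matches a brute-force pairwise scan", {
  b <- make_bouts(make_bout(c("a", "a", "a")))
  tab <- count_transitions(b, species = c("a", "b"))
  expect_equal(tab["a", "a"], 2L)
  expect_equal(sum(tab), 2L)
  # single-visit bouts contribute no transitions
  b2 <- make_bouts(make_bout("a"), make_bout(c("b", "a")))
  expect_equal(sum(count_transitions(b2, c("a", "b"))), 1L)

  set.seed(21)
  bouts <- lapply(1:100, function(i) {
    make_bout(sample(c("a", "b"), 1 + rpois(1, 3), replace = TRUE),
      id = paste0("b", i)
    )
  })
  bouts <- structure(bouts, class = "foraging_bouts")
  tab <- count_transitions(bouts, c("a", "b"))
  # oracle: enumerate every consecutive pair independently
  pairs <- do.call(rbind, lapply(bouts, function(b) {
    v <- b$visits
    if (length(v) < 2) {
      return(NULL)
    }
    cbind(v[-length(v)], v[-1])
  }))
  for (from in c("a", "b")) {
    for (to in c("a", "b")) {
      expect_equal(
        tab[from, to],
        sum(pairs[, 1] == from & pairs[, 2] == to)
      )
    }
  }
  expect_equal(
    sum(tab),
    sum(vapply(bouts, function(b) length(b$visits) - 1L, integer(1)))
  )
})

test_that("unknown visit labels are rejected naming the bout", {
  b <- make_bouts(make_bout(c("a", "zz"), id = "weird"))
  expect_error(
    count_transitions(b, species = c("a", "b")),
    regexp = "weird", class = "ri_input_error"
  )
})

test_that("ethological RI reproduces the Habenaria choice-array values", {
  lim_dav <- habenaria_transitions("lim_dav")
  expect_equal(round(ethological_ri(lim_dav, "lim"), 3), 0.882)
  expect_equal(round(ethological_ri(lim_dav, "dav"), 3), 0.647)
  lim_del <- habenaria_transitions("lim_del")
  expect_equal(round(ethological_ri(lim_del, "lim"), 3), 0.667)
  expect_equal(round(ethological_ri(lim_del, "del"), 3), 0.733)
})

test_that("ethological RI only depends on the pooled transition table", {
  # same visits split into different bouts give the same RI
  one <- make_bouts(make_bout(c("a", "a", "b", "a", "a")))
  two <- make_bouts(
    make_bout(c("a", "a", "b"), id = "b1"),
    make_bout(c("b", "a", "a"), id = "b2")
  )
  expect_equal(
    ethological_ri(count_transitions(one, c("a", "b")), "a"),
    ethological_ri(count_transitions(two, c("a", "b")), "a")
  )
})

test_that("bout constancy handles pure, alternating and short bouts", {
  expect_equal(bout_constancy(make_bout(rep("a", 4)), species = c("a", "b")), 1)
  expect_equal(
    bout_constancy(make_bout(c("a", "b", "a", "b")), species = c("a", "b")),
    -1
  )
  expect_true(is.na(bout_constancy(make_bout("a"), species = c("a", "b"))))
  # agreement with direct substitution into the closed form
  set.seed(22)
  for (i in 1:50) {
    v <- sample(c("a", "b"), 2 + rpois(1, 4), replace = TRUE)
    ci <- bout_constancy(make_bout(v), species = c("a", "b"))
    c_obs <- mean(v[-length(v)] == v[-1])
    p <- mean(v == "a")
    e <- p^2 + (1 - p)^2
    expected <- if (c_obs + e - 2 * c_obs * e == 0) 1 else {
      (c_obs - e) / (c_obs + e - 2 * c_obs * e)
    }
    expect_equal(ci, expected)
  }
})

test_that("constancy summaries average per-bout CI with sample SD", {
  # four all-conspecific bouts: the published 1.00 +/- 0.00 convention
  b <- make_bouts(
    make_bout(rep("lim", 5), "b1", "Trichoplusia intermixta"),
    make_bout(rep("lim", 5), "b2", "Trichoplusia intermixta"),
    make_bout(rep("lim", 4), "b3", "Trichoplusia intermixta"),
    make_bout(rep("lim", 4), "b4", "Trichoplusia intermixta")
  )
  out <- constancy_summary(b, species = c("lim", "dav"))
  expect_equal(out$mean_ci, 1)
  expect_equal(out$sd_ci, 0)
  expect_equal(out$n_bouts, 4)
  # mixed bouts: mean/SD match direct computation over per-bout values
  b2 <- make_bouts(
    make_bout(c("a", "a", "b", "b"), "c1", "m"),
    make_bout(c("a", "b", "a", "b"), "c2", "m"),
    make_bout(rep("a", 6), "c3", "m"),
    make_bout("a", "c4", "m") # too short: excluded
  )
  ci <- vapply(
    b2[1:3],
    function(x) bout_constancy(x, species = c("a", "b")), numeric(1)
  )
  out2 <- constancy_summary(b2, pollinator = "m", species = c("a", "b"))
  expect_equal(out2$n_bouts, 3)
  expect_equal(out2$mean_ci, mean(ci))
  expect_equal(out2$sd_ci, sd(ci))
  # a single estimable bout reports SD 0 with n flagged
  b3 <- make_bouts(make_bout(c("a", "b", "b"), "d1", "solo"))
  out3 <- constancy_summary(b3, species = c("a", "b"))
  expect_equal(out3$n_bouts, 1)
  expect_equal(out3$sd_ci, 0)
})

test_that("G-test reproduces published statistics and the null case", {
  g1 <- g_test_transitions(30, 4)
  expect_equal(round(unname(g1$statistic), 2), 22.50)
  expect_equal(unname(g1$parameter), 1)
  expect_lt(g1$p.value, 0.001)
  g2 <- g_test_transitions(23, 4)
  expect_equal(round(unname(g2$statistic), 2), 14.78)
  expect_lt(g2$p.value, 0.001)
  g3 <- g_test_transitions(12, 12)
  expect_equal(unname(g3$statistic), 0)
  expect_equal(g3$p.value, 1)
})

test_that("G statistic agrees with a brute-force evaluation and is symmetric", {
  set.seed(23)
  for (i in 1:1000) {
    o <- rpois(2, sample(1:50, 1))
    if (sum(o) == 0) o <- c(1, 0)
    g <- unname(g_test_transitions(o[1], o[2])$statistic)
    expect_equal(g, g_oracle(o[1], o[2]), tolerance = 1e-10)
    expect_equal(
      g, unname(g_test_transitions(o[2], o[1])$statistic),
      tolerance = 1e-12
    )
    expect_gte(g, -1e-12)
  }
})
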