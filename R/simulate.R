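# Synthetic field datasets with the statistical structure the analysis
# assumes: normally distributed flowering windows, Markov foraging bouts
# with a one-parameter constancy dial, and binomial/multinomial cross
# outcomes.  Every generator is deterministic under the config seed and
# writes data that satisfy the ingestion validators by construction.

#' Simulation configuration for a two-species study
#'
#' Defaults emulate a field study of two co-flowering orchid species
#' sharing a hawkmoth pollinator: about 30 flowering individuals per
#' species with broadly overlapping month-long flowering windows; choice
#' arrays yielding short foraging bouts (mean 3 visits) with strong but
#' imperfect floral constancy; hand-pollination arms of about 30 pistils,
#' 60 flowers and 30 fruits with high conspecific success and roughly 300
#' seeds scored per fruit in four embryo classes.
#'
#' @param seed Integer RNG seed (mandatory; all generators derive their
#'   randomness from it).
#' @param species Labels of the two species.
#' @param phenology List: per-species vectors \code{n},
#'   \code{start_mean}, \code{start_sd} (day-of-year of first flower),
#'   \code{duration_mean}, \code{duration_sd} (days).
#' @param foraging List: \code{n_bouts}; \code{length_mean} (mean bout
#'   length in visits; lengths are 1 + geometric); \code{kappa} in
#'   \code{[0, 1]}, the constancy parameter interpolating between
#'   abundance-random foraging (0) and perfect constancy (1);
#'   \code{abundance}, relative abundance of the first species.
#' @param crosses List: \code{n_pistils}, \code{n_flowers},
#'   \code{n_fruits} per arm; \code{tube_load_mean} (Poisson mean pollen
#'   tubes germinating on a stigma, truncated at 1);
#'   \code{p_style}, \code{p_ovary}, \code{p_fruit}: length-2 vectors
#'   \code{c(intra, inter)} of per-tube / per-flower success
#'   probabilities; \code{seeds_per_fruit}; \code{embryo_intra},
#'   \code{embryo_inter}: probabilities of the (large, small, aborted,
#'   empty) embryo classes, each summing to 1.
#' @return Validated config list of class \code{ri_sim_config}.
#' @export
sim_config <- function(seed,
                       species = c("A", "B"),
                       phenology = list(
                         n = c(30, 27),
                         start_mean = c(182, 186), start_sd = c(3, 3),
                         duration_mean = c(30, 30), duration_sd = c(4, 4)
                       ),
                       foraging = list(
                         n_bouts = 40, length_mean = 3,
                         kappa = 0.85, abundance = 0.5
                       ),
                       crosses = list(
                         n_pistils = 30, n_flowers = 60, n_fruits = 30,
                         tube_load_mean = 8,
                         p_style = c(intra = 0.9, inter = 0.85),
                         p_ovary = c(intra = 0.65, inter = 0.6),
                         p_fruit = c(intra = 0.95, inter = 0.9),
                         seeds_per_fruit = 300,
                         embryo_intra = c(
                           large = 0.8, small = 0.1,
                           aborted = 0.05, empty = 0.05
                         ),
                         embryo_inter = c(
                           large = 0.7, small = 0.12,
                           aborted = 0.1, empty = 0.08
                         )
                       )) {
  if (missing(seed) || !is.numeric(seed)) {
    stop_input("sim_config needs an integer seed")
  }
  if (length(species) != 2) stop_input("exactly two species required")
  ph <- lapply(phenology, unlist) # tolerate YAML-style nested lists
  for (f in c("n", "start_mean", "start_sd", "duration_mean", "duration_sd")) {
    if (is.null(ph[[f]])) stop_input(paste("phenology$", f, "missing"))
    ph[[f]] <- rep_len(ph[[f]], 2)
  }
  if (any(ph$n < 0)) stop_input("phenology n must be non-negative")
  fo <- foraging
  if (fo$kappa < 0 || fo$kappa > 1) stop_input("kappa must lie in [0, 1]")
  if (fo$abundance < 0 || fo$abundance > 1) {
    stop_input("abundance must lie in [0, 1]")
  }
  if (fo$length_mean < 1) stop_input("length_mean must be >= 1")
  cr <- lapply(crosses, unlist)
  probs <- c(cr$p_style, cr$p_ovary, cr$p_fruit)
  if (any(probs < 0) || any(probs > 1)) {
    stop_input("cross success probabilities must lie in [0, 1]")
  }
  for (f in c("embryo_intra", "embryo_inter")) {
    if (length(cr[[f]]) != 4 || abs(sum(cr[[f]]) - 1) > 1e-8 ||
      any(cr[[f]] < 0)) {
      stop_input(paste(f, "must be 4 non-negative probabilities summing to 1"))
    }
  }
  structure(
    list(
      seed = as.integer(seed), species = species,
      phenology = ph, foraging = fo, crosses = cr
    ),
    class = "ri_sim_config"
  )
}

#' Simulate per-individual flowering records
#'
#' Each individual's first flowering day is a rounded normal draw and its
#' duration \code{max(1, round(normal))} days, per the species'
#' parameters.
#'
#' @param config An \code{ri_sim_config}.
#' @return Flowering-records data frame (may have zero rows if both
#'   \code{n} are 0).
#' @export
simulate_phenology <- function(config) {
  stopifnot(inherits(config, "ri_sim_config"))
  set.seed(config$seed)
  ph <- config$phenology
  rows <- lapply(1:2, function(i) {
    n <- ph$n[i]
    if (n == 0) {
      return(NULL)
    }
    start <- round(stats::rnorm(n, ph$start_mean[i], ph$start_sd[i]))
    dur <- pmax(1, round(stats::rnorm(n, ph$duration_mean[i], ph$duration_sd[i])))
    data.frame(
      individual_id = sprintf("%s_%03d", config$species[i], seq_len(n)),
      species = config$species[i],
      site = "sim",
      first_flower_day = as.integer(start),
      last_flower_day = as.integer(start + dur - 1L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      individual_id = character(0), species = character(0),
      site = character(0), first_flower_day = integer(0),
      last_flower_day = integer(0), stringsAsFactors = FALSE
    )
  }
  out
}

#' Simulate pollinator foraging bouts in a two-species array
#'
#' The first visit of a bout goes to the first species with probability
#' equal to its relative abundance.  Each later visit stays on the
#' current species with probability
#' \code{kappa + (1 - kappa) * abundance(current)} and otherwise
#' switches: \code{kappa = 0} is abundance-random foraging (transitions
#' independent of the current species), \code{kappa = 1} perfect
#' constancy.  Bout lengths are \code{1 + Geometric}, giving a mean of
#' \code{length_mean} visits.
#'
#' @param config An \code{ri_sim_config}.
#' @return A \code{foraging_bouts} list.
#' @export
simulate_bouts <- function(config) {
  stopifnot(inherits(config, "ri_sim_config"))
  set.seed(config$seed + 1L)
  fo <- config$foraging
  sp <- config$species
  abund <- c(fo$abundance, 1 - fo$abundance)
  names(abund) <- sp
  bouts <- lapply(seq_len(fo$n_bouts), function(j) {
    len <- 1L + stats::rgeom(1, prob = 1 / fo$length_mean)
    visits <- character(len)
    visits[1] <- sample(sp, 1, prob = abund)
    if (len > 1) {
      for (k in 2:len) {
        cur <- visits[k - 1]
        p_stay <- fo$kappa + (1 - fo$kappa) * abund[[cur]]
        visits[k] <- if (stats::runif(1) < p_stay) cur else setdiff(sp, cur)
      }
    }
    list(
      bout_id = sprintf("bout_%03d", j),
      pollinator = "moth_sim",
      visits = visits
    )
  })
  structure(bouts, class = "foraging_bouts")
}

rpois_pos <- function(n, lambda) {
  # Poisson truncated at >= 1, via inverse CDF on a uniform above P(X = 0)
  u <- stats::runif(n, min = stats::dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Simulate hand-pollination experiments
#'
#' For each species as maternal parent, three arms are generated (self,
#' intraspecific cross, interspecific cross; the self arm uses the
#' intraspecific probabilities).  Pollen tubes germinating on a stigma
#' are truncated-Poisson; style and ovary penetration are binomial
#' thinnings, so the nesting \code{ovary <= style <= stigma} holds by
#' construction.  Fruit set is Bernoulli per flower; each fruit's seeds
#' are one multinomial draw over the four embryo classes.
#'
#' @param config An \code{ri_sim_config}.
#' @return List with data frames \code{pistils}, \code{fruits},
#'   \code{seeds}.
#' @export
simulate_crosses <- function(config) {
  stopifnot(inherits(config, "ri_sim_config"))
  set.seed(config$seed + 2L)
  cr <- config$crosses
  sp <- config$species
  arms <- expand.grid(
    maternal = sp, treatment = c("self", "intra_cross", "inter_cross"),
    stringsAsFactors = FALSE
  )
  arms$paternal <- ifelse(
    arms$treatment == "inter_cross",
    ifelse(arms$maternal == sp[1], sp[2], sp[1]),
    arms$maternal
  )
  arms$idx <- ifelse(arms$treatment == "inter_cross", 2L, 1L)

  pistils <- do.call(rbind, lapply(seq_len(nrow(arms)), function(a) {
    n <- cr$n_pistils
    stigma <- rpois_pos(n, cr$tube_load_mean)
    style <- stats::rbinom(n, stigma, cr$p_style[arms$idx[a]])
    ovary <- stats::rbinom(n, style, cr$p_ovary[arms$idx[a]])
    data.frame(
      pistil_id = sprintf(
        "%s_%s_%03d", arms$maternal[a], arms$treatment[a], seq_len(n)
      ),
      maternal_species = arms$maternal[a],
      paternal_species = arms$paternal[a],
      treatment = arms$treatment[a],
      tubes_on_stigma = stigma,
      tubes_in_style = style,
      tubes_in_ovary = ovary,
      stringsAsFactors = FALSE
    )
  }))

  fruits <- do.call(rbind, lapply(seq_len(nrow(arms)), function(a) {
    data.frame(
      maternal_species = arms$maternal[a],
      paternal_species = arms$paternal[a],
      treatment = arms$treatment[a],
      flowers_treated = cr$n_flowers,
      fruits_set = stats::rbinom(1, cr$n_flowers, cr$p_fruit[arms$idx[a]]),
      stringsAsFactors = FALSE
    )
  }))

  seeds <- do.call(rbind, lapply(seq_len(nrow(arms)), function(a) {
    probs <- if (arms$idx[a] == 2) cr$embryo_inter else cr$embryo_intra
    counts <- t(stats::rmultinom(cr$n_fruits, cr$seeds_per_fruit, probs))
    data.frame(
      fruit_id = sprintf(
        "%s_%s_f%03d", arms$maternal[a], arms$treatment[a],
        seq_len(cr$n_fruits)
      ),
      maternal_species = arms$maternal[a],
      paternal_species = arms$paternal[a],
      treatment = arms$treatment[a],
      n_large = counts[, 1], n_small = counts[, 2],
      n_aborted = counts[, 3], n_empty = counts[, 4],
      stringsAsFactors = FALSE
    )
  }))

  rownames(pistils) <- rownames(fruits) <- rownames(seeds) <- NULL
  list(pistils = pistils, fruits = fruits, seeds = seeds)
}

#' Simulate a complete two-species field dataset
#'
#' Runs all three generators and returns the tables the analysis
#' functions ingest.
#'
#' @param config An \code{ri_sim_config}.
#' @return List with \code{phenology}, \code{bouts} (a
#'   \code{foraging_bouts} list), \code{visits} (the same bouts in
#'   long-format rows), \code{pistils}, \code{fruits}, \code{seeds}.
#' @export
simulate_dataset <- function(config) {
  crosses <- simulate_crosses(config)
  bouts <- simulate_bouts(config)
  list(
    phenology = simulate_phenology(config),
    bouts = bouts,
    visits = bouts_to_visits(bouts),
    pistils = crosses$pistils,
    fruits = crosses$fruits,
    seeds = crosses$seeds
  )
}

#' Convert a bout list to a long-format visit table
#'
#' @param bouts A \code{foraging_bouts} list.
#' @return Data frame with columns \code{bout_id}, \code{pollinator},
#'   \code{visit_order}, \code{plant_species}.
#' @export
bouts_to_visits <- function(bouts) {
  do.call(rbind, lapply(bouts, function(b) {
    data.frame(
      bout_id = b$bout_id,
      pollinator = b$pollinator,
      visit_order = seq_along(b$visits),
      plant_species = b$visits,
      stringsAsFactors = FALSE
    )
  }))
}
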