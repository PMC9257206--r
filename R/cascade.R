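# The barrier cascade: assembling per-barrier RI values for one directed
# species pair, sequential cumulation, absolute contributions, weighted
# total isolation and bootstrap intervals.

#' Assemble the barrier ladder for one cross direction
#'
#' Collects per-barrier RI values in the fixed life-cycle order
#' phenology, ethological, style, ovary, fruit, seed.  Each barrier entry
#' may be a plain RI value, a \code{stage_success} object (its RI is
#' computed), or \code{NULL}/\code{NA} for a barrier that could not be
#' estimated (e.g. no choice-array data because the species do not share
#' pollinators).  Non-estimable barriers are flagged and skipped during
#' cumulation -- never imputed as zero, which would silently understate
#' the contribution of later barriers.
#'
#' @param direction Length-2 character vector \code{c(maternal, paternal)}.
#' @param phenology,ethological,style,ovary,fruit,seed Per-barrier RI
#'   values (or \code{stage_success} objects / \code{NULL}).
#' @param overlap Optional \code{phenology_overlap} for the focal
#'   (maternal) species, enabling \code{\link{ri_total_weighted}}.
#' @return Object of class \code{ri_ladder}: data frame with columns
#'   \code{barrier}, \code{ri}, \code{estimable}; attributes
#'   \code{direction} and \code{overlap}.
#' @export
assemble_ladder <- function(direction, phenology = NULL, ethological = NULL,
                            style = NULL, ovary = NULL, fruit = NULL,
                            seed = NULL, overlap = NULL) {
  entries <- list(
    phenology = phenology, ethological = ethological,
    style = style, ovary = ovary, fruit = fruit, seed = seed
  )
  ri <- vapply(entries, function(e) {
    if (is.null(e) || (is.atomic(e) && length(e) == 1 && is.na(e))) {
      return(NA_real_)
    }
    if (inherits(e, "stage_success")) {
      return(stage_ri(e))
    }
    as.numeric(e)
  }, numeric(1))
  estimable <- !is.na(ri)
  if (!any(estimable)) stop_input("no estimable barrier in the ladder")
  if (any(ri[estimable] < -1 | ri[estimable] > 1)) {
    stop_input("barrier RI values must lie in [-1, 1]")
  }
  out <- data.frame(
    barrier = RI_BARRIERS, ri = unname(ri), estimable = unname(estimable),
    stringsAsFactors = FALSE
  )
  structure(out,
    direction = direction, overlap = overlap,
    class = c("ri_ladder", "data.frame")
  )
}

#' Run the sequential cascade over a barrier ladder
#'
#' Applies \code{\link{ri_cumulative}} and \code{\link{ri_contributions}}
#' to the estimable barriers in life-cycle order.  The final cumulative
#' value is the total RI; it is exactly 1 whenever any estimable barrier
#' has RI = 1.  When the ladder carries a phenology overlap, the
#' weighted total (\code{\link{ri_total_weighted}}) is reported alongside.
#'
#' @param ladder An \code{ri_ladder} from \code{\link{assemble_ladder}}.
#' @return Object of class \code{ri_cascade}: list with the per-barrier
#'   \code{table} (barrier, ri, estimable, cumulative, contribution),
#'   \code{total} (recurrence total), \code{total_weighted} (or NA),
#'   and \code{direction}.
#' @export
run_cascade <- function(ladder) {
  stopifnot(inherits(ladder, "ri_ladder"))
  est <- ladder$estimable
  cum_est <- ri_cumulative(ladder$ri[est])
  ac_est <- ri_contributions(cum_est)
  tab <- data.frame(
    barrier = ladder$barrier, ri = ladder$ri, estimable = est,
    cumulative = NA_real_, contribution = NA_real_,
    stringsAsFactors = FALSE
  )
  tab$cumulative[est] <- cum_est
  tab$contribution[est] <- ac_est
  overlap <- attr(ladder, "overlap")
  tw <- if (is.null(overlap)) NA_real_ else ri_total_weighted(ladder, overlap)
  structure(
    list(
      table = tab,
      total = cum_est[length(cum_est)],
      total_weighted = tw,
      direction = attr(ladder, "direction")
    ),
    class = "ri_cascade"
  )
}

#' Total isolation weighted by shared/unshared flowering
#'
#' Builds the end-to-end success components of \code{\link{ri_total}}
#' from the post-phenology barriers of a ladder.  Each barrier's RI value
#' \code{r} corresponds to normalised per-stage success proportions
#' \code{h = (1 - r)/2} (heterospecific) and \code{c = (1 + r)/2}
#' (conspecific); end-to-end success during the shared period is the
#' product over estimable post-phenology barriers, \code{Hs = prod(h)},
#' \code{Cs = prod(c)}.  Outside the shared period the heterospecific
#' partner is absent, so \code{Hu = 0} and \code{Cu = Cs}.
#'
#' @param ladder An \code{ri_ladder}.
#' @param overlap A \code{phenology_overlap} for the maternal species
#'   (defaults to the one attached to the ladder).
#' @return Weighted total RI value.
#' @export
ri_total_weighted <- function(ladder, overlap = attr(ladder, "overlap")) {
  stopifnot(inherits(ladder, "ri_ladder"))
  if (is.null(overlap)) stop_input("no phenology overlap available")
  post <- ladder$estimable & ladder$barrier != "phenology"
  r <- ladder$ri[post]
  Hs <- prod((1 - r) / 2)
  Cs <- prod((1 + r) / 2)
  ri_total(S = overlap$S, U = overlap$U, Hs = Hs, Cs = Cs, Hu = 0, Cu = Cs)
}

#' @export
print.ri_cascade <- function(x, digits = 3, ...) {
  cat(
    "Sequential reproductive isolation cascade:",
    paste(x$direction, collapse = " (female) x "), "(male)\n"
  )
  tab <- x$table
  tab$ri <- round(tab$ri, digits)
  tab$cumulative <- round(tab$cumulative, digits)
  tab$contribution <- round(tab$contribution, digits)
  print(tab, row.names = FALSE)
  cat("Total RI (sequential):", round(x$total, digits), "\n")
  if (!is.na(x$total_weighted)) {
    cat(
      "Total RI (phenology-weighted):",
      round(x$total_weighted, digits), "\n"
    )
  }
  invisible(x)
}

# --- top-level interface -------------------------------------------------

#' Quantify reproductive isolation between two species from field data
#'
#' The package's main entry point: takes the raw observation tables --
#' flowering records, choice-array foraging bouts, pistil pollen-tube
#' assays, fruit-set records, embryo scorings -- for one species pair and
#' returns the full barrier decomposition for both cross directions:
#' per-barrier RI, cumulative RI, absolute contributions, total isolation
#' (sequential and phenology-weighted), and per-barrier asymmetry between
#' the reciprocal directions.
#'
#' Any observation table may be \code{NULL}; the corresponding barriers
#' are flagged non-estimable and skipped (not zero-filled).
#'
#' @param phenology Flowering records (see \code{\link{flowering_records}}).
#' @param bouts A \code{foraging_bouts} list or long-format visit table.
#' @param pistils,fruits,seeds Hand-pollination tables (see
#'   \code{\link{pistil_assays}}, \code{\link{fruit_records}},
#'   \code{\link{seed_assays}}).
#' @param pair Length-2 character vector of the two species.
#' @param site Optional site restriction for phenology.
#' @param mode Stage summarisation mode, see \code{\link{stage_success}}.
#' @return Object of class \code{ri_isolation}: list with
#'   \code{cascades} (one \code{ri_cascade} per direction, named
#'   "A x B" = A maternal), \code{asymmetry} (per-barrier data frame),
#'   and \code{pair}.
#' @examples
#' cfg <- sim_config(seed = 1)
#' dat <- simulate_dataset(cfg)
#' fit <- ri_isolation(
#'   phenology = dat$phenology, bouts = dat$bouts,
#'   pistils = dat$pistils, fruits = dat$fruits, seeds = dat$seeds,
#'   pair = c("A", "B")
#' )
#' fit
#' @export
ri_isolation <- function(phenology = NULL, bouts = NULL, pistils = NULL,
                         fruits = NULL, seeds = NULL, pair, site = NULL,
                         mode = c("proportion", "count")) {
  mode <- match.arg(mode)
  if (length(pair) != 2) stop_input("pair must name exactly two species")
  if (!is.null(bouts) && is.data.frame(bouts)) {
    bouts <- foraging_bouts(bouts, species = pair)
  }

  pheno_tab <- if (!is.null(phenology)) {
    phenology_ri_pair(phenology, pair[1], pair[2], site = site)
  }
  trans <- if (!is.null(bouts)) count_transitions(bouts, species = pair)

  one_direction <- function(maternal, paternal) {
    direction <- c(maternal, paternal)
    pheno_ri <- overlap <- NULL
    if (!is.null(pheno_tab)) {
      row <- pheno_tab[pheno_tab$focal == maternal, ]
      pheno_ri <- row$ri_pheno
      overlap <- structure(
        list(
          S = row$S, U = row$U,
          focal_species = maternal, partner_species = paternal
        ),
        class = "phenology_overlap"
      )
    }
    etho_ri <- if (!is.null(trans)) {
      tryCatch(ethological_ri(trans, focal = maternal),
        ri_undefined_error = function(e) NA_real_
      )
    }
    stage_or_na <- function(stage, tab_name, tab) {
      if (is.null(tab)) {
        return(NULL)
      }
      tryCatch(
        stage_success(
          pistils = if (tab_name == "pistils") tab,
          fruits = if (tab_name == "fruits") tab,
          seeds = if (tab_name == "seeds") tab,
          stage = stage, direction = direction, mode = mode
        ),
        ri_undefined_error = function(e) NA_real_
      )
    }
    ladder <- tryCatch(
      assemble_ladder(
        direction = direction,
        phenology = pheno_ri,
        ethological = etho_ri,
        style = stage_or_na("style", "pistils", pistils),
        ovary = stage_or_na("ovary", "pistils", pistils),
        fruit = stage_or_na("fruit", "fruits", fruits),
        seed = stage_or_na("seed", "seeds", seeds),
        overlap = overlap
      ),
      ri_input_error = function(e) NULL
    )
    if (is.null(ladder)) {
      # no estimable barrier in this direction: empty cascade placeholder
      return(structure(
        list(
          table = data.frame(
            barrier = RI_BARRIERS, ri = NA_real_, estimable = FALSE,
            cumulative = NA_real_, contribution = NA_real_,
            stringsAsFactors = FALSE
          ),
          total = NA_real_, total_weighted = NA_real_,
          direction = direction
        ),
        class = "ri_cascade"
      ))
    }
    run_cascade(ladder)
  }

  fwd <- one_direction(pair[1], pair[2])
  bwd <- one_direction(pair[2], pair[1])
  if (is.na(fwd$total) && is.na(bwd$total)) {
    stop_input("no estimable barrier in either direction")
  }
  asym <- data.frame(
    barrier = RI_BARRIERS,
    ri_forward = fwd$table$ri,
    ri_reverse = bwd$table$ri,
    asymmetry = ifelse(
      fwd$table$estimable & bwd$table$estimable,
      ri_asymmetry(fwd$table$ri, bwd$table$ri), NA_real_
    ),
    stringsAsFactors = FALSE
  )
  out <- list(
    cascades = stats::setNames(
      list(fwd, bwd),
      c(
        paste(pair, collapse = " x "),
        paste(rev(pair), collapse = " x ")
      )
    ),
    asymmetry = asym,
    pair = pair
  )
  class(out) <- "ri_isolation"
  out
}

#' @export
print.ri_isolation <- function(x, digits = 3, ...) {
  cat(
    "Reproductive isolation between", x$pair[1], "and", x$pair[2],
    "(directions: maternal x paternal)\n\n"
  )
  for (cascade in x$cascades) {
    print(cascade, digits = digits)
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.ri_isolation <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  cat("Per-barrier asymmetry between reciprocal directions:\n")
  asym <- object$asymmetry
  asym$asymmetry <- round(asym$asymmetry, digits)
  asym$ri_forward <- round(asym$ri_forward, digits)
  asym$ri_reverse <- round(asym$ri_reverse, digits)
  print(asym, row.names = FALSE)
  invisible(object)
}

#' Per-barrier RI values of a fitted isolation object
#'
#' @param object An \code{ri_isolation} object.
#' @param ... Unused.
#' @return Numeric matrix, barriers in rows, directions in columns.
#' @export
coef.ri_isolation <- function(object, ...) {
  m <- vapply(object$cascades, function(x) x$table$ri, numeric(6))
  rownames(m) <- RI_BARRIERS
  m
}

#' Plot the barrier contribution decomposition
#'
#' One panel per direction: bars are each barrier's absolute contribution
#' to total isolation, the line is the cumulative RI after each barrier.
#'
#' @param x An \code{ri_isolation} object.
#' @param ... Passed to \code{barplot}.
#' @export
plot.ri_isolation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$cascades)))
  on.exit(graphics::par(op))
  for (nm in names(x$cascades)) {
    tab <- x$cascades[[nm]]$table
    mids <- graphics::barplot(tab$contribution,
      names.arg = tab$barrier,
      ylim = c(min(0, tab$contribution, na.rm = TRUE), 1),
      ylab = "absolute contribution / cumulative RI",
      main = nm, las = 2, ...
    )
    ok <- tab$estimable
    graphics::lines(mids[ok], tab$cumulative[ok], type = "b", pch = 19)
  }
  invisible(x)
}

# --- bootstrap -----------------------------------------------------------

#' Nonparametric bootstrap intervals for barrier and total RI
#'
#' Resamples the raw observations with replacement, independently within
#' each arm -- flowering individuals within species, foraging bouts,
#' pistils within treatment arm, flowers within fruit-set arm, fruits
#' within seed arm -- recomputes the full cascade per replicate, and
#' returns percentile intervals.  Deterministic under a fixed seed.
#'
#' @inheritParams ri_isolation
#' @param direction Length-2 vector \code{c(maternal, paternal)}.
#' @param B Number of bootstrap replicates.
#' @param seed Mandatory RNG seed for reproducibility.
#' @param level Confidence level (default 0.95, percentile method).
#' @return Data frame with one row per barrier plus one for the total:
#'   \code{estimate}, \code{lower}, \code{upper}, \code{n_ok} (replicates
#'   where the quantity was estimable), and \code{unstable} (fewer than 5
#'   observations in some contributing arm).
#' @export
ri_bootstrap <- function(phenology = NULL, bouts = NULL, pistils = NULL,
                         fruits = NULL, seeds = NULL, direction,
                         B = 2000, seed, level = 0.95,
                         mode = c("proportion", "count")) {
  mode <- match.arg(mode)
  if (missing(seed)) stop_input("a seed is mandatory for the bootstrap")
  set.seed(seed)
  pair <- direction
  if (!is.null(bouts) && is.data.frame(bouts)) {
    bouts <- foraging_bouts(bouts)
  }

  resample_rows <- function(x, group) {
    idx <- unlist(lapply(
      split(seq_len(nrow(x)), group),
      function(i) sample(i, length(i), replace = TRUE)
    ))
    x[idx, , drop = FALSE]
  }
  # fruit batches are expanded to one row per flower so flowers resample
  expand_fruits <- function(fr) {
    idx <- rep(seq_len(nrow(fr)), fr$flowers_treated)
    out <- fr[idx, , drop = FALSE]
    out$flowers_treated <- 1L
    out$fruits_set <- unlist(Map(
      function(n, k) c(rep(1L, k), rep(0L, n - k)),
      fr$flowers_treated, fr$fruits_set
    ))
    out
  }
  fruits_expanded <- if (!is.null(fruits)) expand_fruits(fruit_records(fruits))

  smallest_arm <- function() {
    sizes <- integer(0)
    if (!is.null(pistils)) {
      arms <- cross_arms(pistils, direction)
      sizes <- c(sizes, nrow(arms$intra), nrow(arms$inter))
    }
    if (!is.null(fruits_expanded)) {
      arms <- cross_arms(fruits_expanded, direction)
      sizes <- c(sizes, nrow(arms$intra), nrow(arms$inter))
    }
    if (!is.null(seeds)) {
      arms <- cross_arms(seeds, direction)
      sizes <- c(sizes, nrow(arms$intra), nrow(arms$inter))
    }
    if (!is.null(bouts)) sizes <- c(sizes, length(bouts))
    sizes
  }
  unstable <- length(smallest_arm()) > 0 && min(smallest_arm()) < 5

  one_fit <- function(ph, bo, pi, fr, se) {
    fit <- ri_isolation(
      phenology = ph, bouts = bo, pistils = pi, fruits = fr, seeds = se,
      pair = pair, mode = mode
    )
    cascade <- fit$cascades[[paste(direction, collapse = " x ")]]
    c(stats::setNames(cascade$table$ri, cascade$table$barrier),
      total = cascade$total
    )
  }

  est <- one_fit(phenology, bouts, pistils, fruits, seeds)
  draws <- matrix(NA_real_, nrow = B, ncol = length(est),
    dimnames = list(NULL, names(est))
  )
  for (b in seq_len(B)) {
    ph <- if (!is.null(phenology)) {
      resample_rows(phenology, phenology$species)
    }
    bo <- if (!is.null(bouts)) {
      structure(bouts[sample(length(bouts), replace = TRUE)],
        class = "foraging_bouts"
      )
    }
    pi <- if (!is.null(pistils)) {
      resample_rows(pistils, interaction(
        pistils$maternal_species, pistils$paternal_species,
        pistils$treatment
      ))
    }
    fr <- if (!is.null(fruits_expanded)) {
      resample_rows(fruits_expanded, interaction(
        fruits_expanded$maternal_species,
        fruits_expanded$paternal_species, fruits_expanded$treatment
      ))
    }
    se <- if (!is.null(seeds)) {
      resample_rows(seeds, interaction(
        seeds$maternal_species, seeds$paternal_species, seeds$treatment
      ))
    }
    draws[b, ] <- tryCatch(
      one_fit(ph, bo, pi, fr, se),
      ri_error = function(e) rep(NA_real_, length(est))
    )
  }
  alpha <- (1 - level) / 2
  out <- data.frame(
    quantity = names(est),
    estimate = unname(est),
    lower = apply(draws, 2, stats::quantile,
      probs = alpha, na.rm = TRUE, names = FALSE
    ),
    upper = apply(draws, 2, stats::quantile,
      probs = 1 - alpha, na.rm = TRUE, names = FALSE
    ),
    n_ok = apply(draws, 2, function(x) sum(!is.na(x))),
    unstable = unstable,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[!is.na(out$estimate), , drop = FALSE]
}
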