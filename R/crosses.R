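# Hand-pollination experiments: pistil pollen-tube assays, fruit set and
# embryo scoring, summarised into per-stage conspecific/heterospecific
# success and stage RI values.
#
# Treatments follow the field design: "self" (self-pollination),
# "intra_cross" (conspecific pollen from a distant plant), "inter_cross"
# (heterospecific pollen).  Self-pollinations measure compatibility, not
# isolation, and are excluded from interspecific RI.

CROSS_TREATMENTS <- c("self", "intra_cross", "inter_cross")
CROSS_STAGES <- c("style", "ovary", "fruit", "seed")

validate_cross_table <- function(x, need, what) {
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop_input(paste0(
      what, " table missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  if (!all(x$treatment %in% CROSS_TREATMENTS)) {
    bad <- which(!(x$treatment %in% CROSS_TREATMENTS))[1]
    stop_input(paste0(
      "unknown treatment '", x$treatment[bad], "' in ", what,
      " table row ", bad
    ))
  }
  x
}

#' Validate a pistil pollen-tube assay table
#'
#' Checks the nesting invariant that tube counts cannot increase along the
#' pistil: \code{tubes_in_ovary <= tubes_in_style <= tubes_on_stigma}.
#'
#' @param pistils Data frame with columns \code{pistil_id},
#'   \code{maternal_species}, \code{paternal_species}, \code{treatment},
#'   \code{tubes_on_stigma}, \code{tubes_in_style}, \code{tubes_in_ovary}.
#' @return The validated data frame.
#' @export
pistil_assays <- function(pistils) {
  pistils <- validate_cross_table(
    pistils,
    c(
      "pistil_id", "maternal_species", "paternal_species", "treatment",
      "tubes_on_stigma", "tubes_in_style", "tubes_in_ovary"
    ),
    "pistil"
  )
  bad <- which(pistils$tubes_in_ovary > pistils$tubes_in_style |
    pistils$tubes_in_style > pistils$tubes_on_stigma)
  if (length(bad) > 0) {
    stop_input(paste0(
      "tube counts violate ovary <= style <= stigma in row(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  pistils
}

#' Validate a fruit-set table
#'
#' @param fruits Data frame with columns \code{maternal_species},
#'   \code{paternal_species}, \code{treatment}, \code{flowers_treated},
#'   \code{fruits_set}.
#' @return The validated data frame.
#' @export
fruit_records <- function(fruits) {
  fruits <- validate_cross_table(
    fruits,
    c(
      "maternal_species", "paternal_species", "treatment",
      "flowers_treated", "fruits_set"
    ),
    "fruit"
  )
  if (any(fruits$fruits_set > fruits$flowers_treated) ||
    any(fruits$fruits_set < 0)) {
    stop_input("fruits_set must lie in [0, flowers_treated]")
  }
  fruits
}

#' Validate a seed (embryo scoring) table
#'
#' Seeds from each fruit are scored into four embryo classes: large,
#' small (half-sized), aborted, empty.
#'
#' @param seeds Data frame with columns \code{fruit_id},
#'   \code{maternal_species}, \code{paternal_species}, \code{treatment},
#'   \code{n_large}, \code{n_small}, \code{n_aborted}, \code{n_empty}.
#' @return The validated data frame.
#' @export
seed_assays <- function(seeds) {
  seeds <- validate_cross_table(
    seeds,
    c(
      "fruit_id", "maternal_species", "paternal_species", "treatment",
      "n_large", "n_small", "n_aborted", "n_empty"
    ),
    "seed"
  )
  counts <- seeds[, c("n_large", "n_small", "n_aborted", "n_empty")]
  if (any(as.matrix(counts) < 0)) {
    stop_input("embryo category counts must be non-negative")
  }
  seeds
}

#' Record whether a fruit counts as set
#'
#' A flower converts into a fruit only when the capsule is dense and
#' turgid; soft, hollow capsules are not counted as fruit set (they are
#' still retained for embryo scoring).
#'
#' @param turgid Logical vector: capsule dense and turgid?
#' @return Logical fruit-set indicator (pass-through).
#' @export
fruit_call <- function(turgid) {
  as.logical(turgid)
}

# Select the intraspecific and interspecific arms of a cross table for one
# maternal x paternal direction.
cross_arms <- function(x, direction) {
  maternal <- direction[1]
  paternal <- direction[2]
  intra <- x$maternal_species == maternal & x$treatment == "intra_cross"
  inter <- x$maternal_species == maternal &
    x$paternal_species == paternal & x$treatment == "inter_cross"
  list(
    intra = x[intra, , drop = FALSE],
    inter = x[inter, , drop = FALSE]
  )
}

#' Conspecific and heterospecific success at one post-pollination stage
#'
#' Summarises the hand-pollination data for one maternal x paternal
#' direction into the C (intraspecific arm) and H (interspecific arm)
#' values that feed \code{\link{ri_index}}:
#' \itemize{
#'   \item \code{style}: mean per-pistil proportion
#'     \code{tubes_in_style / tubes_on_stigma};
#'   \item \code{ovary}: mean per-pistil proportion
#'     \code{tubes_in_ovary / tubes_in_style} (pistils with no tube in the
#'     style are excluded from this conditional proportion);
#'   \item \code{fruit}: fruit-set proportion
#'     \code{sum(fruits_set) / sum(flowers_treated)};
#'   \item \code{seed}: pooled large-embryo rate
#'     \code{sum(n_large) / sum(all scored seeds)} over fruits, which
#'     equals the seeds-scored-weighted mean of per-fruit rates.
#' }
#' With \code{mode = "count"} the style/ovary stages use summed raw tube
#' counts and the fruit stage raw fruit counts instead of proportions --
#' a sensitivity mode for unequal pollen loads or flower numbers.
#'
#' @param pistils,fruits,seeds The assay tables (only the one relevant to
#'   \code{stage} is required; others may be \code{NULL}).
#' @param stage One of \code{"style"}, \code{"ovary"}, \code{"fruit"},
#'   \code{"seed"}.
#' @param direction Length-2 character vector \code{c(maternal, paternal)}.
#' @param mode \code{"proportion"} (default) or \code{"count"}.
#' @return Object of class \code{stage_success}: list with \code{stage},
#'   \code{direction}, \code{conspecific}, \code{heterospecific},
#'   \code{n_intra}, \code{n_inter}.
#' @export
stage_success <- function(pistils = NULL, fruits = NULL, seeds = NULL,
                          stage, direction,
                          mode = c("proportion", "count")) {
  stage <- match.arg(stage, CROSS_STAGES)
  mode <- match.arg(mode)
  tab <- switch(stage,
    style = ,
    ovary = pistil_assays(pistils),
    fruit = fruit_records(fruits),
    seed = seed_assays(seeds)
  )
  arms <- cross_arms(tab, direction)
  if (nrow(arms$intra) == 0 || nrow(arms$inter) == 0) {
    stop_undefined(
      "missing intraspecific or interspecific arm; stage not estimable",
      barrier = stage, direction = direction
    )
  }
  value <- function(arm) {
    switch(stage,
      style = if (mode == "proportion") {
        ok <- arm$tubes_on_stigma > 0
        mean(arm$tubes_in_style[ok] / arm$tubes_on_stigma[ok])
      } else {
        sum(arm$tubes_in_style)
      },
      ovary = if (mode == "proportion") {
        ok <- arm$tubes_in_style > 0
        if (!any(ok)) 0 else mean(arm$tubes_in_ovary[ok] / arm$tubes_in_style[ok])
      } else {
        sum(arm$tubes_in_ovary)
      },
      fruit = if (mode == "proportion") {
        sum(arm$fruits_set) / sum(arm$flowers_treated)
      } else {
        sum(arm$fruits_set)
      },
      seed = {
        tot <- sum(arm$n_large + arm$n_small + arm$n_aborted + arm$n_empty)
        if (tot == 0) 0 else sum(arm$n_large) / tot
      }
    )
  }
  structure(
    list(
      stage = stage, direction = direction,
      conspecific = value(arms$intra), heterospecific = value(arms$inter),
      n_intra = nrow(arms$intra), n_inter = nrow(arms$inter)
    ),
    class = "stage_success"
  )
}

#' @export
print.stage_success <- function(x, ...) {
  cat(
    "Stage '", x$stage, "' (", paste(x$direction, collapse = " x "),
    "): C = ", signif(x$conspecific, 4), " (n = ", x$n_intra,
    "), H = ", signif(x$heterospecific, 4), " (n = ", x$n_inter, ")\n",
    sep = ""
  )
  invisible(x)
}

#' RI of one post-pollination stage
#'
#' Applies \code{\link{ri_index}} to a stage's conspecific and
#' heterospecific success.
#'
#' @param success A \code{stage_success} object.
#' @return RI value in \code{[-1, 1]}.
#' @export
stage_ri <- function(success) {
  stopifnot(inherits(success, "stage_success"))
  ri_index(
    C = success$conspecific, H = success$heterospecific,
    barrier = success$stage, direction = success$direction
  )
}
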