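#' habRI: sequential reproductive isolation barriers from field data
#'
#' Tools to quantify reproductive isolation (RI) between co-flowering plant
#' species and decompose it into a sequence of pre- and post-pollination
#' barriers: flowering phenology, pollinator foraging behaviour (ethological
#' isolation), pollen-tube growth through style and ovary, fruit set, and
#' seed (embryo) development.
#'
#' The central index for one barrier is
#' \deqn{RI = 1 - 2 \frac{H}{H + C}}
#' where \eqn{C} is conspecific and \eqn{H} heterospecific reproductive
#' success at that stage.  \code{RI = 1} means complete isolation,
#' \code{0} no isolation, negative values a heterospecific advantage.
#' Barriers act sequentially, so each one's absolute contribution is its
#' incremental effect after all earlier barriers
#' (\code{\link{ri_cumulative}}, \code{\link{ri_contributions}}).
#'
#' The typical entry point for a full analysis is
#' \code{\link{ri_isolation}}; the individual index functions
#' (\code{\link{ri_index}}, \code{\link{ri_phenology}},
#' \code{\link{constancy_index}}, \code{\link{ri_total}}) operate on plain
#' numbers and are exported for direct use.
#'
#' @keywords internal
"_PACKAGE"

# Canonical life-cycle order of barriers; cascades always report in this order.
RI_BARRIERS <- c("phenology", "ethological", "style", "ovary", "fruit", "seed")

#' Signal an undefined-index condition
#'
#' Used when an RI index has a zero denominator (no successes in either
#' arm), so downstream reporting can mark the barrier "not estimable"
#' instead of receiving a sentinel value.
#'
#' @noRd
stop_undefined <- function(message, barrier = NULL, direction = NULL) {
  if (!is.null(barrier)) {
    message <- paste0(message, " [barrier: ", barrier, "]")
  }
  if (!is.null(direction)) {
    message <- paste0(
      message, " [direction: ", paste(direction, collapse = " x "), "]"
    )
  }
  stop(errorCondition(message,
    barrier = barrier, direction = direction,
    class = c("ri_undefined_error", "ri_error")
  ))
}

stop_input <- function(message) {
  stop(errorCondition(message, class = c("ri_input_error", "ri_error")))
}

#' Reproductive isolation index from conspecific and heterospecific success
#'
#' Computes \code{RI = 1 - 2 H / (H + C)} for one barrier, where \code{C}
#' is the conspecific (intraspecific) and \code{H} the heterospecific
#' (interspecific) success.  Counts and rates are interchangeable: the
#' index is invariant to a common scale factor.
#'
#' @param C Non-negative conspecific success (count or rate).  May be a
#'   vector; recycled against \code{H}.
#' @param H Non-negative heterospecific success (count or rate).
#' @param barrier,direction Optional labels used only to annotate the
#'   error when \code{C + H == 0} leaves the index undefined.
#' @return Numeric in \code{[-1, 1]}: 1 iff \code{H == 0}, 0 iff
#'   \code{H == C}, -1 iff \code{C == 0}.
#' @examples
#' ri_index(C = 16, H = 1) # 0.882: strong ethological isolation
#' ri_index(C = 7, H = 7) # 0: no isolation
#' ri_index(C = 0, H = 5) # -1: heterospecific advantage
#' @export
ri_index <- function(C, H, barrier = NULL, direction = NULL) {
  if (!is.numeric(C) || !is.numeric(H)) {
    stop_input("C and H must be numeric")
  }
  if (any(C < 0, na.rm = TRUE) || any(H < 0, na.rm = TRUE)) {
    stop_input("C and H must be non-negative")
  }
  n <- max(length(C), length(H))
  C <- rep_len(C, n)
  H <- rep_len(H, n)
  if (any(C + H == 0, na.rm = TRUE)) {
    stop_undefined(
      "RI undefined: conspecific and heterospecific success are both zero",
      barrier = barrier, direction = direction
    )
  }
  1 - 2 * H / (H + C)
}

#' Phenological isolation from shared and unshared flowering time
#'
#' \code{RI_pheno = 1 - S / (S + U)} where \code{S} is the proportion of a
#' focal species' flowering time shared with the partner and \code{U} the
#' unshared proportion.  With \code{S + U = 1} (proportions of the focal
#' window) this is simply \code{U}.
#'
#' @param S Shared flowering proportion in \code{[0, 1]} (or a
#'   \code{phenology_overlap} object from \code{\link{overlap_proportions}},
#'   in which case \code{U} is taken from it).
#' @param U Unshared flowering proportion in \code{[0, 1]}.
#' @return Numeric in \code{[0, 1]}: 1 for fully disjoint flowering,
#'   0 for complete overlap.
#' @examples
#' ri_phenology(S = 0, U = 0.4) # disjoint: 1
#' ri_phenology(S = 0.5, U = 0.5) # half overlap: 0.5
#' @export
ri_phenology <- function(S, U) {
  if (inherits(S, "phenology_overlap")) {
    U <- S$U
    S <- S$S
  }
  if (any(S < 0) || any(U < 0) || any(S > 1) || any(U > 1)) {
    stop_input("S and U must be proportions in [0, 1]")
  }
  if (any(S + U == 0)) {
    stop_undefined("phenological RI undefined: S + U = 0",
      barrier = "phenology"
    )
  }
  1 - S / (S + U)
}

#' Pollinator constancy index
#'
#' Contrasts the observed proportion of conspecific moves \code{c} within
#' a foraging bout against the expectation \code{e = p^2 + (1 - p)^2}
#' under random foraging, where \code{p} is the proportion of visits to
#' one of the two plant species:
#' \deqn{CI = \frac{c - e}{c + e - 2ce}}
#' CI = 1 is complete constancy, 0 matches the random expectation, -1 is
#' perfect alternation.  When a bout visits a single species, \code{p}
#' is 0 or 1 so \code{e = 1} and \code{c = 1}; the denominator vanishes
#' and the limit value 1 is returned.
#'
#' @param c Observed proportion of conspecific transitions, in \code{[0, 1]}.
#' @param p Proportion of visits to one of the two species, in \code{[0, 1]}.
#' @return CI in \code{[-1, 1]}.
#' @examples
#' constancy_index(c = 1, p = 0.5) # complete constancy: 1
#' constancy_index(c = 0.5, p = 0.5) # matches random expectation: 0
#' constancy_index(c = 0, p = 0.5) # perfect alternation: -1
#' @export
constancy_index <- function(c, p) {
  if (any(c < 0) || any(c > 1) || any(p < 0) || any(p > 1)) {
    stop_input("c and p must be proportions in [0, 1]")
  }
  e <- p^2 + (1 - p)^2
  denom <- c + e - 2 * c * e
  out <- ifelse(denom == 0 & c == 1, 1, (c - e) / denom)
  if (any(denom == 0 & c != 1)) {
    stop_undefined("constancy index undefined: zero denominator with c != 1")
  }
  out
}

#' Total reproductive isolation weighted by shared/unshared flowering
#'
#' Combines end-to-end heterospecific and conspecific success over the
#' shared (\code{Hs}, \code{Cs}) and unshared (\code{Hu}, \code{Cu})
#' flowering periods, weighted by the shared and unshared flowering
#' proportions \code{S} and \code{U}:
#' \deqn{RI_{total} = 1 - 2\frac{S H_s + U H_u}{(S H_s + U H_u) + (S C_s + U C_u)}}
#' By construction \code{Hu = 0} when the heterospecific partner cannot
#' pollinate outside the shared period, which is the default.  With
#' \code{U = 0} this reduces exactly to \code{\link{ri_index}(Cs, Hs)}.
#'
#' @param S,U Shared/unshared flowering proportions.
#' @param Hs,Cs Heterospecific/conspecific end-to-end success during the
#'   shared flowering period (products of per-stage success proportions).
#' @param Hu,Cu The same for the unshared period.  Defaults: \code{Hu = 0},
#'   \code{Cu = Cs}.
#' @return RI value in \code{[-1, 1]}.
#' @examples
#' ri_total(S = 1, U = 0, Hs = 0.1, Cs = 0.9) # = ri_index(0.9, 0.1) = 0.8
#' ri_total(S = 0.4, U = 0.6, Hs = 0, Cs = 0.8) # no heterospecific success: 1
#' @export
ri_total <- function(S, U, Hs, Cs, Hu = 0, Cu = Cs) {
  vals <- c(S, U, Hs, Cs, Hu, Cu)
  if (any(vals < 0)) stop_input("all components must be non-negative")
  het <- S * Hs + U * Hu
  con <- S * Cs + U * Cu
  if (het + con == 0) {
    stop_undefined("total RI undefined: zero denominator")
  }
  1 - 2 * het / (het + con)
}

#' Cumulative isolation along a sequence of barriers
#'
#' Barriers act in life-cycle order; each one can only remove gene flow
#' not already blocked by earlier barriers.  The cumulative strength after
#' barrier \code{i} follows the sequential discounting recurrence
#' \deqn{RI_{1,i} = RI_{1,i-1} + RI_i (1 - RI_{1,i-1}), \quad RI_{1,0} = 0.}
#' A barrier with \code{RI = 1} makes the cumulative value exactly 1,
#' where it stays.  For all-non-negative inputs the result equals
#' \code{1 - prod(1 - ri)}.
#'
#' @param ri Numeric vector of per-barrier RI values in \code{[-1, 1]},
#'   in the order the barriers act.
#' @return Numeric vector of cumulative values \code{RI[1,i]}, same length.
#' @examples
#' ri_cumulative(c(0.605, 0.667, 1.0)) # complete isolation by barrier 3
#' @export
ri_cumulative <- function(ri) {
  if (length(ri) == 0) {
    return(numeric(0))
  }
  if (any(!is.finite(ri)) || any(ri < -1) || any(ri > 1)) {
    stop_input("per-barrier RI values must be finite and in [-1, 1]")
  }
  out <- numeric(length(ri))
  acc <- 0
  for (i in seq_along(ri)) {
    acc <- if (ri[i] == 1) 1 else acc + ri[i] * (1 - acc)
    out[i] <- acc
  }
  out
}

#' Absolute contribution of each barrier to total isolation
#'
#' Telescoping differences of the cumulative sequence:
#' \code{AC_i = RI[1,i] - RI[1,i-1]} with \code{RI[1,0] = 0}, so the
#' contributions sum exactly to the final cumulative (total) RI.
#'
#' @param cumulative Cumulative RI sequence from \code{\link{ri_cumulative}}.
#' @return Numeric vector of per-barrier absolute contributions.
#' @examples
#' ri_contributions(c(0.5, 0.75, 1.0)) # 0.5, 0.25, 0.25
#' @export
ri_contributions <- function(cumulative) {
  if (length(cumulative) == 0) {
    return(numeric(0))
  }
  diff(c(0, cumulative))
}

#' Asymmetry of a barrier between reciprocal cross directions
#'
#' The absolute difference between the RI values of the two reciprocal
#' directions of a species pair.
#'
#' @param ri_forward,ri_reverse RI values in \code{[-1, 1]} for the two
#'   directions.
#' @return Non-negative asymmetry value.
#' @examples
#' ri_asymmetry(0.882, 0.647) # 0.235
#' @export
ri_asymmetry <- function(ri_forward, ri_reverse) {
  abs(ri_forward - ri_reverse)
}
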