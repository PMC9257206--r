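# Bundled example data from a published field study of three sympatric
# Habenaria orchids (H. limprichtii "lim", H. davidii "dav", H. delavayi
# "del") in the Lijiang area of Yunnan: hawkmoth floral-transition counts
# from two-species choice arrays, per-pollinator bout summaries, and the
# study's per-barrier RI values and totals for the six cross directions.
# The del-involving ethological entries are not estimable because those
# species pairs do not share pollinators.

#' Hawkmoth floral-transition counts from the Habenaria choice arrays
#'
#' Transition counts between the two species of each experimental array:
#' \code{lim_dav} (H. limprichtii vs H. davidii, totals 16/14/3/1 over 11
#' bouts) and \code{lim_del} (H. limprichtii vs H. delavayi, totals
#' 10/13/2/2 over 9 bouts).
#'
#' @param array \code{"lim_dav"} or \code{"lim_del"}.
#' @param pollinator Optional pollinator label to restrict to; default
#'   sums over pollinators.
#' @return A \code{transition_table} (2 x 2 count matrix).
#' @examples
#' ethological_ri(habenaria_transitions("lim_dav"), focal = "lim") # 0.882
#' @export
habenaria_transitions <- function(array = c("lim_dav", "lim_del"),
                                  pollinator = NULL) {
  array <- match.arg(array)
  path <- system.file("extdata", "habenaria_transitions.csv",
    package = "habRI", mustWork = TRUE
  )
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw <- raw[raw$array == array, , drop = FALSE]
  if (!is.null(pollinator)) {
    raw <- raw[raw$pollinator == pollinator, , drop = FALSE]
    if (nrow(raw) == 0) stop_input("unknown pollinator for this array")
  }
  species <- strsplit(array, "_")[[1]]
  tab <- matrix(0L, 2, 2, dimnames = list(from = species, to = species))
  for (i in seq_len(nrow(raw))) {
    tab[raw$from[i], raw$to[i]] <- tab[raw$from[i], raw$to[i]] +
      as.integer(raw$count[i])
  }
  structure(tab, class = c("transition_table", "matrix"))
}

#' Per-pollinator bout summaries from the Habenaria choice arrays
#'
#' Bout counts (total and with at least one interspecific transition) and
#' the published constancy summaries per pollinator and array.  The
#' published mean/SD for pollinators with mixed bouts cannot be
#' re-derived without the unpublished per-bout visit sequences; they are
#' carried for reference only.
#'
#' @return Data frame with columns \code{array}, \code{pollinator},
#'   \code{n_bouts}, \code{n_inter_bouts}, \code{ci_mean}, \code{ci_sd}.
#' @export
habenaria_pollinators <- function() {
  path <- system.file("extdata", "habenaria_pollinators.csv",
    package = "habRI", mustWork = TRUE
  )
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published per-barrier RI ladders for the Habenaria species pairs
#'
#' The study's per-barrier RI values for the six maternal x paternal
#' directions, in cascade order.  The style stage was not reported
#' separately (pollen-tube success was scored at the ovary), and the
#' ethological barrier is not estimable for the dav/del pair (no shared
#' pollinators); those entries are \code{NA}.
#'
#' @return Data frame with columns \code{maternal}, \code{paternal},
#'   \code{barrier}, \code{ri}.
#' @examples
#' lad <- habenaria_ri_ladders()
#' subset(lad, maternal == "lim" & paternal == "del")
#' @export
habenaria_ri_ladders <- function() {
  dirs <- list(
    c("lim", "dav"), c("dav", "lim"),
    c("lim", "del"), c("del", "lim"),
    c("dav", "del"), c("del", "dav")
  )
  ri <- list(
    c(0.026, 0.882, NA, -0.006, -0.004, 0.044),
    c(0.011, 0.647, NA, 0.029, 0.002, -0.013),
    c(0.605, 0.667, NA, 0.798, 1, 1),
    c(0.559, 0.733, NA, 0.500, 1, 1),
    c(0.667, NA, NA, 0.913, 1, 1),
    c(0.558, NA, NA, 0.450, 1, 1)
  )
  do.call(rbind, Map(function(d, r) {
    data.frame(
      maternal = d[1], paternal = d[2],
      barrier = RI_BARRIERS, ri = r,
      stringsAsFactors = FALSE
    )
  }, dirs, ri))
}

#' Published total RI values for the Habenaria cross directions
#'
#' @return Data frame with columns \code{maternal}, \code{paternal},
#'   \code{ri_total}.
#' @export
habenaria_totals <- function() {
  data.frame(
    maternal = c("lim", "dav", "lim", "del", "dav", "del"),
    paternal = c("dav", "lim", "del", "lim", "del", "dav"),
    ri_total = c(0.895, 0.660, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}
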