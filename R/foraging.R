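# Pollinator foraging bouts in two-species choice arrays: transition
# tables, ethological isolation, per-pollinator constancy, and the
# likelihood-ratio G-test of intra- vs interspecific transitions.

#' Construct a list of foraging bouts from a long-format visit table
#'
#' @param visits Data frame with one row per flower visit and columns
#'   \code{bout_id}, \code{pollinator}, \code{visit_order},
#'   \code{plant_species}.
#' @param species Optional character vector of the two array species; when
#'   given, any other visit label is a validation error naming the bout.
#' @return A list of bouts, each a list with \code{bout_id},
#'   \code{pollinator} and the ordered character vector \code{visits};
#'   class \code{foraging_bouts}.
#' @export
foraging_bouts <- function(visits, species = NULL) {
  need <- c("bout_id", "pollinator", "visit_order", "plant_species")
  miss <- setdiff(need, names(visits))
  if (length(miss) > 0) {
    stop_input(paste(
      "visit table missing column(s):",
      paste(miss, collapse = ", ")
    ))
  }
  if (!is.null(species)) {
    bad <- !(visits$plant_species %in% species)
    if (any(bad)) {
      stop_input(paste0(
        "unknown plant species '",
        visits$plant_species[which(bad)[1]], "' in bout '",
        visits$bout_id[which(bad)[1]], "'"
      ))
    }
  }
  split_idx <- split(seq_len(nrow(visits)), visits$bout_id)
  bouts <- lapply(split_idx, function(i) {
    i <- i[order(visits$visit_order[i])]
    list(
      bout_id = as.character(visits$bout_id[i[1]]),
      pollinator = as.character(visits$pollinator[i[1]]),
      visits = as.character(visits$plant_species[i])
    )
  })
  structure(unname(bouts), class = "foraging_bouts")
}

#' Count floral transitions across foraging bouts
#'
#' Each pair of consecutive visits within a bout is one transition;
#' single-visit bouts contribute none.  Transitions never span bouts.
#'
#' @param bouts A \code{foraging_bouts} list (or plain list of bouts).
#' @param species Character vector of the two array species, giving row
#'   and column order; defaults to the sorted labels seen in the data.
#' @return A 2 x 2 integer matrix of class \code{transition_table};
#'   \code{x[from, to]} counts transitions from species \code{from} to
#'   species \code{to}.
#' @export
count_transitions <- function(bouts, species = NULL) {
  if (length(bouts) == 0) stop_input("no foraging bouts")
  labels <- unique(unlist(lapply(bouts, `[[`, "visits")))
  if (is.null(species)) species <- sort(labels)
  if (length(species) != 2) {
    stop_input("a transition table needs exactly two array species")
  }
  unknown <- setdiff(labels, species)
  if (length(unknown) > 0) {
    offender <- vapply(
      bouts,
      function(b) any(b$visits %in% unknown), logical(1)
    )
    stop_input(paste0(
      "unknown plant species '", unknown[1], "' in bout '",
      bouts[[which(offender)[1]]]$bout_id, "'"
    ))
  }
  tab <- matrix(0L, 2, 2, dimnames = list(from = species, to = species))
  for (b in bouts) {
    v <- b$visits
    if (length(v) < 2) next
    from <- v[-length(v)]
    to <- v[-1]
    for (k in seq_along(from)) {
      tab[from[k], to[k]] <- tab[from[k], to[k]] + 1L
    }
  }
  structure(tab, class = c("transition_table", "matrix"))
}

#' @export
print.transition_table <- function(x, ...) {
  cat("Floral transition counts (from row to column):\n")
  print(unclass(x))
  intra <- sum(diag(unclass(x)))
  cat(
    "intraspecific:", intra, " interspecific:", sum(x) - intra, "\n"
  )
  invisible(x)
}

#' Ethological isolation from a transition table
#'
#' For the focal species, conspecific success \code{C} is the number of
#' focal-to-focal transitions and heterospecific success \code{H} the
#' number of transitions from the other species into the focal one --
#' i.e. the moves that deliver heterospecific pollen to focal stigmas.
#' \code{\link{ri_index}} is then applied.
#'
#' @param table A \code{transition_table}.
#' @param focal Focal species label (must be a dimname of \code{table}).
#' @return Ethological RI value in \code{[-1, 1]}.
#' @examples
#' bouts <- foraging_bouts(data.frame(
#'   bout_id = 1, pollinator = "moth", visit_order = 1:4,
#'   plant_species = c("a", "a", "b", "a")
#' ))
#' ethological_ri(count_transitions(bouts), focal = "a")
#' @export
ethological_ri <- function(table, focal) {
  species <- rownames(table)
  if (!(focal %in% species)) {
    stop_input(paste0("focal species '", focal, "' not in transition table"))
  }
  other <- setdiff(species, focal)
  C <- table[focal, focal]
  H <- table[other, focal]
  if (C + H == 0) {
    stop_undefined("no transitions into the focal species",
      barrier = "ethological", direction = c(focal, other)
    )
  }
  ri_index(C = C, H = H, barrier = "ethological", direction = c(focal, other))
}

#' Constancy index of a single foraging bout
#'
#' \code{c} is the proportion of conspecific transitions within the bout
#' and \code{p} the proportion of the bout's visits to the first array
#' species; \code{\link{constancy_index}} is applied.  A bout visiting a
#' single species has \code{p} of 0 or 1, hence \code{e = 1} and
#' \code{c = 1}, and takes the limit value \code{CI = 1}.
#'
#' @param bout One bout (list with a \code{visits} vector).
#' @param species The two array species; first element defines \code{p}.
#'   Defaults to the sorted labels in the bout.
#' @return CI in \code{[-1, 1]}, or \code{NA_real_} for a bout with fewer
#'   than two visits (not estimable, excluded from summaries).
#' @export
bout_constancy <- function(bout, species = NULL) {
  v <- bout$visits
  if (length(v) < 2) {
    return(NA_real_)
  }
  if (is.null(species)) species <- sort(unique(v))
  c_obs <- mean(v[-length(v)] == v[-1])
  p <- mean(v == species[1])
  constancy_index(c = c_obs, p = p)
}

#' Per-pollinator constancy summary (mean and SD of CI)
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' per-bout constancy over each pollinator's estimable bouts.  A single
#' estimable bout is reported with SD 0 and flagged by \code{n_bouts = 1}.
#'
#' @param bouts A \code{foraging_bouts} list.
#' @param pollinator Optional single pollinator label to restrict to.
#' @param species Passed to \code{\link{bout_constancy}}.
#' @return Data frame with columns \code{pollinator}, \code{n_bouts}
#'   (estimable bouts), \code{mean_ci}, \code{sd_ci}.
#' @export
constancy_summary <- function(bouts, pollinator = NULL, species = NULL) {
  if (!is.null(pollinator)) {
    bouts <- Filter(function(b) b$pollinator == pollinator, bouts)
  }
  if (length(bouts) == 0) stop_input("no bouts for the requested pollinator")
  ci <- vapply(bouts, bout_constancy, numeric(1), species = species)
  who <- vapply(bouts, `[[`, character(1), "pollinator")
  keep <- !is.na(ci)
  if (!any(keep)) stop_input("no estimable bouts (all have < 2 visits)")
  ci <- ci[keep]
  who <- who[keep]
  out <- do.call(rbind, lapply(split(ci, who), function(x) {
    data.frame(
      n_bouts = length(x),
      mean_ci = mean(x),
      sd_ci = if (length(x) > 1) stats::sd(x) else 0,
      stringsAsFactors = FALSE
    )
  }))
  out <- cbind(
    data.frame(pollinator = rownames(out), stringsAsFactors = FALSE),
    out
  )
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio G-test of intra- versus interspecific transitions
#'
#' Goodness-of-fit G-test of the observed intraspecific and interspecific
#' transition counts against equal expected counts:
#' \deqn{G = 2 \sum_i O_i \ln(O_i / E_i), \quad E_i = (O_1 + O_2)/2}
#' with 1 degree of freedom; zero cells contribute nothing to the sum.
#' No continuity correction is applied.
#'
#' @param intra,inter Non-negative transition counts.
#' @return An object of class \code{htest} with the G statistic,
#'   \code{df = 1}, and the chi-square p-value.
#' @examples
#' g_test_transitions(30, 4) # G = 22.50, p < 0.001
#' @export
g_test_transitions <- function(intra, inter) {
  if (intra < 0 || inter < 0) stop_input("counts must be non-negative")
  if (intra + inter == 0) stop_input("both counts are zero")
  obs <- c(intra, inter)
  expd <- rep(sum(obs) / 2, 2)
  terms <- ifelse(obs > 0, obs * log(obs / expd), 0)
  G <- 2 * sum(terms)
  p <- stats::pchisq(G, df = 1, lower.tail = FALSE)
  structure(
    list(
      statistic = c(G = G), parameter = c(df = 1), p.value = p,
      method = "Likelihood-ratio G-test (equal expected counts)",
      data.name = sprintf("intra = %g, inter = %g", intra, inter),
      observed = obs, expected = expd
    ),
    class = "htest"
  )
}
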