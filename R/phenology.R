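# Flowering phenology: species-level windows and temporal isolation.
#
# A species' flowering window is the union, over individuals, of the closed
# day-of-year intervals [first_flower_day, last_flower_day].  Day resolution
# is integer days; field observations are typically made every few days, so
# sub-day precision would be spurious.

#' Validate a table of per-individual flowering records
#'
#' @param records Data frame with columns \code{individual_id},
#'   \code{species}, \code{site}, \code{first_flower_day},
#'   \code{last_flower_day}.  Days are integer day-of-year; ISO dates are
#'   accepted and converted.
#' @return The validated data frame with integer day columns.
#' @export
flowering_records <- function(records) {
  need <- c(
    "individual_id", "species", "site",
    "first_flower_day", "last_flower_day"
  )
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    stop_input(paste(
      "flowering records missing column(s):",
      paste(miss, collapse = ", ")
    ))
  }
  records$first_flower_day <- as_day_of_year(records$first_flower_day)
  records$last_flower_day <- as_day_of_year(records$last_flower_day)
  bad <- which(records$first_flower_day > records$last_flower_day)
  if (length(bad) > 0) {
    stop_input(paste0(
      "first_flower_day > last_flower_day in row(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  records
}

# Accept integer day-of-year or ISO-8601 dates.
as_day_of_year <- function(x) {
  if (inherits(x, "Date")) {
    return(as.integer(format(x, "%j")))
  }
  if (is.character(x)) {
    num <- suppressWarnings(as.numeric(x))
    if (all(!is.na(num))) {
      x <- num
    } else {
      d <- as.Date(x)
      if (any(is.na(d))) stop_input("unparseable flowering dates")
      return(as.integer(format(d, "%j")))
    }
  }
  if (!is.numeric(x) || any(is.na(x)) || any(x != round(x)) ||
    any(x < 1) || any(x > 366)) {
    stop_input("flowering days must be integer day-of-year in 1..366")
  }
  as.integer(x)
}

#' Build a species-level flowering window
#'
#' The window is the union over individuals of their closed flowering
#' intervals; both the first and last observed flowering day count.
#'
#' @param records Flowering records (see \code{\link{flowering_records}}).
#' @param species Species label to build the window for.
#' @param site Optional site label; if given, only that site's records are
#'   used (default pools all sites).
#' @return An object of class \code{species_window}: list with
#'   \code{species} and \code{days} (sorted unique integer days).
#' @export
build_window <- function(records, species, site = NULL) {
  records <- flowering_records(records)
  keep <- records$species == species
  if (!is.null(site)) keep <- keep & records$site == site
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop_input(paste0("no flowering records for species '", species, "'"))
  }
  days <- sort(unique(unlist(Map(
    seq.int, rec$first_flower_day, rec$last_flower_day
  ))))
  structure(list(species = species, days = as.integer(days)),
    class = "species_window"
  )
}

#' @export
print.species_window <- function(x, ...) {
  cat(
    "Flowering window for", x$species, "-", length(x$days), "days,",
    "day", min(x$days), "to", max(x$days), "\n"
  )
  invisible(x)
}

#' Shared and unshared flowering proportions for a focal species
#'
#' \code{S} is the fraction of the focal species' flowering days also
#' flowered by the partner; \code{U = 1 - S} is the unshared fraction.
#' Proportions are of the focal window, so the measure is directional.
#'
#' @param focal,partner \code{species_window} objects from
#'   \code{\link{build_window}}.
#' @return Object of class \code{phenology_overlap}: list with \code{S},
#'   \code{U}, \code{focal_species}, \code{partner_species}.
#' @export
overlap_proportions <- function(focal, partner) {
  stopifnot(
    inherits(focal, "species_window"),
    inherits(partner, "species_window")
  )
  if (length(focal$days) == 0 || length(partner$days) == 0) {
    stop_input("empty flowering window")
  }
  shared <- sum(focal$days %in% partner$days)
  S <- shared / length(focal$days)
  structure(
    list(
      S = S, U = 1 - S,
      focal_species = focal$species, partner_species = partner$species
    ),
    class = "phenology_overlap"
  )
}

#' Directional phenological isolation for a species pair
#'
#' Builds both species' windows and applies \code{\link{ri_phenology}} in
#' each direction.  The two directional values differ whenever the window
#' lengths differ.
#'
#' @param records Flowering records.
#' @param species_a,species_b Species labels.
#' @param site Optional site restriction (default pools sites).
#' @return Data frame with one row per direction: \code{focal},
#'   \code{partner}, \code{S}, \code{U}, \code{ri_pheno}.
#' @export
phenology_ri_pair <- function(records, species_a, species_b, site = NULL) {
  wa <- build_window(records, species_a, site = site)
  wb <- build_window(records, species_b, site = site)
  ab <- overlap_proportions(wa, wb)
  ba <- overlap_proportions(wb, wa)
  data.frame(
    focal = c(species_a, species_b),
    partner = c(species_b, species_a),
    S = c(ab$S, ba$S),
    U = c(ab$U, ba$U),
    ri_pheno = c(ri_phenology(ab), ri_phenology(ba)),
    stringsAsFactors = FALSE
  )
}
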