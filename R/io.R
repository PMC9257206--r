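# CSV ingestion with schema validation, simulated-dataset export with a
# reproducibility manifest, and report assembly.

read_validated_csv <- function(path, validator, what) {
  if (!file.exists(path)) {
    stop_input(paste0(what, " file not found: ", path))
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(validator(x), ri_input_error = function(e) {
    stop_input(paste0("in ", path, ": ", conditionMessage(e)))
  })
}

#' Read field observation tables from CSV
#'
#' Schema-validating readers for the five observation tables.  Flowering
#' days may be ISO-8601 dates or integer day-of-year.  Bout files may be
#' long format (one row per visit: \code{bout_id}, \code{pollinator},
#' \code{visit_order}, \code{plant_species}) or one row per bout with a
#' \code{visits} column of ';'-delimited species labels.
#'
#' @param path Path to a CSV file with a header row.
#' @return The validated table; \code{read_bouts_csv} returns a
#'   \code{foraging_bouts} list.
#' @name read_csv_tables
NULL

#' @rdname read_csv_tables
#' @export
read_flowering_csv <- function(path) {
  read_validated_csv(path, flowering_records, "flowering")
}

#' @rdname read_csv_tables
#' @export
read_bouts_csv <- function(path) {
  if (!file.exists(path)) stop_input(paste0("bout file not found: ", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("visits" %in% names(x)) {
    long <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
      v <- strsplit(x$visits[i], ";", fixed = TRUE)[[1]]
      data.frame(
        bout_id = x$bout_id[i], pollinator = x$pollinator[i],
        visit_order = seq_along(v), plant_species = v,
        stringsAsFactors = FALSE
      )
    }))
    return(foraging_bouts(long))
  }
  foraging_bouts(x)
}

#' @rdname read_csv_tables
#' @export
read_pistils_csv <- function(path) {
  read_validated_csv(path, pistil_assays, "pistil")
}

#' @rdname read_csv_tables
#' @export
read_fruits_csv <- function(path) {
  read_validated_csv(path, fruit_records, "fruit")
}

#' @rdname read_csv_tables
#' @export
read_seeds_csv <- function(path) {
  read_validated_csv(path, seed_assays, "seed")
}

#' Write a simulated dataset to a directory of CSV files
#'
#' Writes \code{phenology.csv}, \code{bouts.csv}, \code{pistils.csv},
#' \code{fruits.csv}, \code{seeds.csv} in the schemas the readers expect,
#' plus \code{manifest.json} recording the seed, the full configuration,
#' the package version and the MD5 checksum of every file -- enough to
#' reproduce the run exactly.  Identical seeds produce byte-identical
#' files.
#'
#' @param config An \code{ri_sim_config}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated_dataset <- function(config, dir) {
  stopifnot(inherits(config, "ri_sim_config"))
  dat <- simulate_dataset(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    phenology = "phenology.csv", bouts = "bouts.csv",
    pistils = "pistils.csv", fruits = "fruits.csv", seeds = "seeds.csv"
  )
  tables <- list(
    phenology = dat$phenology, bouts = dat$visits,
    pistils = dat$pistils, fruits = dat$fruits, seeds = dat$seeds
  )
  for (nm in names(files)) {
    utils::write.csv(tables[[nm]], file.path(dir, files[[nm]]),
      row.names = FALSE, quote = FALSE
    )
  }
  manifest <- list(
    seed = config$seed,
    species = config$species,
    config = config[c("phenology", "foraging", "crosses")],
    package_version = as.character(utils::packageVersion("habRI")),
    files = as.list(tools::md5sum(file.path(dir, unname(files))))
  )
  names(manifest$files) <- unname(files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a simulated (or equivalently formatted) dataset directory
#'
#' @param dir Directory containing the five CSV tables written by
#'   \code{\link{write_simulated_dataset}} (missing tables are allowed
#'   and returned as \code{NULL}, degrading analyses to the estimable
#'   barriers).
#' @return List with \code{phenology}, \code{bouts}, \code{pistils},
#'   \code{fruits}, \code{seeds}.
#' @export
read_dataset <- function(dir) {
  maybe <- function(file, reader) {
    p <- file.path(dir, file)
    if (file.exists(p)) reader(p) else NULL
  }
  list(
    phenology = maybe("phenology.csv", read_flowering_csv),
    bouts = maybe("bouts.csv", read_bouts_csv),
    pistils = maybe("pistils.csv", read_pistils_csv),
    fruits = maybe("fruits.csv", read_fruits_csv),
    seeds = maybe("seeds.csv", read_seeds_csv)
  )
}

#' Write the cascade report for a fitted isolation object
#'
#' Emits, per direction, a CSV table (barrier, RI, cumulative RI,
#' absolute contribution, asymmetry versus the reverse direction) and a
#' JSON report carrying both total variants, plus a long-format table of
#' all directions ready for plotting a contribution figure.
#'
#' @param fit An \code{ri_isolation} object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the long-format report data frame.
#' @export
write_cascade_report <- function(fit, dir) {
  stopifnot(inherits(fit, "ri_isolation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- list()
  for (nm in names(fit$cascades)) {
    cascade <- fit$cascades[[nm]]
    tab <- cascade$table
    tab$asymmetry <- fit$asymmetry$asymmetry
    slug <- gsub(" x ", "_x_", nm, fixed = TRUE)
    utils::write.csv(tab, file.path(dir, paste0("cascade_", slug, ".csv")),
      row.names = FALSE
    )
    jsonlite::write_json(
      list(
        direction = cascade$direction,
        barriers = tab,
        total_sequential = cascade$total,
        total_weighted = cascade$total_weighted
      ),
      file.path(dir, paste0("cascade_", slug, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    )
    tab$direction <- nm
    long[[nm]] <- tab
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL
  utils::write.csv(long, file.path(dir, "contributions_long.csv"),
    row.names = FALSE
  )
  invisible(long)
}
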