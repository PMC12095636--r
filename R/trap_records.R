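#' @name trap-records
#' @title Trap monitoring records
#'
#' @description
#' A trap record is one trapping session: a count of eggs or adults of one
#' species collected at one trap on one date, together with the trap's site
#' and its role (treated with sterile-male releases, or untreated control).
#' Records are held in an ordinary data frame with a fixed seven-column
#' schema and validated invariants: counts are non-negative integers,
#' categorical fields are drawn from closed vocabularies, and
#' (trap_id, date, species, stage) is unique within a dataset.
NULL

.zone_levels    <- c("treated", "control")
.species_levels <- c("aegypti", "albopictus", "aedes_spp")
.stage_levels   <- c("egg", "adult")
.record_cols    <- c("trap_id", "site_id", "zone", "species", "stage", "date", "count")

#' Validate and construct trap records
#'
#' @param df data frame with columns `trap_id`, `site_id`, `zone`
#'   (`"treated"`/`"control"`), `species` (`"aegypti"`, `"albopictus"`,
#'   `"aedes_spp"`), `stage` (`"egg"`/`"adult"`), `date` (Date or ISO-8601
#'   string) and `count` (non-negative integer).
#' @return the validated data frame with class `"trap_records"`.
#' @export
trap_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.record_cols, names(df))
  if (length(missing))
    stop("trap records are missing columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[.record_cols]
  problems <- .validate_record_fields(df)
  if (length(problems)) stop("invalid trap records:\n", paste(problems, collapse = "\n"))
  df$trap_id <- as.character(df$trap_id)
  df$site_id <- as.character(df$site_id)
  df$date <- as.Date(df$date)
  df$count <- as.integer(round(df$count))
  key <- paste(df$trap_id, df$date, df$species, df$stage, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop(sprintf("duplicate (trap_id, date, species, stage) key at row %d: %s / %s / %s / %s",
                 dup, df$trap_id[dup], df$date[dup], df$species[dup], df$stage[dup]))
  }
  class(df) <- c("trap_records", "data.frame")
  df
}

.validate_record_fields <- function(df, line_offset = 0L) {
  problems <- character(0)
  note <- function(rows, field, what) {
    if (length(rows))
      sprintf("row %d, field '%s': %s", rows + line_offset, field, what)
    else character(0)
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  problems <- c(problems, note(bad, "count", "must be a non-negative integer"))
  dts <- suppressWarnings(as.Date(as.character(df$date), format = "%Y-%m-%d"))
  problems <- c(problems, note(which(is.na(dts)), "date", "must be an ISO-8601 date (YYYY-MM-DD)"))
  for (spec in list(c("zone", ".zone_levels"), c("species", ".species_levels"),
                    c("stage", ".stage_levels"))) {
    lv <- get(spec[2])
    bad <- which(!(as.character(df[[spec[1]]]) %in% lv))
    problems <- c(problems, note(bad, spec[1],
                                 paste0("must be one of: ", paste(lv, collapse = ", "))))
  }
  problems
}

#' Read trap records from a CSV file
#'
#' The file must be comma-separated UTF-8 with a header declaring the seven
#' schema columns. Every row is either parsed or rejected with its line
#' number and offending field; duplicate (trap_id, date, species, stage)
#' keys raise an integrity error.
#'
#' @param path path to a CSV file.
#' @return a `trap_records` data frame.
#' @export
read_trap_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(.record_cols, names(raw))
  if (length(missing))
    stop("header of ", path, " is missing columns: ", paste(missing, collapse = ", "))
  problems <- .validate_record_fields(raw, line_offset = 1L)  # +1 for header line
  if (length(problems))
    stop("parse errors in ", path, ":\n", paste(problems, collapse = "\n"))
  raw$count <- as.integer(raw$count)
  trap_records(raw)
}

#' Write trap records to CSV
#'
#' @param records a `trap_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trap_records <- function(records, path) {
  records <- trap_records(records)
  out <- as.data.frame(records)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Release events
#'
#' @param df data frame with columns `date`, `site_id`, `n_males`, `boosted`.
#' @return validated data frame with class `"release_events"`.
#' @export
release_events <- function(df) {
  stopifnot(is.data.frame(df), all(c("date", "site_id", "n_males", "boosted") %in% names(df)))
  df$date <- as.Date(df$date)
  if (any(is.na(df$date))) stop("release events: invalid date")
  if (any(df$n_males < 0 | df$n_males != round(df$n_males)))
    stop("release events: n_males must be a non-negative integer")
  df$n_males <- as.integer(df$n_males)
  df$boosted <- as.logical(df$boosted)
  class(df) <- c("release_events", "data.frame")
  df
}

#' @rdname release_events
#' @param path CSV path.
#' @export
read_release_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  release_events(utils::read.csv(path))
}

#' @rdname release_events
#' @param events a `release_events` data frame.
#' @export
write_release_events <- function(events, path) {
  out <- as.data.frame(release_events(events))
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Site specification
#'
#' A trial site: identifier, role, boundary polygon in planar metric
#' coordinates, and declared area in hectares. The polygon must be simple
#' and its area must agree with the declared `area_ha` within 15%.
#'
#' @param site_id identifier.
#' @param role `"treated"` or `"control"`.
#' @param boundary two-column matrix of polygon vertices (meters), open ring.
#' @param area_ha declared area in hectares.
#' @return an object of class `"site_spec"`.
#' @export
site_spec <- function(site_id, role, boundary, area_ha) {
  role <- match.arg(role, .zone_levels)
  boundary <- as.matrix(boundary)
  stopifnot(ncol(boundary) == 2, nrow(boundary) >= 3)
  if (!is_simple_polygon(boundary)) stop("site boundary must be a simple closed polygon")
  if (area_ha <= 0) stop("area_ha must be positive")
  poly_ha <- polygon_area(boundary) / 1e4
  if (abs(poly_ha - area_ha) > 0.15 * area_ha)
    stop(sprintf("polygon area (%.2f ha) disagrees with declared area_ha (%.2f) by more than 15%%",
                 poly_ha, area_ha))
  structure(list(site_id = as.character(site_id), role = role,
                 boundary = boundary, area_ha = area_ha),
            class = "site_spec")
}
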