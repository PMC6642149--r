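#' Construct and validate a table of shell observation records
#'
#' One row per photographed snail. Required columns: `record_id` (unique
#' opaque string), `latitude`/`longitude` (decimal degrees WGS84),
#' `day_number` (integer days since the season start, 1 = 1 April), `colour`
#' (`"yellow"`, `"pink"`, `"brown"`), `banding_code` (five-slot code, or `NA`
#' when the bands could not be scored), `view` (`"lateral"` or `"apical"`)
#' and `dark_lip` (logical; `FALSE` marks a photograph without a visible dark
#' aperture lip, i.e. possibly the white-lipped *C. hortensis*).
#'
#' @param df data.frame with the columns above (extra columns are kept).
#' @return `df` validated, with class `c("shell_records", "data.frame")`.
#' @export
shell_records <- function(df) {
  req <- c("record_id", "latitude", "longitude", "day_number",
           "colour", "banding_code", "view", "dark_lip")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  stopifnot(all(df$latitude >= -90 & df$latitude <= 90),
            all(df$longitude >= -180 & df$longitude <= 180),
            all(df$day_number >= 1))
  bad <- setdiff(unique(df$colour), c("yellow", "pink", "brown"))
  if (length(bad)) stop("unknown colour level(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$view), c("lateral", "apical"))
  if (length(bad)) stop("unknown view level(s): ", paste(bad, collapse = ", "))
  df$record_id <- as.character(df$record_id)
  df$dark_lip <- as.logical(df$dark_lip)
  class(df) <- unique(c("shell_records", class(df)))
  df
}

#' Read an observation table from CSV
#'
#' Expects header columns `record_id, latitude, longitude, date, colour,
#' banding_code, view, dark_lip` with ISO-8601 dates. `day_number` is derived
#' as days since 1 April of the record's own year (1 April = day 1), the start
#' of the recording season.
#'
#' @param path CSV file path.
#' @return a `shell_records` data.frame.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character",
                                       banding_code = "character"))
  if ("date" %in% names(df) && !"day_number" %in% names(df)) {
    d <- as.Date(df$date)
    origin <- as.Date(paste0(format(d, "%Y"), "-04-01"))
    df$day_number <- as.integer(d - origin) + 1L
  }
  df$banding_code[df$banding_code %in% c("", "NA")] <- NA_character_
  shell_records(df)
}

#' Write an observation table to CSV
#'
#' Inverse of [read_observations()]; `day_number` is written back as an
#' ISO-8601 date in `season_year` (day 1 = 1 April).
#'
#' @param records a `shell_records` data.frame.
#' @param path output CSV path.
#' @param season_year calendar year used to reconstruct dates.
#' @export
write_observations <- function(records, path, season_year = 2017L) {
  df <- as.data.frame(records)
  df$date <- format(as.Date(paste0(season_year, "-04-01")) + df$day_number - 1L)
  cols <- c("record_id", "latitude", "longitude", "date", "colour",
            "banding_code", "view", "dark_lip")
  utils::write.csv(df[, c(cols, setdiff(names(df), c(cols, "day_number")))],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Exclusion boxes where the white-lipped congener C. hortensis is common
# enough that photographs without a visible dark lip cannot be trusted to be
# C. nemoralis. Strict inequalities on decimal degrees; boundary points are
# retained.
.hortensis_boxes <- list(
  limburg   = function(lat, lon) lat < 51.2,
  groningen = function(lat, lon) lat > 53 & lon > 6.5,
  nijmegen  = function(lat, lon) lat > 51.8 & lat < 52 & lon > 5.75
)

#' Filter observation records into analysis sets
#'
#' Applies the data-cleaning rules in order: (1) duplicate `record_id`s are
#' collapsed to their first occurrence; (2) records past the season end are
#' dropped; (3) records *without* a visible dark lip are dropped if they fall
#' inside one of three regions where the white-lipped *C. hortensis* is
#' relatively common (southern Limburg: latitude < 51.2; north-east Groningen:
#' latitude > 53 and longitude > 6.5; the area around Nijmegen:
#' 51.8 < latitude < 52 and longitude > 5.75) — dark-lip records are retained
#' everywhere. The survivors form the colour set. The banding set additionally
#' requires a lateral view (apical photographs hide the lower bands), a
#' parseable banding code, and one of the four main banding types.
#'
#' @param records a `shell_records` data.frame (see [shell_records()]).
#' @param season_end_day last retained day number (default 198 = 15 October
#'   for a 1-April season start).
#' @return list with elements `colour` (records for ground-colour analyses),
#'   `banding` (subset also usable for banding analyses, with columns
#'   `main_type` and `n_bands`/`n_fusions` added), and `rejections`
#'   (data.frame `record_id`, `rule`, `scope` — `scope` is `"record"` for
#'   rows dropped everywhere and `"banding"` for rows kept in the colour set
#'   only).
#' @export
filter_records <- function(records, season_end_day = 198L) {
  records <- shell_records(as.data.frame(records))
  rej <- list()
  note <- function(ids, rule, scope) {
    if (length(ids))
      rej[[length(rej) + 1L]] <<- data.frame(record_id = ids, rule = rule,
                                             scope = scope,
                                             stringsAsFactors = FALSE)
  }

  dup <- duplicated(records$record_id)
  note(records$record_id[dup], "duplicate_id", "record")
  records <- records[!dup, , drop = FALSE]

  late <- records$day_number > season_end_day
  note(records$record_id[late], "past_season_end", "record")
  records <- records[!late, , drop = FALSE]

  for (box in names(.hortensis_boxes)) {
    inside <- .hortensis_boxes[[box]](records$latitude, records$longitude)
    drop <- !records$dark_lip & inside
    note(records$record_id[drop], paste0("no_dark_lip_", box), "record")
    records <- records[!drop, , drop = FALSE]
  }

  colour_set <- records

  apical <- records$view == "apical"
  note(records$record_id[apical], "apical_view", "banding")
  banding <- records[!apical, , drop = FALSE]

  pat <- lapply(banding$banding_code, function(code) {
    if (is.na(code)) return(NULL)
    tryCatch(parse_banding_code(code), error = function(e) NULL)
  })
  ok <- !vapply(pat, is.null, TRUE)
  note(banding$record_id[!ok], "banding_code_missing_or_malformed", "banding")
  banding <- banding[ok, , drop = FALSE]
  pat <- pat[ok]

  banding$main_type <- vapply(pat, `[[`, "", "main_type")
  banding$n_bands <- vapply(pat, function(p) length(p$bands_present), 1L)
  banding$n_fusions <- vapply(pat, `[[`, 1L, "fusion_count")
  other <- banding$main_type == "other"
  note(banding$record_id[other], "banding_type_other", "banding")
  banding <- banding[!other, , drop = FALSE]

  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(record_id = character(0), rule = character(0),
               scope = character(0), stringsAsFactors = FALSE)
  rownames(colour_set) <- rownames(banding) <- NULL
  list(colour = colour_set, banding = banding, rejections = rejections)
}

#' Write the filter rejection log as CSV
#'
#' @param rejections the `rejections` element of [filter_records()] output.
#' @param path output CSV path.
#' @export
write_rejection_log <- function(rejections, path) {
  utils::write.csv(rejections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
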