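# Bundled example data: published tracking summaries of Common Woodpigeons
# tagged in Hesse (Germany), Lisbon (Portugal) and south-western France --
# a GPS transmitter deployment table and the annual-schedule table of
# first/last transmitted signals per annual-cycle phase. These small tables
# are the worked inputs for the phenology arithmetic and for
# migration-incidence counts.

#' Bundled GPS transmitter deployment table
#'
#' One row per GPS-tagged woodpigeon: deployment and end-of-transmission
#' dates, capture region, and the bird's migration annotation (`"Yes (FR)"`
#' for migrants wintering in France, `"Yes (DE)"` for within-Germany
#' movers, `"No"` for residents, `"-"` for birds tagged too late to
#' classify).
#'
#' @return data.frame with `deploy_date` and `end_date` parsed as `Date`.
#' @export
woodpigeonDeployments <- function() {
  df <- utils::read.csv(system.file("extdata", "gps_deployments.csv",
                                    package = "palumbus"),
                        stringsAsFactors = FALSE,
                        colClasses = c(transmitter_id = "character"))
  df$deploy_date <- as.Date(df$deploy_date)
  df$end_date <- as.Date(df$end_date)
  df
}

#' Bundled annual-schedule phase table
#'
#' First and last transmitted signal per annual-cycle phase for tracked
#' woodpigeons (12 Argos birds tagged on wintering grounds, 7 migrating GPS
#' birds tagged on breeding grounds), rows in temporal order per
#' individual. `start_truncated` marks phases opened by the start of
#' transmission (tagging) or with an unobserved boundary; `end_truncated`
#' marks phases cut off by the end of transmission. `complete` is derived:
#' both boundaries observed.
#'
#' @return data.frame compatible with [phenologySummary()] and
#'   [phenologyDurations()].
#' @export
woodpigeonPhases <- function() {
  df <- utils::read.csv(system.file("extdata", "annual_schedule_phases.csv",
                                    package = "palumbus"),
                        stringsAsFactors = FALSE,
                        colClasses = c(individual_id = "character"))
  df$first_signal <- as.Date(df$first_signal)
  df$last_signal <- as.Date(df$last_signal)
  df$complete <- !df$start_truncated & !df$end_truncated &
    !is.na(df$first_signal) & !is.na(df$last_signal)
  df
}

#' Identifiers of the long-distance (France) GPS migrants in a phase table
#'
#' @param phases A phase table ([woodpigeonPhases()] format).
#' @return Character vector of individual ids whose wintering area lies in
#'   France.
#' @export
franceMigrants <- function(phases) {
  w <- phases[phases$phase == "wintering" & grepl("^FR", phases$area), ,
              drop = FALSE]
  unique(w$individual_id)
}

#' Count migration strategies among the tagged birds
#'
#' @param deployments A [woodpigeonDeployments()] data.frame.
#' @param country Capture country to restrict to (default `"DE"`).
#' @return list: `n_birds`, `n_migrants_abroad` (annotation `"Yes (FR)"`),
#'   `n_migrants_within` (`"Yes (DE)"`), `n_residents`.
#' @export
countMigrants <- function(deployments, country = "DE") {
  sub <- deployments[deployments$country == country, , drop = FALSE]
  list(n_birds = nrow(sub),
       n_migrants_abroad = sum(grepl("^Yes \\(FR\\)", sub$migration)),
       n_migrants_within = sum(grepl("^Yes \\(DE\\)", sub$migration)),
       n_residents = sum(sub$migration == "No"))
}

#' Migration incidence per winter season
#'
#' For each winter season, the denominator is the number of birds (captured
#' in `country`) whose transmission window spans the season start
#' (1 November): deployed before it and still transmitting on it. The
#' numerator is the number of those birds with an autumn-migration interval
#' opening between August of the season year and January of the next. The
#' percentage is rounded to one decimal.
#'
#' @param deployments A [woodpigeonDeployments()] data.frame.
#' @param phases A phase table with autumn-migration rows
#'   ([woodpigeonPhases()] or [segmentAnnualCycle()] output).
#' @param country Capture country to restrict to (default `"DE"`).
#' @return data.frame `winter`, `n_tracked`, `n_migrating`, `pct_migrating`.
#' @export
migrationIncidence <- function(deployments, phases, country = "DE") {
  dep <- deployments[deployments$country == country, , drop = FALSE]
  years <- sort(unique(c(as.integer(format(dep$deploy_date, "%Y")),
                         as.integer(format(dep$end_date, "%Y")))))
  aut <- phases[phases$phase == "autumn_migration" &
                  !is.na(phases$first_signal), , drop = FALSE]
  out <- NULL
  for (y in seq(min(years), max(years))) {
    nov1 <- as.Date(sprintf("%d-11-01", y))
    tracked <- dep$deploy_date < nov1 & dep$end_date >= nov1
    if (!any(tracked)) next
    onset <- as.Date(aut$first_signal)
    inSeason <- onset >= as.Date(sprintf("%d-08-01", y)) &
      onset <= as.Date(sprintf("%d-01-31", y + 1))
    migIds <- unique(aut$individual_id[inSeason])
    nMig <- sum(dep$transmitter_id[tracked] %in% migIds)
    out <- rbind(out, data.frame(
      winter = sprintf("%d/%02d", y, (y + 1L) %% 100),
      n_tracked = sum(tracked), n_migrating = nMig,
      pct_migrating = round(100 * nMig / sum(tracked), 1),
      stringsAsFactors = FALSE))
  }
  out
}
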