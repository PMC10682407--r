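# Station-table I/O, the per-row index pipeline and the deterministic
# synthetic-weather fixture generator.

.CANON_COLS <- c("Ta", "RH", "VP", "v", "height", "N", "G", "Tmrt",
                 "lat", "lon", "elev", "doy", "hour", "tz", "time")

.FIXTURE_PRESETS <- list(
  temperate = list(lat = 48.0, lon = 7.8, elev = 270, tz = 1,
                   ta_mean = 15, ta_amp = 6, ta_sd = 1.2,
                   rh_mean = 65, rh_slope = 2.5, rh_min = 20, rh_max = 100,
                   v_mean = 3, v_sd = 1.2, start_doy = 170),
  `hot-humid` = list(lat = 23.5, lon = 121.5, elev = 30, tz = 8,
                     ta_mean = 28, ta_amp = 4, ta_sd = 0.8,
                     rh_mean = 78, rh_slope = 2.0, rh_min = 40, rh_max = 100,
                     v_mean = 2.5, v_sd = 1.0, start_doy = 200),
  cold = list(lat = 60.2, lon = 25.0, elev = 50, tz = 2,
              ta_mean = -5, ta_amp = 3, ta_sd = 1.0,
              rh_mean = 80, rh_slope = 1.5, rh_min = 40, rh_max = 100,
              v_mean = 4, v_sd = 1.5, start_doy = 20))

#' Generate a deterministic synthetic station series
#'
#' Hourly pseudo-random weather emulating a plausible mid-latitude
#' diurnal station record: sinusoidal diurnal air temperature with AR(1)
#' noise, relative humidity anti-correlated with temperature, bounded
#' AR(1) wind at 10 m, and cloud octas as a persistent Markov chain.
#' The site is fixed per climate preset.  The same seed yields a
#' bit-identical table.
#'
#' @param seed Integer seed.
#' @param days Number of simulated days (>= 1).
#' @param climate One of `"temperate"`, `"hot-humid"`, `"cold"`.
#' @return A `data.frame` (class `station_table`) with columns `doy`,
#'   `hour`, `tz`, `lat`, `lon`, `elev`, `Ta`, `RH`, `v`, `height`, `N`.
#' @examples
#' head(generate_fixture_series(seed = 1, days = 2))
#' @export
generate_fixture_series <- function(seed, days,
                                    climate = c("temperate", "hot-humid",
                                                "cold")) {
  climate <- match.arg(climate)
  if (days < 1) stop("days must be >= 1")
  p <- .FIXTURE_PRESETS[[climate]]
  n <- days * 24
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  hour <- rep(0:23, days)
  doy <- p$start_doy + rep(seq_len(days) - 1, each = 24)
  diurnal <- -cos(2 * pi * (hour - 2) / 24)    # minimum near 05 LT

  ar1 <- function(n, sd, phi = 0.8) {
    x <- numeric(n)
    eps <- stats::rnorm(n, 0, sd * sqrt(1 - phi ^ 2))
    x[1] <- stats::rnorm(1, 0, sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i]
    x
  }
  ta <- p$ta_mean + p$ta_amp * diurnal + ar1(n, p$ta_sd)
  rh <- pmin(p$rh_max, pmax(p$rh_min,
                            p$rh_mean - p$rh_slope * (ta - p$ta_mean) +
                              ar1(n, 4)))
  v <- pmin(12, pmax(0.3, p$v_mean + ar1(n, p$v_sd)))

  # persistent cloud octas: stay with prob 0.7, else random walk step
  N <- integer(n)
  N[1] <- sample(0:8, 1)
  u <- stats::runif(n)
  step <- sample(c(-2L, -1L, 1L, 2L), n, replace = TRUE)
  for (i in 2:n) {
    N[i] <- if (u[i] < 0.7) N[i - 1] else
      min(8L, max(0L, N[i - 1] + step[i]))
  }

  out <- data.frame(doy = doy, hour = hour, tz = p$tz, lat = p$lat,
                    lon = p$lon, elev = p$elev, Ta = round(ta, 2),
                    RH = round(rh, 1), v = round(v, 2), height = 10,
                    N = N)
  class(out) <- c("station_table", "data.frame")
  out
}

#' Read a station CSV into a validated table
#'
#' Parses a UTF-8 CSV with header into canonical columns (`Ta`, `RH`,
#' `VP`, `v`, `height`, `N`, `G`, `Tmrt`, `lat`, `lon`, `elev`, `doy`,
#' `hour`, `tz`; matching is case-insensitive).  Humidity is normalised
#' so both VP and RH are present, and wind is reduced to 1.1 m through
#' [wind_at_height()] using the `height` column (default 10 m, the
#' standard measurement height).  Rows violating the record invariants
#' are dropped with a logged reason, never silently.  An ISO-8601
#' `time` column is parsed to `doy`/`hour` when present.
#'
#' @param path CSV file path.
#' @param column_map Named character vector renaming input columns to
#'   canonical ones, e.g. `c(temp = "Ta")`, applied before validation.
#' @param default_height Wind measurement height used when the table
#'   has no `height` column, m.
#' @return A `station_table` data frame with wind at 1.1 m in column
#'   `v` (original speed kept in `v_orig`).
#' @export
read_station_csv <- function(path, column_map = NULL,
                             default_height = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    for (from in names(column_map)) {
      idx <- which(tolower(names(df)) == tolower(from))
      if (length(idx)) names(df)[idx[1]] <- column_map[[from]]
    }
  }
  canon <- match(tolower(names(df)), tolower(.CANON_COLS))
  names(df)[!is.na(canon)] <- .CANON_COLS[canon[!is.na(canon)]]

  if ("time" %in% names(df) && !all(c("doy", "hour") %in% names(df))) {
    tt <- as.POSIXlt(df$time, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS",
                                    "%Y-%m-%dT%H:%M",
                                    "%Y-%m-%d %H:%M"))
    df$doy <- tt$yday + 1
    df$hour <- tt$hour + tt$min / 60 + tt$sec / 3600
    if (!"tz" %in% names(df)) df$tz <- 0
  }

  if (!"Ta" %in% names(df)) stop("missing mandatory column: Ta")
  if (!any(c("RH", "VP") %in% names(df))) {
    stop("missing mandatory column: one of RH or VP")
  }
  if (!"v" %in% names(df)) stop("missing mandatory column: v")

  if (!"height" %in% names(df)) df$height <- default_height

  keep <- rep(TRUE, nrow(df))
  reasons <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    bad <- NULL
    if (!is.finite(r$Ta)) bad <- "Ta not finite"
    else if ("RH" %in% names(df) && is.finite(r$RH) &&
             (r$RH < 0 || r$RH > 100)) bad <- "RH out of range"
    else if ("VP" %in% names(df) && is.finite(r$VP) && r$VP < 0) {
      bad <- "VP negative"
    } else if (!is.finite(r$v) || r$v < 0) bad <- "v invalid"
    else if (r$height <= 0) bad <- "height not positive"
    if (!is.null(bad)) {
      keep[i] <- FALSE
      reasons[i] <- bad
    }
  }
  if (any(!keep)) {
    for (i in which(!keep)) {
      message(sprintf("read_station_csv: row %d skipped (%s)", i,
                      reasons[i]))
    }
    df <- df[keep, , drop = FALSE]
  }

  if (!"VP" %in% names(df)) df$VP <- NA_real_
  if (!"RH" %in% names(df)) df$RH <- NA_real_
  fill_vp <- is.na(df$VP) & !is.na(df$RH)
  df$VP[fill_vp] <- vp_rh_exchange(df$Ta[fill_vp], RH = df$RH[fill_vp])
  fill_rh <- is.na(df$RH) & !is.na(df$VP)
  df$RH[fill_rh] <- suppressWarnings(
    vp_rh_exchange(df$Ta[fill_rh], VP = df$VP[fill_rh]))

  df$v_orig <- df$v
  df$v <- wind_at_height(df$v, df$height, target_height = 1.1)
  rownames(df) <- NULL
  class(df) <- c("station_table", "data.frame")
  df
}

#' Write a station table to CSV
#'
#' @param table A `station_table` (or plain data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Compute thermal indices for every row of a station table
#'
#' Per-row pipeline: humidity exchange, wind reduction (done at read
#' time), optional Tmrt simulation, then the requested index engines.
#' Requested outputs are appended as documented columns (`PMV`, `Teq`,
#' `hclo`; `SET`; `PET` plus `PET_*`; `mPET` plus `mPET_*`; `UTCI`).
#' Per-row failures are recorded in an `error` column and the run
#' continues.
#'
#' @param table A `station_table` (e.g. from [read_station_csv()] or
#'   [generate_fixture_series()]).  Note wind must already be at 1.1 m;
#'   [generate_fixture_series()] returns 10 m winds, which
#'   [compute_indices()] reduces using the `height` column.
#' @param subj A [subject_profile()].
#' @param indices Character subset of `c("PMV", "SET", "PET", "mPET",
#'   "UTCI")`.
#' @param simulate_tmrt Logical; simulate Tmrt from the site columns
#'   (`lat`, `lon`, `elev`, `doy`, `hour`, `tz`, optional `N`, `G`)
#'   instead of requiring a `Tmrt` column.
#' @param config A [radiation_config()] used when `simulate_tmrt` (its
#'   `N`/`G` are overridden per row by table columns when present).
#' @return The table with appended index columns and an `error` column.
#' @export
compute_indices <- function(table, subj = subject_profile(),
                            indices = c("PET", "UTCI"),
                            simulate_tmrt = FALSE,
                            config = radiation_config()) {
  indices <- match.arg(indices, c("PMV", "SET", "PET", "mPET", "UTCI"),
                       several.ok = TRUE)
  df <- as.data.frame(table)
  if (nrow(df) == 0) stop("empty table")
  if (!simulate_tmrt && !"Tmrt" %in% names(df)) {
    stop("Tmrt column required unless simulate_tmrt = TRUE")
  }
  if (simulate_tmrt &&
      !all(c("lat", "lon", "doy", "hour", "tz") %in% names(df))) {
    stop("simulate_tmrt = TRUE requires site columns lat, lon, doy, hour, tz")
  }
  if (!"v_orig" %in% names(df) && "height" %in% names(df)) {
    df$v_orig <- df$v
    df$v <- wind_at_height(df$v, df$height, target_height = 1.1)
  }
  if (!"VP" %in% names(df)) {
    if (!"RH" %in% names(df)) stop("table needs a VP or RH column")
    df$VP <- vp_rh_exchange(df$Ta, RH = df$RH)
  }

  out_cols <- list()
  add <- function(lst, prefix = NULL) {
    for (nm in names(lst)) {
      col <- if (is.null(prefix) || nm == prefix) nm else
        paste0(prefix, "_", nm)
      if (is.null(out_cols[[col]])) {
        out_cols[[col]] <<- rep(NA_real_, nrow(df))
      }
      out_cols[[col]][i] <<- lst[[nm]]
    }
  }
  errors <- rep(NA_character_, nrow(df))

  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    res <- tryCatch({
      tmrt <- if (simulate_tmrt) {
        cfg <- config
        if ("N" %in% names(df) && is.finite(r$N)) cfg$N <- r$N
        if ("G" %in% names(df) && is.finite(r$G)) cfg$G <- r$G
        st <- site_time(r$lon, r$lat,
                        if ("elev" %in% names(df)) r$elev else 0,
                        day_of_year = r$doy, hour_of_day = r$hour,
                        timezone_offset = r$tz)
        tmrt_calc(Ta = r$Ta, VP = r$VP, v = r$v, site = st,
                  config = cfg)$Tmrt
      } else r$Tmrt
      rec <- meteo_record(Ta = r$Ta, VP = r$VP, v = r$v, Tmrt = tmrt)
      row_out <- list(Tmrt_used = tmrt)
      if ("PMV" %in% indices) {
        pm <- pmv_calc(rec, subj)
        row_out <- c(row_out, list(PMV = pm$PMV, Teq = pm$Teq,
                                   hclo = pm$hclo))
      }
      if ("SET" %in% indices) {
        row_out <- c(row_out, list(SET = set_star(rec, subj)))
      }
      if ("PET" %in% indices) {
        pe <- suppressWarnings(pet_calc(rec, subj))
        row_out <- c(row_out, list(
          PET = pe$PET, PET_Tcore = pe$Tcore, PET_Tsk = pe$Tsk,
          PET_Tcl = pe$Tcl, PET_wetsk = pe$wetsk,
          PET_metabolic_rate = pe$metabolic_rate,
          PET_respiratory_flux = pe$respiratory_flux,
          PET_convective_flux = pe$convective_flux,
          PET_radiative_flux = pe$radiative_flux,
          PET_diffuse_flux = pe$diffuse_flux,
          PET_sweating_flux = pe$sweating_flux))
      }
      if ("mPET" %in% indices) {
        mp <- suppressWarnings(mpet_calc(rec, subj))
        row_out <- c(row_out, list(
          mPET = mp$mPET, mPET_Tcore = mp$Tcore, mPET_Tsk_mm = mp$Tsk_mm,
          mPET_Tcl = mp$Tcl, mPET_vpts = mp$vpts, mPET_wetsk = mp$wetsk,
          mPET_icl = mp$icl, mPET_sk_wetted_mm = mp$sk_wetted_mm,
          mPET_metabolic_rate = mp$metabolic_rate,
          mPET_wet_sum = mp$wet_sum,
          mPET_convective_flux = mp$convective_flux,
          mPET_radiative_flux = mp$radiative_flux,
          mPET_respiratory_flux = mp$respiratory_flux,
          mPET_energy_balance = mp$energy_balance))
      }
      if ("UTCI" %in% indices) {
        row_out <- c(row_out,
                     list(UTCI = suppressMessages(
                       utci_calc(rec, clamp = TRUE))))
      }
      row_out
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[i] <- res
    } else {
      add(res)
    }
  }

  for (col in names(out_cols)) df[[col]] <- out_cols[[col]]
  df$error <- errors
  class(df) <- c("station_table", "data.frame")
  df
}
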