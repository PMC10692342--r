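#' Daily mean THI per weather station
#'
#' Computes the hourly THI from temperature and relative humidity and
#' averages it within each station and calendar day.
#'
#' @param weather data.frame with columns `station_id`, `timestamp`
#'   (`POSIXct`, `Date`, or a string parseable by [as.POSIXct()]), `temp_c`
#'   and `rh_pct`. `(station_id, timestamp)` pairs must be unique.
#' @return data.frame with columns `station_id`, `date` (`Date`), `thi`
#'   (daily mean of hourly THI) and `n_hours` (hours contributing).
#' @export
daily_thi <- function(weather) {
  stopifnot(is.data.frame(weather),
            all(c("station_id", "timestamp", "temp_c", "rh_pct") %in% names(weather)))
  ts <- weather$timestamp
  if (!inherits(ts, "POSIXct") && !inherits(ts, "Date")) {
    ts <- as.POSIXct(ts, tz = "UTC")
  }
  if (anyDuplicated(paste(weather$station_id, format(ts)))) {
    stop("duplicated (station_id, timestamp) pairs in weather table")
  }
  date <- as.Date(ts)
  thi <- thi_hourly(weather$temp_c, weather$rh_pct)
  key <- paste(weather$station_id, date, sep = "\r")
  sums <- rowsum(cbind(thi = thi, n = 1), key, reorder = TRUE)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(
    station_id = vapply(parts, `[[`, "", 1L),
    date = as.Date(vapply(parts, `[[`, "", 2L)),
    thi = sums[, "thi"] / sums[, "n"],
    n_hours = as.integer(sums[, "n"]),
    row.names = NULL
  )
  out[order(out$station_id, out$date), , drop = FALSE]
}

# Day-offset windows before birth: WK1 spans offsets 0..7 (8 days, literal
# reading of the printed "0 to 7 d"); WK2..WK12 span the usual 7-day blocks
# 8..14, 15..21, ..., 78..84.
week_offsets <- function(week) {
  stopifnot(week >= 1L, week <= 12L)
  if (week == 1L) 0:7 else ((week - 1L) * 7L + 1L):(week * 7L)
}

# daily THI values per calf for day offsets 0..max_offset before birth,
# as a calves x (max_offset+1) matrix (NA where the station has no record)
calf_daily_matrix <- function(daily, calves, assignment, max_offset = 84L) {
  st_map <- assignment$station_id[match(calves$herd_id, assignment$herd_id)]
  if (anyNA(st_map)) {
    stop("no weather station assigned for herd(s): ",
         paste(unique(calves$herd_id[is.na(st_map)]), collapse = ", "))
  }
  stations <- sort(unique(daily$station_id))
  day0 <- min(daily$date)
  ndays <- as.integer(max(daily$date) - day0) + 1L
  D <- matrix(NA_real_, nrow = length(stations), ncol = ndays)
  D[cbind(match(daily$station_id, stations),
          as.integer(daily$date - day0) + 1L)] <- daily$thi
  si <- match(st_map, stations)
  if (anyNA(si)) {
    stop("assigned station(s) absent from daily THI table: ",
         paste(unique(st_map[is.na(si)]), collapse = ", "))
  }
  bcol <- as.integer(as.Date(calves$birth_date) - day0) + 1L
  out <- matrix(NA_real_, nrow = nrow(calves), ncol = max_offset + 1L)
  for (off in 0:max_offset) {
    col <- bcol - off
    ok <- col >= 1L & col <= ndays
    out[ok, off + 1L] <- D[cbind(si[ok], col[ok])]
  }
  rownames(out) <- as.character(calves$calf_id)
  colnames(out) <- paste0("d", 0:max_offset)
  out
}

#' Weekly prenatal THI means
#'
#' Averages daily THI over the twelve gestation windows before birth
#' (WK1 = day offsets 0-7 before birth, WK2 = 8-14, ..., WK12 = 78-84,
#' day 0 being the birth date). A window mean is reported as `NA` when fewer
#' than `coverage` of its days have a daily THI value.
#'
#' @param daily Output of [daily_thi()].
#' @param calves data.frame with columns `calf_id`, `herd_id`, `birth_date`.
#' @param assignment Herd-to-station map from [assign_nearest_station()].
#' @param coverage Minimum fraction of days with data per window
#'   (default 0.8).
#' @return Numeric matrix (calves x 12) with columns `wk1`..`wk12`; rows
#'   named by `calf_id`. Attribute `n_missing` counts missing window values.
#' @export
weekly_window_means <- function(daily, calves, assignment, coverage = 0.8) {
  M <- calf_daily_matrix(daily, calves, assignment, max_offset = 84L)
  out <- matrix(NA_real_, nrow = nrow(calves), ncol = 12L,
                dimnames = list(as.character(calves$calf_id),
                                paste0("wk", 1:12)))
  for (w in 1:12) {
    cols <- week_offsets(w) + 1L
    sub <- M[, cols, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    mu <- rowSums(sub, na.rm = TRUE) / n_ok
    mu[n_ok < coverage * length(cols)] <- NA_real_
    out[, w] <- mu
  }
  structure(out, n_missing = sum(is.na(out)))
}

#' First principal component of late-gestation daily THI
#'
#' Column-standardised (correlation-matrix) principal component analysis of
#' the calves x days matrix of daily THI over the last weeks of gestation,
#' returning the score on the first component. Rows with any missing day are
#' dropped (their scores are `NA`); the eigenvector sign is fixed so that the
#' score correlates positively with the row-mean THI, making "high PC1 = hot"
#' reproducible.
#'
#' @param mat Numeric matrix, calves in rows, day offsets in columns.
#' @return Numeric vector of PC1 scores, `NA` for dropped rows. Attributes:
#'   `n_dropped` (rows with missing days), `var_explained` (fraction of
#'   total standardised variance on PC1), `rotation` (the loading vector).
#' @export
pc1_daily_thi <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  complete <- stats::complete.cases(mat)
  if (sum(complete) < 2L) {
    stop("need at least 2 complete rows for principal component analysis (have ",
         sum(complete), ")")
  }
  X <- mat[complete, , drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  scores_c <- rep(0, nrow(X))
  rot <- rep(0, ncol(mat))
  varex <- 0
  if (any(keep)) {
    Z <- scale(X[, keep, drop = FALSE])
    sv <- svd(Z, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    s <- as.numeric(Z %*% v)
    rm_ <- rowMeans(X)
    if (stats::sd(s) > 0 && stats::sd(rm_) > 0 &&
        stats::cor(s, rm_) < 0) {
      s <- -s
      v <- -v
    }
    scores_c <- s
    rot[keep] <- v
    varex <- sv$d[1L]^2 / sum(sv$d^2)
  }
  out <- rep(NA_real_, nrow(mat))
  out[complete] <- scores_c
  names(out) <- rownames(mat)
  structure(out, n_dropped = sum(!complete), var_explained = varex,
            rotation = rot)
}

#' Per-calf prenatal heat-load covariates
#'
#' End-to-end construction of the gestation covariates: daily THI per
#' station, nearest-station assignment, weekly window means WK1-WK12, the
#' first principal component of daily THI over the last `pc_days` days of
#' gestation (day offsets `0 .. pc_days - 1`), and the scaled versions of
#' all 13 covariates.
#'
#' @param weather Hourly weather table (see [daily_thi()]).
#' @param stations,herds Coordinate tables (see [assign_nearest_station()]).
#' @param calves data.frame with `calf_id`, `herd_id`, `birth_date`.
#' @param coverage Window coverage threshold, see [weekly_window_means()].
#' @param pc_days Number of late-gestation days entering the PCA
#'   (default 56, i.e. offsets 0-55).
#' @param thi_anchors,pc1_anchors Scaling specs (lists with
#'   `min_val`/`max_val`).
#' @return data.frame with columns `calf_id`, `wk1..wk12`, `pc1`,
#'   `s_wk1..s_wk12`, `s_pc1`.
#' @export
gestation_covariates <- function(weather, stations, herds, calves,
                                 coverage = 0.8, pc_days = 56L,
                                 thi_anchors = thi_scaling(),
                                 pc1_anchors = pc1_scaling()) {
  daily <- daily_thi(weather)
  assignment <- assign_nearest_station(herds, stations)
  wk <- weekly_window_means(daily, calves, assignment, coverage = coverage)
  M <- calf_daily_matrix(daily, calves, assignment, max_offset = pc_days - 1L)
  pc1 <- pc1_daily_thi(M)
  out <- data.frame(calf_id = calves$calf_id, wk, pc1 = as.numeric(pc1),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (w in 1:12) {
    out[[paste0("s_wk", w)]] <- scale_covariate(out[[paste0("wk", w)]],
                                                thi_anchors)
  }
  out$s_pc1 <- scale_covariate(out$pc1, pc1_anchors)
  out
}
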