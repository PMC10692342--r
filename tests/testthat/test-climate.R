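test_that("hourly THI matches the defining formula at hand-evaluated points", {
  expect_equal(thi_hourly(25, 50), 71.775)
  # at T = 130/9 the humidity factor (1.8 T - 26) vanishes: THI = 58
  expect_equal(thi_hourly(130 / 9, 0), 58)
  expect_equal(thi_hourly(130 / 9, 37), 58)
  expect_equal(thi_hourly(130 / 9, 100), 58)
  # at RH = 100 the (0.55 - 0.0055 RH) factor vanishes: THI = 1.8 T + 32
  expect_equal(thi_hourly(0, 100), 32)
  expect_equal(thi_hourly(c(25, 0), c(50, 100)), c(71.775, 32))
})

test_that("THI input validation names the offending record", {
  expect_error(thi_hourly(65, 50), "temperature out of range")
  expect_error(thi_hourly(c(20, 25), c(50, 120)), "humidity out of range.*2")
})

test_that("THI is monotone in T below saturation and in RH above 130/9 degC", {
  tt <- seq(-20, 45, by = 0.5)
  for (rh in c(0, 30, 60, 99)) {
    expect_true(all(diff(thi_hourly(tt, rh)) > 0))
  }
  rh <- seq(0, 100, by = 1)
  # dTHI/dRH = 0.0055 * (1.8 T - 26): positive above 130/9, negative below
  expect_true(all(diff(thi_hourly(20, rh)) > 0))
  expect_true(all(diff(thi_hourly(10, rh)) < 0))
})

test_that("covariate scaling maps anchors and midpoints and clamps outside", {
  expect_equal(scale_covariate(c(17, 44.5, 72), thi_scaling()), c(-1, 0, 1))
  expect_equal(scale_covariate(-2, pc1_scaling()), 0)
  expect_equal(scale_covariate(c(10, 80), thi_scaling()), c(-1, 1))
  v <- seq(17, 72, length.out = 23)
  expect_equal(unscale_covariate(scale_covariate(v, thi_scaling()),
                                 thi_scaling()), v)
  expect_true(all(abs(scale_covariate(stats::runif(100, -50, 150),
                                      thi_scaling())) <= 1))
})

test_that("haversine distance has the expected geometry", {
  expect_equal(haversine_km(12, 34, 12, 34), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-10)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-10)
  expect_equal(haversine_km(52.5, 13.4, 53.6, 10.0),
               haversine_km(53.6, 10.0, 52.5, 13.4))
  expect_error(haversine_km(95, 0, 0, 0), "latitude")
})

test_that("haversine agrees with an independent geodesy implementation", {
  skip_if_not_installed("geosphere")
  set.seed(1)
  a <- cbind(stats::runif(20, -180, 180), stats::runif(20, -85, 85))
  b <- cbind(stats::runif(20, -180, 180), stats::runif(20, -85, 85))
  ref <- geosphere::distHaversine(a, b, r = 6371000) / 1000
  expect_equal(haversine_km(a[, 2], a[, 1], b[, 2], b[, 1]), ref,
               tolerance = 1e-9)
})

test_that("nearest-station assignment matches exhaustive search with tie rule", {
  herds <- data.frame(herd_id = c("H1", "H2", "H3"),
                      lat = c(52.1, 53.0, 52.6), lon = c(11.2, 12.5, 13.9))
  one <- data.frame(station_id = "S9", lat = 50, lon = 10)
  expect_equal(unique(assign_nearest_station(herds, one)$station_id), "S9")

  st <- data.frame(station_id = c("S1", "S2"),
                   lat = c(52.1, 53.0), lon = c(11.2, 12.5))
  asn <- assign_nearest_station(herds, st)
  expect_equal(asn$station_id[1], "S1")
  expect_equal(asn$distance_km[1], 0)

  set.seed(3)
  herds2 <- data.frame(herd_id = paste0("H", 1:12),
                       lat = stats::runif(12, 50, 55),
                       lon = stats::runif(12, 8, 15))
  st2 <- data.frame(station_id = paste0("S", 1:5),
                    lat = stats::runif(5, 50, 55),
                    lon = stats::runif(5, 8, 15))
  asn2 <- assign_nearest_station(herds2, st2)
  for (i in seq_len(nrow(herds2))) {
    dd <- haversine_km(herds2$lat[i], herds2$lon[i], st2$lat, st2$lon)
    expect_equal(asn2$station_id[i], st2$station_id[which.min(dd)])
    expect_equal(asn2$distance_km[i], min(dd))
  }
  # exact tie broken by lowest station id
  tie_st <- data.frame(station_id = c("S2", "S1"),
                       lat = c(52, 54), lon = c(12, 12))
  tie_h <- data.frame(herd_id = "H1", lat = 53, lon = 12)
  expect_equal(assign_nearest_station(tie_h, tie_st)$station_id, "S1")
  expect_error(assign_nearest_station(herds, st[0, ]), "at least one")
})

make_daily <- function(thi_fun, days = 120, station = "S1",
                       origin = as.Date("2011-01-01")) {
  date <- origin + seq_len(days) - 1
  data.frame(station_id = station, date = date, thi = thi_fun(seq_len(days)),
             n_hours = 24L)
}

test_that("weekly windows average the printed day ranges (WK1 = 0-7 d)", {
  asn <- data.frame(herd_id = "H1", station_id = "S1", distance_km = 0)
  calves <- data.frame(calf_id = "C1", herd_id = "H1",
                       birth_date = as.Date("2011-04-11"))
  # constant daily THI: every window equals the constant
  wkc <- weekly_window_means(make_daily(function(d) rep(55, length(d))),
                             calves, asn)
  expect_equal(unname(wkc["C1", ]), rep(55, 12))
  # daily THI equal to the day offset: WK1 = mean(0:7), WK2 = mean(8:14) = 11
  bd <- as.Date("2011-04-11")
  daily <- make_daily(function(d) rep(0, length(d)))
  daily$thi <- as.numeric(bd - daily$date)  # offset before birth
  wko <- weekly_window_means(daily, calves, asn)
  expect_equal(unname(wko["C1", "wk1"]), mean(0:7))
  expect_equal(unname(wko["C1", "wk2"]), 11)
  expect_equal(unname(wko["C1", "wk12"]), mean(78:84))
})

test_that("weekly windows match an explicit loop oracle on random series", {
  set.seed(7)
  n_st <- 2
  daily <- do.call(rbind, lapply(1:n_st, function(s)
    make_daily(function(d) stats::rnorm(length(d), 50, 8),
               station = paste0("S", s), days = 200)))
  asn <- data.frame(herd_id = c("H1", "H2"), station_id = c("S1", "S2"))
  calves <- data.frame(calf_id = paste0("C", 1:20),
                       herd_id = sample(c("H1", "H2"), 20, TRUE),
                       birth_date = as.Date("2011-01-01") +
                         sample(90:199, 20, TRUE))
  wk <- weekly_window_means(daily, calves, asn)
  for (i in 1:20) {
    st <- asn$station_id[match(calves$herd_id[i], asn$herd_id)]
    sub <- daily[daily$station_id == st, ]
    for (w in 1:12) {
      offs <- if (w == 1) 0:7 else ((w - 1) * 7 + 1):(w * 7)
      vals <- sapply(offs, function(o) {
        d <- calves$birth_date[i] - o
        v <- sub$thi[sub$date == d]
        if (length(v)) v else NA_real_
      })
      expect_equal(unname(wk[i, w]), mean(vals), tolerance = 1e-10)
    }
  }
})

test_that("weekly windows below the coverage threshold are missing, not zero", {
  asn <- data.frame(herd_id = "H1", station_id = "S1")
  daily <- make_daily(function(d) rep(50, length(d)), days = 120)
  # remove 3 of the 7 days of WK2 (offsets 8..14): coverage 4/7 < 0.8
  bd <- as.Date("2011-04-11")
  daily <- daily[!(daily$date %in% (bd - c(8, 9, 10))), ]
  calves <- data.frame(calf_id = "C1", herd_id = "H1", birth_date = bd)
  wk <- weekly_window_means(daily, calves, asn)
  expect_true(is.na(wk["C1", "wk2"]))
  expect_equal(unname(wk["C1", "wk1"]), 50)
  expect_equal(attr(wk, "n_missing"), 1L)
})

test_that("PC1 scores match an explicit correlation-matrix eigen oracle", {
  # all rows identical: no variance anywhere, all scores 0
  m0 <- matrix(rep(c(50, 52, 54, 56), each = 5), 5, 4)
  expect_equal(as.numeric(pc1_daily_thi(m0)), rep(0, 5))

  # rank-1 structure: scores ordered with the row level, hot rows positive
  m1 <- outer(c(40, 45, 50, 55, 60), rep(1, 6)) +
    matrix(stats::rnorm(30, 0, 1e-4), 5, 6)
  s1 <- pc1_daily_thi(m1)
  expect_true(all(diff(s1) > 0))
  expect_gt(s1[5], 0)

  set.seed(11)
  m <- matrix(stats::rnorm(20, 50, 6), 5, 4)
  s <- pc1_daily_thi(m)
  Z <- scale(m)
  R <- stats::cor(m)
  ev <- eigen(R, symmetric = TRUE)
  v <- ev$vectors[, 1]
  ref <- drop(Z %*% v)
  if (stats::cor(ref, rowMeans(m)) < 0) ref <- -ref
  expect_equal(as.numeric(s), ref, tolerance = 1e-10)
  expect_error(pc1_daily_thi(m[1, , drop = FALSE]), "at least 2")
})

test_that("PC1 drops incomplete rows and records the count", {
  set.seed(2)
  m <- matrix(stats::rnorm(40, 50, 5), 8, 5)
  m[3, 2] <- NA
  s <- pc1_daily_thi(m)
  expect_true(is.na(s[3]))
  expect_equal(attr(s, "n_dropped"), 1L)
  expect_equal(sum(is.na(s)), 1L)
})

test_that("gestation covariates table carries scaled versions in [-1, 1]", {
  cfg <- tiny_config(seed = 5)
  wx <- simulate_weather(cfg)
  pop <- simulate_population(cfg)
  cov <- gestation_covariates(wx$weather, wx$stations, pop$herds, pop$calves)
  expect_equal(nrow(cov), nrow(pop$calves))
  s_cols <- c(paste0("s_wk", 1:12), "s_pc1")
  expect_true(all(abs(as.matrix(cov[, s_cols])) <= 1, na.rm = TRUE))
  expect_equal(cov$s_wk4,
               scale_covariate(cov$wk4, thi_scaling()))
})
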