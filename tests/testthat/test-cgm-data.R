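write_cgm_csv <- function(times, values, path = tempfile(fileext = ".csv")) {
  utils::write.csv(data.frame(timestamp = times, glucose_mg_dl = values),
                   path, row.names = FALSE)
  path
}

test_that("CGM tables are read, sorted, and duplicate timestamps averaged", {
  ts <- c("2021-03-01T00:00:00", "2021-03-01T00:05:00", "2021-03-01T00:10:00")
  tab <- read_cgm_table(write_cgm_csv(ts, c(100, 110, 120)))
  expect_equal(tab$glucose, c(100, 110, 120))
  expect_true(!is.unsorted(tab$time, strictly = TRUE))
  # shuffled rows give the identical sorted output
  tab2 <- read_cgm_table(write_cgm_csv(ts[c(3, 1, 2)], c(120, 100, 110)))
  expect_equal(tab2, tab)
  # two readings at the same minute collapse to their mean
  tab3 <- read_cgm_table(write_cgm_csv(
    c("2021-03-01T00:00:00", "2021-03-01T00:05:00", "2021-03-01T00:05:00"),
    c(100, 108, 112)))
  expect_equal(tab3$glucose, c(100, 110))
})

test_that("malformed rows raise format errors naming the row", {
  p1 <- write_cgm_csv(c("2021-03-01T00:00:00", "not-a-time"), c(100, 110))
  expect_error(read_cgm_table(p1), "row 2")
  p2 <- write_cgm_csv(c("2021-03-01T00:00:00", "2021-03-01T00:05:00"),
                      c("100", "high"))
  expect_error(read_cgm_table(p2), "row 2")
  expect_error(read_cgm_table(tempfile()), "not found")
})

test_that("resampling interpolates short gaps and marks long ones missing", {
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  rec <- data.frame(time = t0 + 60 * c(0, 5), glucose = c(100, 110))
  s <- resample_to_minute_grid(rec, max_gap_minutes = 10)
  expect_equal(s$values, c(100, 102, 104, 106, 108, 110))
  expect_false(any(s$missing))
  # a 30-minute gap exceeds the tolerance: interior minutes 1..29 missing
  rec2 <- data.frame(time = t0 + 60 * c(0, 30), glucose = c(100, 110))
  s2 <- resample_to_minute_grid(rec2, max_gap_minutes = 10)
  expect_equal(which(s2$missing), 2:30)
  expect_equal(s2$values[c(1, 31)], c(100, 110))  # endpoints preserved
  expect_error(resample_to_minute_grid(rec2[1, ]), "at least 2")
})

test_that("a gap-free 5-minute-sampled day resamples with zero missing minutes", {
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  times <- t0 + 60 * seq(0, 1439, by = 5)
  vals <- smooth_signal(length(times))
  s <- resample_to_minute_grid(data.frame(time = times, glucose = vals))
  expect_equal(sum(s$missing), 0)
  expect_length(s$values, 1436)
  # exact at every original reading minute
  expect_equal(s$values[seq(1, 1436, by = 5)], vals)
})

test_that("day filtering keeps exactly the complete days, grouped consecutively", {
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  vals <- smooth_signal(3 * 1440)
  miss <- rep(FALSE, 3 * 1440)
  miss[1440 + 700 + 1:20] <- TRUE  # 20-minute dropout inside day 2
  g <- find_continuous_day_groups(cgm_series(vals, t0, miss))
  expect_length(g, 2)
  expect_equal(vapply(g, function(x) x$n_days, integer(1)), c(1L, 1L))
  expect_equal(format(g[[2]]$start_time, "%Y-%m-%d"), "2021-03-03")
  # two clean days form one 2880-minute group
  g2 <- find_continuous_day_groups(cgm_series(vals[1:2880], t0))
  expect_length(g2, 1)
  expect_length(g2[[1]]$values, 2880)
  # all days holed -> nothing survives
  miss3 <- rep(FALSE, 3 * 1440); miss3[c(10, 1500, 3000)] <- TRUE
  expect_length(find_continuous_day_groups(cgm_series(vals, t0, miss3)), 0)
})

test_that("a series starting mid-day never counts its partial days", {
  t0 <- as.POSIXct("2021-03-01 12:00:00", tz = "UTC")
  g <- find_continuous_day_groups(cgm_series(smooth_signal(2 * 1440), t0))
  expect_length(g, 1)  # only March 2 is fully covered
  expect_equal(format(g[[1]]$start_time, "%Y-%m-%d"), "2021-03-02")
})

test_that("surviving days equal a brute-force day scan for random gap patterns", {
  t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  n_days <- 5
  vals <- smooth_signal(n_days * 1440)
  set.seed(123)
  for (rep in 1:10) {
    miss <- rep(FALSE, n_days * 1440)
    gaps <- sample(n_days * 1440 - 60, sample(0:4, 1))
    for (g0 in gaps) miss[g0 + seq_len(sample(1:90, 1))] <- TRUE
    groups <- find_continuous_day_groups(cgm_series(vals, t0, miss))
    complete <- vapply(seq_len(n_days), function(d) {
      !any(miss[((d - 1) * 1440 + 1):(d * 1440)])
    }, logical(1))
    surviving <- unlist(lapply(groups, function(g) {
      d0 <- as.numeric(difftime(g$start_time, t0, units = "days")) + 1
      seq(d0, length.out = g$n_days)
    }))
    expect_equal(sort(surviving), which(complete))
    # groups are maximal runs: consecutive groups are separated by a bad day
    expect_true(all(vapply(groups, function(g) g$n_days >= 1, logical(1))))
  }
})

test_that("the PA mask covers closed intervals, unions overlaps, clips and warns", {
  grp <- make_group(smooth_signal(1440))
  d0 <- grp$start_time
  ev <- activity_events(at_minute(d0, 600), at_minute(d0, 660), "aerobic")
  m <- pa_mask(grp, ev)
  expect_equal(sum(m), 61)                      # inclusive interval
  expect_equal(which(m), 601:661)               # minutes 600..660, 1-based index
  expect_equal(sum(pa_mask(grp, NULL)), 0)
  ev2 <- activity_events(at_minute(d0, c(600, 630)), at_minute(d0, c(660, 700)),
                         c("aerobic", "aerobic"))
  expect_equal(sum(pa_mask(grp, ev2)), 101)     # union 600..700, no double count
  ev3 <- activity_events(at_minute(d0, 2000), at_minute(d0, 2060), "anaerobic")
  expect_warning(m3 <- pa_mask(grp, ev3), "outside")
  expect_equal(sum(m3), 0)
  expect_error(activity_events(d0, d0, "aerobic"), "start < end")
  expect_error(activity_events(d0, d0 + 60, "jogging"), "unknown activity")
})

test_that("activity tables read back through their CSV dialect", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(start = "2021-03-01T10:00:00",
                              end = "2021-03-01T11:00:00", type = "anaerobic"),
                   path, row.names = FALSE)
  ev <- read_activity_table(path)
  expect_equal(ev$pa_type, "anaerobic")
  expect_equal(as.numeric(ev$end - ev$start, units = "mins"), 60)
})

test_that("the day-group index serializes per-patient survivors", {
  groups <- find_continuous_day_groups(
    cgm_series(smooth_signal(2 * 1440),
               as.POSIXct("2021-03-01", tz = "UTC"), patient_id = "p1"))
  path <- tempfile(fileext = ".json")
  write_day_group_index(groups, path)
  idx <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(idx$patient_id, "p1")
  expect_equal(idx$n_days, 2)
  expect_equal(idx$n_minutes, 2880)
})
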