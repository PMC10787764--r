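test_that("tracked fraction and coverage mask count by hand", {
  x <- matrix(0, 3, 10); y <- matrix(0, 3, 10)
  x[1, 5] <- NA; y[1, 5] <- NA
  g <- make_grid(x, y)
  tf <- tracked_fraction(g)
  expect_equal(tf[5], 2 / 3)
  expect_equal(tf[-5], rep(1, 9), ignore_attr = TRUE)

  # boundary-inclusive threshold on a 10-individual grid
  x <- matrix(0, 10, 3); y <- matrix(0, 10, 3)
  x[1:5, 1] <- NA; y[1:5, 1] <- NA     # 5/10 tracked
  x[1:6, 2] <- NA; y[1:6, 2] <- NA     # 4/10 tracked
  x[1:3, 3] <- NA; y[1:3, 3] <- NA     # 7/10 tracked
  g <- make_grid(x, y)
  expect_equal(coverage_mask(g, 0.5), c(TRUE, FALSE, TRUE))
  expect_equal(coverage_mask(g, 0.8), c(FALSE, FALSE, FALSE))
})

test_that("single-second gaps are filled at the midpoint, longer gaps kept", {
  x <- matrix(c(0, NA, 2, 5, NA, NA, 8), 1)
  y <- matrix(c(0, NA, 0, 1, NA, NA, 4), 1)
  g <- interpolate_gaps(make_grid(x, y))
  expect_equal(g$x[1, 2], 1, ignore_attr = TRUE)
  expect_equal(g$y[1, 2], 0, ignore_attr = TRUE)
  expect_true(g$interpolated[1, 2])
  expect_true(all(is.na(g$x[1, 5:6])))    # two consecutive gaps untouched
  # idempotent; no-gap grids unchanged
  expect_identical(interpolate_gaps(g), g)
  full <- make_grid(matrix(1:6, 2), matrix(1:6, 2))
  expect_identical(interpolate_gaps(full), full)
})

test_that("interpolated points lie on the segment between their neighbours", {
  set.seed(41)
  x <- matrix(cumsum(rnorm(50)), 1); y <- matrix(cumsum(rnorm(50)), 1)
  drop <- sample(2:49, 10)
  x[1, drop] <- NA; y[1, drop] <- NA
  g0 <- make_grid(x, y)
  g <- interpolate_gaps(g0)
  filled <- which(g$interpolated[1, ])
  for (t in filled) {
    mx <- (g$x[1, t - 1] + g$x[1, t + 1]) / 2
    my <- (g$y[1, t - 1] + g$y[1, t + 1]) / 2
    expect_equal(g$x[1, t], mx)
    expect_equal(g$y[1, t], my)
  }
})

test_that("outlier removal touches exactly the planted points", {
  area <- study_area(xlim = c(-100, 100), ylim = c(-100, 100))
  set.seed(42)
  x <- matrix(rnorm(1000, 0, 10), 4); y <- matrix(rnorm(1000, 0, 10), 4)
  g0 <- make_grid(x, y)
  expect_identical(suppressMessages(remove_outliers(g0, area))$x, g0$x)

  planted <- cbind(sample(4, 3, TRUE), sample(250, 3))
  x[planted] <- 5e5; y[planted] <- 5e5    # 500 km away
  g <- suppressMessages(remove_outliers(make_grid(x, y), area))
  expect_equal(attr(g, "n_removed"), 3)
  expect_true(all(is.na(g$x[planted])))
  expect_equal(sum(is.na(g$x)), 3)
})

test_that("polygonal study areas use point-in-polygon containment", {
  tri <- study_area(polygon = cbind(c(0, 10, 0), c(0, 0, 10)))
  x <- matrix(c(1, 8), 1); y <- matrix(c(1, 8), 1)  # (8,8) outside triangle
  g <- suppressMessages(remove_outliers(make_grid(x, y), tri))
  expect_false(is.na(g$x[1, 1]))
  expect_true(is.na(g$x[1, 2]))
  expect_error(study_area(xlim = c(0, 0), ylim = c(0, 1)))
})

test_that("projection round-trips within 1e-6 degrees", {
  origin <- c(36.9, 0.29)
  lon <- 36.9 + runif(20, -0.05, 0.05)
  lat <- 0.29 + runif(20, -0.05, 0.05)
  pl <- project_lonlat(lon, lat, origin)
  ll <- unproject_xy(pl$x, pl$y, origin)
  expect_equal(ll$lon, lon, tolerance = 1e-6)
  expect_equal(ll$lat, lat, tolerance = 1e-6)
})

test_that("reader skips unknown ids, errors on bad timestamps, splits days", {
  md <- data.frame(id = c("A", "B"), sex = c("M", "F"), group = "G1")
  df <- data.frame(
    `individual-local-identifier` = c("A", "B", "ghost", "A"),
    timestamp = c("2023-03-01 06:00:00", "2023-03-01 06:00:00",
                  "2023-03-01 06:00:01", "2023-03-02 06:00:00"),
    `location-long` = 36.9, `location-lat` = 0.29, check.names = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_warning(grids <- read_trajectories(path, md), "ghost")
  expect_equal(length(grids), 2)          # two calendar days
  expect_setequal(grids[[1]]$ids, c("A", "B"))

  df$timestamp[2] <- "not a time"
  write.csv(df, path, row.names = FALSE)
  expect_error(suppressWarnings(read_trajectories(path, md)), "row 2")
})

test_that("a complete two-individual table gives full coverage", {
  md <- data.frame(id = c("A", "B"), sex = c("M", "F"), group = "G1")
  ts <- format(as.POSIXct("2023-03-01 06:00:00", tz = "UTC") + 0:9,
               "%Y-%m-%d %H:%M:%S")
  df <- data.frame(`individual-local-identifier` = rep(c("A", "B"), each = 10),
                   timestamp = rep(ts, 2),
                   `location-long` = 36.9 + runif(20, 0, 1e-4),
                   `location-lat` = 0.29 + runif(20, 0, 1e-4),
                   check.names = FALSE)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  g <- read_trajectories(path, md)[[1]]
  expect_equal(tracked_fraction(g), rep(1, 10), ignore_attr = TRUE)
})

test_that("simulated Movebank output reads back to the simulated grid", {
  cfg <- sim_config(n_agents = 4, n_males = 2, episodes = data.frame(
    type = "pull", initiators = 1L, theta_deg = NA_real_))
  sim <- simulate_group(cfg, seed = 19)
  path <- tempfile(fileext = ".csv")
  write_movebank_csv(sim, path)
  g <- read_trajectories(path, sim$metadata, origin = cfg$origin_lonlat)[[1]]
  expect_identical(g$ids, sim$grid$ids)
  expect_identical(g$times, sim$grid$times)
  # de-projection followed by re-projection loses well under GPS accuracy
  expect_lt(max(abs(g$x - sim$grid$x), na.rm = TRUE), 1e-4)
  expect_lt(max(abs(g$y - sim$grid$y), na.rm = TRUE), 1e-4)
})
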