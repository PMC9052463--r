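test_that("wide CSV parses into a panel with derived time scores", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("country,1987,1988\nA,30,29\nB,10,9.5", path)
  pan <- read_panel(path, layout = "wide")
  expect_s3_class(pan, "trajmix_panel")
  expect_equal(pan$unit_ids, c("A", "B"))
  expect_equal(pan$years, c(1987L, 1988L))
  expect_equal(pan$time_scores, c(0, 1))
  expect_equal(unname(pan$values), matrix(c(30, 10, 29, 9.5), 2, 2))
  expect_false(any(pan$missing_mask))
})

test_that("an empty wide cell becomes a missing value and nothing else", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("country,1987,1988,1989\nA,30,29,28\nB,10,,9", path)
  pan <- read_panel(path, layout = "wide")
  expect_equal(sum(pan$missing_mask), 1L)
  expect_true(pan$missing_mask["B", "1988"])
  expect_equal(pan$values["A", ], c("1987" = 30, "1988" = 29, "1989" = 28))
})

test_that("long and wide layouts produce identical panels", {
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".csv")
  writeLines("country,1987,1988\nA,30,29\nB,10,9.5", wide)
  writeLines("unit,year,value\nA,1987,30\nA,1988,29\nB,1987,10\nB,1988,9.5",
             long)
  expect_equal(read_panel(wide, layout = "wide"),
               read_panel(long, layout = "long"))
})

test_that("panel validation rejects malformed inputs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("country,1987,1988\nA,30,29\nA,10,9.5", path)
  expect_error(read_panel(path, "wide"), "Duplicate")

  writeLines("country,1987,1988\nA,30,abc\nB,10,9.5", path)
  expect_error(read_panel(path, "wide"), "abc")

  writeLines("country,1987,1988\nA,30,\nB,10,9.5", path)
  expect_error(read_panel(path, "wide"), "at least 2")

  writeLines("country,1987,1988\nA,30,101\nB,10,9.5", path)
  expect_error(read_panel(path, "wide"), "\\[0, 100\\]")
})

test_that("write_panel/read_panel round-trips both layouts exactly", {
  sim <- simulate_panel(asia_underweight_spec(missing_rate = 0.05), seed = 8)
  for (layout in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_panel(sim$panel, path, layout = layout)
    back <- read_panel(path, layout = layout)
    expect_equal(back, sim$panel, info = layout)
  }
})

test_that("descriptive statistics match hand values and a brute-force oracle", {
  vals <- matrix(c(10, 10, 10, 10, 10,
                   1, 2, 3, 2.5, 1.5), 5, 2)
  pan <- trajmix:::new_panel(letters[1:5], c(2000L, 2001L), vals)
  st <- descriptive_stats(pan)
  expect_equal(st$min[1], 10)
  expect_equal(st$max[1], 10)
  expect_equal(st$mean[1], 10)
  expect_equal(st$median[1], 10)
  expect_equal(st$sd[1], 0)

  pan3 <- trajmix:::new_panel(letters[1:3], c(2000L, 2001L),
                              matrix(c(1, 2, 3, 5, 5, 5), 3, 2))
  st3 <- descriptive_stats(pan3, years = 2000L)
  expect_equal(st3$mean, 2)
  expect_equal(st3$sd, 1)
  expect_equal(st3$median, 2)

  # independent order-statistics oracle on a realistic panel
  sim <- simulate_panel(asia_underweight_spec(), seed = 3)
  st <- descriptive_stats(sim$panel, years = seq(1987, 2016, 5))
  for (j in seq_along(st$year)) {
    v <- unname(sort(sim$panel$values[, match(st$year[j], sim$panel$years)]))
    n <- length(v)
    expect_equal(st$min[j], v[1])
    expect_equal(st$max[j], v[n])
    expect_equal(st$mean[j], sum(v) / n)
    expect_equal(st$sd[j], sqrt(sum((v - sum(v) / n)^2) / (n - 1)))
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(st$median[j], med)
  }
})

test_that("descriptive statistics ignore unit order and other years' missingness", {
  sim <- simulate_panel(asia_underweight_spec(), seed = 4)
  pan <- sim$panel
  st <- descriptive_stats(pan, years = c(1990L, 2000L))

  perm <- withr::with_seed(1, sample(nrow(pan$values)))
  pan2 <- trajmix:::new_panel(pan$unit_ids[perm], pan$years,
                              pan$values[perm, ], pan$time_scores)
  expect_equal(descriptive_stats(pan2, years = c(1990L, 2000L)), st)

  vals <- pan$values
  vals[5, match(2010L, pan$years)] <- NA
  pan3 <- trajmix:::new_panel(pan$unit_ids, pan$years, vals, pan$time_scores)
  expect_equal(descriptive_stats(pan3, years = c(1990L, 2000L)), st)

  expect_error(descriptive_stats(pan, years = 1950L), "not in the panel")
})
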