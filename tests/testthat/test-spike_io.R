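test_that("Klusters loader converts samples to seconds and skips noise clusters", {
  res <- tempfile(fileext = ".res"); clu <- tempfile(fileext = ".clu")
  writeLines(c("20000", "40000"), res)
  writeLines(c("3", "2", "3"), clu)
  trains <- load_klusters(res, clu, sampling_rate_hz = 20000, animal_id = "r1")
  expect_length(trains, 2L)
  expect_equal(trains$clu2$spikes, 1.0)
  expect_equal(trains$clu3$spikes, 2.0)
  expect_equal(trains$clu2$animal_id, "r1")

  writeLines(c("60000", "20000", "40000"), res)  # ids 0 and 1 are noise
  writeLines(c("3", "0", "1", "2"), clu)
  expect_length(load_klusters(res, clu), 1L)
})

test_that("Klusters loader handles empty input and malformed files", {
  res <- tempfile(); clu <- tempfile()
  writeLines(character(), res); writeLines("1", clu)
  expect_length(load_klusters(res, clu), 0L)

  writeLines(c("100", "200"), res); writeLines(c("2", "2"), clu)
  expect_error(load_klusters(res, clu), "mismatch")

  writeLines(c("200", "100"), res); writeLines(c("2", "2", "2"), clu)
  expect_warning(tr <- load_klusters(res, clu), "not monotone")
  expect_equal(tr$clu2$spikes, c(100, 200) / 20000)
})

test_that("Klusters round trip reproduces random spike times at sample resolution", {
  set.seed(11)
  samples <- sort(sample.int(20000 * 600, 1000))
  tr <- spike_train("u1", "r1", "pyramidal", samples / 20000)
  res <- tempfile(); clu <- tempfile()
  write_klusters(list(tr), res, clu)
  back <- load_klusters(res, clu, animal_id = "r1")
  expect_length(back, 1L)
  expect_equal(back[[1]]$spikes, tr$spikes, tolerance = 1 / 20000)
  expect_length(back[[1]]$spikes, 1000L)
})

test_that("tabular spike interchange groups, sorts, and round-trips", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,animal_id,cell_type,time_s",
               "c1,a1,pyramidal,2.5", "c1,a1,pyramidal,1.5"), f)
  trains <- load_tabular_spikes(f)
  expect_length(trains, 1L)
  expect_equal(trains$c1$spikes, c(1.5, 2.5))  # shuffled input is sorted
  expect_equal(trains$c1$cell_type, "pyramidal")

  set.seed(3)
  orig <- list(poisson_train(2, 0, 100, "p1", "a1", "pyramidal"),
               poisson_train(8, 0, 100, "i1", "a1", "interneuron"))
  write_tabular_spikes(orig, f)
  back <- load_tabular_spikes(f)
  expect_equal(back$p1$spikes, orig[[1]]$spikes)
  expect_equal(back$i1$spikes, orig[[2]]$spikes)
  expect_equal(back$i1$cell_type, "interneuron")
})

test_that("tabular loader rejects negative times with a count and bad headers hard", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cell_id,animal_id,cell_type,time_s",
               "c1,a1,unknown,1.0", "c1,a1,unknown,-0.5"), f)
  expect_message(trains <- load_tabular_spikes(f), "rejected 1 row")
  expect_equal(trains$c1$spikes, 1.0)

  writeLines(c("cell,animal,type,t", "c1,a1,unknown,1.0"), f)
  expect_error(load_tabular_spikes(f), "header")
})

test_that("session table loads the four-session paradigm and validates invariants", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("label,start_s,end_s", "FAM1,0,1500", "NOV,1500,3000",
               "FAML,3000,4500", "FAM2,4500,6000"), f)
  sset <- load_session_table(f)
  expect_equal(sset$sessions$label, c("FAM1", "NOV", "FAML", "FAM2"))
  expect_equal(session_interval(sset, "FAML"), c(3000, 4500))

  # out-of-order rows are reordered by start_s
  writeLines(c("label,start_s,end_s", "NOV,1500,3000", "FAM1,0,1500"), f)
  expect_equal(load_session_table(f)$sessions$label, c("FAM1", "NOV"))

  writeLines(c("label,start_s,end_s", "FAM1,0,1500", "NOV,1000,2500"), f)
  expect_error(load_session_table(f), "overlap")

  writeLines(c("label,start_s,end_s", "SLEEP,0,1500"), f)
  expect_error(load_session_table(f), "unknown session label")

  writeLines(c("label,start_s,end_s", "FAM1,0,1500", "LIGHT,2000,2001"), f)
  expect_error(load_session_table(f), "light interval")
})

test_that("light rows round-trip through the session table", {
  sset <- session_set(data.frame(label = c("FAM1", "REST"),
                                 start_s = c(0, 1500), end_s = c(1500, 2580)),
                      data.frame(start_s = c(1500, 1503), end_s = c(1500.5, 1503.5)))
  f <- tempfile(fileext = ".csv")
  write_session_table(sset, f)
  back <- load_session_table(f)
  expect_equal(back$light_intervals, sset$light_intervals)
  expect_equal(back$sessions, sset$sessions)
})

test_that("pair table round-trips bit-stably with missing values preserved", {
  f <- tempfile(fileext = ".csv")
  empty <- data.frame(pair_id = character(), pre_id = character(),
                      post_id = character(), animal_id = character(),
                      peak_z = numeric(), significant = logical(),
                      passes_filters = logical())
  write_pair_table(empty, f)
  expect_equal(nrow(read_pair_table(f)), 0L)

  set.seed(21)
  tab <- data.frame(pair_id = sprintf("p%02d", 1:78), pre_id = "x",
                    post_id = "y", animal_id = rep(c("a1", "a2"), 39),
                    peak_z = rnorm(78), significant = TRUE,
                    passes_filters = TRUE,
                    trans_FAM1 = runif(78), trans_FAML = runif(78))
  tab$trans_FAML[c(3, 10)] <- NA  # zero-reference sessions stay missing
  write_pair_table(tab, f)
  back <- read_pair_table(f)
  expect_identical(back$peak_z, tab$peak_z)
  expect_identical(back$trans_FAM1, tab$trans_FAM1)
  expect_identical(is.na(back$trans_FAML), is.na(tab$trans_FAML))
  f2 <- tempfile(); write_pair_table(back, f2)
  expect_identical(readLines(f), readLines(f2))

  expect_error(write_pair_table(tab[, -5], f), "peak_z")
  writeLines(c("pair_id,pre_id", "a,b"), f)
  expect_error(read_pair_table(f), "mandatory")
})
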