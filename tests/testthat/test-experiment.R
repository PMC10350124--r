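test_that("condition grids expand sweeps crossed with noise conditions", {
  grid <- build_condition_grid(list(
    sweep = list(n_channels = c(4, 6)),
    snr = list("quiet", 5)
  ))
  expect_equal(nrow(grid), 4)
  expect_equal(anyDuplicated(grid$label), 0L)
  # unswept parameters take the defaults (100 Hz envelope cutoff etc.)
  expect_true(all(grid$env_cutoff == 100))
  expect_true(all(grid$dynamic_range_db == "full"))
  expect_true(all(grid$quant_steps == "infinite"))
  expect_error(build_condition_grid(list(sweep = list())), "at least one")
  expect_error(build_condition_grid(list(sweep = list(bogus = 1))), "unknown")
})

test_that("out-of-range sweep values warn in paper mode and error in strict", {
  cfg <- list(sweep = list(n_channels = 5))
  expect_warning(build_condition_grid(cfg), "outside")
  expect_error(build_condition_grid(cfg, strict = TRUE), "outside")
  cfg2 <- list(sweep = list(dynamic_range_db = 200))
  expect_warning(build_condition_grid(cfg2), "outside")
})

test_that("grid configs round-trip through YAML", {
  cfg <- list(sweep = list(env_cutoff = c(50, 100)), snr = list("quiet"),
              material = "sentences")
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  grid <- build_condition_grid(f)
  expect_equal(nrow(grid), 2)
  expect_equal(grid$env_cutoff, c(50, 100))
  unlink(f)
})

test_that("the clean pipeline with an identity recognizer scores 100%", {
  stim <- tiny_stimuli()
  script <- stats::setNames(stim$transcript, stim$id)
  grid <- build_condition_grid(list(sweep = list(n_channels = c(6, 8))))
  res <- run_experiment(stim, grid, mock_recognizer(script),
                        reps = 5, base_seed = 1)
  expect_equal(nrow(res$scores), 10) # 2 conditions x 5 reps
  expect_true(all(res$scores$percent == 100))
  expect_equal(table(res$scores$label) |> as.integer(), c(5L, 5L))
})

test_that("experiment runs are reproducible under a fixed base seed", {
  stim <- tiny_stimuli()
  script <- stats::setNames(stim$transcript, stim$id)
  grid <- build_condition_grid(list(sweep = list(n_channels = 6),
                                    snr = list(5)))
  r1 <- run_experiment(stim, grid, mock_recognizer(script), reps = 2,
                       base_seed = 42)
  r2 <- run_experiment(stim, grid, mock_recognizer(script), reps = 2,
                       base_seed = 42)
  expect_identical(r1$scores, r2$scores)
  expect_identical(summarize_experiment(r1), summarize_experiment(r2))
})

test_that("word-list material routes through the alignment scorer", {
  stim <- tiny_stimuli()
  script <- stats::setNames(c("the boy ran home now", "dog sat down"), stim$id)
  grid <- build_condition_grid(list(sweep = list(n_channels = 8),
                                    material = "word_lists"))
  res <- run_experiment(stim, grid, mock_recognizer(script), reps = 1)
  # 4/4 with one insertion deleted + 3/4 with "a" missing = 7 of 8
  expect_equal(res$scores$n_correct, 7L)
  expect_equal(res$scores$n_total, 8L)
})

test_that("recognizer failures are recorded as empty transcriptions", {
  stim <- tiny_stimuli()
  flaky <- recognizer(function(audio, id) {
    if (id == "s2") stop("decoder crashed") else "the boy ran home"
  }, name = "flaky")
  grid <- build_condition_grid(list(sweep = list(n_channels = 8)))
  expect_message(
    res <- run_experiment(stim, grid, flaky, reps = 1),
    "recorded as empty"
  )
  expect_equal(res$scores$n_correct, 4L)
  expect_equal(res$scores$n_total, 8L)
})

test_that("summaries report mean, spread and repetition counts per condition", {
  fake <- structure(
    list(
      scores = tibble::tibble(
        label = rep(c("a", "b"), each = 2), rep = rep(1:2, 2),
        n_correct = c(8L, 9L, 4L, 5L), n_total = rep(10L, 4),
        percent = c(80, 90, 40, 50)
      ),
      conditions = tibble::tibble(label = c("a", "b"), snr = "quiet"),
      reps = 2L, base_seed = 1L, recognizer = "mock", n_stimuli = 1L
    ),
    class = "vocoder_experiment"
  )
  s <- summarize_experiment(fake)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_percent, c(85, 45))
  expect_equal(s$sd_percent[1], stats::sd(c(80, 90)))
  expect_equal(s$sd_percent[1], 7.071, tolerance = 1e-3)
  expect_equal(s$n_reps, c(2L, 2L))
  # aggregation ignores repetition order
  fake2 <- fake
  fake2$scores <- fake$scores[c(2, 1, 4, 3), ]
  expect_equal(summarize_experiment(fake2)$mean_percent, s$mean_percent)
  # single repetition reports SD 0
  fake3 <- fake
  fake3$scores <- fake$scores[c(1, 3), ]
  expect_equal(summarize_experiment(fake3)$sd_percent, c(0, 0))
})

test_that("tidy and glance expose broom-style views", {
  stim <- tiny_stimuli()
  script <- stats::setNames(stim$transcript, stim$id)
  grid <- build_condition_grid(list(sweep = list(n_channels = c(6, 8))))
  res <- run_experiment(stim, grid, mock_recognizer(script), reps = 2)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_true(all(c("label", "percent", "n_channels", "snr") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_conditions, 2L)
  expect_equal(gl$n_presentations, 2 * 2 * 2)
})

test_that("presentation counts multiply out the design", {
  expect_equal(presentation_count(60, 5, 900), 270000)
  expect_equal(presentation_count(200, 5, 900), 900000)
})

test_that("results round-trip to CSV and JSON", {
  stim <- tiny_stimuli()
  script <- stats::setNames(stim$transcript, stim$id)
  grid <- build_condition_grid(list(sweep = list(n_channels = 8)))
  res <- run_experiment(stim, grid, mock_recognizer(script), reps = 1)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_results(res, csv = csv, json = json)
  back <- utils::read.csv(csv)
  expect_equal(back$mean_percent, 100)
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js$scores$percent, 100)
  unlink(c(csv, json))
})
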