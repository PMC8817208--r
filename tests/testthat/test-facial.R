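# Facial expressivity: AU table parsing, confidence filtering, baseline
# normalization and the composite.

test_that("AU tables read from CSV with confidence unit normalization", {
  df <- make_au_df(intensity = 0.5, n = 3)
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  tab <- read_au_table(path)
  expect_s3_class(tab, "au_frame_table")
  expect_equal(nrow(tab), 3)
  expect_equal(ncol(tab), 4 + 17)
  # percent-scaled confidence divided by 100 on load
  df2 <- df
  df2$confidence <- c(79, 80, 95)
  write.csv(df2, path, row.names = FALSE)
  expect_equal(read_au_table(path)$confidence, c(0.79, 0.80, 0.95))
  # missing AU column errors by name
  df3 <- df[, setdiff(names(df), "AU12_r")]
  write.csv(df3, path, row.names = FALSE)
  expect_error(read_au_table(path), "AU12_r")
  # non-numeric cell errors with its row
  df4 <- df
  df4$AU05_r <- as.character(df4$AU05_r)
  df4$AU05_r[2] <- "oops"
  write.csv(df4, path, row.names = FALSE)
  expect_error(read_au_table(path), "row 2")
  unlink(path)
})

test_that("the 0.80 confidence boundary is inclusive and success gates", {
  tab <- au_frame_table(make_au_df(n = 3, confidence = c(0.79, 0.80, 0.95)))
  kept <- filter_confidence(tab)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "fraction_dropped"), 1 / 3)
  all_low <- filter_confidence(au_frame_table(make_au_df(n = 4,
                                                         confidence = 0.5)))
  expect_equal(nrow(all_low), 0)
  er <- facial_expressivity(all_low)
  expect_true(is_missing_marker(er$facial_expressivity))
  tab_s <- au_frame_table(make_au_df(n = 3, confidence = 0.95,
                                     success = c(1, 0, 1)))
  expect_equal(nrow(filter_confidence(tab_s)), 2)
  all_high <- au_frame_table(make_au_df(n = 5, confidence = 0.9))
  expect_equal(nrow(filter_confidence(all_high)), 5)
})

test_that("baseline profile averages frames and floors zero AUs", {
  df <- make_au_df(n = 3, confidence = 0.95)
  df$AU01_r <- c(0.2, 0.4, 0.6)
  bp <- baseline_profile(filter_confidence(au_frame_table(df)))
  expect_equal(unname(bp$means[["AU01_r"]]), 0.4)
  expect_equal(bp$n_frames_used, 3)
  df$AU04_r <- 0
  bp2 <- baseline_profile(filter_confidence(au_frame_table(df)))
  expect_equal(unname(bp2$means[["AU04_r"]]), 1e-3)
  expect_true("04" %in% bp2$floored)
  empty <- filter_confidence(au_frame_table(make_au_df(n = 2,
                                                       confidence = 0.1)))
  expect_error(baseline_profile(empty), "no usable baseline")
})

test_that("normalization divides by the per-AU baseline mean", {
  base <- filter_confidence(au_frame_table(make_au_df(n = 4,
                                                      intensity = 0.5)))
  bp <- baseline_profile(base)
  same <- normalize_aus(base, bp)
  expect_equal(mean(as.matrix(same[, paste0("AU", AU_SET, "_r")])), 1,
               tolerance = 1e-12)
  resp <- filter_confidence(au_frame_table(make_au_df(n = 4,
                                                      intensity = 1.0)))
  expect_equal(facial_expressivity(normalize_aus(resp,
                                                 bp))$facial_expressivity$value,
               2, tolerance = 1e-12)
})

test_that("expressivity is the grand mean over frames and AUs", {
  df <- make_au_df(n = 2, intensity = 1)
  df[1, paste0("AU", AU_SET, "_r")] <- 1.0
  df[2, paste0("AU", AU_SET, "_r")] <- 3.0
  df[, "AU01_r"] <- c(2.0, 4.0)
  tab <- au_frame_table(df)
  # 2x2 hand fixture on a reduced AU set
  small <- au_frame_table(df[, c("frame", "timestamp", "confidence",
                                 "success", "AU01_r", "AU02_r")],
                          aus = c("01", "02"))
  expect_equal(facial_expressivity(small)$facial_expressivity$value,
               mean(c(2, 1, 4, 3)))
})

test_that("expressivity is scale-equivariant and order-invariant", {
  s <- synth_au_table(expressivity_multiplier = 1.7, n_frames = 60, seed = 9)
  bp <- baseline_profile(filter_confidence(s$baseline))
  resp <- filter_confidence(s$response)
  e1 <- facial_expressivity(normalize_aus(resp, bp))$facial_expressivity$value
  scaled <- resp
  for (col in paste0("AU", AU_SET, "_r")) scaled[[col]] <- 3 * scaled[[col]]
  e3 <- facial_expressivity(normalize_aus(scaled,
                                          bp))$facial_expressivity$value
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
  shuffled <- resp[sample(nrow(resp)), ]
  es <- facial_expressivity(normalize_aus(shuffled,
                                          bp))$facial_expressivity$value
  expect_equal(es, e1, tolerance = 1e-12)
})

test_that("raising the confidence threshold never keeps more frames", {
  s <- synth_au_table(n_frames = 200, dropout_fraction = 0.25, seed = 4)
  kept <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99),
                 function(th) nrow(filter_confidence(s$response, th)), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("synthesized expressivity multipliers round-trip within 5%", {
  for (k in c(1.0, 2.5)) {
    s <- synth_au_table(expressivity_multiplier = k, n_frames = 150,
                        baseline_frames = 120, dropout_fraction = 0,
                        seed = 2)
    er <- expressivity_from_table(
      au_frame_table(rbind(as.data.frame(s$baseline),
                           as.data.frame(s$response))),
      baseline_end_seconds = 120 / 30)
    expect_lt(abs(er$facial_expressivity$value - k) / k, 0.05)
  }
})
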