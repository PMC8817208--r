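# Aggregation, Pearson correlation, Benjamini-Hochberg adjustment,
# correlation tables and test-retest ICC.

test_that("assessment aggregation averages non-missing values per cell", {
  rows <- tibble::tibble(
    participant_id = c("A", "A", "A", "B", "B", "B", "C"),
    task_context = "evoked_vocal",
    marker = "hnr",
    value = c(2, 4, 6, 5, NA, 7, NA))
  prof <- aggregate_assessments(rows)
  expect_equal(prof$value[prof$participant_id == "A"], 4)
  expect_equal(prof$value[prof$participant_id == "B"], 6)
  expect_equal(prof$n_assessments[prof$participant_id == "B"], 2)
  expect_true(is.na(prof$value[prof$participant_id == "C"]))
  expect_equal(prof$n_assessments[prof$participant_id == "C"], 0)
})

test_that("pearson_corr matches the definitional oracle on seeded draws", {
  expect_equal(pearson_corr(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    got <- pearson_corr(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p_raw, want$p, tolerance = 1e-12)
  }
  # symmetry and affine invariance / sign flip
  set.seed(100)
  x <- rnorm(20)
  y <- rnorm(20)
  expect_equal(pearson_corr(x, y)$r, pearson_corr(y, x)$r)
  expect_equal(pearson_corr(3 * x + 2, y)$r, pearson_corr(x, y)$r,
               tolerance = 1e-12)
  expect_equal(pearson_corr(-x, y)$r, -pearson_corr(x, y)$r,
               tolerance = 1e-12)
})

test_that("degenerate correlation inputs are flagged, not NaN", {
  out <- pearson_corr(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(out$r))
  expect_match(out$note, "constant")
  short <- pearson_corr(c(1, 2), c(3, 4))
  expect_match(short$note, "fewer than 3")
  withmiss <- pearson_corr(c(1, 2, NA, 4, 5), c(2, 4, 6, NA, 10))
  expect_equal(withmiss$n, 3)
})

test_that("BH adjustment reproduces the step-up procedure exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (rep in 1:1000) {
    p <- runif(sample(1:25, 1))
    got <- bh_adjust(p)
    want <- oracle_bh(p)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15))
    expect_true(all(got <= 1))
    expect_equal(bh_adjust(got), oracle_bh(got), tolerance = 1e-12)
  }
})

make_test_cohort <- function(n = 40, seed = 5, targets = NULL) {
  mm <- MARKER_MODEL_DEFAULTS
  if (!is.null(targets)) mm$target_r <- targets
  simulate_cohort(cohort_params(n_participants = n, marker_model = mm,
                                seed = seed))
}

test_that("correlation tables recover programmed dependence directions", {
  b <- make_test_cohort(n = 60, seed = 21)
  prof <- aggregate_assessments(b$marker_rows)
  clin <- clinical_scores_table(b$panss)
  tab <- correlation_table(prof, clin)
  f0_cell <- tab[tab$task_context == "evoked_vocal" &
                   tab$marker == "f0_mean" &
                   tab$scale == "negative_marder", ]
  expect_lt(f0_cell$r, 0) # programmed negative marker-severity loading
  jit_cell <- tab[tab$task_context == "evoked_vocal" &
                    tab$marker == "jitter_local" &
                    tab$scale == "negative_marder", ]
  expect_gt(jit_cell$r, 0)
  expect_true(all(tab$p_adjusted >= tab$p_raw - 1e-15, na.rm = TRUE))
  # permuting participant order leaves the table unchanged
  perm <- sample(nrow(prof))
  tab2 <- correlation_table(prof[perm, ], clin)
  expect_equal(tab, tab2)
})

test_that("constant marker columns are flagged per cell", {
  b <- make_test_cohort(n = 10, seed = 3)
  prof <- aggregate_assessments(b$marker_rows)
  prof$value[prof$marker == "hnr"] <- 15
  tab <- correlation_table(prof, clinical_scores_table(b$panss))
  hnr_cells <- tab[tab$marker == "hnr" & tab$scale == "total", ]
  expect_true(all(is.na(hnr_cells$r)))
  expect_true(all(grepl("constant", hnr_cells$note)))
})

test_that("ICC(A,1) matches its ANOVA closed form and known extremes", {
  set.seed(41)
  w1 <- rnorm(30, 10, 2)
  expect_equal(icc_test_retest(w1, w1)$icc, 1, tolerance = 1e-9)
  w2 <- w1 + rnorm(30, 0, 1)
  expect_equal(icc_test_retest(w1, w2)$icc, oracle_icc_a1(w1, w2),
               tolerance = 1e-9)
  a <- rnorm(200)
  b <- rnorm(200)
  expect_lt(abs(icc_test_retest(a, b)$icc), 0.15)
  z <- icc_test_retest(rep(1, 10), rep(1, 10))
  expect_true(is.na(z$icc))
  expect_match(z$note, "zero variance")
})
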