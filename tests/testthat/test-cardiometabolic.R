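# a reference with round numbers so every z-score is hand-checkable
toy_ref <- function() {
  grid <- expand.grid(sex = c("male", "female"), age_year = 8:12,
                      stringsAsFactors = FALSE)
  comp <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(sex = grid$sex[i], age_year = grid$age_year[i],
                   component = c("triglycerides", "hdl", "glucose",
                                 "sbp", "dbp"),
                   mean = c(80, 50, 85, 100, 60),
                   sd = c(40, 10, 5, 10, 8))
  }))
  waist <- dplyr::mutate(tibble::as_tibble(grid), waist_p90 = 75)
  mets_reference(comp, waist)
}

panel_row <- function(waist = 70, sbp = 100, dbp = 60, tg = 80, hdl = 50,
                      glucose = 85, sex = "male", age = 10) {
  tibble::tibble(participant_id = "X", sex = sex, age_year = age,
                 waist_cm = waist, sbp = sbp, dbp = dbp,
                 triglycerides = tg, hdl = hdl, glucose = glucose)
}

test_that("HOMA follows the printed formula with mg/dL glucose converted", {
  # glucose 18.016 mg/dL is exactly 1 mmol/L, so insulin 22.5 gives HOMA 1
  expect_equal(compute_homa(22.5, 18.016), 1, tolerance = 1e-9)
  expect_equal(compute_homa(0, 123), 0)
  expect_equal(compute_homa(12, 90), 12 * (90 / 18.016) / 22.5,
               tolerance = 1e-12)
  expect_equal(compute_homa(12, 90), 2.664, tolerance = 1e-3)
  expect_error(compute_homa(-1, 90), "nonnegative")
})

test_that("HOMA is linear in insulin and in glucose separately", {
  set.seed(11)
  ins <- runif(20, 2, 40); glu <- runif(20, 60, 120)
  expect_equal(compute_homa(2 * ins, glu), 2 * compute_homa(ins, glu))
  expect_equal(compute_homa(ins, 3 * glu), 3 * compute_homa(ins, glu))
})

test_that("MetS classification matches a brute-force count over all 2^5 combos", {
  ref <- toy_ref()
  combos <- expand.grid(ob = c(FALSE, TRUE), bp = c(FALSE, TRUE),
                        tg = c(FALSE, TRUE), hdl = c(FALSE, TRUE),
                        glu = c(FALSE, TRUE))
  for (r in seq_len(nrow(combos))) {
    cm <- combos[r, ]
    p <- panel_row(waist = if (cm$ob) 80 else 70,
                   sbp = if (cm$bp) 135 else 100,
                   tg = if (cm$tg) 160 else 80,
                   hdl = if (cm$hdl) 35 else 50,
                   glucose = if (cm$glu) 105 else 85)
    res <- classify_mets(p, ref)
    expected_count <- sum(unlist(cm))   # independent brute-force counter
    expect_equal(res$factor_count, expected_count)
    expect_equal(res$has_mets, expected_count >= 3)
    expect_equal(unname(unlist(res[, c("central_obesity", "elevated_bp",
                                       "elevated_tg", "low_hdl",
                                       "impaired_glucose")])),
                 unname(unlist(cm)))
  }
})

test_that("every printed cutoff boundary is inclusive/exclusive as stated", {
  ref <- toy_ref()
  flag <- function(p, col) classify_mets(p, ref)[[col]]
  expect_true(flag(panel_row(sbp = 130), "elevated_bp"))    # >= 130 inclusive
  expect_false(flag(panel_row(sbp = 129.9), "elevated_bp"))
  expect_true(flag(panel_row(dbp = 85), "elevated_bp"))     # >= 85 inclusive
  expect_false(flag(panel_row(dbp = 84.9), "elevated_bp"))
  expect_true(flag(panel_row(tg = 150), "elevated_tg"))     # >= 150 inclusive
  expect_false(flag(panel_row(tg = 149.9), "elevated_tg"))
  expect_false(flag(panel_row(hdl = 40), "low_hdl"))        # < 40 strict
  expect_true(flag(panel_row(hdl = 39.9), "low_hdl"))
  expect_true(flag(panel_row(glucose = 100), "impaired_glucose"))
  expect_false(flag(panel_row(glucose = 99.9), "impaired_glucose"))
  expect_true(flag(panel_row(waist = 75), "central_obesity")) # >= p90
  expect_false(flag(panel_row(waist = 74.9), "central_obesity"))
})

test_that("raising any risk component never decreases the factor count", {
  ref <- toy_ref()
  set.seed(12)
  for (rep in 1:20) {
    p <- panel_row(waist = runif(1, 60, 90), sbp = runif(1, 90, 140),
                   dbp = runif(1, 50, 95), tg = runif(1, 40, 200),
                   hdl = runif(1, 30, 70), glucose = runif(1, 70, 110))
    base <- classify_mets(p, ref)$factor_count
    worse <- p
    worse$waist_cm <- worse$waist_cm + 10
    worse$sbp <- worse$sbp + 10
    worse$triglycerides <- worse$triglycerides + 40
    worse$hdl <- worse$hdl - 10
    worse$glucose <- worse$glucose + 10
    expect_gte(classify_mets(worse, ref)$factor_count, base)
  }
})

test_that("missing components mark the classification incomplete", {
  ref <- toy_ref()
  p <- panel_row(); p$hdl <- NA
  res <- classify_mets(p, ref)
  expect_false(res$mets_complete)
  expect_true(is.na(res$has_mets))
})

test_that("the MetS z-score sums component z-scores with HDL reversed", {
  ref <- toy_ref()
  expect_equal(compute_mets_z(panel_row(), ref), 0)            # at means
  expect_equal(compute_mets_z(panel_row(tg = 120), ref), 1)    # +1 SD TG
  # HDL one SD above its mean lowers the composite under the default sign
  expect_equal(compute_mets_z(panel_row(hdl = 60), ref), -1)
  expect_equal(compute_mets_z(panel_row(hdl = 60), ref,
                              hdl_direction = "raw"), 1)
  # affine reparameterization: shifting a stratum mean by delta shifts the
  # composite by -delta/sd
  ref2 <- toy_ref()
  ref2$components$mean[ref2$components$component == "glucose"] <-
    ref2$components$mean[ref2$components$component == "glucose"] + 5
  expect_equal(compute_mets_z(panel_row(), ref2),
               compute_mets_z(panel_row(), ref) - 5 / 5)
  expect_error(compute_mets_z(panel_row(age = 14), ref), "stratum")
})

test_that("center z-scores are standardized within each center", {
  set.seed(13)
  x <- rnorm(50, 10, 2)
  ct <- rep(c("vitoria", "granada"), 25)
  x[ct == "granada"] <- x[ct == "granada"] + 3
  z <- center_zscore(x, ct)
  for (c0 in unique(ct)) {
    expect_equal(mean(z[ct == c0]), 0, tolerance = 1e-9)
    expect_equal(sd(z[ct == c0]), 1, tolerance = 1e-9)
  }
  # single shared center reduces to the ordinary z-score
  expect_equal(center_zscore(x, rep("a", 50)), as.numeric(scale(x)))

  # 6-value fixture against hand-computed z-scores:
  # center A: 2, 4, 6 (mean 4, sd 2); center B: 10, 20, 30 (mean 20, sd 10)
  z6 <- center_zscore(c(2, 4, 6, 10, 20, 30),
                      c("A", "A", "A", "B", "B", "B"))
  expect_equal(z6, c(-1, 0, 1, -1, 0, 1))

  expect_error(center_zscore(c(1, 2, 5), c("A", "A", "B")),
               "fewer than 2")
  expect_error(center_zscore(c(1, 1, 5, 5), c("A", "A", "B", "B")),
               "zero variance")
})

test_that("only the four skewed measures are log-transformed", {
  d <- tibble::tibble(participant_id = c("a", "b"),
                      triglycerides = c(89.9, 120), ggt = c(15, 20),
                      insulin = c(10, 12), homa = c(1, 2.5),
                      total_chol = c(170, 150))
  out <- transform_outcomes(d)
  expect_equal(out$log_triglycerides[1], log(89.9))
  expect_equal(out$log_triglycerides[1], 4.499, tolerance = 1e-3)
  expect_equal(out$log_homa[1], 0)
  expect_equal(out$total_chol, d$total_chol)
  expect_false("log_total_chol" %in% names(out))
  man <- attr(out, "transform_manifest")
  expect_equal(sum(man$transform == "natural_log"), 4)

  d$ggt[2] <- 0
  expect_error(transform_outcomes(d), "participant b")
})
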