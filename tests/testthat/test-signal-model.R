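test_that("theoretical log2-ratio behaves like the contamination signal model", {
  # diploid signal is the null value regardless of contamination or background
  expect_equal(theoretical_log2ratio(2, p = 0.37, b = 1.1), 0)
  # pure normal cells give the diploid signal even at copy number 0
  expect_equal(theoretical_log2ratio(0, p = 1, b = 0.5), 0)
  # the three-copy mean at 20% contamination sets the published SNR label 1.5
  m3 <- theoretical_log2ratio(3, p = 0.2, b = 1.47)
  expect_equal(m3, 0.299, tolerance = 2e-3)
  expect_equal(round(m3 / 0.2, 1), 1.5)
  # strictly increasing in copy number for p < 1
  for (p in c(0, 0.2, 0.8)) {
    expect_true(all(diff(theoretical_log2ratio(0:6, p = p)) > 0))
  }
  # every mean shrinks monotonically to 0 as contamination grows
  for (j in c(0, 1, 3, 6)) {
    ms <- theoretical_log2ratio(j, p = seq(0, 1, 0.1))
    expect_true(all(diff(abs(ms)) <= 1e-12))
    expect_equal(ms[length(ms)], 0)
  }
  expect_error(theoretical_log2ratio(-1), "non-negative")
  expect_error(theoretical_log2ratio(2, p = 1.5), "\\[0, 1\\]")
})

test_that("background calibration recovers b by least squares", {
  # published means for CN 1, 3, 4, 5 pin b near 1.47 (grid oracle agreement)
  pairs <- data.frame(cn = c(1, 3, 4, 5),
                      log2ratio = c(-0.49, 0.365, 0.657, 0.899))
  b <- calibrate_background(pairs)
  expect_equal(b, grid_background(pairs$cn, pairs$log2ratio), tolerance = 1e-3)
  expect_equal(b, 1.47, tolerance = 5e-3)
  # and the implied zero-copy mean matches the published -1.24
  expect_equal(theoretical_log2ratio(0, 0, b), -1.239, tolerance = 1e-3)
  # a single exactly-constructed pair inverts exactly
  expect_equal(
    calibrate_background(data.frame(cn = 3, log2ratio = log2((3 + 2) / (2 + 2)))),
    2, tolerance = 1e-6
  )
  # calibrating from the zero-copy mean alone cross-checks the same b
  expect_equal(calibrate_background(data.frame(cn = 0, log2ratio = -1.24)),
               grid_background(0, -1.24), tolerance = 1e-3)
  # round trip: noiseless pairs generated at known b return b
  for (b0 in c(0.5, 1.47, 3)) {
    pairs0 <- data.frame(cn = c(0, 1, 3, 4),
                         log2ratio = theoretical_log2ratio(c(0, 1, 3, 4), 0, b0))
    expect_equal(calibrate_background(pairs0), b0, tolerance = 1e-5)
  }
  expect_error(calibrate_background(data.frame(cn = 2, log2ratio = 0)),
               "unidentifiable")
})

test_that("default classes are the seven disjoint intervals around the class means", {
  cls <- cn_classes()
  expect_equal(nrow(cls), 7)
  expect_equal(cls$cn, c(0L, 1L, 2L, 3L, 4L, 5L, 6L))
  # published intervals, diploid one symmetric about 0
  expect_equal(cls$lower, c(-2, -0.6, -0.05, 0.15, 0.45, 0.75, 0.95))
  expect_equal(cls$upper, c(-0.8, -0.25, 0.05, 0.4, 0.66, 0.9, 1.3))
  expect_equal(cls$lower[cls$cn == 3], 0.15)
  expect_equal(cls$upper[cls$cn == 3], 0.4)
  # pairwise disjoint, strictly increasing, diploid contains 0
  expect_true(all(cls$lower[-1] > cls$upper[-7]))
  expect_true(cls$lower[3] < 0 && cls$upper[3] > 0)
  # intervals contain the contamination-shrunk means up to p = 0.2 for CN 1-5
  # (CN 0 and >5 are anchored at the uncontaminated means instead)
  for (p in seq(0, 0.2, by = 0.05)) {
    m <- theoretical_log2ratio(cls$cn, p = p)
    inside <- m > cls$lower & m < cls$upper
    expect_true(all(inside[2:6]), info = paste("p =", p))
  }
  m0 <- theoretical_log2ratio(cls$cn, p = 0)
  expect_true(all(m0 > cls$lower & m0 < cls$upper))
})

test_that("contamination-centered classes shrink toward 0 and stay disjoint", {
  cls0 <- cn_classes_contaminated(p = 0, half_widths = 0.1)
  expect_equal(cls0$theoretical_mean,
               theoretical_log2ratio(c(0:5, 6), 0, 1.47))
  # tiny widths are left unshrunk
  tiny <- cn_classes_contaminated(p = 0, half_widths = 0.01)
  expect_equal(tiny$upper - tiny$lower, rep(0.02, 7))
  # generous widths get shrunk to disjointness
  wide <- cn_classes_contaminated(p = 0, half_widths = 0.5)
  expect_true(all(wide$lower[-1] > wide$upper[-7]))
  # non-diploid centers move strictly toward 0 with contamination
  cls2 <- cn_classes_contaminated(p = 0.2, half_widths = 0.1)
  nondip <- cls2$cn != 2
  expect_true(all(abs(cls2$theoretical_mean[nondip]) <
                    abs(cls0$theoretical_mean[nondip])))
  expect_true(cls2$lower[3] < 0 && cls2$upper[3] > 0)
  expect_error(cn_classes_contaminated(p = 1), "collapse")
})

test_that("class tables export as tab-delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classes(cn_classes(), path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 7)
  expect_equal(back$lower, cn_classes()$lower)
  expect_equal(back$theoretical_mean, cn_classes()$theoretical_mean)
})
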