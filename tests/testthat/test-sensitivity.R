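p0 <- default_parameters()
base <- incremental_result(p0)

test_that("one-way evaluation perturbs a single parameter over its range", {
  ow <- one_way(p0, "mdTimeB")
  expect_equal(ow$lowInput, 3.1)
  expect_equal(ow$highInput, 8.1)
  expect_identical(ow$costA_low, ow$costA_high) # A ignores ultrasound time
  expect_gt(ow$diff_low, 0)
  expect_lt(ow$diff_high, 0)
  # At the upper extreme the ultrasound protocol is ~3% more costly.
  expect_equal(round(100 * (ow$costB_high - ow$costA_high) / ow$costA_high),
               3)

  # Varying the technician time moves protocol A and, through the diverted
  # patients, protocol B: diff at techTimeA = 10 is
  # 15.93 - (13.216 + 0.078252 * 15.93).
  ow_tech <- one_way(p0, "techTimeA")
  expect_equal(ow_tech$costA_low, 15.93, tolerance = 1e-12)
  expect_equal(ow_tech$diff_low, 15.93 - (13.216 + 0.078252 * 15.93),
               tolerance = 1e-12)

  expect_error(one_way(p0, "bogus"), "unknown parameter.*mdTimeB")
})

test_that("a degenerate range reproduces the base case at both ends", {
  p <- p0
  p$times$rnTimeB <- list(central = 5.6, low = 5.6, high = 5.6)
  ow <- one_way(p, "rnTimeB")
  expect_identical(ow$diff_low, ow$diff_high)
  expect_equal(ow$diff_low, base$absoluteSavings, tolerance = 1e-12)
})

test_that("central-value evaluation matches the base case bit-for-bit", {
  for (lab in parameter_labels()) {
    ctr <- parameter_range(p0, lab)[["central"]]
    r <- incremental_result(set_parameter(p0, lab, ctr))
    expect_identical(r$absoluteSavings, base$absoluteSavings)
    expect_identical(r$costA, base$costA)
    expect_identical(r$costB, base$costB)
  }
})

test_that("tornado entries are swing-sorted with a fixed tie-break", {
  tor <- tornado(p0)
  expect_equal(nrow(tor), 7L) # wages excluded by default
  expect_true(all(diff(tor$swing) <= 0))
  expect_identical(tor$parameter[1], "mdTimeB")
  # Linearity: the bedside-physician-time swing is wage * range width.
  expect_equal(tor$swing[tor$parameter == "mdTimeB"], 1.72 * (8.1 - 3.1),
               tolerance = 1e-9)
  # Exactly one parameter flips the savings negative at an extreme.
  flips <- tor$parameter[tor$diff_low < 0 | tor$diff_high < 0]
  expect_identical(flips, "mdTimeB")

  tor_w <- tornado(p0, include_wages = TRUE)
  expect_equal(nrow(tor_w), 11L)
  expect_true(all(tor_w$diff_low[tor_w$parameter != "mdTimeB"] > 0))
  expect_true(all(tor_w$diff_high[tor_w$parameter != "mdTimeB"] > 0))

  # Percent metric rescales by the base protocol-A cost.
  tor_pct <- tornado(p0, metric = "percent")
  expect_equal(tor_pct$swing, 100 * tor$swing / base$costA)

  # Determinism: identical call, identical ordering; collapsed ranges give
  # all-zero swings ordered lexicographically (the tie-break).
  expect_identical(tornado(p0), tor)
  p_flat <- p0
  for (lab in parameter_labels(include_wages = FALSE)) {
    ctr <- parameter_range(p0, lab)[["central"]]
    loc <- if (lab %in% c("pMalposition", "pPneumothorax")) "probabilities"
           else "times"
    p_flat[[loc]][[lab]] <- list(central = ctr, low = ctr, high = ctr)
  }
  tor_flat <- tornado(p_flat)
  expect_true(all(tor_flat$swing == 0))
  expect_identical(tor_flat$parameter, sort(tor_flat$parameter))
})

test_that("two-way grids span both ranges and agree with one-way corners", {
  tw <- two_way(p0, "mdTimeB", "rnTimeB")
  expect_equal(dim(tw$diff), c(11L, 11L))
  expect_equal(range(tw$xValues), c(3.1, 8.1))
  # Corner at (8.1, 8.1): hand arithmetic.
  expect_equal(tw$diff[11, 11],
               18.48 - (8.1 * 1.72 + 8.1 * 0.64 +
                          (0.068 + 0.932 * 0.011) * 18.48),
               tolerance = 1e-12)
  # Corner equals the composed direct evaluation.
  p_corner <- set_parameter(set_parameter(p0, "mdTimeB", 3.1), "rnTimeB", 8.1)
  expect_equal(tw$diff[1, 11],
               incremental_result(p_corner)$absoluteSavings,
               tolerance = 1e-12)
  # Center cell of the odd grid is the base case.
  expect_equal(tw$diff[6, 6], base$absoluteSavings, tolerance = 1e-12)

  tw2 <- two_way(p0, "techTimeA", "pMalposition", gridPoints = 2)
  expect_equal(dim(tw2$diff), c(2L, 2L))
  long <- two_way_long(tw2)
  expect_equal(nrow(long), 4L)
  expect_equal(long$diff, as.vector(tw2$diff))

  expect_error(two_way(p0, "mdTimeB", "mdTimeB"), "distinct")
})

test_that("break-even roots match an independent bisection oracle", {
  # Bedside physician time in the ultrasound protocol: the one parameter
  # whose range contains a break-even.
  root <- break_even(p0, "mdTimeB")
  expect_equal(round(root, 2), 7.82)
  f <- function(t) incremental_result(set_parameter(p0, "mdTimeB", t))$absoluteSavings
  expect_lt(abs(f(root)), 1e-9)
  expect_lt(abs(root - bisect_root(f, 3.1, 8.1)), 1e-6)

  # Technician time: root sits below the sensitivity range (B is cheaper
  # everywhere within it), still found in the extended window.
  root_tech <- break_even(p0, "techTimeA")
  expect_lt(root_tech, 10)
  f_tech <- function(t) incremental_result(set_parameter(p0, "techTimeA", t))$absoluteSavings
  expect_lt(abs(f_tech(root_tech)), 1e-9)
  expect_lt(abs(root_tech - bisect_root(f_tech, 0, 10)), 1e-6)

  # Pneumothorax probability cannot flip the comparison anywhere in [0, 1].
  expect_true(is.na(break_even(p0, "pPneumothorax")))
})

test_that("break-even handles flat cost differences", {
  # Degenerate construction: zero-duration ultrasound tasks and certain
  # malposition make protocol B cost exactly protocol A for every value of
  # the pneumothorax probability -> the difference is identically zero and
  # the central value is returned.
  p <- set_parameter(set_parameter(p0, "mdTimeB", 0), "rnTimeB", 0)
  p <- set_parameter(p, "pMalposition", 1)
  p$probabilities$pPneumothorax <- list(central = 0.2, low = 0.1, high = 0.4)
  expect_equal(break_even(p, "pPneumothorax", convention = "sequential"),
               0.2)

  # Flat but nonzero difference: no break-even exists.
  p2 <- set_parameter(p, "rnTimeB", 2)
  expect_true(is.na(break_even(p2, "pPneumothorax",
                               convention = "sequential")))
})
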