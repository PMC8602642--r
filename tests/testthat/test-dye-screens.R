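test_that("thymol blue scoring uses the A435/A545 ratio and guards the division", {
  plate <- data.frame(
    plate_id = 1L, well = c("A1", "A3", "B2", "A4"),
    row = c("A", "A", "B", "A"), col = c(1L, 3L, 2L, 4L),
    od590 = 1, a435 = c(0.4, 0.5, 9.9, 0.3), a545 = c(0.8, 0, 9.9, 0.6),
    occupied = c(TRUE, TRUE, FALSE, FALSE),
    control = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  sc <- tb_score(plate)
  expect_identical(nrow(sc), 2L)             # controls and empties excluded
  expect_equal(sc$value[sc$well == "A1"], 0.5)
  a3 <- sc[sc$well == "A3", ]
  expect_false(a3$valid)
  expect_identical(a3$reason_invalid, "division_hazard")
  expect_true(is.na(a3$value))
})

test_that("a full assay plate scores 94 occupied wells (96 minus 2 controls)", {
  layout <- make_cc_layout(sprintf("s%02d", 1:94))
  ro <- generate_plate_readouts(layout, sim_config(seed = 2))
  expect_identical(nrow(tb_score(ro$endpoint)), 94L)
})

test_that("the two-point calibration line is recovered exactly", {
  # hand solve through (pH 2.0, r 0.2) and (pH 3.4, r 1.6):
  # slope = 1.4 / 1.4 = 1.0; intercept = 2.0 - 1.0 * 0.2 = 1.8
  cal <- fit_tb_calibration(data.frame(ph = c(2.0, 3.4), ratio = c(0.2, 1.6)))
  expect_equal(cal$slope, 1.0)
  expect_equal(cal$intercept, 1.8)
  perfect <- data.frame(ph = seq(2, 3.4, length.out = 5))
  perfect$ratio <- (perfect$ph - 1.8)
  expect_equal(fit_tb_calibration(perfect)$r_squared, 1.0)
  expect_error(fit_tb_calibration(data.frame(ph = 2.5, ratio = 1)), ">= 2")
  expect_error(fit_tb_calibration(
    data.frame(ph = c(2, 3), ratio = c(1, 1))), "variance")
})

test_that("calibration recovers a known line from noisy standards within 3 SE", {
  set.seed(6)
  ph <- runif(40, 2, 3.4)
  ratio <- (ph - 1.8) / 1.0 + rnorm(40, 0, 0.01)
  cal <- fit_tb_calibration(data.frame(ph = ph, ratio = ratio))
  fit <- stats::lm(ph ~ ratio)
  se <- summary(fit)$coefficients["ratio", "Std. Error"]
  expect_lt(abs(cal$slope - 1.0), 3 * se)
})

test_that("ratio-to-pH conversion flags extrapolation and round-trips the line", {
  ident <- structure(list(slope = 1, intercept = 0, r_squared = 1,
                          valid_ph_range = c(2, 3.4)),
                     class = "tb_calibration")
  out <- ratio_to_ph(ident, c(2.5, 4.0))
  expect_equal(out$ph, c(2.5, 4.0))
  expect_identical(out$in_range, c(TRUE, FALSE))
  cal <- fit_tb_calibration(data.frame(ph = c(2.0, 2.7, 3.4),
                                       ratio = c(0.2, 0.9, 1.6)))
  ph_in <- seq(2.05, 3.35, length.out = 7)
  expect_equal(ratio_to_ph(cal, (ph_in - 1.8))$ph, ph_in, tolerance = 1e-9)
})

test_that("kinetic rate fitting matches closed-form least squares", {
  exact <- bpb_rate(seq(1.0, 0.4, by = -0.1))
  expect_equal(exact$V, 0.1)
  expect_equal(exact$r_squared, 1.0)
  flat <- bpb_rate(rep(0.7, 7))
  expect_equal(flat$V, 0)
  expect_equal(flat$r_squared, 0)
  set.seed(3)
  for (i in 1:20) {
    y <- 1 - 0.05 * (0:6) + rnorm(7, 0, 0.02)
    got <- bpb_rate(y)
    fit <- stats::lm(y ~ t, data = data.frame(y = y, t = 0:6))
    expect_equal(got$V, -unname(coef(fit)[2]), tolerance = 1e-12)
    expect_equal(got$r_squared, summary(fit)$r.squared, tolerance = 1e-12)
  }
  expect_error(bpb_rate(c(1, NA, 1, 1, 1, 1, 1)), "non-finite")
  expect_error(bpb_rate(rep(1, 3), times = rep(2, 3)), "time variance")
})

test_that("rate scores are invalidated for poor fits and failed growth", {
  plate <- data.frame(
    plate_id = 1L, well = c("A1", "A3", "A4"), row = "A", col = c(1L, 3L, 4L),
    od590 = c(1.2, 1.0, 0.0), a435 = 1, a545 = 1,
    occupied = TRUE, control = FALSE, stringsAsFactors = FALSE)
  set.seed(10)
  kin <- rbind(
    data.frame(plate_id = 1L, well = "A1", t_min = 0:6,
               a600 = 1 - 0.072 * (0:6)),          # V = 0.072, R2 = 1
    data.frame(plate_id = 1L, well = "A3", t_min = 0:6,
               a600 = rnorm(7, 0.7, 0.3)),          # no trend: R2 < 0.5
    data.frame(plate_id = 1L, well = "A4", t_min = 0:6,
               a600 = 1 - 0.05 * (0:6)))
  sc <- bpb_score(plate, kin)
  expect_equal(sc$value[sc$well == "A1"], 0.072 / 1.2, tolerance = 1e-9)
  expect_identical(sc$reason_invalid[sc$well == "A3"], "low_r2")
  expect_identical(sc$reason_invalid[sc$well == "A4"], "no_growth")
})

test_that("plate outlier bounds follow the inclusive quartile convention", {
  sc <- tb_score(plate_from_values(c(1:8, 100)))
  out <- call_plate_outliers(sc)
  expect_equal(out$q1, 3)
  expect_equal(out$q3, 7)
  expect_equal(out$ub, 13)
  expect_identical(out$flags$outlier[out$flags$value == 100], "above")
  expect_identical(sum(out$flags$outlier != "none"), 1L)

  same <- call_plate_outliers(tb_score(plate_from_values(c(rep(5, 8), 6))))
  expect_identical(same$flags$outlier[same$flags$value == 6], "above")
  expect_identical(sum(same$flags$outlier != "none"), 1L)

  tight <- call_plate_outliers(tb_score(plate_from_values(c(4, 5, 6, 7, 5))))
  expect_true(all(tight$flags$outlier == "none"))
  expect_warning(expect_null(
    call_plate_outliers(tb_score(plate_from_values(c(1, 2, 3))))),
    "fewer than 4")
})

test_that("quartiles equal a sorting-based interpolation oracle on random plates", {
  set.seed(12)
  for (i in 1:500) {
    v <- rnorm(sample(4:94, 1))
    out <- call_plate_outliers(tb_score(plate_from_values(v)))
    expect_equal(out$q1, oracle_quantile_inc(v, 0.25), tolerance = 1e-12)
    expect_equal(out$q3, oracle_quantile_inc(v, 0.75), tolerance = 1e-12)
  }
})

test_that("control wells never enter the quartile computation", {
  plate <- plate_from_values(rep(c(1, 1.1), 10))
  ctrl <- data.frame(plate_id = 1L, well = c("B2", "E7"),
                     row = c("B", "E"), col = c(2L, 7L),
                     od590 = 1, a435 = c(500, -500), a545 = 1,
                     occupied = FALSE, control = TRUE,
                     stringsAsFactors = FALSE)
  with_ctrl <- call_plate_outliers(tb_score(rbind(plate, ctrl)))
  without <- call_plate_outliers(tb_score(plate))
  expect_identical(with_ctrl$q1, without$q1)
  expect_identical(with_ctrl$ub, without$ub)
})

test_that("the majority / 1-of-2 hit rule is applied per strain with coherent direction", {
  flags <- data.frame(
    plate_id = 1L,
    well = sprintf("W%d", 1:13),
    value = 0,
    outlier = c("below", "none",                       # s1: 1 of 2
                "above", "none", "none",               # s2: 1 of 3
                rep("below", 4), rep("none", 2),       # s3: 4 of 6
                "below", "above"),                     # s4: mixed
    stringsAsFactors = FALSE)
  strain_wells <- data.frame(
    strain_id = c("s1", "s1", "s2", "s2", "s2", rep("s3", 6), "s4", "s4"),
    plate_id = 1L, well = sprintf("W%d", 1:13),
    stringsAsFactors = FALSE)
  hits <- call_hits(strain_wells, flags)
  h <- function(s) hits[hits$strain_id == s, ]
  expect_true(h("s1")$is_hit)
  expect_identical(h("s1")$direction, "below")
  expect_false(h("s2")$is_hit)                 # 1 of 3 is not over half
  expect_true(h("s3")$is_hit)
  expect_identical(h("s3")$direction, "below")
  expect_false(h("s4")$is_hit)                 # direction-incoherent
  expect_error(call_hits(rbind(strain_wells, strain_wells[1, ]), flags),
               "more than one strain")
})

test_that("screen merging follows inclusion-exclusion on gene sets", {
  tb <- paste0("g", 1:282)
  bpb <- paste0("g", c(1:60, 1001:1022))
  m <- merge_screens(tb, bpb)
  expect_identical(m$n_tb, 282L)
  expect_identical(m$n_bpb, 82L)
  expect_identical(m$n_both, 60L)
  expect_identical(m$n_union, 304L)
  expect_identical(m$n_union, m$n_tb + m$n_bpb - m$n_both)
  disjoint <- merge_screens(c("a", "b"), c("c"))
  expect_identical(disjoint$n_union, 3L)
  same <- merge_screens(c("a", "b"), c("a", "b"))
  expect_identical(same$n_union, 2L)
})
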