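test_that("Ernst angle formula, rounding, and limits", {
  expect_equal(ernst_angle(1738, 717.2), 84.91535, tolerance = 1e-6)
  expect_equal(ernst_angle_deg(1738, 717.2), 85)
  expect_equal(ernst_angle(1386, 717.2), 81.67525, tolerance = 1e-6)
  expect_equal(ernst_angle_deg(1386, 717.2), 82)
  # TR >> T1 limit -> 90 degrees
  expect_equal(ernst_angle(1e9, 717.2), 90)
  # TR = T1 -> acos(1/e) = 68.4151 degrees (closed form, high precision)
  expect_equal(ernst_angle(717.2, 717.2), acos(exp(-1)) * 180 / pi)
  expect_equal(ernst_angle(717.2, 717.2), 68.41511, tolerance = 1e-6)
  expect_error(ernst_angle(-1, 717.2), "positive")
})

test_that("rounded Ernst angles reproduce both printed flip-angle lists", {
  for (res in c("3.4mm", "4mm")) {
    g <- reference_protocol_grid(res)
    expect_identical(ernst_angle_deg(g$tr, 717.2), g$fa)
  }
})

test_that("BOLD SNR model matches an independent arithmetic recomputation", {
  # 3.4 mm rows TE = 55 (TR 2879, FA 89) and TE = 65 (TR 3259, FA 89),
  # T1 = 717.2, T2* = 86; expected values recomputed term by term
  ref <- function(te, tr, fa) {
    e1 <- exp(-tr / 717.2)
    3.4^3 * te * sqrt(32.1) * ((1 - e1) * sin(fa * pi / 180) /
                                 (1 - e1 * cos(fa * pi / 180))) * exp(-te / 86)
  }
  mk <- function(te, tr, fa) epi_protocol(
    voxel_dims = 3.4, etl = 70, n_slices = 38, te = te, tr = tr,
    flip_angle = fa, echo_spacing = 32.1 / 70)
  rel <- relaxation_params(717.2, 86, "GM")
  s55 <- snr_bold(mk(55, 2879, 89), rel)
  s65 <- snr_bold(mk(65, 3259, 89), rel)
  expect_equal(s55, ref(55, 2879, 89), tolerance = 1e-12)
  expect_equal(s65, ref(65, 3259, 89), tolerance = 1e-12)
  # frozen derived oracle: the ratio before 1/sqrt(TR) weighting
  expect_equal(s55 / s65, 0.9434798, tolerance = 1e-6)

  # TE -> 0 kills the signal linearly
  tiny <- epi_protocol(voxel_dims = 1, etl = 2, n_slices = 1, te = 1e-6,
                       tr = 1000, flip_angle = 45, echo_spacing = 1e-6,
                       prep_time = 0)
  expect_lt(snr_bold(tiny, rel), 1e-5)

  # TR >> T1 at 90 degrees: steady-state bracket -> 1
  sat <- mk(55, 5e5, 90)
  expect_equal(snr_bold(sat, rel),
               3.4^3 * 55 * sqrt(32.1) * exp(-55 / 86), tolerance = 1e-9)

  expect_error(snr_bold(mk(55, 2879, NULL), rel), "flip angle")
})

test_that("snr_bold at the exact Ernst angle matches the algebraic identity", {
  rel <- relaxation_params(717.2, 86, "GM")
  for (tr in c(900, 1738, 3259)) {
    fa <- ernst_angle(tr, rel$t1)
    p <- epi_protocol(voxel_dims = 3.4, etl = 70, n_slices = 38, te = 55,
                      tr = tr, flip_angle = fa, echo_spacing = 0.45)
    e1 <- exp(-tr / rel$t1)
    ident <- 3.4^3 * 55 * sqrt(p$tad) * exp(-55 / 86) *
      sqrt((1 - e1) / (1 + e1))
    expect_equal(snr_bold(p, rel), ident, tolerance = 1e-10)
  }
})

test_that("time-series averaging and the fixed-scan-time identity", {
  expect_equal(timeseries_snr(3, 64), 24)
  expect_equal(timeseries_snr(3, 1), 3)
  expect_error(timeseries_snr(3, 0), ">= 1")
  expect_equal(contrast_efficiency(0, 100), 0)
  # quadrupling TR at fixed SNR halves efficiency
  expect_equal(contrast_efficiency(10, 4000), contrast_efficiency(10, 1000) / 2)
  expect_error(contrast_efficiency(10, 0), "positive")
  # sqrt(TS/TR) * SNR = sqrt(TS) * eta for TS a multiple of TR
  for (tr in c(500, 2879)) for (n in c(8, 64)) {
    ts <- n * tr
    expect_equal(timeseries_snr(7, ts / tr),
                 sqrt(ts) * contrast_efficiency(7, tr))
  }
})

test_that("grid-mode TE optimization finds the efficiency optimum", {
  g <- reference_protocol_grid("3.4mm")
  for (t2s in c(86, 86.3, 78.5)) {
    ec <- optimize_te(relaxation_params(717.2, t2s, "GM"),
                      g$te, g$tr, g$fa, voxel_volume = 3.4^3)
    expect_s3_class(ec, "efficiency_curve")
    expect_equal(attr(ec, "te_opt"), 55)
    expect_equal(ec$eta, ec$snr_bold / sqrt(ec$tr))
    expect_true(attr(ec, "te_opt") %in% ec$te)
  }
  # efficiency ordering on the printed grid (frozen derived ordering)
  ec <- optimize_te(relaxation_params(717.2, 86, "GM"), g$te, g$tr, g$fa)
  eta <- ec$eta
  expect_gt(eta[g$te == 55], eta[g$te == 65])
  expect_gt(eta[g$te == 65], eta[g$te == 45])
  # flip angles default to the exact Ernst angle when not supplied
  ec2 <- optimize_te(relaxation_params(717.2, 86, "GM"), g$te, g$tr)
  expect_equal(ec2$fa, ernst_angle(g$tr, 717.2))
  expect_equal(attr(ec2, "te_opt"), 55)

  expect_error(optimize_te(default_relaxation("GM"), numeric(0)), "empty")
  expect_error(optimize_te(default_relaxation("GM"), c(25, 25, 35)),
               "strictly increasing")
})

test_that("continuous-mode optimum: TE = T2* when TR is decoupled, else below", {
  rel <- relaxation_params(717.2, 86.3, "GM")
  ec <- optimize_te(rel, mode = "continuous", tr = 3000,
                    interval = c(5, 300))
  expect_identical(attr(ec, "te_opt"), 86.3)
  # with TR strictly increasing in TE the optimum moves below T2*
  for (nsl in c(16, 38)) {
    eci <- optimize_te(rel, mode = "continuous",
                       tr_fun = function(te) tr_for_te(te, nsl, 20.76),
                       interval = c(5, 300))
    expect_lt(attr(eci, "te_opt"), rel$t2star)
  }
})
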