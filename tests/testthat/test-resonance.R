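test_that("normalised power spectra peak at exactly one", {
  cfg <- two_cell_config(ref_resonant(), R_GJ = 100)
  ps <- power_function(function(w) two_cell_ghat(cfg, "m-", 10, 100, w))
  expect_equal(max(ps$P), 1)
  expect_true(all(ps$P >= 0))
})

test_that("the preferred frequency equals the analytic decay-rate minimiser", {
  mp <- ref_resonant()
  cfg <- two_cell_config(mp, R_GJ = 100)
  # every segment formula decreases in gamma, so Omega0 = argmin gamma(omega):
  # omega* = 1/sqrt(C L) - r/L in internal units
  om_star <- 1 / sqrt(mp$C * mp$L) - mp$r / mp$L
  for (seg in c("m-", "m+", "n-")) {
    om0 <- find_omega0(function(w) two_cell_ghat(cfg, seg, 10, 100, w))
    expect_equal(om0, om_star, tolerance = 1e-4)
  }
})

test_that("a passive network is low-pass: the maximum sits at the interval edge", {
  cfg <- two_cell_config(ref_passive(), R_GJ = 100)
  expect_warning(
    om0 <- find_omega0(function(w) two_cell_ghat(cfg, "m-", 10, 100, w)),
    "boundary")
  expect_equal(om0, 1e-3)
})

test_that("the cross-cell spectrum is more band-limited than the same-cell ones", {
  cfg <- two_cell_config(ref_resonant(), R_GJ = 100)
  gh <- function(seg) function(w) two_cell_ghat(cfg, seg, 10, 100, w)
  om0 <- find_omega0(gh("m-"))
  at2 <- function(seg) {
    ps <- power_function(gh(seg), Omega = seq(0.01, 2.5, by = 0.005))
    stats::approx(ps$Omega, ps$P, xout = 2 * om0)$y
  }
  expect_lt(at2("n-"), at2("m-"))
  expect_lt(at2("n-"), at2("m+"))
})

test_that("Omega0 is invariant under rescaling of the response", {
  cfg <- two_cell_config(ref_resonant(), R_GJ = 100)
  gh <- function(w) two_cell_ghat(cfg, "m-", 10, 100, w)
  expect_equal(find_omega0(gh), find_omega0(function(w) 7.3 * gh(w)),
               tolerance = 1e-7)
  a <- power_function(gh)
  b <- power_function(function(w) 7.3 * gh(w))
  expect_equal(a$P, b$P, tolerance = 1e-12)
})

test_that("somatic Omega0 depends on the coupling resistance in the two-soma network", {
  cfg <- network_fixture("sweep_all_resonant")
  sw <- sweep_gj_location(cfg, L_GJ = c(100, 300), R_GJ = c(100, 1000))
  wide <- merge(sw[sw$R_GJ_MOhm == 100, ], sw[sw$R_GJ_MOhm == 1000, ],
                by = c("cell", "L_GJ_um"))
  expect_gt(max(abs(wide$omega0_rad_per_ms.x - wide$omega0_rad_per_ms.y)), 1e-3)
})

test_that("sweep trends follow the soma/dendrite membrane combination", {
  lg <- seq(50, 500, by = 150)
  sw <- sweep_gj_location(network_fixture("sweep_passive_soma"),
                          L_GJ = lg, R_GJ = 100)
  expect_true(all(sweep_trend(sw)$trend == "increasing"))
  sw2 <- sweep_gj_location(network_fixture("sweep_resonant_soma_passive_dendrites"),
                           L_GJ = lg, R_GJ = 100)
  expect_true(all(sweep_trend(sw2)$trend == "decreasing"))
  expect_error(sweep_gj_location(network_fixture("sweep_passive_soma"),
                                 L_GJ = numeric(0)), "empty")
})
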