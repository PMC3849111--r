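test_that("at the junction the two cells' responses sum to the free-cable kernel", {
  cfg <- two_cell_config(ref_resonant(), R_GJ = 100)
  om <- rand_omega(10)
  y <- 100
  total <- two_cell_ghat(cfg, "m-", 0, y, om) + two_cell_ghat(cfg, "n-", 0, y, om)
  free <- ghat_infinite(cfg$params_m, y, om) / cfg$params_m$cpl
  expect_lt(rel_err(total, free), 1e-12)
})

test_that("with the gap junction removed the stimulated cable is free and the other silent", {
  mp <- ref_resonant()
  cfg <- two_cell_config(mp, R_GJ = 1e12)
  om <- rand_omega(8)
  expect_lt(rel_err(two_cell_ghat(cfg, "m-", 10, 100, om),
                    ghat_infinite(mp, 90, om) / mp$cpl), 1e-10)
  expect_lt(max(Mod(two_cell_ghat(cfg, "n-", 10, 100, om)) /
                  Mod(ghat_infinite(mp, 110, om) / mp$cpl)), 1e-10)
})

test_that("the heterogeneous formulas reduce to the identical-cell ones", {
  mp <- ref_resonant()
  het <- two_cell_config(mp, R_GJ = 100, params_n = membrane_params(
    a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5))
  idn <- two_cell_config(mp, R_GJ = 100)
  om <- rand_omega(20)
  for (seg in c("m-", "m+", "n-")) {
    expect_equal(two_cell_ghat(het, seg, 17, 80, om),
                 two_cell_ghat(idn, seg, 17, 80, om))
  }
})

# The un-simplified four-class expansion: leading single-passage terms plus,
# per reverberation order n, separate reflected (-p_GJ) and transmitted
# (1 - p_GJ) inner contributions.  The package implements only the compact
# resummed form; their equality is an algebraic identity worth guarding.
four_class_ghat2 <- function(cfg, om, x0, y0, n_max = 40) {
  p <- cfg$params
  k <- dendrotrips:::.two_soma_kernels(cfg, om)
  gh <- function(d) exp(-k$g * abs(d)) / (2 * p$D * k$g)
  refl <- 2 * k$ps - 1
  tot <- k$pgj * gh(y0 - x0) + k$pgj * refl * gh(y0 + x0)
  for (n in 0:n_max) {
    common <- (-2 * k$pgj * refl)^n * k$pgj * refl *
      (gh(y0 - x0 + 2 * (n + 1) * cfg$L_GJ) +
         refl * gh(y0 + x0 + 2 * (n + 1) * cfg$L_GJ))
    tot <- tot + common * ((-k$pgj) + (1 - k$pgj))
  }
  tot / p$cpl
}

test_that("the compact word series equals the four-class expansion", {
  cfg <- two_soma_config(ref_resonant(), ref_soma_resonant(), N = 4,
                         L_GJ = 100, R_GJ = 100)
  om <- rand_omega(15)
  for (x0 in c(0, 35)) {
    expect_lt(rel_err(word_series_ghat(cfg, 2, om, x0 = x0, n_max = 40),
                      four_class_ghat2(cfg, om, x0, cfg$y0)), 1e-12)
  }
})

test_that("perfect coupling symmetrises the two somatic responses", {
  cfg <- two_soma_config(ref_resonant(), ref_soma_resonant(), N = 4,
                         L_GJ = 100, R_GJ = 1e-10)
  om <- rand_omega(10)
  w1 <- word_series_ghat(cfg, 1, om)
  w2 <- word_series_ghat(cfg, 2, om)
  expect_lt(rel_err(w1, w2), 1e-8)
  # both equal p_s * Ghat_inf(y0) / cpl (p_GJ = 1/2 kills the series)
  k <- dendrotrips:::.two_soma_kernels(cfg, om)
  ref <- k$ps * ghat_infinite(cfg$params, cfg$y0, om) / cfg$params$cpl
  expect_lt(rel_err(w1, ref), 1e-8)
})

test_that("the word series is converged well before the default truncation", {
  for (nm in c("sweep_passive_soma", "sweep_resonant_soma_passive_dendrites",
               "sweep_all_resonant")) {
    cfg <- network_fixture(nm)
    om <- as.complex(seq(0.05, 2, length.out = 30))
    a <- word_series_ghat(cfg, 1, om, n_max = 10)
    b <- word_series_ghat(cfg, 1, om, n_max = 20)
    expect_lt(rel_err(a, b), 1e-6)
    a2 <- word_series_ghat(cfg, 2, om, n_max = 10)
    b2 <- word_series_ghat(cfg, 2, om, n_max = 20)
    expect_lt(rel_err(a2, b2), 1e-6)
  }
})

test_that("the shifted-pole kernel F obeys its boundary cases", {
  mp <- ref_passive()
  q <- mp$ra / 100
  expect_equal(passive_F(110, c(-3, 0), q, mp), c(0, 0))
  # q = 0: plain heat kernel complementary-error profile
  t <- c(1, 5, 20)
  expect_equal(passive_F(110, t, 0, mp),
               0.5 * exp(-t / mp$tau) * pracma::erfc(110 / (2 * sqrt(mp$D * t))),
               tolerance = 1e-12)
  expect_error(passive_F(1, 1, q, ref_resonant()), "passive")
})

test_that("time-domain segment responses sum to the free-cable solution", {
  mp <- ref_passive()
  cfg <- two_cell_config(mp, R_GJ = 100)
  t <- seq(0.5, 50, by = 1.5)
  x <- 10; y <- 100
  sum_mn <- passive_two_cell_G(cfg, "m-", x, y, t) +
    passive_two_cell_G(cfg, "n-", x, y, t)
  expect_lt(rel_to_max(sum_mn, passive_ginf(x - y, t, mp) / mp$cpl), 1e-12)
  # early times: nothing has crossed the junction yet
  expect_lt(max(abs(passive_two_cell_G(cfg, "n-", x, y, c(1e-4, 1e-3)))), 1e-20)
  # rectangular responses: the gap-junction corrections cancel in the sum
  vm <- passive_rect_response(cfg, "m-", x, y, t)
  vn <- passive_rect_response(cfg, "n-", x, y, t)
  B <- dendrotrips:::.passive_B
  ref <- (B(x - y, t, mp, 2) - B(x - y, t - 5, mp, 2)) / mp$cpl
  expect_equal(vm + vn, ref, tolerance = 1e-9)
})

test_that("degenerate partial-fraction coefficients are flagged", {
  mp <- ref_passive()
  r_degenerate <- mp$ra * sqrt(mp$D * mp$tau)
  cfg <- two_cell_config(mp, R_GJ = r_degenerate)
  expect_error(passive_rect_response(cfg, "n-", 10, 100, 1:5), "perturb")
})
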