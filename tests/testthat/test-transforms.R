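test_that("both inversion schemes recover a textbook transform pair", {
  f <- function(w) 1 / (w + 0.5)
  t <- seq(0.1, 20, by = 0.25)
  ref <- exp(-0.5 * t)
  vb <- inverse_laplace(f, t, estimate_error = FALSE)
  expect_lt(rel_to_max(vb, ref), 1e-8)
  vt <- inverse_laplace(f, t, method = "talbot", estimate_error = FALSE)
  expect_lt(max(abs(vt - ref) / ref), 1e-8) # pointwise for the Talbot contour
})

test_that("numerical inversion matches the passive closed forms", {
  mp <- ref_passive()
  t <- seq(0.5, 50, by = 0.5)
  # free cable at x = 90 um
  ref <- passive_ginf(90, t, mp)
  v <- inverse_laplace(function(w) ghat_infinite(mp, 90, w), t,
                       estimate_error = FALSE)
  expect_lt(rel_to_max(v, ref), 1e-6)
  # shifted-pole kernel at x = 110 um, q = ra / R_GJ
  q <- mp$ra / 100
  fh <- function(w) {
    g <- gamma_branch(mp, w)
    exp(-g * 110) / ((g + q) * 2 * mp$D * g)
  }
  refF <- passive_F(110, t, q, mp)
  vF <- inverse_laplace(fh, t, estimate_error = FALSE)
  expect_lt(rel_to_max(vF, refF), 1e-6)
  # the two schemes agree independently of the oracle
  vF2 <- inverse_laplace(fh, t, method = "talbot", estimate_error = FALSE)
  expect_lt(rel_to_max(vF, vF2), 1e-6)
})

test_that("t <= 0 inverts to zero and low-order runs carry an error estimate", {
  v <- inverse_laplace(function(w) 1 / (w + 1), c(-2, 0, 1))
  expect_equal(v[1:2], c(0, 0))
  expect_warning(
    inverse_laplace(function(w) 1 / (w + 1), seq(0.5, 10, by = 0.5),
                    M = 6, tol = 1e-10),
    "estimated relative accuracy")
})

test_that("stimulus transforms follow their closed forms", {
  expect_equal(stimulus_laplace(stimulus("delta"), rand_omega(4)),
               rep(1 + 0i, 4))
  s <- stimulus("rectangular", eta0 = 2, tau_R = 5)
  expect_equal(stimulus_laplace(s, 0), 10 + 0i) # eta0 * tau_R at omega -> 0
  expect_equal(stimulus_laplace(s, 1e-9), 10 + 0i, tolerance = 1e-7)
  expect_equal(stimulus_laplace(s, 1), (2 * (1 - exp(-5))) + 0i)
  expect_error(stimulus_laplace(stimulus("chirp"), 1), "chirp")
  expect_error(stimulus("rectangular", tau_R = -1))
})

test_that("rectangular responses match the closed-form pulse solutions", {
  mp <- ref_passive()
  cfg <- two_cell_config(mp, R_GJ = 100)
  s <- stimulus("rectangular", eta0 = 2, tau_R = 5)
  t <- seq(0.5, 50, by = 0.5)
  for (seg in c("m-", "m+", "n-")) {
    v <- voltage_response(function(w) two_cell_ghat(cfg, seg, 10, 100, w), s, t)
    ref <- passive_rect_response(cfg, seg, 10, 100, t, eta0 = 2, tau_R = 5)
    expect_lt(rel_to_max(v, ref), 1e-5)
  }
})

test_that("voltage responses are linear in the stimulus amplitude", {
  cfg <- two_cell_config(ref_resonant(), R_GJ = 100)
  gh <- function(w) two_cell_ghat(cfg, "m-", 10, 100, w)
  t <- seq(1, 40, by = 1)
  v1 <- voltage_response(gh, stimulus("rectangular", eta0 = 2, tau_R = 5), t)
  v2 <- voltage_response(gh, stimulus("rectangular", eta0 = 4, tau_R = 5), t)
  expect_lt(max(abs(v2 - 2 * v1)) / max(abs(v1)), 1e-12)
})

test_that("pulse responses are causal and transient", {
  cfg <- two_cell_config(ref_resonant(), R_GJ = 100)
  gh <- function(w) two_cell_ghat(cfg, "m-", 10, 100, w)
  s <- stimulus("rectangular", eta0 = 2, tau_R = 5)
  t <- c(-5, -0.1, 0, seq(1, 60, by = 1), 150, 600)
  v <- voltage_response(gh, s, t)
  expect_equal(v[t <= 0], rep(0, 3))
  # the transient dies out on the slow inductive timescale L/r = 50 ms:
  # several orders down within three of those, effectively zero by twelve
  expect_lt(abs(v[t == 150]), 1e-4 * max(abs(v)))
  expect_lt(abs(v[t == 600]), 1e-6 * max(abs(v)))
})

test_that("a delta stimulus returns the time-domain Green's function", {
  cfg <- two_cell_config(ref_passive(), R_GJ = 100)
  gh <- function(w) two_cell_ghat(cfg, "n-", 10, 100, w)
  t <- seq(0.5, 30, by = 0.5)
  expect_equal(as.vector(voltage_response(gh, stimulus("delta"), t)),
               as.vector(inverse_laplace(gh, t, estimate_error = FALSE)),
               tolerance = 1e-10)
})

test_that("the chirp transient peaks at the frequency-domain magnitude maximum", {
  cfg <- two_cell_config(ref_resonant(), R_GJ = 100)
  gh <- function(w) two_cell_ghat(cfg, "m-", 10, 100, w)
  # Fourier-magnitude maximiser (imaginary Laplace axis)
  Om <- seq(0.05, 2, by = 0.002)
  Pf <- Mod(gh(complex(real = 0, imaginary = Om)))
  Om_f <- Om[which.max(Pf)]
  s <- stimulus("chirp", A = 1, omega_rate = 0.003)
  t <- seq(0, 120, by = 0.25)
  v <- voltage_response(gh, s, t)
  t_peak <- t[which.max(abs(v))]
  inst <- 2 * s$omega_rate * t_peak
  expect_lt(abs(inst - Om_f) / Om_f, 0.1)
})
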