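test_that("the two-cable network has exactly the trips of the closed forms", {
  net <- network_fixture("two_cell_identical")
  x <- point_location("m_minus", 10)
  y <- point_location("m_minus", 100)
  ex <- enumerate_trips(net, x, y, cutoff = 5000)
  expect_equal(n_trips(ex), 2) # direct |x - y| and gap-junction image x + y
  expect_equal(ex$lengths, c(90, 110))
  om <- rand_omega(5)
  p <- p_gj_pair(net, "gj", om)
  expect_equal(trip_coefficient(ex, 1, om), rep(1 + 0i, 5))
  expect_equal(trip_coefficient(ex, 2, om), -p$p_n) # reflection off the GJ
  # crossing to the other cell: a single transmitted trip
  exn <- enumerate_trips(net, point_location("n_plus", 10), y, cutoff = 5000)
  expect_equal(n_trips(exn), 1)
  expect_equal(exn$lengths, 110)
  expect_equal(trip_coefficient(exn, 1, om), p$p_m)
})

test_that("scaled trip lengths mix the decay rates of the traversed branches", {
  mp <- ref_resonant()
  mpn <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 25)
  net <- two_cell_network(mp, R_GJ = 100, params_n = mpn)
  y <- point_location("m_minus", 100)
  ex <- enumerate_trips(net, point_location("n_minus", 40), y, cutoff = 5000)
  expect_equal(n_trips(ex), 1)
  om <- rand_omega(6)
  expect_equal(scaled_trip_length(ex, 1, om),
               gamma_branch(mpn, om) * 40 + gamma_branch(mp, om) * 100)
  # homogeneous: common factor gamma times the physical length
  exh <- enumerate_trips(network_fixture("two_cell_identical"),
                         point_location("m_minus", 10), y, cutoff = 5000)
  expect_equal(scaled_trip_length(exh, 2, om), gamma_branch(mp, om) * 110)
})

test_that("the degenerate x = y trip counts once with zero length", {
  net <- network_fixture("two_cell_identical")
  loc <- point_location("m_minus", 50)
  ex <- enumerate_trips(net, loc, loc, cutoff = 500)
  expect_equal(sum(ex$lengths == 0), 1)
  expect_equal(scaled_trip_length(ex, 1, 1 + 1i), 0 + 0i)
})

test_that("a cutoff below the shortest trip raises an empty-expansion error", {
  net <- network_fixture("two_cell_identical")
  expect_error(enumerate_trips(net, point_location("m_minus", 10),
                               point_location("m_minus", 100), cutoff = 50),
               "below the shortest")
})

test_that("trip multiplicity doubles per reverberation shell on the two-soma network", {
  net <- network_fixture("two_soma_resonant") # L_GJ = 100
  y <- locate(net, point_location("c1.d1", 110))
  ex <- enumerate_trips(net, point_location("c1.d1", 0), y, cutoff = 110 + 2 * 100 * 5 + 1)
  counts <- table(round(ex$lengths))
  expect_equal(as.numeric(counts), 2 * 2^(0:5))
  expect_equal(as.numeric(names(counts)), 110 + 2 * 100 * (0:5))
})

test_that("a soma-reflection-then-crossing trip carries (2 p_s - 1) p_GJ", {
  net <- network_fixture("two_soma_resonant")
  y <- locate(net, point_location("c1.d1", 110))
  x0 <- 40
  ex <- enumerate_trips(net, locate(net, point_location("c2.d1", x0)), y,
                        cutoff = 400)
  om <- rand_omega(4)
  p <- p_gj_pair(net, "gj", om)
  ps <- p_soma(net, "c2.soma", "c2.d1_p", om)
  # shortest trip: x0 -> gj -> y (crossing), length (L_GJ - x0) + 10
  i1 <- which(ex$lengths == (100 - x0) + 10)
  expect_length(i1, 1)
  expect_equal(trip_coefficient(ex, i1, om), p$p_m)
  # next: x0 -> soma -> gj -> y, length (L_GJ + x0) + 10
  i2 <- which(ex$lengths == (100 + x0) + 10)
  expect_length(i2, 1)
  expect_equal(trip_coefficient(ex, i2, om), (2 * ps - 1) * p$p_m)
})

test_that("the assembled response is reciprocal up to the source-branch prefactor", {
  net <- network_fixture("two_soma_resonant")
  om <- rand_omega(6)
  mp <- ref_resonant()
  g <- gamma_branch(mp, om)
  a <- locate(net, point_location("c1.d1", 130))
  b <- locate(net, point_location("c2.d3", 60))
  gab <- greens_laplace(net, a, b, om, tol = 1e-10)
  gba <- greens_laplace(net, b, a, om, tol = 1e-10)
  # D gamma Ghat(x, y) is symmetric for equal-parameter branches
  expect_lt(rel_err(gab * mp$D * g, gba * mp$D * g), 1e-8)
})

test_that("x at a node gives the same response under both segment conventions", {
  net <- network_fixture("two_soma_resonant")
  y <- locate(net, point_location("c1.d1", 150))
  om <- rand_omega(5)
  g_prox <- greens_laplace(net, point_location("c1.d1_p", 100), y, om, tol = 1e-10)
  g_dist <- greens_laplace(net, point_location("c1.d1_d", 0), y, om, tol = 1e-10)
  expect_lt(rel_err(g_prox, g_dist), 1e-8)
})

test_that("an enormous gap-junction resistance decouples the cells", {
  mp <- ref_resonant()
  net <- two_cell_network(mp, R_GJ = 1e9)
  y <- point_location("m_minus", 100)
  om <- 0 + 0i # DC response
  same <- greens_laplace(net, point_location("m_minus", 10), y, om)
  cross <- greens_laplace(net, point_location("n_minus", 10), y, om)
  expect_lt(Mod(cross) / Mod(same), 1e-8)
  # and the connected cell reduces to the free infinite cable
  free <- ghat_infinite(mp, 90, om) / mp$cpl
  expect_lt(rel_err(same, free), 1e-7)
})
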