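test_that("the cable decay rate matches hand-computed reference values", {
  mp <- ref_resonant()
  # gamma^2(0) = (1/tau + 1/(C r)) / D = (0.5 + 10) / 5e4 per um^2
  expect_equal(Re(gamma_branch(mp, 0)), sqrt(10.5 / 5e4), tolerance = 1e-12)
  expect_equal(Re(gamma_branch(mp, 0)), 0.01449138, tolerance = 1e-6)
  mpp <- ref_passive()
  expect_equal(Re(gamma_branch(mpp, 0)), sqrt(0.5 / 5e4), tolerance = 1e-12)
  expect_equal(Re(gamma_branch(mpp, 0)), 0.0031623, tolerance = 1e-4)
})

test_that("the resonant kernel approaches the passive one as r grows", {
  big_r <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 1e9, L_H_cm2 = 5)
  om <- c(1 + 1i, rand_omega(20))
  expect_lt(rel_err(gamma_branch(big_r, om), gamma_branch(ref_passive(), om)),
            1e-6)
})

test_that("gamma evaluation at the inductive pole raises", {
  mp <- ref_resonant()
  pole <- -mp$r / mp$L # -0.02 / ms
  expect_error(gamma_branch(mp, pole), "pole")
  sp <- ref_soma_resonant()
  expect_error(gamma_soma(sp, -sp$rs / sp$Ls), "pole")
})

test_that("the square-root branch keeps Re(gamma) positive on inversion contours", {
  mp <- ref_resonant()
  # Bromwich-series nodes for t in [0.5, 100]
  for (t in c(0.5, 5, 100)) {
    om <- (16 * log(10) / 3 + 1i * pi * (0:32)) / t
    expect_true(all(Re(gamma_branch(mp, om)) > 0))
  }
  # fixed-Talbot nodes
  th <- (1:19) * pi / 20
  s <- (2 * 20 / 5) * th * (cos(th) / sin(th) + 1i)
  expect_true(all(Re(gamma_branch(mp, s / 10)) > 0))
})

test_that("the infinite-cable kernel is even in x with value 1/(2 D gamma) at the origin", {
  mp <- ref_resonant()
  om <- rand_omega(10)
  for (x in c(3.7, 120)) {
    expect_equal(ghat_infinite(mp, x, om), ghat_infinite(mp, -x, om))
  }
  g <- gamma_branch(mp, om)
  expect_equal(ghat_infinite(mp, 0, om), 1 / (2 * mp$D * g))
})

test_that("branch-node coefficients are normalised and follow admittance ratios", {
  mp <- ref_resonant()
  thin <- membrane_params(a_um = 1, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
  cfg <- list(
    branches = list(
      list(id = "p", cell = "c", length_um = "inf", prox_node = "bp",
           diameter_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5),
      list(id = "q", cell = "c", length_um = "inf", prox_node = "bp",
           diameter_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5),
      list(id = "s", cell = "c", length_um = "inf", prox_node = "bp",
           diameter_um = 1, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)),
    nodes = list(list(id = "bp", kind = "branch_point")))
  net <- build_network(cfg)
  om <- rand_omega(15)
  ps <- sapply(c("p", "q", "s"), function(b) p_branch(net, "bp", b, om))
  expect_equal(rowSums(ps), rep(1 + 0i, length(om)))
  expect_equal(ps[, "p"], ps[, "q"])
  # p_p / p_s = z_p / z_s
  expect_equal(ps[, "p"] / ps[, "s"],
               z_branch(mp, om) / z_branch(thin, om))
  expect_error(p_branch(net, "bp", "zz", om), "not incident")
})

test_that("three identical branches give p = 1/3 at any omega", {
  cfg <- list(
    branches = lapply(1:3, function(i)
      list(id = paste0("b", i), cell = "c", length_um = "inf",
           prox_node = "bp", diameter_um = 2, tau_ms = 2)),
    nodes = list(list(id = "bp", kind = "branch_point")))
  net <- build_network(cfg)
  expect_equal(p_branch(net, "bp", "b1", rand_omega(5)),
               rep(1 / 3 + 0i, 5))
})

test_that("somatic coefficients reduce to z/(N z + gamma_s) for identical dendrites", {
  mp <- ref_resonant()
  sp <- ref_soma_resonant()
  net <- two_soma_network(mp, sp, N = 4, L_GJ = 100, R_GJ = 100)
  om <- rand_omega(20)
  got <- p_soma(net, "c1.soma", "c1.d2", om)
  z <- z_branch(mp, om)
  expect_equal(got, z / (4 * z + gamma_soma(sp, om)))
  # a soma of vanishing admittance behaves like a plain branch point
  huge <- soma_params(as_um = 0.01, Cs_uF_cm2 = 1e-6, Rs_Ohm_cm2 = 1e9)
  net2 <- two_soma_network(mp, huge, N = 4, L_GJ = 100, R_GJ = 100)
  expect_equal(p_soma(net2, "c1.soma", "c1.d2", 1 + 0i), 0.25 + 0i,
               tolerance = 1e-8)
})

test_that("gap-junction coefficients match the closed form and its limits", {
  mp <- ref_resonant()
  net <- network_fixture("two_cell_identical")
  p0 <- p_gj_pair(net, "gj", 0 + 0i)
  z0 <- Re(gamma_branch(mp, 0)) / mp$ra
  expect_equal(Re(p0$p_m), 1 / (2 * (z0 * 100 + 1)), tolerance = 1e-12)
  expect_equal(Re(p0$p_m), 0.0900479, tolerance = 1e-6)
  # strong and absent coupling
  weak <- p_gj_pair(two_cell_network(mp, R_GJ = 1e12), "gj", 0 + 0i)
  expect_lt(Mod(weak$p_m), 1e-10)
  tight <- p_gj_pair(two_cell_network(mp, R_GJ = 1e-12), "gj", 0 + 0i)
  expect_equal(Re(tight$p_m), 0.5, tolerance = 1e-9)
})

test_that("heterogeneous gap-junction coefficients swap under relabelling and reduce when equal", {
  mp <- ref_resonant()
  mpn <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 25)
  om <- rand_omega(100)
  ab <- dendrotrips:::.two_cell_pgj(two_cell_config(mp, 100, params_n = mpn), om)
  ba <- dendrotrips:::.two_cell_pgj(two_cell_config(mpn, 100, params_n = mp), om)
  expect_equal(ab$p_m, ba$p_n)
  expect_equal(ab$p_n, ba$p_m)
  same <- dendrotrips:::.two_cell_pgj(two_cell_config(mp, 100), om)
  z <- z_branch(mp, om)
  expect_equal(same$p_m, 1 / (2 * (z * 100 + 1)))
  expect_equal(same$p_m, same$p_n)
})
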