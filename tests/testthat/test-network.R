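test_that("the two-cable network builds with one gap junction and four semi-infinite segments", {
  net <- two_cell_network(ref_resonant(), R_GJ = 100)
  expect_s3_class(net, "dendro_network")
  expect_equal(nrow(net$branches), 4)
  expect_true(all(is.infinite(net$branches$length)))
  kinds <- vapply(net$nodes, `[[`, character(1), "kind")
  expect_equal(unname(kinds), "gap_junction")
  expect_setequal(net$cells, c("m", "n"))
})

test_that("node-form configurations round-trip through serialisation", {
  net <- network_fixture("two_cell_hetero_L25")
  cfg <- network_to_config(net)
  net2 <- build_network(cfg)
  expect_identical(network_to_config(net2), cfg)
})

test_that("cell-form configurations build trees, split gap-junction hosts and round-trip", {
  mk <- function() list(
    cells = list(
      list(id = "a", soma = list(as_um = 25),
           branches = list(
             list(id = "d1", length_um = "inf", parent = "root",
                  diameter_um = 2, tau_ms = 2),
             list(id = "d2", length_um = 150, parent = "root",
                  diameter_um = 2, tau_ms = 2),
             list(id = "d2a", length_um = "inf", parent = "d2",
                  diameter_um = 1, tau_ms = 2)),
           terminals = list()),
      list(id = "b", soma = list(as_um = 20),
           branches = list(
             list(id = "d1", length_um = "inf", parent = "root",
                  diameter_um = 2, tau_ms = 2),
             list(id = "d2", length_um = "inf", parent = "root",
                  diameter_um = 2, tau_ms = 2)))),
    gap_junctions = list(list(R_MOhm = 100,
                              site_1 = list(cell = "a", branch = "d1", x_um = 80),
                              site_2 = list(cell = "b", branch = "d1", x_um = 120))))
  net <- build_network(mk())
  expect_equal(nrow(net$branches), 7) # two hosts split into _p/_d
  expect_true(all(c("a.d1_p", "a.d1_d", "b.d1_p", "b.d1_d") %in% net$branches$id))
  # the serialised node form rebuilds identically
  cfg <- network_to_config(net)
  expect_identical(network_to_config(build_network(cfg)), cfg)
})

test_that("invalid topologies are rejected with informative messages", {
  mp <- ref_resonant()
  # a gap junction with three incident ends
  bad <- network_to_config(two_cell_network(mp, R_GJ = 100))
  bad$branches <- bad$branches[1:3]
  bad$nodes[[1]]$pair_n <- list("n_minus")
  expect_error(build_network(bad), "4 incident")
  # dangling branch end
  bad2 <- network_to_config(two_cell_network(mp, R_GJ = 100))
  bad2$branches[[1]]$prox_node <- "nowhere"
  expect_error(build_network(bad2), "not declared")
  # negative electrical parameter
  bad3 <- network_to_config(two_cell_network(mp, R_GJ = 100))
  bad3$branches[[1]]$Ra_Ohm_cm <- -5
  expect_error(build_network(bad3), "strictly positive")
  # non-positive gap-junction resistance
  bad4 <- network_to_config(two_cell_network(mp, R_GJ = 100))
  bad4$nodes[[1]]$R_MOhm <- 0
  expect_error(build_network(bad4), "R_GJ")
})

test_that("gap junctions at a branch tip are rejected", {
  cfg <- list(
    cells = list(
      list(id = "a", soma = list(as_um = 25),
           branches = list(list(id = "d1", length_um = 200, parent = "root",
                                diameter_um = 2, tau_ms = 2))),
      list(id = "b", soma = list(as_um = 25),
           branches = list(list(id = "d1", length_um = "inf", parent = "root",
                                diameter_um = 2, tau_ms = 2)))),
    gap_junctions = list(list(R_MOhm = 100,
                              site_1 = list(cell = "a", branch = "d1", x_um = 200),
                              site_2 = list(cell = "b", branch = "d1", x_um = 50))))
  expect_error(build_network(cfg), "strictly inside")
})

test_that("removing gap junctions decomposes the network into its cells", {
  net <- network_fixture("two_soma_resonant")
  comp <- dendrotrips:::.cell_components(net)
  expect_equal(length(unique(comp$component)), 2)
  agg <- tapply(comp$component, comp$cell, function(x) length(unique(x)))
  expect_true(all(agg == 1))
})

test_that("locate resolves split-branch coordinates and flags nodes", {
  net <- two_soma_network(ref_resonant(), ref_soma_passive(), N = 4,
                          L_GJ = 100, R_GJ = 100)
  l1 <- locate(net, point_location("c1.d1", 40))
  expect_equal(l1$branch, "c1.d1_p"); expect_equal(l1$x, 40)
  l2 <- locate(net, point_location("c1.d1", 140))
  expect_equal(l2$branch, "c1.d1_d"); expect_equal(l2$x, 40)
  # the gap-junction point itself is assigned to the proximal segment
  l3 <- locate(net, point_location("c1.d1", 100))
  expect_equal(l3$branch, "c1.d1_p"); expect_equal(l3$x, 100)
  expect_equal(attr(l3, "node"), "gj")
  expect_error(locate(net, point_location("c1.d1_p", 101)), "beyond")
  expect_error(locate(net, point_location("no.such", 1)), "unknown branch")
})

test_that("shipped fixture files match the in-code constructors", {
  for (nm in c("two_cell_identical", "two_cell_hetero_L25", "two_cell_passive",
               "two_soma_resonant")) {
    path <- system.file("extdata", paste0(nm, ".yaml"), package = "dendrotrips")
    expect_true(nzchar(path))
    expect_identical(network_to_config(read_network(path)),
                     network_to_config(network_fixture(nm)))
  }
})

test_that("SWC import collapses the soma and cuts dendrites at branch points", {
  path <- system.file("extdata", "synthetic_neuron.swc", package = "dendrotrips")
  cell <- read_swc(path, cell_id = "swc")
  expect_equal(cell$soma$as_um, 18) # 2 * mean(radius of the two soma samples)
  lens <- sort(vapply(cell$branches, `[[`, numeric(1), "length_um"))
  d <- sqrt(60^2 + 40^2)
  expect_equal(lens, sort(c(80, d, 2 * d, 140)), tolerance = 1e-9)
  net <- build_network(list(cells = list(cell)))
  kinds <- table(vapply(net$nodes, `[[`, character(1), "kind"))
  expect_equal(unname(kinds[["branch_point"]]), 1)
  expect_equal(unname(kinds[["terminal_closed"]]), 3)
})

test_that("seeded random networks are reproducible and valid", {
  a <- random_network(42)
  b <- random_network(42)
  expect_identical(yaml::as.yaml(network_to_config(a)),
                   yaml::as.yaml(network_to_config(b)))
  d <- random_network(43)
  expect_false(identical(yaml::as.yaml(network_to_config(a)),
                         yaml::as.yaml(network_to_config(d))))
  for (sd in 1:6) {
    expect_s3_class(random_network(sd), "dendro_network")
  }
})
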