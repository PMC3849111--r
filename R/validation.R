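# Validation surface: numerical residuals of the boundary conditions that
# the assembled Green's function must satisfy at every node (value continuity
# and current balance, including the gap-junction conditions with
# conductance g_GJ = 1/R_GJ), plus a seeded random-network generator used by
# the property suite.

# Ghat at several offsets into a segment away from a given node, reusing one
# trip enumeration per offset across all omega.  The farthest offset is
# computed first and its magnitude used as the accuracy floor for the
# others: right next to an open terminal the response itself nearly cancels,
# and plain relative truncation there would be ill-conditioned.
.ghat_at_offsets <- function(net, seg, node_id, offsets, y, omega, tol) {
  j <- match(seg, net$branches$id)
  at_prox <- identical(net$branches$prox_node[j], node_id)
  len <- net$branches$length[j]
  out <- matrix(0 + 0i, nrow = length(omega), ncol = length(offsets))
  # One converged enumeration at an anchor point a healthy distance from the
  # node (where the response has a well-conditioned magnitude even when image
  # trips nearly cancel at the node itself, as next to an open terminal);
  # the finite-difference offsets shift only the first leg of every trip and
  # are re-evaluated from the same expansion.
  anchor <- max(max(offsets), min(25, if (is.finite(len)) len / 2 else 25))
  if (is.finite(len) && anchor > 0.9 * len) anchor <- 0.9 * len
  # never anchor on top of the stimulus point: the direct self-term would
  # dominate the anchor magnitude and let the series truncate too shallowly
  # for the near-node points
  yl <- locate(net, y)
  if (yl$branch == seg) {
    y_off <- if (at_prox) yl$x else len - yl$x
    if (abs(anchor - y_off) < 0.5 * y_off) {
      anchor <- max(max(offsets), y_off / 2)
    }
  }
  if (is.finite(len) && len <= 4 * max(offsets)) {
    stop(sprintf("segment '%s' is too short (%g um) for the finite-difference step",
                 seg, len), call. = FALSE)
  }
  x0 <- if (at_prox) anchor else len - anchor
  st <- new.env(parent = emptyenv())
  greens_laplace(net, point_location(seg, x0), y, omega, tol = tol, state = st)
  for (k in seq_along(offsets)) {
    x <- if (at_prox) offsets[k] else len - offsets[k]
    out[, k] <- .greens_shifted(st$expansion, omega, x)
  }
  out
}

# one-sided first derivative away from the node from values at offsets
# (0, h/2, h, 2h): second-order stencils at steps h and h/2, plus one
# Richardson extrapolation.
.oneside_deriv <- function(vals, h) {
  d_h <- (-3 * vals[, 1] + 4 * vals[, 3] - vals[, 4]) / (2 * h)
  d_h2 <- (-3 * vals[, 1] + 4 * vals[, 2] - vals[, 3]) / h
  (4 * d_h2 - d_h) / 3
}

.residual_rows <- function(node_id, type, omega, residual) {
  data.frame(node = node_id, type = type,
             omega_re = Re(omega), omega_im = Im(omega),
             residual = residual, stringsAsFactors = FALSE)
}

#' Gap-junction boundary residuals of the assembled Green's function
#'
#' Checks, at a gap-junction node, that the sum-over-trips solution satisfies
#' value continuity along each host dendrite and the current-balance
#' conditions `(1/ra_m)(dG_m-/dx + dG_m+/dx) = g_GJ (G_m- - G_n-)` (and the
#' m/n-swapped condition), using one-sided finite-difference derivatives of
#' the trip-expansion response.  Residuals are relative: continuity is scaled
#' by the largest node value, current balance by the largest participating
#' term.
#'
#' @param net a `dendro_network`.
#' @param node_id id of a gap-junction node.
#' @param y stimulus [point_location()] (away from the node).
#' @param omega complex vector (1/ms).
#' @param step finite-difference step (um).
#' @param tol truncation tolerance of the underlying trip series (the
#'   residuals inherit roughly ten times this level).
#' @return A data frame with columns `node`, `type`, `omega_re`, `omega_im`,
#'   `residual`.
#' @export
gj_boundary_residual <- function(net, node_id, y, omega, step = 1e-2,
                                 tol = 1e-7) {
  nd <- net$nodes[[node_id]]
  if (is.null(nd) || nd$kind != "gap_junction") {
    stop(sprintf("node '%s' is not a gap junction", node_id), call. = FALSE)
  }
  omega <- as.complex(omega)
  segs <- c(nd$gj$m, nd$gj$n)
  offs <- c(0, step / 2, step, 2 * step)
  vals <- lapply(segs, function(s)
    .ghat_at_offsets(net, s, node_id, offs, y, omega, tol))
  names(vals) <- segs
  G0 <- vapply(vals, function(v) v[, 1], complex(length(omega)))
  G0 <- matrix(G0, nrow = length(omega))
  der <- vapply(vals, .oneside_deriv, complex(length(omega)), h = step)
  der <- matrix(der, nrow = length(omega))

  scale <- apply(abs(G0), 1, max)
  ra_m <- .branch_params(net, nd$gj$m[1])$ra
  ra_n <- .branch_params(net, nd$gj$n[1])$ra
  ggj <- 1 / nd$R_GJ

  res_cont_m <- abs(G0[, 1] - G0[, 2]) / scale
  res_cont_n <- abs(G0[, 3] - G0[, 4]) / scale
  lhs_m <- (der[, 1] + der[, 2]) / ra_m
  rhs_m <- ggj * (G0[, 1] - G0[, 3])
  den_m <- pmax(abs(lhs_m), abs(rhs_m), (abs(der[, 1]) + abs(der[, 2])) / ra_m)
  lhs_n <- (der[, 3] + der[, 4]) / ra_n
  rhs_n <- ggj * (G0[, 3] - G0[, 1])
  den_n <- pmax(abs(lhs_n), abs(rhs_n), (abs(der[, 3]) + abs(der[, 4])) / ra_n)

  rbind(.residual_rows(node_id, "value_continuity_m", omega, res_cont_m),
        .residual_rows(node_id, "value_continuity_n", omega, res_cont_n),
        .residual_rows(node_id, "current_balance_m", omega,
                       abs(lhs_m - rhs_m) / den_m),
        .residual_rows(node_id, "current_balance_n", omega,
                       abs(lhs_n - rhs_n) / den_n))
}

#' Boundary residuals at branch points, somata and terminals
#'
#' Laplace-domain analogues of the node conditions: continuity of the
#' potential and Kirchhoff current balance at branch points; the somatic
#' condition `sum_k (1/ra_k) dG_k/dx = gamma_s(omega) G` at a lumped soma
#' (derivatives taken away from the node); zero derivative at closed
#' terminals; zero value at open terminals.
#'
#' @inheritParams gj_boundary_residual
#' @param node_id id of a branch-point, soma or terminal node.
#' @param step finite-difference step (um); the default is larger than for
#'   the gap-junction residuals because next to a terminal the response is
#'   dominated by near-cancelling image trips, and a very small step would
#'   demand disproportionate series accuracy (the Richardson-extrapolated
#'   stencil keeps the differencing error far below the residual tolerance).
#' @export
soma_branch_residuals <- function(net, node_id, y, omega, step = 0.5,
                                  tol = 1e-7) {
  nd <- net$nodes[[node_id]]
  if (is.null(nd)) stop(sprintf("unknown node '%s'", node_id), call. = FALSE)
  omega <- as.complex(omega)
  segs <- nd$incident$branch
  offs <- c(0, step / 2, step, 2 * step)
  vals <- lapply(segs, function(s)
    .ghat_at_offsets(net, s, node_id, offs, y, omega, tol))
  G0 <- matrix(vapply(vals, function(v) v[, 1], complex(length(omega))),
               nrow = length(omega))
  der <- matrix(vapply(vals, .oneside_deriv, complex(length(omega)), h = step),
                nrow = length(omega))
  ras <- vapply(segs, function(s) .branch_params(net, s)$ra, numeric(1))

  if (nd$kind %in% c("terminal_closed", "terminal_open")) {
    p <- .branch_params(net, segs[1])
    g <- gamma_branch(p, omega)
    if (nd$kind == "terminal_closed") {
      # derivative should vanish; natural derivative scale is gamma * |G|
      res <- abs(der[, 1]) / pmax(abs(g) * abs(G0[, 1]),
                                  abs(der[, 1]), .Machine$double.xmin)
      return(.residual_rows(node_id, "closed_end_no_flux", omega, res))
    }
    interior <- abs(vals[[1]][, 4])
    res <- abs(G0[, 1]) / pmax(interior, .Machine$double.xmin)
    return(.residual_rows(node_id, "open_end_zero_value", omega, res))
  }

  scale <- apply(abs(G0), 1, max)
  out <- list()
  if (length(segs) > 1) {
    for (k in 2:length(segs)) {
      out[[length(out) + 1L]] <-
        .residual_rows(node_id, sprintf("value_continuity_%d", k - 1L),
                       omega, abs(G0[, 1] - G0[, k]) / scale)
    }
  }
  currents <- sweep(der, 2, ras, "/")
  lhs <- rowSums(currents)
  den <- pmax(rowSums(abs(currents)), .Machine$double.xmin)
  if (nd$kind == "branch_point") {
    out[[length(out) + 1L]] <-
      .residual_rows(node_id, "current_balance", omega, abs(lhs) / den)
  } else if (nd$kind == "soma") {
    rhs <- gamma_soma(nd$soma, omega) * G0[, 1]
    out[[length(out) + 1L]] <-
      .residual_rows(node_id, "current_balance", omega,
                     abs(lhs - rhs) / pmax(den, abs(rhs)))
  } else {
    stop(sprintf("node '%s' has kind '%s'; use gj_boundary_residual for gap junctions",
                 node_id, nd$kind), call. = FALSE)
  }
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# seeded random networks for property tests

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.log_uniform <- function(center, decades = 1) {
  center * 10^stats::runif(1, -decades, decades)
}

# smallest Re gamma over real omega in [0, 5] 1/ms (the slowest spatial decay
# met along right-half-plane evaluation points); sets the electrotonic scale
# used to place gap junctions and finite branches
.lambda_slowest <- function(params) {
  om <- seq(0, 5, by = 0.02)
  1 / min(Re(gamma_branch(params, om)))
}

#' Seeded random two-cell network
#'
#' Generates a reproducible random pair of cells joined by one dendro-dendritic
#' gap junction, for property testing of the boundary-condition residuals.
#' Each cell has a lumped soma (passive or resonant), `N` in 2..4 semi-infinite
#' dendrites with cell-specific electrical constants drawn log-uniformly
#' within `decades` decades of the reference set (diameter 2 um, C 1 uF/cm^2,
#' Ra 100 Ohm cm, tau 2 ms, r 100 Ohm cm^2, L 5 H cm^2), and optionally one
#' branch point carrying a finite closed- or open-ended child and a
#' semi-infinite child.  The gap junction sits on the first dendrite of each
#' cell at 0.8..2 electrotonic lengths from the soma (lengths scale with each
#' cell's slowest spatial decay rate so the trip series converges at a
#' predictable rate), with R_GJ log-uniform in 1..1000 MOhm.
#'
#' @param seed integer seed.
#' @param decades half-width of the log-uniform parameter ranges.
#' @param p_resonant probability that a cell's dendrites are resonant.
#' @param p_branch probability of the extra branch point per cell.
#' @return A validated `dendro_network`.  The generating configuration is
#'   attached as attribute `"config"`.
#' @export
random_network <- function(seed, decades = 1, p_resonant = 0.7,
                           p_branch = 0.5) {
  .with_seed(seed, {
    cells <- list()
    gj_sites <- list()
    for (ci in 1:2) {
      cid <- paste0("c", ci)
      resonant <- stats::runif(1) < p_resonant
      mp_args <- list(
        diameter_um = .log_uniform(2, decades / 2),
        C_uF_cm2 = .log_uniform(1, decades / 2),
        Ra_Ohm_cm = .log_uniform(100, decades / 2),
        tau_ms = .log_uniform(2, decades / 2))
      if (resonant) {
        mp_args$r_Ohm_cm2 <- .log_uniform(100, decades / 2)
        mp_args$L_H_cm2 <- .log_uniform(5, decades / 2)
      }
      mp <- do.call(membrane_params, c(list(a_um = mp_args$diameter_um),
                                       mp_args[-1]))
      lambda <- .lambda_slowest(mp)
      soma <- list(as_um = .log_uniform(25, decades / 4),
                   Cs_uF_cm2 = .log_uniform(1, decades / 4),
                   Rs_Ohm_cm2 = .log_uniform(2000, decades / 4))
      if (stats::runif(1) < 0.5) {
        soma$rs_Ohm_cm2 <- .log_uniform(1, decades / 4)
        soma$Ls_H_cm2 <- .log_uniform(0.1, decades / 4)
      }
      N <- sample(2:4, 1)
      branches <- list(list(id = "d1", length_um = "inf", parent = "root"))
      terminals <- list()
      has_branch_pt <- stats::runif(1) < p_branch
      if (has_branch_pt) {
        # dendrite 2 becomes a finite stem carrying one semi-infinite and one
        # terminated child
        branches[[2]] <- list(id = "d2",
                              length_um = stats::runif(1, 0.8, 2) * lambda,
                              parent = "root")
        branches[[3]] <- list(id = "d2a", length_um = "inf", parent = "d2")
        branches[[4]] <- list(id = "d2b",
                              length_um = stats::runif(1, 0.8, 2) * lambda,
                              parent = "d2")
        terminals$d2b <- sample(c("closed", "open"), 1)
      } else {
        branches[[2]] <- list(id = "d2", length_um = "inf", parent = "root")
      }
      if (N >= 3) {
        for (k in 3:N) {
          branches[[length(branches) + 1L]] <-
            list(id = paste0("d", k), length_um = "inf", parent = "root")
        }
      }
      branches <- lapply(branches, function(b) c(b, mp_args))
      cells[[ci]] <- list(id = cid, soma = soma, branches = branches,
                          terminals = terminals)
      gj_sites[[ci]] <- list(cell = cid, branch = "d1",
                             x_um = stats::runif(1, 0.8, 2) * lambda)
    }
    config <- list(
      cells = cells,
      gap_junctions = list(list(R_MOhm = .log_uniform(sqrt(1000), 1.5),
                                site_1 = gj_sites[[1]],
                                site_2 = gj_sites[[2]])))
    net <- build_network(config)
    attr(net, "config") <- config
    net
  })
}

# ---------------------------------------------------------------------------
# named configurations used throughout the examples and tests

#' Named example configurations
#'
#' Parameter sets used across the documentation and the validation suite:
#' \describe{
#'   \item{two_cell_identical}{two identical resonant infinite cables
#'     (a 2 um, C 1 uF/cm^2, Ra 100 Ohm cm, tau 2 ms, r 100 Ohm cm^2,
#'     L 5 H cm^2), R_GJ 100 MOhm.}
#'   \item{two_cell_hetero_L25}{as above with L = 25 H cm^2 in cell n.}
#'   \item{two_cell_passive}{the passive variant (no resonant path).}
#'   \item{two_soma_resonant}{two cells, each a resonant soma (diameter
#'     25 um, Cs 1, Rs 2000, rs 1 Ohm cm^2, Ls 0.1 H cm^2) with N = 4
#'     resonant semi-infinite dendrites; gap junction at 100 um, 100 MOhm.}
#'   \item{sweep_passive_soma}{two-soma configuration with passive somata and
#'     resonant dendrites (for location sweeps).}
#'   \item{sweep_resonant_soma_passive_dendrites}{resonant somata, passive
#'     dendrites.}
#'   \item{sweep_all_resonant}{resonant somata and dendrites.}
#' }
#'
#' @param name one of the names above.
#' @return A `dendro_network` (two_cell_* / two_soma_*) or a
#'   [two_soma_config()] (sweep_*).
#' @export
network_fixture <- function(name = c("two_cell_identical",
                                     "two_cell_hetero_L25",
                                     "two_cell_passive",
                                     "two_soma_resonant",
                                     "sweep_passive_soma",
                                     "sweep_resonant_soma_passive_dendrites",
                                     "sweep_all_resonant")) {
  name <- match.arg(name)
  res_dend <- membrane_params(a_um = 2, C_uF_cm2 = 1, Ra_Ohm_cm = 100,
                              tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
  pas_dend <- membrane_params(a_um = 2, C_uF_cm2 = 1, Ra_Ohm_cm = 100,
                              tau_ms = 2)
  pas_soma <- soma_params(as_um = 25, Cs_uF_cm2 = 1, Rs_Ohm_cm2 = 2000)
  res_soma <- soma_params(as_um = 25, Cs_uF_cm2 = 1, Rs_Ohm_cm2 = 2000,
                          rs_Ohm_cm2 = 1, Ls_H_cm2 = 0.1)
  switch(name,
    two_cell_identical = two_cell_network(res_dend, R_GJ = 100),
    two_cell_hetero_L25 = two_cell_network(
      res_dend, R_GJ = 100,
      params_n = membrane_params(a_um = 2, C_uF_cm2 = 1, Ra_Ohm_cm = 100,
                                 tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 25)),
    two_cell_passive = two_cell_network(pas_dend, R_GJ = 100),
    two_soma_resonant = two_soma_network(res_dend, res_soma, N = 4,
                                         L_GJ = 100, R_GJ = 100),
    sweep_passive_soma = two_soma_config(res_dend, pas_soma, N = 4,
                                         L_GJ = 100, R_GJ = 100),
    sweep_resonant_soma_passive_dendrites =
      two_soma_config(pas_dend, res_soma, N = 4, L_GJ = 100, R_GJ = 100),
    sweep_all_resonant = two_soma_config(res_dend, res_soma, N = 4,
                                         L_GJ = 100, R_GJ = 100))
}
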