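# Frequency-domain scalar kernels.  All functions accept a complex vector of
# Laplace arguments omega (units 1/ms) and are vectorised over it.

#' Spatial decay rate gamma(omega) of a cable
#'
#' For resonant membrane
#' `gamma^2(omega) = (1/tau + omega + 1/(C (r + omega L))) / D`;
#' the passive form drops the inductive-path term (the r -> Inf limit).  The
#' square root is taken on the branch with `Re(gamma) >= 0`, which guarantees
#' decaying solutions `exp(-gamma |x|)` in the right half-plane.
#'
#' @param params a [membrane_params()] object.
#' @param omega complex vector of Laplace arguments (1/ms).
#' @return Complex vector `gamma(omega)` (1/um).
#' @examples
#' mp <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
#' gamma_branch(mp, 0) # ~0.014491
#' @export
gamma_branch <- function(params, omega) {
  stopifnot(inherits(params, "membrane_params"))
  omega <- as.complex(omega)
  g2 <- 1 / params$tau + omega
  if (params$resonant) {
    num <- params$r + omega * params$L
    if (any(abs(num) <= 1e-12 * (params$r + abs(omega) * params$L))) {
      stop("gamma evaluated at the inductive pole omega = -r/L", call. = FALSE)
    }
    g2 <- g2 + 1 / (params$C * num)
  }
  g <- sqrt(g2 / params$D)
  flip <- Re(g) < 0 | (Re(g) == 0 & Im(g) < 0)
  g[flip] <- -g[flip]
  g
}

#' Characteristic admittance z(omega) = gamma(omega) / ra of a semi-infinite cable
#'
#' @inheritParams gamma_branch
#' @return Complex vector (1/MOhm).
#' @export
z_branch <- function(params, omega) {
  gamma_branch(params, omega) / params$ra
}

#' Laplace-domain Green's function of the infinite cable
#'
#' `ghat_infinite(params, x, omega) = exp(-gamma |x|) / (2 D gamma)`, the
#' building block of every sum-over-trips term.  Even in `x`.  Note this is
#' the bare kernel: responses in mV/nA carry an additional `1/cpl` prefactor
#' (capacitance per unit length), applied by the solution-level functions.
#'
#' @inheritParams gamma_branch
#' @param x distance (um); scalar or vector conformable with `omega`.
#' @return Complex vector.
#' @export
ghat_infinite <- function(params, x, omega) {
  g <- gamma_branch(params, omega)
  exp(-g * abs(x)) / (2 * params$D * g)
}

#' Somatic admittance gamma_s(omega)
#'
#' `gamma_s = Cs omega + 1/Rs + 1/(rs + Ls omega)` in absolute units (1/MOhm),
#' using the constants of [soma_params()] (already scaled by the somatic
#' membrane area).  For a passive soma the inductive-path term is absent.
#'
#' @param soma a [soma_params()] object.
#' @param omega complex vector (1/ms).
#' @return Complex vector (1/MOhm).
#' @export
gamma_soma <- function(soma, omega) {
  stopifnot(inherits(soma, "soma_params"))
  omega <- as.complex(omega)
  gs <- soma$Cs * omega + 1 / soma$Rs
  if (soma$resonant) {
    den <- soma$rs + soma$Ls * omega
    if (any(abs(den) <= 1e-12 * (soma$rs + abs(omega) * soma$Ls))) {
      stop("gamma_soma evaluated at the inductive pole omega = -rs/Ls",
           call. = FALSE)
    }
    gs <- gs + 1 / den
  }
  gs
}

# incident branch ids at a node (each row of the incidence table is an end)
.incident_branches <- function(net, node_id) {
  nd <- net$nodes[[node_id]]
  if (is.null(nd)) stop(sprintf("unknown node '%s'", node_id), call. = FALSE)
  nd$incident$branch
}

.branch_params <- function(net, branch_id) {
  i <- match(branch_id, net$branches$id)
  if (is.na(i)) stop(sprintf("unknown branch '%s'", branch_id), call. = FALSE)
  net$params[[net$branches$param_class[i]]]
}

#' Node coefficient p_k at a regular branching node
#'
#' `p_k = z_k / sum_n z_n`, the sum running over all branches incident to the
#' node.  A trip passing from another branch onto branch k picks up `2 p_k`;
#' a trip reflecting back along branch k picks up `2 p_k - 1`.
#'
#' @param net a network object (see [build_network()]).
#' @param node_id id of a `branch_point` node.
#' @param branch_id id of a branch incident to the node.
#' @param omega complex vector (1/ms).
#' @return Complex vector.
#' @export
p_branch <- function(net, node_id, branch_id, omega) {
  nd <- net$nodes[[node_id]]
  if (is.null(nd) || nd$kind != "branch_point") {
    stop(sprintf("node '%s' is not a branch_point", node_id), call. = FALSE)
  }
  ids <- .incident_branches(net, node_id)
  if (!branch_id %in% ids) {
    stop(sprintf("branch '%s' is not incident to node '%s'", branch_id, node_id),
         call. = FALSE)
  }
  zs <- lapply(ids, function(b) z_branch(.branch_params(net, b), omega))
  ztot <- Reduce(`+`, zs)
  zs[[match(branch_id, ids)]] / ztot
}

#' Node coefficient p_{s,k} at a lumped soma
#'
#' `p_{s,k} = z_k / (sum_n z_n + gamma_s)`; trips through the soma onto branch
#' k pick up `2 p_{s,k}`, reflections `2 p_{s,k} - 1`.  For N identical
#' dendrites this reduces to `p_s = z / (N z + gamma_s)`.
#'
#' @inheritParams p_branch
#' @param node_id id of a `soma` node.
#' @return Complex vector.
#' @export
p_soma <- function(net, node_id, branch_id, omega) {
  nd <- net$nodes[[node_id]]
  if (is.null(nd) || nd$kind != "soma") {
    stop(sprintf("node '%s' is not a soma", node_id), call. = FALSE)
  }
  ids <- .incident_branches(net, node_id)
  if (!branch_id %in% ids) {
    stop(sprintf("branch '%s' is not incident to node '%s'", branch_id, node_id),
         call. = FALSE)
  }
  zs <- lapply(ids, function(b) z_branch(.branch_params(net, b), omega))
  ztot <- Reduce(`+`, zs) + gamma_soma(nd$soma, omega)
  zs[[match(branch_id, ids)]] / ztot
}

#' Gap-junction transmission coefficients
#'
#' For a gap junction of resistance `R_GJ` joining dendrite m (segments
#' m-, m+) of one cell to dendrite n (segments n-, n+) of another,
#' `p_GJ,m = z_m / (z_m + z_n + 2 R_GJ z_m z_n)` and symmetrically for n.
#' With identical cables both reduce to `1 / (2 (z R_GJ + 1))`.  A trip
#' crossing from dendrite n to dendrite m picks up `p_GJ,m`; passing straight
#' through along dendrite m picks up `1 - p_GJ,n`; reflecting back along
#' dendrite m picks up `-p_GJ,n` (and the same with m and n swapped).
#'
#' @inheritParams p_branch
#' @param node_id id of a `gap_junction` node.
#' @return A list with complex vectors `p_m` and `p_n`.
#' @export
p_gj_pair <- function(net, node_id, omega) {
  nd <- net$nodes[[node_id]]
  if (is.null(nd) || nd$kind != "gap_junction") {
    stop(sprintf("node '%s' is not a gap_junction", node_id), call. = FALSE)
  }
  zm <- z_branch(.branch_params(net, nd$gj$m[1]), omega)
  zn <- z_branch(.branch_params(net, nd$gj$n[1]), omega)
  den <- zm + zn + 2 * nd$R_GJ * zm * zn
  list(p_m = zm / den, p_n = zn / den)
}
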