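# Internal unit system: micrometre, millisecond, millivolt, nanoampere, megaohm.
# With these choices mV/nA = MOhm, capacitance is in nF (= ms/MOhm) and all
# Ohmic relations are coefficient-free.  Specific (per-area) constants quoted
# in the conventional cm-based units are converted at ingest.
.UF_CM2 <- 1e-5 # 1 uF/cm^2   = 1e-5 nF/um^2
.OHM_CM2 <- 100 # 1 Ohm cm^2  = 100  MOhm um^2
.OHM_CM <- 1e-2 # 1 Ohm cm    = 0.01 MOhm um
.H_CM2 <- 1e5   # 1 H cm^2    = 1e5  MOhm ms um^2

.check_pos <- function(x, name) {
  if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)) {
    stop(sprintf("'%s' must be a single strictly positive number", name), call. = FALSE)
  }
  invisible(x)
}

#' Electrical membrane parameters of a dendritic branch
#'
#' Bundles the specific electrical constants of a cable segment and converts
#' them into the package's internal unit system (um, ms, mV, nA, MOhm).
#' Passive ('RC') membrane is obtained by omitting the resonant-path constants
#' `r_Ohm_cm2` and `L_H_cm2`; supplying both models quasi-active ('LRC')
#' membrane with an inductive pathway (resistance r in series with an
#' inductance L), the linearisation appropriate for subthreshold resonances
#' carried by currents such as Ih.
#'
#' @param a_um branch diameter (um).
#' @param C_uF_cm2 specific membrane capacitance (uF/cm^2).
#' @param Ra_Ohm_cm cytoplasmic (axial) resistivity (Ohm cm).
#' @param R_Ohm_cm2 specific leak resistance (Ohm cm^2). Give either this or
#'   `tau_ms`.
#' @param tau_ms membrane time constant (ms); equivalent to
#'   `R_Ohm_cm2 = tau_ms / C_uF_cm2 * 1e3`.
#' @param r_Ohm_cm2 resonant-path resistance (Ohm cm^2), or `NULL` for passive
#'   membrane.
#' @param L_H_cm2 resonant-path inductance (H cm^2); required iff `r_Ohm_cm2`
#'   is given.
#'
#' @return An object of class `membrane_params` holding both the quoted values
#'   and the internal-unit fields `C` (nF/um^2), `R`, `r` (MOhm um^2), `L`
#'   (MOhm ms um^2), `Ra` (MOhm um), `a` (um), plus the derived constants
#'   `D` (um^2/ms), `tau` (ms), `ra` (MOhm/um) and `cpl` (capacitance per unit
#'   length, nF/um).
#' @seealso [derive_cable_constants()], [gamma_branch()]
#' @examples
#' mp <- membrane_params(a_um = 2, tau_ms = 2, r_Ohm_cm2 = 100, L_H_cm2 = 5)
#' derive_cable_constants(mp)
#' @export
membrane_params <- function(a_um, C_uF_cm2 = 1, Ra_Ohm_cm = 100,
                            R_Ohm_cm2 = NULL, tau_ms = NULL,
                            r_Ohm_cm2 = NULL, L_H_cm2 = NULL) {
  .check_pos(a_um, "a_um")
  .check_pos(C_uF_cm2, "C_uF_cm2")
  .check_pos(Ra_Ohm_cm, "Ra_Ohm_cm")
  if (is.null(R_Ohm_cm2) == is.null(tau_ms)) {
    stop("give exactly one of 'R_Ohm_cm2' or 'tau_ms'", call. = FALSE)
  }
  if (is.null(R_Ohm_cm2)) {
    .check_pos(tau_ms, "tau_ms")
    R_Ohm_cm2 <- tau_ms / C_uF_cm2 * 1e3 # tau = C R: (uF/cm^2)(Ohm cm^2) = 1e-3 ms
  }
  .check_pos(R_Ohm_cm2, "R_Ohm_cm2")
  if (is.null(r_Ohm_cm2) != is.null(L_H_cm2)) {
    stop("'r_Ohm_cm2' and 'L_H_cm2' must both be given (resonant) or both absent (passive)",
         call. = FALSE)
  }
  .check_pos(r_Ohm_cm2, "r_Ohm_cm2")
  .check_pos(L_H_cm2, "L_H_cm2")

  C <- C_uF_cm2 * .UF_CM2
  R <- R_Ohm_cm2 * .OHM_CM2
  Ra <- Ra_Ohm_cm * .OHM_CM
  a <- a_um
  obj <- list(
    C = C, R = R, Ra = Ra, a = a,
    r = if (is.null(r_Ohm_cm2)) NULL else r_Ohm_cm2 * .OHM_CM2,
    L = if (is.null(L_H_cm2)) NULL else L_H_cm2 * .H_CM2,
    resonant = !is.null(r_Ohm_cm2),
    D = a / (4 * Ra * C),
    tau = C * R,
    ra = 4 * Ra / (pi * a^2),
    cpl = C * pi * a,
    quoted = list(a_um = a_um, C_uF_cm2 = C_uF_cm2, Ra_Ohm_cm = Ra_Ohm_cm,
                  R_Ohm_cm2 = R_Ohm_cm2, r_Ohm_cm2 = r_Ohm_cm2,
                  L_H_cm2 = L_H_cm2)
  )
  class(obj) <- "membrane_params"
  obj
}

#' @export
print.membrane_params <- function(x, ...) {
  kind <- if (x$resonant) "resonant ('LRC')" else "passive ('RC')"
  cat(sprintf("<membrane_params> %s\n", kind))
  cat(sprintf("  a = %g um, C = %g uF/cm^2, Ra = %g Ohm cm, R = %g Ohm cm^2\n",
              x$quoted$a_um, x$quoted$C_uF_cm2, x$quoted$Ra_Ohm_cm, x$quoted$R_Ohm_cm2))
  if (x$resonant) {
    cat(sprintf("  r = %g Ohm cm^2, L = %g H cm^2\n", x$quoted$r_Ohm_cm2, x$quoted$L_H_cm2))
  }
  cat(sprintf("  derived: D = %g um^2/ms, tau = %g ms, ra = %g MOhm/um\n",
              x$D, x$tau, x$ra))
  invisible(x)
}

#' Derived cable constants of a branch
#'
#' Returns the diffusion coefficient `D = a / (4 Ra C)`, the membrane time
#' constant `tau = C R` and the axial resistance per unit length
#' `ra = 4 Ra / (pi a^2)` in internal units.
#'
#' @param params a [membrane_params()] object.
#' @return A list with components `D` (um^2/ms), `tau` (ms), `ra` (MOhm/um).
#' @examples
#' derive_cable_constants(membrane_params(a_um = 2, tau_ms = 2))
#' @export
derive_cable_constants <- function(params) {
  stopifnot(inherits(params, "membrane_params"))
  list(D = params$D, tau = params$tau, ra = params$ra)
}

#' Electrical parameters of a lumped soma
#'
#' The cell body is treated as a single iso-potential node with its own
#' membrane admittance.  Specific constants are converted to absolute ones
#' using the total somatic membrane area `pi * as^2` (sphere of diameter
#' `as`), so that the somatic admittance is commensurate (in 1/MOhm) with the
#' characteristic admittances `z = gamma / ra` of the attached cables.  A
#' passive soma omits `rs_Ohm_cm2`/`Ls_H_cm2` and drops the inductive-path
#' term of the admittance entirely.
#'
#' @param as_um soma diameter (um).
#' @param Cs_uF_cm2 specific somatic capacitance (uF/cm^2).
#' @param Rs_Ohm_cm2 specific somatic leak resistance (Ohm cm^2).
#' @param rs_Ohm_cm2 resonant-path resistance (Ohm cm^2), or `NULL`.
#' @param Ls_H_cm2 resonant-path inductance (H cm^2); required iff
#'   `rs_Ohm_cm2` is given.
#' @return An object of class `soma_params` with absolute internal fields
#'   `Cs` (nF), `Rs` (MOhm), `rs` (MOhm), `Ls` (MOhm ms) and `area` (um^2).
#' @seealso [gamma_soma()]
#' @examples
#' soma_params(as_um = 25, Cs_uF_cm2 = 1, Rs_Ohm_cm2 = 2000)
#' @export
soma_params <- function(as_um, Cs_uF_cm2 = 1, Rs_Ohm_cm2 = 2000,
                        rs_Ohm_cm2 = NULL, Ls_H_cm2 = NULL) {
  .check_pos(as_um, "as_um")
  .check_pos(Cs_uF_cm2, "Cs_uF_cm2")
  .check_pos(Rs_Ohm_cm2, "Rs_Ohm_cm2")
  if (is.null(rs_Ohm_cm2) != is.null(Ls_H_cm2)) {
    stop("'rs_Ohm_cm2' and 'Ls_H_cm2' must both be given (resonant) or both absent (passive)",
         call. = FALSE)
  }
  .check_pos(rs_Ohm_cm2, "rs_Ohm_cm2")
  .check_pos(Ls_H_cm2, "Ls_H_cm2")
  area <- pi * as_um^2
  obj <- list(
    as_um = as_um,
    area = area,
    Cs = Cs_uF_cm2 * .UF_CM2 * area,
    Rs = Rs_Ohm_cm2 * .OHM_CM2 / area,
    rs = if (is.null(rs_Ohm_cm2)) NULL else rs_Ohm_cm2 * .OHM_CM2 / area,
    Ls = if (is.null(Ls_H_cm2)) NULL else Ls_H_cm2 * .H_CM2 / area,
    resonant = !is.null(rs_Ohm_cm2),
    quoted = list(as_um = as_um, Cs_uF_cm2 = Cs_uF_cm2, Rs_Ohm_cm2 = Rs_Ohm_cm2,
                  rs_Ohm_cm2 = rs_Ohm_cm2, Ls_H_cm2 = Ls_H_cm2)
  )
  class(obj) <- "soma_params"
  obj
}

#' @export
print.soma_params <- function(x, ...) {
  kind <- if (x$resonant) "resonant ('LRC')" else "passive ('RC')"
  cat(sprintf("<soma_params> %s, diameter %g um (area %.4g um^2)\n",
              kind, x$as_um, x$area))
  cat(sprintf("  Cs = %g nF, Rs = %g MOhm", x$Cs, x$Rs))
  if (x$resonant) cat(sprintf(", rs = %g MOhm, Ls = %g MOhm ms", x$rs, x$Ls))
  cat("\n")
  invisible(x)
}

# parameter identity used to group branches into gamma-classes
.params_key <- function(p) {
  paste(format(c(p$C, p$R, p$Ra, p$a,
                 if (p$resonant) c(p$r, p$L) else c(-1, -1)),
               digits = 17), collapse = "|")
}
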