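# Shared parameter sets and helpers for the test suite.

ref_resonant <- function() {
  membrane_params(a_um = 2, C_uF_cm2 = 1, Ra_Ohm_cm = 100, tau_ms = 2,
                  r_Ohm_cm2 = 100, L_H_cm2 = 5)
}

ref_passive <- function() {
  membrane_params(a_um = 2, C_uF_cm2 = 1, Ra_Ohm_cm = 100, tau_ms = 2)
}

ref_soma_passive <- function() {
  soma_params(as_um = 25, Cs_uF_cm2 = 1, Rs_Ohm_cm2 = 2000)
}

ref_soma_resonant <- function() {
  soma_params(as_um = 25, Cs_uF_cm2 = 1, Rs_Ohm_cm2 = 2000,
              rs_Ohm_cm2 = 1, Ls_H_cm2 = 0.1)
}

# random Laplace arguments in the right half-plane
rand_omega <- function(n, re_max = 2, im_max = 2) {
  complex(real = stats::runif(n, 0, re_max),
          imaginary = stats::runif(n, -im_max, im_max))
}

rel_err <- function(a, b) max(Mod(a - b) / pmax(Mod(b), .Machine$double.xmin))

# relative to the largest magnitude (for time-domain curves spanning decades)
rel_to_max <- function(a, b) max(abs(a - b)) / max(abs(b))
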