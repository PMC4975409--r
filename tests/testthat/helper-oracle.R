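# Independent scalar oracle for the four-variable model: every current and
# gate equation written out term by term, straight from the model
# definition, with the H(0) = 1 Heaviside convention. Used to cross-check
# ionic_derivatives(); intentionally slow and explicit.
oracle_derivs <- function(u, v, w, s, p) {
  H <- function(x) if (x >= 0) 1 else 0

  tau_vminus <- if (H(u - p[["theta_vminus"]]) == 1) p[["tau_v2m"]] else p[["tau_v1m"]]
  tau_wminus <- p[["tau_w1m"]] +
    (p[["tau_w2m"]] - p[["tau_w1m"]]) *
    (1 + tanh(p[["k_wm"]] * (u - p[["u_wm"]]))) / 2
  tau_so <- p[["tau_so1"]] +
    (p[["tau_so2"]] - p[["tau_so1"]]) *
    (1 + tanh(p[["k_so"]] * (u - p[["u_so"]]))) / 2
  tau_s <- if (H(u - p[["theta_w"]]) == 1) p[["tau_s2"]] else p[["tau_s1"]]
  tau_o <- if (H(u - p[["theta_o"]]) == 1) p[["tau_o2"]] else p[["tau_o1"]]

  v_inf <- if (u < p[["theta_vminus"]]) 1 else 0
  w_inf <- if (H(u - p[["theta_o"]]) == 1) {
    p[["w_inf_star"]]
  } else {
    1 - u / p[["tau_winf"]]
  }
  s_inf <- (1 + tanh(p[["k_s"]] * (u - p[["u_s"]]))) / 2

  J_fi <- -v * H(u - p[["theta_v"]]) * (u - p[["theta_v"]]) *
    (p[["u_u"]] - u) / p[["tau_fi"]]
  J_so <- (u - p[["u_o"]]) * (1 - H(u - p[["theta_w"]])) / tau_o +
    H(u - p[["theta_w"]]) / tau_so
  J_si <- -H(u - p[["theta_w"]]) * w * s / p[["tau_si"]]

  dv <- if (H(u - p[["theta_v"]]) == 1) {
    -v / p[["tau_vp"]]
  } else {
    (v_inf - v) / tau_vminus
  }
  dw <- if (H(u - p[["theta_w"]]) == 1) {
    -w / p[["tau_wp"]]
  } else {
    (w_inf - w) / tau_wminus
  }
  ds <- (s_inf - s) / tau_s

  c(J_ion = J_fi + J_so + J_si, dv = dv, dw = dw, ds = ds)
}

# relative agreement helper: |a - b| <= tol * max(|a|, |b|, 1)
expect_rel_equal <- function(a, b, tol) {
  testthat::expect_lte(max(abs(a - b) / pmax(abs(a), abs(b), 1)), tol)
}
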