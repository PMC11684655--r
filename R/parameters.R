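#' Default model parameters
#'
#' Returns the full constant set of the detailed compartment model, grouped
#' as a flat named list. Time is in seconds; Ca2+, IP3, glutamate and
#' dopamine concentrations in uM; Na+ and K+ in mM; membrane potential in
#' mV; current densities in pA/um^2; diffusion coefficients in um^2/s.
#'
#' Gating and metabolic forms follow the classical IP3-receptor /
#' calcium-signalling literature (Li-Rinzel receptor gating, Hill-type
#' SERCA, PLC-beta/PLC-delta IP3 metabolism, Luo-Rudy NCX kinetics,
#' saturable Na+/K+-ATPase). Maximal-rate gains were fixed by calibrating
#' the model's dose-response behaviour (see the package vignette); the
#' physical constants and dissociation constants are literature values.
#'
#' Several entries are derived, not free: the leak conductances `g_nal`,
#' `g_kl` and the ER leak permeability `p_caerl` are solved from the
#' requirement that the nominal resting state (`ca_i0`, `na_i0`, ... below)
#' is an exact equilibrium of every compartment, and the resting membrane
#' potential `v0` sits at the NCX reversal potential `3*E_Na - 2*E_Ca`.
#' Use [finalize_parameters()] after overriding any constant.
#'
#' @param ... named overrides applied before the derived entries are solved.
#' @return an object of class `astro_parameters` (named list).
#' @export
#' @examples
#' p <- default_parameters()
#' p$v0          # resting potential, mV
#' p2 <- default_parameters(p_ncx = 0)   # NCX knocked out
default_parameters <- function(...) {
  p <- list(
    # physical constants
    faraday  = 96485,     # C/mol
    cm       = 0.01,      # membrane capacitance, pF/um^2
    rtf      = 26.73,     # RT/F at 310 K, mV
    # ER-to-cytosol volume ratio (geometry)
    a_er = 0.15, b_er = 0.073, c_er = 2.34,
    lateral_only = TRUE,
    # IP3 receptor (Li-Rinzel gating constants)
    d1 = 0.13, d2 = 1.049, d3 = 0.9434, d5 = 0.08234,
    a2 = 0.2,             # 1/(uM s)
    p_ip3r = 2.0e-4,      # pA/um^2 per uM of ER-cytosol Ca gradient
    # SERCA pump
    p_serca = 2.0e-3,     # pA/um^2
    k_serca = 0.1,        # uM
    # ER leak permeability: derived (rest balance), may be overridden
    p_caerl = NA_real_,   # pA/um^2 per uM
    # NCX, Luo-Rudy kinetics
    p_ncx = 4.0e-3,       # pA/um^2 (J_NCXmax)
    k_ncx_na = 87.5,      # mM
    k_ncx_ca = 1380,      # uM
    eta_ncx = 0.35, ksat_ncx = 0.1,
    # glutamate transporter
    p_glut = 1.5e-3,      # pA/um^2 (J_GluTmax)
    k_glut = 5,           # uM
    # Na/K ATPase
    p_nka = 0.16,         # pA/um^2
    k_nka_na = 10,        # mM
    k_nka_k = 1.5,        # mM
    # leak conductances: derived (rest balance), pA/um^2/mV
    g_nal = NA_real_, g_kl = NA_real_,
    # IP3 metabolism (uM/s rates)
    o_beta_glu = 10.5, k_r_glu = 1.3, k_p_glu = 10, k_pi_glu = 0.6,
    o_beta_da  = 0.06, k_r_da = 0.5, k_p_da = 10, k_pi_da = 0.6,
    o_delta = 0.02, kappa_delta = 1.5, k_delta = 0.1,
    o_3k = 2.0, k_d_3k = 0.7, k_3_3k = 1.0,
    omega_5p = 0.05,      # 1/s
    # transmitter kinetics
    g_glu_decay = 100,    # 1/s
    g_da_decay = 4.201,   # 1/s
    rho_glu = 0.5,        # uM per release event
    rho_da = 3,           # uM per release event
    # diffusion coefficients, um^2/s (effective, crowded-cytosol values)
    d_ca = 0.8, d_ip3 = 2, d_cae = 0.8, d_caer = 30,
    d_na = 20, d_k = 20, d_glu = 5, d_da = 5,
    # nominal resting concentrations
    ca_i0 = 0.1, ca_e0 = 1800, ca_er0 = 120,   # uM
    na_i0 = 15, na_e0 = 145, k_i0 = 100, k_e0 = 3,  # mM
    # include ER current densities in the membrane-potential equation
    include_er_currents = TRUE,
    # reduced-model average IP3R gate (see the simplified-model functions)
    h_avg = 0.68,
    # derived at finalization
    ip3_0 = NA_real_, h0 = NA_real_, v0 = NA_real_
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  finalize_parameters(p)
}

#' Solve the derived (rest-consistent) parameter entries
#'
#' Computes the resting IP3 concentration (balance of PLC-delta synthesis
#' against degradation), the resting IP3R gate `h0`, the resting potential
#' `v0` at NCX reversal, and the leak rates `g_nal`, `g_kl`, `p_caerl`
#' that make the nominal resting state an exact equilibrium. Entries that
#' were set explicitly (non-`NA`) are kept.
#'
#' @param p parameter list as from [default_parameters()].
#' @return finalized `astro_parameters` object.
#' @export
finalize_parameters <- function(p) {
  # resting IP3: S_delta = D_3K + D_5P at ca_i0
  f <- function(ip3) plc_delta(p$ca_i0, ip3, p) -
    deg_3k(p$ca_i0, ip3, p) - deg_5p(ip3, p)
  p$ip3_0 <- stats::uniroot(f, c(1e-9, 50), tol = 1e-14)$root
  q2 <- p$d2 * (p$ip3_0 + p$d1) / (p$ip3_0 + p$d3)
  p$h0 <- q2 / (q2 + p$ca_i0)
  e_na <- p$rtf * log(p$na_e0 / p$na_i0)
  e_k  <- p$rtf * log(p$k_e0 / p$k_i0)
  e_ca <- p$rtf / 2 * log(p$ca_e0 / p$ca_i0)
  p$v0 <- 3 * e_na - 2 * e_ca         # NCX reversal: J_NCX(rest) = 0
  j_nka0 <- p$p_nka * nka_activation(p$na_i0, p$k_e0, p)
  if (is.na(p$g_nal)) p$g_nal <- 3 * j_nka0 / (e_na - p$v0)
  if (is.na(p$g_kl))  p$g_kl  <- 2 * j_nka0 / (p$v0 - e_k)
  if (p$g_nal < 0 || p$g_kl < 0)
    stop("rest construction failed: negative leak conductance")
  if (is.na(p$p_caerl)) {
    gate <- ip3r_open(p$ca_i0, p$ip3_0, p$h0, p)
    delta <- p$ca_er0 - p$ca_i0
    serca <- p$p_serca * hill2(p$ca_i0, p$k_serca)
    p$p_caerl <- (serca - p$p_ip3r * gate * delta) / delta
    if (p$p_caerl < 0)
      stop("rest construction failed: IP3R rest flux exceeds SERCA; ",
           "reduce p_ip3r or ca_er0")
  }
  class(p) <- "astro_parameters"
  p
}

#' @export
print.astro_parameters <- function(x, ...) {
  cat("astro_parameters: detailed astrocyte compartment model constants\n")
  cat(sprintf("  rest: ca_i %.3g uM, ip3 %.4g uM, v %.4g mV, h %.4g\n",
              x$ca_i0, x$ip3_0, x$v0, x$h0))
  cat(sprintf("  gains: p_ip3r %.3g, p_serca %.3g, p_ncx %.3g, p_glut %.3g (pA/um^2)\n",
              x$p_ip3r, x$p_serca, x$p_ncx, x$p_glut))
  cat(sprintf("  PLCbeta: glu %.3g, da %.3g uM/s; D: Ca %.3g, IP3 %.3g um^2/s\n",
              x$o_beta_glu, x$o_beta_da, x$d_ca, x$d_ip3))
  invisible(x)
}

#' Modify parameters by name
#'
#' @param params an `astro_parameters` object.
#' @param ... named replacements; derived entries are re-solved unless
#'   explicitly supplied.
#' @return updated `astro_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  ov <- list(...)
  bad <- setdiff(names(ov), names(unclass(params)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p <- unclass(params)
  # re-derive rest-consistent entries unless the caller pins them
  for (dv in c("g_nal", "g_kl", "p_caerl", "ip3_0", "h0", "v0"))
    if (!dv %in% names(ov)) p[[dv]] <- NA_real_
  p[names(ov)] <- ov
  finalize_parameters(p)
}

# -- elementary kinetic terms (shared by detailed and simplified models) ----

hill2 <- function(x, k) x^2 / (x^2 + k^2)

ip3r_open <- function(ca, ip3, h, p) {
  m <- ip3 / (ip3 + p$d1)
  n <- ca / (ca + p$d5)
  (m * n * h)^3
}

plc_beta <- function(agonist, ca, o_beta, k_r, k_p, k_pi) {
  if (o_beta == 0) return(agonist * 0)
  keff <- k_r * (1 + (k_p / k_r) * ca / (ca + k_pi))
  a <- agonist^0.7
  o_beta * a / (a + keff^0.7)
}

plc_delta <- function(ca, ip3, p)
  p$o_delta / (1 + ip3 / p$kappa_delta) * hill2(ca, p$k_delta)

deg_3k <- function(ca, ip3, p)
  p$o_3k * ca^4 / (ca^4 + p$k_d_3k^4) * ip3 / (ip3 + p$k_3_3k)

deg_5p <- function(ip3, p) p$omega_5p * ip3

nka_activation <- function(na_i, k_e, p)
  na_i^1.5 / (na_i^1.5 + p$k_nka_na^1.5) * k_e / (k_e + p$k_nka_k)

ncx_current <- function(ca_i, ca_e, na_i, na_e, v, p) {
  phi <- v / p$rtf
  ef <- exp(p$eta_ncx * phi)
  er <- exp((p$eta_ncx - 1) * phi)
  num <- na_i^3 * ca_e * ef - na_e^3 * ca_i * er
  den <- (p$k_ncx_na^3 + na_e^3) * (p$k_ncx_ca + ca_e) * (1 + p$ksat_ncx * er)
  p$p_ncx * num / den
}

glut_current <- function(glu, p) p$p_glut * glu / (glu + p$k_glut)
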