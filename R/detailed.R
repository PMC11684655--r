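#' @useDynLib astroca, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Names of the twelve state variables of a detailed compartment
#' @export
state_variables <- c("ca_i", "ca_e", "ca_er", "ip3", "h",
                     "na_i", "na_e", "k_i", "k_e", "v", "glu", "da")

# conversion factors: current density (pA/um^2) times A/V (1/um) to
# concentration rate; uM/s for divalent Ca2+, mM/s for monovalent ions
conv_factors <- function(p)
  list(kca = 1e9 / (2 * p$faraday), kion = 1e6 / p$faraday,
       kv = 1e3 / p$cm)

#' Geometric quantities of a morphology used by the model
#'
#' @param morph an `astro_morphology`.
#' @param params an `astro_parameters` object (for the ER-ratio constants).
#' @return list with per-compartment surface-to-volume ratios `av`,
#'   ER volume ratios `rer`, volumes `vol`, and the geometric coupling
#'   matrix `G` (`G[j,k] = A_c/(V_j * delta)`, multiplied by a species'
#'   diffusion coefficient to give the coupling strength in 1/s).
#' @export
model_geometry <- function(morph, params = default_parameters()) {
  comp <- morph$compartments
  cyl <- comp$shape == "cylinder"
  av <- 3 / comp$radius
  av[cyl] <- if (params$lateral_only) 2 / comp$radius[cyl] else
    2 / comp$radius[cyl] + 2 / comp$length[cyl]
  list(av = av,
       rer = er_volume_ratio(av, params$a_er, params$b_er, params$c_er),
       vol = compartment_volume(comp$shape, comp$radius, comp$length),
       G = coupling_matrix(morph, D = 1))
}

#' Membrane and ER fluxes of one compartment
#'
#' Evaluates every current density (pA/um^2) and IP3 synthesis/degradation
#' rate (uM/s) of the detailed model at a given state. Sign conventions:
#' positive `j_ip3r`/`j_caerl` move Ca2+ from ER to cytosol, positive
#' `j_serca` the reverse; positive `j_ncx` is reverse-mode exchange
#' (Ca2+ entry, 3 Na+ out); positive leak and pump currents are outward.
#'
#' @param state named numeric vector with entries [state_variables].
#' @param params an `astro_parameters` object.
#' @return named list of fluxes.
#' @export
compute_fluxes <- function(state, params) {
  s <- as.list(state[state_variables])
  p <- params
  list(
    j_ip3r  = p$p_ip3r * ip3r_open(s$ca_i, s$ip3, s$h, p) * (s$ca_er - s$ca_i),
    j_serca = p$p_serca * hill2(s$ca_i, p$k_serca),
    j_caerl = p$p_caerl * (s$ca_er - s$ca_i),
    j_ncx   = ncx_current(s$ca_i, s$ca_e, s$na_i, s$na_e, s$v, p),
    j_glut  = glut_current(s$glu, p),
    j_nka   = p$p_nka * nka_activation(s$na_i, s$k_e, p),
    j_nal   = p$g_nal * (s$v - p$rtf * log(s$na_e / s$na_i)),
    j_kl    = p$g_kl * (s$v - p$rtf * log(s$k_e / s$k_i)),
    s_plcb_glu = plc_beta(s$glu, s$ca_i, p$o_beta_glu, p$k_r_glu,
                          p$k_p_glu, p$k_pi_glu),
    s_plcb_da  = plc_beta(s$da, s$ca_i, p$o_beta_da, p$k_r_da,
                          p$k_p_da, p$k_pi_da),
    s_plcd  = plc_delta(s$ca_i, s$ip3, p),
    d_ip3_3k = deg_3k(s$ca_i, s$ip3, p),
    d_ip5p  = deg_5p(s$ip3, p)
  )
}

#' Right-hand side of the detailed multi-compartment model
#'
#' Reference implementation in R, vectorized over compartments; the
#' simulator uses an equivalent compiled version. The state vector is laid
#' out compartment-by-compartment, twelve entries each, in the order of
#' [state_variables].
#'
#' @param t time (unused; the autonomous dynamics are driven by transmitter
#'   state set through release events).
#' @param y state vector of length `12 * n`.
#' @param morph an `astro_morphology`.
#' @param params an `astro_parameters` object.
#' @param geom optional cached [model_geometry()] result.
#' @return derivative vector of length `12 * n`.
#' @export
rhs_detailed <- function(t, y, morph, params, geom = NULL) {
  n <- nrow(morph$compartments)
  if (length(y) != 12L * n) stop("state length does not match morphology")
  geom <- geom %||% model_geometry(morph, params)
  p <- params
  S <- matrix(y, nrow = n, ncol = 12L, byrow = TRUE)
  colnames(S) <- state_variables
  ca_i <- S[, 1]; ca_e <- S[, 2]; ca_er <- S[, 3]; ip3 <- S[, 4]
  h <- S[, 5]; na_i <- S[, 6]; na_e <- S[, 7]; k_i <- S[, 8]
  k_e <- S[, 9]; v <- S[, 10]; glu <- S[, 11]; da <- S[, 12]
  cf <- conv_factors(p)
  av <- geom$av; rer <- geom$rer
  G <- geom$G; gs <- rowSums(G)
  diffuse <- function(x, D) D * (as.vector(G %*% x) - gs * x)

  j_ip3r  <- p$p_ip3r * ip3r_open(ca_i, ip3, h, p) * (ca_er - ca_i)
  j_serca <- p$p_serca * hill2(ca_i, p$k_serca)
  j_caerl <- p$p_caerl * (ca_er - ca_i)
  j_ncx   <- ncx_current(ca_i, ca_e, na_i, na_e, v, p)
  j_glut  <- glut_current(glu, p)
  j_nka   <- p$p_nka * nka_activation(na_i, k_e, p)
  j_nal   <- p$g_nal * (v - p$rtf * log(na_e / na_i))
  j_kl    <- p$g_kl * (v - p$rtf * log(k_e / k_i))
  er_net  <- j_ip3r - j_serca + j_caerl

  s_bg <- plc_beta(glu, ca_i, p$o_beta_glu, p$k_r_glu, p$k_p_glu, p$k_pi_glu)
  s_bd <- plc_beta(da, ca_i, p$o_beta_da, p$k_r_da, p$k_p_da, p$k_pi_da)
  s_d  <- plc_delta(ca_i, ip3, p)
  d3k  <- deg_3k(ca_i, ip3, p)
  d5p  <- deg_5p(ip3, p)
  q2   <- p$d2 * (ip3 + p$d1) / (ip3 + p$d3)

  na_flux <- cf$kion * av * (3 * j_glut - 3 * j_nka - 3 * j_ncx - j_nal)
  k_flux  <- cf$kion * av * (-j_glut + 2 * j_nka - j_kl)
  er_v <- if (p$include_er_currents) -2 * j_ip3r + 2 * j_serca - 2 * j_caerl
          else 0

  D <- cbind(
    ca_i  = cf$kca * av * j_ncx + cf$kca * av * rer * er_net +
            diffuse(ca_i, p$d_ca),
    ca_e  = -cf$kca * av * j_ncx + diffuse(ca_e, p$d_cae),
    ca_er = -cf$kca * av * er_net + diffuse(ca_er, p$d_caer),
    ip3   = s_bg + s_bd + s_d - d3k - d5p + diffuse(ip3, p$d_ip3),
    h     = p$a2 * (q2 * (1 - h) - ca_i * h),
    na_i  = na_flux + diffuse(na_i, p$d_na),
    na_e  = -na_flux + diffuse(na_e, p$d_na),
    k_i   = k_flux + diffuse(k_i, p$d_k),
    k_e   = -k_flux + diffuse(k_e, p$d_k),
    v     = -cf$kv * (er_v + j_ncx - 2 * j_glut + j_nka + j_nal + j_kl),
    glu   = -p$g_glu_decay * glu + diffuse(glu, p$d_glu),
    da    = -p$g_da_decay * da + diffuse(da, p$d_da)
  )
  as.vector(t(D))
}

#' Analytic resting state of a morphology
#'
#' By construction of the derived parameters (see [finalize_parameters()])
#' the nominal resting point is an exact equilibrium of every compartment,
#' independent of geometry.
#'
#' @param morph an `astro_morphology`.
#' @param params an `astro_parameters` object.
#' @return matrix `n x 12` with columns [state_variables].
#' @export
rest_state_matrix <- function(morph, params = default_parameters()) {
  n <- nrow(morph$compartments)
  p <- params
  m <- matrix(rep(c(p$ca_i0, p$ca_e0, p$ca_er0, p$ip3_0, p$h0,
                    p$na_i0, p$na_e0, p$k_i0, p$k_e0, p$v0, 0, 0),
                  each = n), nrow = n)
  colnames(m) <- state_variables
  m
}

state_to_vector <- function(m) as.vector(t(m))

vector_to_state <- function(y, n) {
  m <- matrix(y, nrow = n, ncol = 12L, byrow = TRUE)
  colnames(m) <- state_variables
  m
}

state_names <- function(n)
  as.vector(t(outer(seq_len(n), state_variables,
                    function(i, v) paste0(v, ".", i))))

#' Resting state by relaxation
#'
#' Integrates the unstimulated model until every state derivative is below
#' `tol`, starting from the analytic resting point (or a supplied initial
#' state). Errors with a diagnostic naming the worst compartment/variable
#' if the relaxation does not converge.
#'
#' @param morph an `astro_morphology`.
#' @param params an `astro_parameters` object.
#' @param tol maximum absolute derivative accepted (per unit per s).
#' @param t_max total relaxation time budget in s.
#' @param init optional initial state matrix (`n x 12`).
#' @return matrix `n x 12` with attribute `"residual"` (max |derivative|).
#' @export
find_rest_state <- function(morph, params = default_parameters(),
                            tol = 1e-9, t_max = 400, init = NULL) {
  geom <- model_geometry(morph, params)
  n <- nrow(morph$compartments)
  y <- state_to_vector(init %||% rest_state_matrix(morph, params))
  ctx <- build_context(geom, params)
  elapsed <- 0
  repeat {
    dy <- rhs_compiled(0, y, ctx)
    if (max(abs(dy)) < tol) break
    if (elapsed >= t_max) {
      worst <- which.max(abs(dy))
      stop(sprintf(
        "rest-state relaxation did not converge: |d %s/dt| = %.3g in compartment %d",
        state_variables[(worst - 1L) %% 12L + 1L], max(abs(dy)),
        (worst - 1L) %/% 12L + 1L))
    }
    step <- min(100, t_max - elapsed)
    sol <- deSolve::lsoda(y, c(0, step),
                          function(t, y, parms) list(rhs_compiled(t, y, parms)),
                          parms = ctx, rtol = 1e-10, atol = 1e-12)
    y <- as.numeric(sol[nrow(sol), -1])
    elapsed <- elapsed + step
  }
  out <- vector_to_state(y, n)
  attr(out, "residual") <- max(abs(rhs_compiled(0, y, ctx)))
  out
}

#' Apply an instantaneous transmitter release to a compartment state
#'
#' Release is a delta-function jump: glutamate events add `rho_glu`
#' (0.5 uM), dopamine events add `rho_da` (3 uM) to the extracellular
#' transmitter concentration; all other variables are unchanged.
#'
#' @param state named state vector (entries of [state_variables]).
#' @param transmitter `"glutamate"` or `"dopamine"`.
#' @param params an `astro_parameters` object.
#' @return updated state vector.
#' @export
apply_release <- function(state, transmitter = c("glutamate", "dopamine"),
                          params = default_parameters()) {
  transmitter <- match.arg(transmitter)
  if (transmitter == "glutamate") state["glu"] <- state["glu"] + params$rho_glu
  else state["da"] <- state["da"] + params$rho_da
  state
}

release_events <- function(protocol, morph, params) {
  n <- nrow(morph$compartments)
  rows <- lapply(protocol$trains, function(tr) {
    if (length(tr$times) == 0L) return(NULL)
    var0 <- if (tr$transmitter == "glutamate") 11L else 12L
    rho <- if (tr$transmitter == "glutamate") params$rho_glu else params$rho_da
    bad <- setdiff(tr$targets, seq_len(n))
    if (length(bad))
      stop("protocol targets missing from morphology: ",
           paste(bad, collapse = ", "))
    expand <- expand.grid(target = tr$targets, time = tr$times)
    data.frame(var = (expand$target - 1L) * 12L + var0,
               time = expand$time, value = rho, method = "add")
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) return(NULL)
  ev[order(ev$time, ev$var), ]
}

#' Simulate the detailed model under a stimulation protocol
#'
#' Integrates the full multi-compartment system with a stiff adaptive
#' solver; transmitter release events are applied as exact state jumps at
#' the Poisson event times. Output is sampled on a fixed grid.
#'
#' @param morph an `astro_morphology`.
#' @param protocol an `astro_protocol` from [make_protocol()].
#' @param params an `astro_parameters` object.
#' @param dt_out output sampling step in s (default 0.01).
#' @param rtol,atol solver tolerances.
#' @param init optional initial state matrix; defaults to the analytic rest.
#' @return an `astro_timeseries`: list with `times`, state matrix `y`
#'   (time by `12 n`, columns named `var.compartment`), `morph`, `protocol`.
#' @export
simulate_detailed <- function(morph, protocol, params = default_parameters(),
                              dt_out = 0.01, rtol = 1e-6, atol = NULL,
                              init = NULL) {
  geom <- model_geometry(morph, params)
  n <- nrow(morph$compartments)
  y0 <- state_to_vector(init %||% rest_state_matrix(morph, params))
  names(y0) <- state_names(n)
  ctx <- build_context(geom, params)
  times <- seq(0, protocol$duration, by = dt_out)
  ev <- release_events(protocol, morph, params)
  atol <- atol %||% default_atol(n)
  sol <- deSolve::lsoda(
    y0, times, function(t, y, parms) list(rhs_compiled(t, y, parms)),
    parms = ctx, rtol = rtol, atol = atol, maxsteps = 50000,
    events = if (!is.null(ev)) list(data = ev) else NULL)
  if (attr(sol, "istate")[1] < 0)
    stop("solver failure in detailed simulation")
  y <- unname(sol[, -1, drop = FALSE])
  colnames(y) <- state_names(n)
  structure(list(times = sol[, 1], y = y, morph = morph,
                 protocol = protocol),
            class = "astro_timeseries")
}

# per-variable absolute tolerances: concentrations in uM/mM vs mV scale
default_atol <- function(n) {
  per_comp <- c(ca_i = 1e-6, ca_e = 1e-3, ca_er = 1e-3, ip3 = 1e-6,
                h = 1e-7, na_i = 1e-6, na_e = 1e-6, k_i = 1e-6,
                k_e = 1e-6, v = 1e-5, glu = 1e-7, da = 1e-7)
  rep(unname(per_comp), n)
}

#' @export
print.astro_timeseries <- function(x, ...) {
  n <- ncol(x$y) / 12L
  cat("astro_timeseries: ", n, " compartments, ",
      length(x$times), " samples over ", max(x$times), " s\n", sep = "")
  invisible(x)
}

#' Extract one variable's traces from a simulation
#'
#' @param ts an `astro_timeseries`.
#' @param var variable name (one of [state_variables], or `"c"`/`"i"` for
#'   simplified-model output).
#' @return matrix time by compartment.
#' @export
get_traces <- function(ts, var = "ca_i") {
  cols <- grep(paste0("^", var, "\\."), colnames(ts$y))
  if (!length(cols)) stop("no such variable: ", var)
  out <- ts$y[, cols, drop = FALSE]
  colnames(out) <- sub("^.*\\.", "", colnames(out))
  out
}

#' Write a simulation to CSV
#'
#' One row per output time, one column per compartment and variable.
#'
#' @param ts an `astro_timeseries`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(data.frame(time = ts$times, ts$y, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
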