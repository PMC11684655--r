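# Reduced two-variable (c, i) model: fast variables (ions, potential,
# extracellular and ER Ca2+) pinned to their resting values, the IP3R gate
# replaced by its average, leaving intracellular Ca2+ (c) and IP3 (i) as
# dimensionless state variables (numerically, concentrations in uM).

# Rescaling constants mapping the stationary mean transmitter concentration
# rho*nu/G (uM) to the dimensionless drives g and d. The glutamate scale
# reproduces the pairs (2 Hz, 2e-5), (5 Hz, 5e-5), (10 Hz, 1e-4); the
# dopamine scale is fixed by the 5 and 10 Hz pairs (1e-3, 2e-3).
GLU_DRIVE_SCALE <- 500      # uM
DA_DRIVE_SCALE <- 3571.43   # uM

#' Dimensionless drive level for a Poisson stimulation frequency
#'
#' Maps a stimulation rate to the mean rescaled transmitter level: the
#' stationary mean concentration `rho * nu / G` of the release-decay
#' process, divided by the rescaling constant of the reduced model
#' (glutamate: 500 uM; dopamine: 3571.43 uM). 2/5/10 Hz glutamate map to
#' g = 2e-5 / 5e-5 / 1e-4 and 5/10 Hz dopamine to d = 1e-3 / 2e-3.
#'
#' @param rate stimulation frequency in Hz (>= 0).
#' @param transmitter `"glutamate"` or `"dopamine"`.
#' @param params an `astro_parameters` object (release sizes and decay rates).
#' @return dimensionless drive.
#' @export
drive_from_frequency <- function(rate, transmitter = c("glutamate", "dopamine"),
                                 params = default_parameters()) {
  transmitter <- match.arg(transmitter)
  if (any(rate < 0)) stop("negative rate")
  if (transmitter == "glutamate")
    params$rho_glu * rate / params$g_glu_decay / GLU_DRIVE_SCALE
  else
    params$rho_da * rate / params$g_da_decay / DA_DRIVE_SCALE
}

drive_to_concentration <- function(g, d) {
  list(glu = g * GLU_DRIVE_SCALE, da = d * DA_DRIVE_SCALE)
}

# PLC-beta synthesis averaged exactly over the stationary shot-noise
# transmitter process (Poisson release, exponential decay), valid in the
# dilute-pulse regime nu/G << 1: each pulse rho*exp(-G t) contributes
# integral (10/7) * ln(1 + (rho/keff)^0.7) / G of receptor occupancy.
plc_beta_shot <- function(mean_conc, rho, ca, o_beta, k_r, k_p, k_pi) {
  if (o_beta == 0 || mean_conc <= 0) return(mean_conc * 0)
  keff <- k_r * (1 + (k_p / k_r) * ca / (ca + k_pi))
  o_beta * (mean_conc / rho) * (10 / 7) * log1p((rho / keff)^0.7)
}

#' Geometry of a single cylindrical (or spherical) compartment
#'
#' @param radius radius in um.
#' @param shape `"cylinder"` or `"sphere"`.
#' @param length cylinder length in um.
#' @param params an `astro_parameters` object.
#' @return list with `av` and `rer`.
#' @export
compartment_geometry <- function(radius, shape = "cylinder", length = 1,
                                 params = default_parameters()) {
  av <- surface_to_volume(radius, shape, length, params$lateral_only)
  list(av = av,
       rer = er_volume_ratio(av, params$a_er, params$b_er, params$c_er),
       radius = radius, shape = shape, length = length)
}

#' Right-hand side of the reduced two-variable model
#'
#' `dc/dt` combines the (linearized-in-state) NCX current, evaluated at the
#' resting ionic concentrations and potential, with the ER fluxes scaled by
#' the compartment's `A/V` and `r_ER`; `di/dt` is the balance of the three
#' PLC synthesis terms and the two degradation terms. The IP3R gate uses
#' the average open fraction `h_avg` (resting value by default) and the ER
#' store is held at its resting content.
#'
#' @param state numeric `c(c, i)`.
#' @param drive numeric `c(g, d)` dimensionless drive levels.
#' @param geom a [compartment_geometry()] result.
#' @param params an `astro_parameters` object.
#' @param h_avg average IP3R gate (default: resting `h0`).
#' @return numeric `c(dc, di)` (per second).
#' @export
rhs_simplified <- function(state, drive, geom, params = default_parameters(),
                           h_avg = params$h_avg) {
  p <- params
  cc <- state[1]; ii <- state[2]
  conc <- drive_to_concentration(drive[1], drive[2])
  kca <- 1e9 / (2 * p$faraday)
  j_ip3r <- p$p_ip3r * ip3r_open(cc, ii, h_avg, p) * (p$ca_er0 - cc)
  j_serca <- p$p_serca * hill2(cc, p$k_serca)
  j_caerl <- p$p_caerl * (p$ca_er0 - cc)
  j_ncx <- ncx_current(cc, p$ca_e0, p$na_i0, p$na_e0, p$v0, p)
  dc <- kca * geom$av * j_ncx +
    kca * geom$av * geom$rer * (j_ip3r - j_serca + j_caerl)
  di <- plc_beta_shot(conc$glu, p$rho_glu, cc, p$o_beta_glu, p$k_r_glu,
                      p$k_p_glu, p$k_pi_glu) +
    plc_beta_shot(conc$da, p$rho_da, cc, p$o_beta_da, p$k_r_da,
                  p$k_p_da, p$k_pi_da) +
    plc_delta(cc, ii, p) - deg_3k(cc, ii, p) - deg_5p(ii, p)
  c(dc, di)
}

# root of dc/dt in i at fixed c (dc/dt is increasing in i); NA if no sign
# change inside the bracket
solve_c_nullcline_i <- function(cc, drive, geom, params, h_avg, i_range) {
  f <- function(ii) rhs_simplified(c(cc, ii), drive, geom, params, h_avg)[1]
  lo <- f(i_range[1]); hi <- f(i_range[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0) return(NA_real_)
  stats::uniroot(f, i_range, tol = 1e-12)$root
}

solve_i_nullcline_i <- function(cc, drive, geom, params, h_avg, i_range) {
  f <- function(ii) rhs_simplified(c(cc, ii), drive, geom, params, h_avg)[2]
  lo <- f(i_range[1]); hi <- f(i_range[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0) return(NA_real_)
  stats::uniroot(f, i_range, tol = 1e-12)$root
}

#' Nullclines of the reduced model
#'
#' Returns both nullclines as `i(c)` point sets on a grid of `c` values.
#' The `c` nullcline depends on the compartment radius (through `A/V` and
#' `r_ER`); the `i` nullcline does not.
#'
#' @param drive numeric `c(g, d)`.
#' @param geom a [compartment_geometry()].
#' @param params an `astro_parameters` object.
#' @param c_range,i_range search ranges (dimensionless).
#' @param n number of grid points in `c`.
#' @param h_avg average IP3R gate.
#' @return list of two data frames (`c_nullcline`, `i_nullcline`) with
#'   columns `c` and `i`; rows where no root lies in `i_range` are dropped.
#' @export
nullclines <- function(drive, geom, params = default_parameters(),
                       c_range = c(1e-3, 2), i_range = c(1e-4, 10),
                       n = 200, h_avg = params$h_avg) {
  if (any(c_range <= 0) || any(i_range <= 0)) stop("ranges must be positive")
  cs <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n))
  ic <- vapply(cs, solve_c_nullcline_i, 0.0, drive, geom, params, h_avg, i_range)
  ii <- vapply(cs, solve_i_nullcline_i, 0.0, drive, geom, params, h_avg, i_range)
  list(c_nullcline = data.frame(c = cs, i = ic)[!is.na(ic), ],
       i_nullcline = data.frame(c = cs, i = ii)[!is.na(ii), ])
}

classify_equilibrium <- function(eig, tol = 1e-8) {
  re <- Re(eig); im <- Im(eig)
  if (any(abs(re) < tol)) return("marginal")
  if (all(re < 0) && any(abs(im) > 0)) return("stable_focus")
  if (all(re < 0)) return("stable_node")
  if (all(re > 0) && any(abs(im) > 0)) return("unstable_focus")
  if (all(re > 0)) return("unstable_node")
  "saddle"
}

fd_jacobian <- function(x0, drive, geom, params, h_avg, rel = 1e-6) {
  J <- matrix(0, 2, 2)
  for (k in 1:2) {
    hstep <- rel * max(abs(x0[k]), 1e-3)
    xp <- x0; xp[k] <- xp[k] + hstep
    xm <- x0; xm[k] <- xm[k] - hstep
    J[, k] <- (rhs_simplified(xp, drive, geom, params, h_avg) -
               rhs_simplified(xm, drive, geom, params, h_avg)) / (2 * hstep)
  }
  J
}

#' Locate and classify equilibria of the reduced model
#'
#' Equilibria are bracketed as intersections of the two nullclines on a
#' grid in `c`, polished by 2-D Newton iteration, and classified from the
#' eigenvalues of a central-finite-difference Jacobian: stable node (real,
#' negative), stable focus (complex, negative real part), unstable focus
#' (complex, positive real part), unstable node, or saddle. Eigenvalues
#' with |Re| < 1e-8 are reported as `marginal`.
#'
#' @inheritParams nullclines
#' @return data frame with columns `c`, `i`, `re1`, `im1`, `re2`, `im2`,
#'   `classification`; zero rows (with a warning) if none found.
#' @export
find_equilibria <- function(drive, geom, params = default_parameters(),
                            c_range = c(1e-3, 10), i_range = c(1e-5, 50),
                            n = 300, h_avg = params$h_avg) {
  inull <- function(cc) solve_i_nullcline_i(cc, drive, geom, params, h_avg,
                                            i_range)
  g <- function(cc) {
    ii <- inull(cc)
    if (is.na(ii)) return(NA_real_)
    rhs_simplified(c(cc, ii), drive, geom, params, h_avg)[1]
  }
  cs <- exp(seq(log(c_range[1]), log(c_range[2]), length.out = n))
  vals <- vapply(cs, g, 0.0)
  roots <- list()
  for (k in seq_len(n)[-1]) {
    if (any(is.na(vals[c(k - 1, k)]))) next
    if (vals[k - 1] == 0 || vals[k - 1] * vals[k] >= 0) next
    cr <- stats::uniroot(g, c(cs[k - 1], cs[k]), tol = 1e-13)$root
    x <- c(cr, inull(cr))
    # Newton polish on the full 2-D system
    for (it in 1:30) {
      fx <- rhs_simplified(x, drive, geom, params, h_avg)
      if (max(abs(fx)) < 1e-13) break
      J <- fd_jacobian(x, drive, geom, params, h_avg)
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      x <- x - step
    }
    roots[[length(roots) + 1L]] <- x
  }
  if (!length(roots)) {
    warning("no equilibria found in the search box")
    return(data.frame(c = numeric(0), i = numeric(0), re1 = numeric(0),
                      im1 = numeric(0), re2 = numeric(0), im2 = numeric(0),
                      classification = character(0)))
  }
  out <- lapply(roots, function(x) {
    J <- fd_jacobian(x, drive, geom, params, h_avg)
    eig <- eigen(J, only.values = TRUE)$values
    data.frame(c = x[1], i = x[2],
               re1 = Re(eig[1]), im1 = Im(eig[1]),
               re2 = Re(eig[2]), im2 = Im(eig[2]),
               classification = classify_equilibrium(eig))
  })
  unique(do.call(rbind, out))
}

#' Simulate the reduced model on a compartment chain
#'
#' Integrates the (c, i) dynamics of every compartment of a morphology,
#' coupled by diffusion of c and i (disable with `couple = FALSE`, which
#' sets both coupling coefficients to zero). The drive is either the
#' stationary mean level implied by each train's rate (`mode = "mean"`) or
#' the event-driven rescaled transmitter dynamics with the protocol's
#' release times applied as jumps (`mode = "events"`).
#'
#' @param morph an `astro_morphology`.
#' @param protocol an `astro_protocol`.
#' @param params an `astro_parameters` object.
#' @param couple logical; diffusive coupling of c and i between adjacent
#'   compartments.
#' @param mode `"events"` (default) or `"mean"`.
#' @param dt_out output step, s.
#' @param h_avg average IP3R gate.
#' @return an `astro_timeseries` with per-compartment variables `c`, `i`,
#'   `glu`, `da`.
#' @export
simulate_simplified <- function(morph, protocol, params = default_parameters(),
                                couple = TRUE, mode = c("events", "mean"),
                                dt_out = 0.01, h_avg = params$h_avg) {
  mode <- match.arg(mode)
  p <- params
  geom <- model_geometry(morph, p)
  n <- nrow(morph$compartments)
  pl <- unclass(p); pl$h_avg <- h_avg
  ctx <- build_context(geom, pl)
  d_ca <- if (couple) p$d_ca else 0
  d_ip3 <- if (couple) p$d_ip3 else 0
  # resting (c, i) of the reduced model: same fixed point as the detailed one
  y0 <- rep(c(p$ca_i0, p$ip3_0, 0, 0), n)
  names(y0) <- as.vector(vapply(seq_len(n), function(j)
    paste0(c("c", "i", "glu", "da"), ".", j), character(4)))
  glu0 <- da0 <- numeric(n)
  ev <- NULL
  if (mode == "mean") {
    for (tr in protocol$trains) {
      mean_conc <- if (tr$transmitter == "glutamate")
        p$rho_glu * tr$rate / p$g_glu_decay else p$rho_da * tr$rate / p$g_da_decay
      if (tr$transmitter == "glutamate") glu0[tr$targets] <- glu0[tr$targets] + mean_conc
      else da0[tr$targets] <- da0[tr$targets] + mean_conc
    }
  } else {
    rows <- lapply(protocol$trains, function(tr) {
      if (!length(tr$times)) return(NULL)
      var0 <- if (tr$transmitter == "glutamate") 3L else 4L
      rho <- if (tr$transmitter == "glutamate") p$rho_glu else p$rho_da
      ex <- expand.grid(target = tr$targets, time = tr$times)
      data.frame(var = (ex$target - 1L) * 4L + var0, time = ex$time,
                 value = rho, method = "add")
    })
    ev <- do.call(rbind, rows)
    if (!is.null(ev)) ev <- ev[order(ev$time, ev$var), ]
  }
  use_mean <- mode == "mean"
  times <- seq(0, protocol$duration, by = dt_out)
  sol <- deSolve::lsoda(
    y0, times,
    function(t, y, parms)
      list(rhs_simplified_chain(t, y, parms, use_mean, glu0, da0, d_ca, d_ip3)),
    parms = ctx, rtol = 1e-8, atol = 1e-10, maxsteps = 50000,
    events = if (!is.null(ev)) list(data = ev) else NULL)
  if (attr(sol, "istate")[1] < 0)
    stop("solver failure in simplified simulation")
  y <- unname(sol[, -1, drop = FALSE])
  colnames(y) <- names(y0)
  structure(list(times = sol[, 1], y = y, morph = morph, protocol = protocol),
            class = "astro_timeseries")
}

#' Export nullclines and equilibria as CSV
#'
#' @param drive numeric `c(g, d)`.
#' @param geom a [compartment_geometry()].
#' @param params an `astro_parameters` object.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
export_phase_plane <- function(drive, geom, params = default_parameters(),
                               dir = ".", prefix = "phase") {
  nc <- nullclines(drive, geom, params)
  eq <- find_equilibria(drive, geom, params)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("c_nullcline", "i_nullcline",
                                   "equilibria"), ".csv"))
  utils::write.csv(nc$c_nullcline, paths[1], row.names = FALSE)
  utils::write.csv(nc$i_nullcline, paths[2], row.names = FALSE)
  utils::write.csv(eq, paths[3], row.names = FALSE)
  invisible(paths)
}
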