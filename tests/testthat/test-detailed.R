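test_that("derived resting parameters close every balance exactly", {
  p <- default_p()
  # resting potential sits at the NCX reversal potential
  e_na <- p$rtf * log(p$na_e0 / p$na_i0)
  e_ca <- p$rtf / 2 * log(p$ca_e0 / p$ca_i0)
  expect_equal(p$v0, 3 * e_na - 2 * e_ca)
  st <- rest_state_matrix(soma_only(), p)[1, ]
  fl <- compute_fluxes(st, p)
  expect_equal(fl$j_ncx, 0, tolerance = 1e-18)
  expect_equal(fl$j_ip3r - fl$j_serca + fl$j_caerl, 0, tolerance = 1e-18)
  expect_equal(3 * fl$j_glut - 3 * fl$j_nka - 3 * fl$j_ncx - fl$j_nal, 0,
               tolerance = 1e-15)
  expect_equal(-fl$j_glut + 2 * fl$j_nka - fl$j_kl, 0, tolerance = 1e-15)
  expect_error(default_parameters(nonsense = 1), "unknown parameter")
})

test_that("fluxes vanish without their agonist and IP3-3K rises with Ca", {
  p <- default_p()
  st <- rest_state_matrix(soma_only(), p)[1, ]
  fl <- compute_fluxes(st, p)
  expect_identical(fl$s_plcb_glu, 0)
  expect_identical(fl$s_plcb_da, 0)
  expect_identical(fl$j_glut, 0)
  st2 <- st; st2["glu"] <- 1
  fl2 <- compute_fluxes(st2, p)
  expect_gt(fl2$s_plcb_glu, 0)
  expect_gt(fl2$j_glut, 0)
  st3 <- st; st3["da"] <- 1
  expect_gt(compute_fluxes(st3, p)$s_plcb_da, 0)
  # Ca-dependent IP3 degradation
  st4 <- st; st4["ca_i"] <- 0.8
  expect_gt(compute_fluxes(st4, p)$d_ip3_3k, fl$d_ip3_3k)
})

test_that("compiled and reference right-hand sides agree", {
  p <- default_p()
  for (kind in c("unipolar", "bifurcated_terminal")) {
    m <- build_morphology(kind)
    geom <- model_geometry(m, p)
    ctx <- build_context(geom, p)
    y <- as.vector(t(rest_state_matrix(m, p)))
    set.seed(11)
    for (rep in 1:5) {
      y2 <- y * exp(rnorm(length(y), 0, 0.08))
      d_r <- rhs_detailed(0, y2, m, p, geom)
      d_c <- rhs_compiled(0, y2, ctx)
      expect_equal(d_c, d_r, tolerance = 1e-10)
    }
  }
})

test_that("sodium and potassium changes are equal and opposite", {
  p <- default_p()
  m <- soma_only()
  y <- as.vector(t(rest_state_matrix(m, p)))
  set.seed(3)
  for (rep in 1:10) {
    y2 <- y * exp(rnorm(length(y), 0, 0.1))
    d <- rhs_detailed(0, y2, m, p)
    expect_equal(d[6], -d[7], tolerance = 1e-12)  # na_i vs na_e
    expect_equal(d[8], -d[9], tolerance = 1e-12)  # k_i vs k_e
  }
})

test_that("diffusion conserves the volume-weighted total of each species", {
  p <- default_p()
  m <- build_morphology("bifurcated_terminal")
  g <- model_geometry(m, p)
  gs <- rowSums(g$G)
  set.seed(5)
  for (rep in 1:10) {
    x <- runif(nrow(m$compartments), 0, 3)
    flux <- as.vector(g$G %*% x) - gs * x
    expect_equal(sum(g$vol * flux), 0, tolerance = 1e-12 * sum(g$vol))
  }
})

test_that("an isolated compartment conserves total Ca, Na and K over 100 s", {
  p <- default_p()
  m <- soma_only()
  g <- model_geometry(m, p)
  init <- rest_state_matrix(m, p)
  init[1, "ca_i"] <- 0.4   # perturb so fluxes are active
  init[1, "ip3"] <- 0.5
  pr <- make_protocol(m, nu_g = 0, nu_d = 0, seed = 1)
  ts <- simulate_detailed(m, pr, p, dt_out = 0.5, init = init,
                          rtol = 1e-8)
  ca_tot <- ts$y[, "ca_i.1"] + ts$y[, "ca_e.1"] + g$rer[1] * ts$y[, "ca_er.1"]
  na_tot <- ts$y[, "na_i.1"] + ts$y[, "na_e.1"]
  k_tot <- ts$y[, "k_i.1"] + ts$y[, "k_e.1"]
  expect_lt(diff(range(ca_tot)), 1e-6 * ca_tot[1])
  expect_lt(diff(range(na_tot)), 1e-6 * na_tot[1])
  expect_lt(diff(range(k_tot)), 1e-6 * k_tot[1])
  # h stays within [0, 1] along the trajectory
  expect_true(all(ts$y[, "h.1"] >= 0 & ts$y[, "h.1"] <= 1))
})

test_that("the relaxed rest state is stationary and self-consistent", {
  p <- default_p()
  m <- build_morphology("unipolar")
  rs <- find_rest_state(m, p)
  expect_lt(attr(rs, "residual"), 1e-9)
  expect_true(all(rs[, "glu"] == 0 & rs[, "da"] == 0))
  # h equals Q2/(Q2 + ca) at rest
  q2 <- p$d2 * (rs[, "ip3"] + p$d1) / (rs[, "ip3"] + p$d3)
  expect_equal(unname(rs[, "h"]), unname(q2 / (q2 + rs[, "ca_i"])),
               tolerance = 1e-9)
})

test_that("transmitter release jumps and decay follow the shot-noise model", {
  p <- default_p()
  st <- rest_state_matrix(soma_only(), p)[1, ]
  st2 <- apply_release(st, "glutamate", p)
  expect_equal(unname(st2["glu"]), 0.5)
  expect_equal(st2[names(st2) != "glu"], st[names(st) != "glu"])
  st3 <- st; st3["da"] <- 1
  expect_equal(unname(apply_release(st3, "dopamine", p)["da"]), 4)
  expect_error(apply_release(st, "gaba"), "arg")
  # between events the concentration decays exponentially at rate G_Glu
  m <- soma_only()
  init <- rest_state_matrix(m, p); init[1, "glu"] <- 0.5
  pr <- make_protocol(m, nu_g = 0, nu_d = 0, seed = 1, duration = 0.1)
  ts <- simulate_detailed(m, pr, p, dt_out = 0.005, init = init, rtol = 1e-8)
  expect_equal(unname(ts$y[, "glu.1"]),
               0.5 * exp(-p$g_glu_decay * ts$times), tolerance = 1e-4)
})

test_that("rest-state re-integration stays at rest in every compartment", {
  p <- default_p()
  m <- build_morphology("unipolar")
  pr <- make_protocol(m, nu_g = 0, nu_d = 0, seed = 1)
  ts <- simulate_detailed(m, pr, p, dt_out = 1)
  ca <- get_traces(ts, "ca_i")
  drift <- apply(ca, 2, function(x) max(abs(x - x[1])))
  expect_true(all(drift < 1e-3))
})

test_that("the reduced model's gate average lies in the detailed h band", {
  # during distal activity the detailed gate h averages well below its
  # resting value; the reduction's constant h_avg must sit in that band
  p <- default_p()
  m <- build_morphology("unipolar")
  pr <- make_protocol(m, nu_g = 5, nu_d = 0, seed = 1)
  ts <- suppressWarnings(simulate_detailed(m, pr, p, dt_out = 0.1))
  h <- get_traces(ts, "h")
  band <- range(colMeans(h[ts$times > 40, 7:9]))
  expect_lt(band[1], p$h0)
  expect_gt(p$h_avg, band[1] - 0.1)
  expect_lt(p$h_avg, band[2] + 0.1)
})
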