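test_that("the reduced squid model keeps a single stable-focus rest near the nullcline minimum", {
  pm <- reduced_hh()
  eqs <- find_equilibria(pm, 0)
  expect_length(eqs, 1)
  expect_identical(eqs[[1]]$classification, "stable focus")
  ## the rest sits near the minimum (in n) of the N-shaped branch
  knee <- find_fold_candidate(pm, 0)
  expect_lt(abs(eqs[[1]]$location[2] - knee$location[2]), 0.1)
})

test_that("the calcium model's reduction has the hourglass portrait with three equilibria", {
  pm <- reduced_hh_ca()
  eqs <- find_equilibria(pm, 0)
  expect_length(eqs, 3)
  cls <- vapply(eqs, `[[`, "", "classification")
  expect_identical(cls[1], "stable node")
  expect_identical(cls[2], "saddle")
  expect_match(cls[3], "^unstable")
  expect_identical(nullcline_topology(pm, 0)$topology, "hourglass")
})

test_that("static gate relations fit and evaluate as specified", {
  d_rel <- hourglass:::static_power(1.5, 3)
  expect_equal(d_rel(0), 0)
  expect_equal(d_rel(1), 1)            # 1.5 clipped to the gate range
  expect_equal(d_rel(1, smooth = TRUE), 1.5)
  expect_equal(d_rel(0.5), 1.5 * 0.125)
  ## self-consistency: a trace generated exactly by d = c n^p returns
  ## (c, p) to three significant figures
  n <- seq(0.05, 0.65, length.out = 400)
  fake <- data.frame(t = seq_along(n), n = n, d = 1.37 * n^2.6)
  fit <- fit_static_gate(fake, "n", "d", "power_law")
  expect_equal(unname(fit$coefficients["c"]), 1.37, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients["p"]), 2.6, tolerance = 1e-3)
  ## degenerate trace errors
  flat <- data.frame(t = 1:50, n = rep(0.3, 50), d = rep(0.1, 50))
  expect_error(fit_static_gate(flat, "n", "d", "power_law"),
               "degenerate")
  ## the frozen linear h(n) relation is close to a fresh least-squares
  ## fit over a spiking trajectory
  tr <- trace_hh()
  win <- c(40, 79)
  fit_h <- fit_static_gate(tr, "n", "h", "linear", window = win)
  frozen <- hourglass_fixture_constants$h_of_n
  expect_equal(unname(fit_h$coefficients["a"]), unname(frozen["a"]),
               tolerance = 0.05)
  expect_equal(unname(fit_h$coefficients["b"]), unname(frozen["b"]),
               tolerance = 0.05)
})

test_that("the total ionic current is monotone in n only without calcium", {
  pm0 <- reduced_hh(); pm1 <- reduced_hh_ca()
  p0 <- ionic_current_profile(pm0, V = 0)
  p1 <- ionic_current_profile(pm1, V = 0)
  ## no calcium: monotone increase (at most one nullcline branch)
  expect_identical(p0$sign_changes, 0L)
  ## with calcium the profile dips: a decreasing mid-range segment
  ## (excitatory recovery) between increasing ends. A microscopic
  ## initial rise from the sodium-inactivation slope precedes the dip,
  ## so the grid count is 2, with the first change confined below
  ## n = 0.05.
  expect_gte(p1$sign_changes, 1L)
  d1 <- diff(p1$profile$i_total)
  n_mid <- p1$profile$n[-1]
  expect_true(all(d1[n_mid > 0.1 & n_mid < 0.5] < 0))
  expect_true(all(d1[n_mid > 0.7 & n_mid < 0.87] > 0))
  expect_true(all(abs(d1[n_mid < 0.05]) < 0.01 * max(abs(d1))))
  ## with g_Ca = 0 the profile equals the no-calcium profile pointwise
  pz <- ionic_current_profile(reduce_hh(build_hh_ca(0, 0)), V = 0)
  expect_equal(pz$profile$i_total, p0$profile$i_total)
})

test_that("n-root counts obey the monotonicity dichotomy on a dense V grid", {
  pm0 <- reduced_hh(); pm1 <- reduced_hh_ca()
  ng <- seq(0, 1, length.out = 800)
  for (V in seq(-10, 60, by = 5)) {
    r0 <- sum(diff(sign(pm0$f(V, ng, 0))) != 0)
    r1 <- sum(diff(sign(pm1$f(V, ng, 0))) != 0)
    expect_lte(r0, 1)
    expect_lte(r1, 2)
  }
})

test_that("planar equilibria lift to near-balanced full-model states", {
  pm <- reduced_hh_ca()
  m <- build_hh_ca(3, -15.6)
  hr <- hourglass_fixture_constants$h_of_n
  peak <- 0
  ## scale: peak ionic current magnitude along the canonical trace
  tr <- trace_hh_ca()
  for (i in seq(1, nrow(tr), by = 40)) {
    gv <- as.list(tr[i, c("m", "h", "n", "d")])
    peak <- max(peak, abs(hourglass:::model_ionic_current(m, tr$v[i], gv)))
  }
  for (e in find_equilibria(pm, 0)) {
    V <- e$location[1]; n <- e$location[2]
    gv <- list(m = hourglass:::hh_m_inf(V),
               h = hourglass:::clip01(hr[1] + hr[2] * n), n = n,
               d = hourglass:::clip01(1.5 * n^3))
    resid <- -hourglass:::model_ionic_current(m, V, gv) + m$pump_current
    expect_lt(abs(resid), 0.05 * peak)
  }
})

test_that("the timescale knob rescales the slow flow without moving the geometry", {
  m <- build_hh_ca(3, -15.6)
  pm1 <- reduce_hh(m, eps = 1)
  pm2 <- reduce_hh(m, eps = 0.25)
  e1 <- find_equilibria(pm1, 0); e2 <- find_equilibria(pm2, 0)
  expect_equal(lapply(e1, `[[`, "location"),
               lapply(e2, `[[`, "location"), tolerance = 1e-8)
  expect_equal(pm2$eps * pm2$g(10, 0.4), 0.25 * pm1$g(10, 0.4))
  nt1 <- nullcline_topology(pm1, 0); nt2 <- nullcline_topology(pm2, 0)
  expect_identical(nt1$topology, nt2$topology)
})

test_that("the reduced TC portrait gains a hyperpolarized lower branch only when deinactivated", {
  m <- build_tc_complete()
  pm_burst <- reduce_tc(m, h_T = 0.59)
  pm_tonic <- reduce_tc(m, h_T = 0.012)
  ## deinactivated: the rest lies far hyperpolarized on a branch that
  ## extends below -80 mV
  eqs_b <- find_equilibria(pm_burst, -0.6)
  rest_b <- eqs_b[[1]]
  expect_lt(rest_b$location[1], -78)
  expect_match(rest_b$classification, "^stable")
  nc <- compute_nullclines(pm_burst, -0.6)
  on_branch <- vapply(nc$v_nullcline, function(b)
    min(sqrt((b$points[, 1] - rest_b$location[1])^2 +
             1e4 * (b$points[, 2] - rest_b$location[2])^2)) < 1,
    logical(1))
  expect_true(any(on_branch))
  ## inactivated: no equilibrium below -70 mV; the rest is depolarized
  eqs_t <- find_equilibria(pm_tonic, 0.2)
  expect_true(all(vapply(eqs_t, function(e) e$location[1], 1) > -70))
})

test_that("reduction errors stay within one spike on matched steps", {
  ## calcium-augmented squid model, 45 ms step at +10 uA/cm^2
  prot <- step_protocol(0, 10, 20, 45)
  full <- simulate(build_hh_ca(3, -15.6, applied_current = prot),
                   t_max = 80)
  pm <- reduced_hh_ca()
  rs <- resting_state(build_hh_ca(3, -15.6), 0)[[1]]
  red <- simulate_planar(pm, initial = c(v = rs[["v"]], n = rs[["n"]]),
                         t_max = 80, I = prot)
  n_full <- count_spikes(full, 50, c(20, 65))
  n_red <- count_spikes(red, 50, c(20, 65))
  expect_lte(abs(n_full - n_red), 1)
})
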