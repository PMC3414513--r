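test_that("the squid model has a unique resting state, a stable focus, matching a bisection oracle", {
  m <- build_hh()
  rs <- resting_state(m, 0, V_range = c(-50, 50))
  expect_length(rs, 1)
  ## independent bisection oracle on the steady-state current written
  ## out from the conductance equations
  iss <- function(V) {
    m_ <- hourglass:::hh_m_inf(V); h_ <- hourglass:::hh_h_inf(V)
    n_ <- hourglass:::hh_n_inf(V)
    -(120 * m_^3 * h_ * (V - 120) + 36 * n_^4 * (V + 12) +
        0.3 * (V - 10.6))
  }
  v_oracle <- uniroot(iss, c(-50, 50), tol = 1e-12)$root
  expect_lt(abs(rs[[1]][["v"]] - v_oracle), 1e-6)
  ## full-state Jacobian: complex leading eigenvalues with negative
  ## real part (damped subthreshold oscillation)
  rhs <- hourglass:::model_rhs(m)
  J <- hourglass:::num_jac(function(y) unlist(rhs(0, y, NULL)),
                           unname(rs[[1]]), h = 1e-6)
  ev <- eigen(J)$values
  expect_true(all(Re(ev) < 0))
  expect_true(any(abs(Im(ev)) > 1e-6))
})

test_that("gate derivatives vanish at the resting state", {
  m <- build_hh()
  rs <- resting_state(m, 0)[[1]]
  rhs <- hourglass:::model_rhs(m)
  d <- unlist(rhs(0, unname(rs), NULL))
  expect_true(all(abs(d) < 1e-8))
})

test_that("a zero-conductance calcium current leaves the vector field unchanged", {
  m0 <- build_hh(); m1 <- build_hh_ca(0, 0)
  rhs0 <- hourglass:::model_rhs(m0); rhs1 <- hourglass:::model_rhs(m1)
  set.seed(42)
  for (i in 1:25) {
    V <- runif(1, -40, 110); g <- runif(4)
    d0 <- unlist(rhs0(0, c(V, g[1:3]), NULL))
    d1 <- unlist(rhs1(0, c(V, g), NULL))
    expect_equal(d1[1:4], d0, tolerance = 0)
  }
  expect_error(build_hh_ca(-1, 0), "non-negative")
})

test_that("ohmic currents vanish at their reversal potential and respect its sign", {
  m <- build_hh_ca(3, -15.6)
  set.seed(7)
  for (cc in m$currents) {
    gv <- setNames(as.list(runif(length(m$gating))), names(m$gating))
    expect_equal(hourglass:::model_ionic_current(
      hourglass:::membrane_model("one", 1, list(cc), m$gating),
      cc$E_rev, gv), 0)
    for (dV in c(-30, 30)) {
      i1 <- hourglass:::model_ionic_current(
        hourglass:::membrane_model("one", 1, list(cc), m$gating),
        cc$E_rev + dV, gv)
      expect_true(sign(i1) %in% c(0, sign(dV)))
    }
  }
})

test_that("simulated gates stay bounded and rest is attracting", {
  tr <- trace_hh_ca()
  for (nm in c("m", "h", "n", "d"))
    expect_true(all(tr[[nm]] >= -1e-9 & tr[[nm]] <= 1 + 1e-9))
  ## long unstimulated run returns to within 0.1 mV of rest
  m <- build_hh_ca(3, -15.6)
  rs <- resting_state(m, 0)[[1]]
  start <- rs; start[["v"]] <- start[["v"]] + 3
  tr2 <- simulate(m, initial = start, t_max = 1000, dt = 0.5)
  expect_lt(max(abs(tr2$v[tr2$t > 500] - rs[["v"]])), 0.1)
})

test_that("halving solver tolerances barely moves the endpoint", {
  m <- build_hh(step_protocol(0, 10, 10, 80))
  t1 <- simulate(m, t_max = 100, rtol = 1e-8, atol = 1e-8)
  t2 <- simulate(m, t_max = 100, rtol = 5e-9, atol = 5e-9)
  expect_lt(abs(tail(t1$v, 1) - tail(t2$v, 1)), 0.01)
})

test_that("initial gate values outside [0,1] are rejected", {
  m <- build_hh()
  expect_error(simulate(m, initial = c(v = 0, m = 1.2, h = 0.5, n = 0.3)),
               "\\[0, 1\\]")
})

test_that("the TC model fires tonically when depolarized and bursts when hyperpolarized", {
  tb <- trace_tc_burst()
  tt <- trace_tc_tonic()
  sb <- hourglass:::upcross_times(tb$t, tb$v, -20, min_sep = 2)
  st <- hourglass:::upcross_times(tt$t, tt$v, -20, min_sep = 2)
  ## burst: delayed, high-frequency, confined to the early step
  expect_gt(sb[1] - 50, 10)
  expect_lt(median(diff(sb)), 6)
  expect_lt(max(sb), 150)
  ## burst ends in an afterdepolarization
  rep_b <- signature_report(tb, threshold = 0, margin_frac = 0.07)
  expect_true(rep_b$adp)
  expect_true(rep_b$plateau)
  ## tonic: regular spiking throughout the step, no plateau
  expect_gt(length(st), 4)
  expect_gt(median(diff(st)), 15)
  ipi <- diff(st)
  expect_lt(max(abs(ipi - median(ipi))), 0.35 * median(ipi))
  rep_t <- signature_report(tt, threshold = 0)
  expect_false(rep_t$plateau)
  expect_false(rep_t$adp)
})

test_that("without the T-current, holding history no longer matters", {
  mk <- function(holding, amp) {
    m <- build_tc_complete(step_protocol(holding, amp, 50, 200))
    m$currents[[3]]$gbar <- 0
    m
  }
  ## same final current level reached from both holdings
  t_dep <- simulate(mk(0.2, 1.4), t_max = 300)
  t_hyp <- simulate(mk(-0.6, 2.2), t_max = 300)
  n_dep <- count_spikes(t_dep, -20, c(50, 250))
  n_hyp <- count_spikes(t_hyp, -20, c(50, 250))
  expect_lte(abs(n_dep - n_hyp), 1)
})
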