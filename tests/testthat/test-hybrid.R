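test_that("the rest point of the continuous dynamics is invariant", {
  for (w0 in c(0.2, -0.2)) {
    hm <- build_transcritical(w0, applied_current = -0.5)
    tr <- simulate_hybrid(hm, t_max = 100)
    expect_length(attr(tr, "spike_times"), 0)
    expect_lt(diff(range(tr$v)), 1e-6)
    expect_lt(diff(range(tr$w)), 1e-6)
  }
  hm <- build_fold(applied_current = -0.5)
  tr <- simulate_hybrid(hm, t_max = 100)
  expect_lt(diff(range(tr$v)), 1e-6)
})

test_that("the sign of the recovery offset selects the firing mode", {
  th <- trace_hybrid_high(); tl <- trace_hybrid_low()
  rep_h <- signature_report(th); rep_l <- signature_report(tl)
  expect_identical(rep_h$classification, "burst_with_signature")
  expect_identical(rep_l$classification, "tonic")
  expect_false(rep_l$adp)
  ## the high-calcium rest is more hyperpolarized, as in recordings
  expect_lt(resting_voltage(th), resting_voltage(tl))
  ## latency contrast exceeds a factor of two
  expect_gt(rep_h$latency, 2 * rep_l$latency)
  ## low-calcium mode: the repolarization descends monotonically and
  ## never rebounds above the final rest (no ADP hump); the slow
  ## adaptation tail may recover toward rest from below
  post <- tl[tl$t > 502, ]
  imin <- which.min(post$v)
  expect_true(all(diff(post$v[1:imin]) < 1e-9))
  final <- tail(post$v, 1)
  expect_lt(max(post$v[imin:nrow(post)]), final + 1e-6)
})

test_that("the low-calcium interspike depolarization follows the adaptation decay", {
  tl <- trace_hybrid_low()
  st <- attr(tl, "spike_times")
  seg <- tl[tl$t > st[2] + 20 & tl$t < st[3] - 1, ]
  expect_true(all(diff(seg$v) > -1e-9))   # slow depolarization
  expect_true(all(diff(seg$z) < 1e-12))   # driven by z decay
})

test_that("reset events are the spikes and respect the threshold", {
  th <- trace_hybrid_high()
  p <- build_tc_hybrid("high_ca")$params
  expect_true(all(th$v <= p$v_threshold + 1e-6))
  expect_identical(detect_spikes(th), attr(th, "spike_times"))
  expect_true(all(diff(attr(th, "spike_times")) > 0))
})

test_that("the burst terminates through adaptation growth while stimulation is on", {
  th <- trace_hybrid_high()
  st <- attr(th, "spike_times")
  expect_gt(length(st), 3)
  expect_lt(max(st), 500)         # burst ends before the step does
  z_first <- th$z[which.min(abs(th$t - st[1]))]
  z_last <- th$z[which.min(abs(th$t - st[length(st)]))]
  expect_gt(z_last, z_first + 2 * build_tc_hybrid("high_ca")$params$d_z)
})

test_that("event times converge when the solver tolerance is halved", {
  hm <- build_tc_hybrid("high_ca", 100, 400)
  t1 <- simulate_hybrid(hm, t_max = 300, rtol = 1e-10, atol = 1e-10)
  t2 <- simulate_hybrid(hm, t_max = 300, rtol = 5e-11, atol = 5e-11)
  s1 <- attr(t1, "spike_times"); s2 <- attr(t2, "spike_times")
  expect_identical(length(s1), length(s2))
  expect_lt(max(abs(s1 - s2)), 1e-5)
})

test_that("the Zeno guard aborts pathological reset loops", {
  hm <- build_transcritical(0.2, params = list(v_reset = 1.99),
                            applied_current = 5)
  expect_error(simulate_hybrid(hm, initial = c(v = 0, w = 0, z = 0),
                               t_max = 100, max_events = 10),
               "Zeno")
})

test_that("the fold baseline spikes tonically under sustained drive", {
  hm <- build_fold(params = list(d_z = 0, d_w = 0.05, eps = 0.05),
                   applied_current = step_protocol(-0.5, 0.7, 20, 200))
  tr <- simulate_hybrid(hm, t_max = 250)
  st <- attr(tr, "spike_times")
  expect_gt(length(st), 5)
  ipi <- diff(st[st > 50])
  expect_lt(max(abs(ipi - median(ipi))), 0.2 * median(ipi))
})

test_that("the calcium modes differ only in the recovery offset", {
  lo <- build_tc_hybrid("low_ca"); hi <- build_tc_hybrid("high_ca")
  p1 <- lo$params; p2 <- hi$params
  expect_identical(names(p1), names(p2))
  same <- setdiff(names(p1), "w0")
  expect_identical(p1[same], p2[same])
  expect_identical(p1$w0, -p2$w0)
  ## removing the adaptation coupling reduces the model to the plain
  ## transcritical dynamics under constant drive
  lo0 <- build_tc_hybrid("low_ca", params = list(d_z = 0))
  plain <- build_transcritical(lo0$params$w0)
  for (s in list(c(-0.5, 0.1, 0), c(0.3, -0.2, 0))) {
    expect_identical(lo0$f(s[1], s[2], s[3], 0.0625),
                     plain$f(s[1], s[2], s[3], 0.0625))
  }
})

test_that("zero-amplitude pulses never add spikes", {
  hm <- build_tc_hybrid("high_ca", 100, 400)
  r <- pulse_robustness(hm, c(150, 250, 350), amplitude = 0, width = 2,
                        t_max = 600)
  expect_identical(r$extra_spikes, 0L)
  expect_true(all(r$per_pulse == "absorbed"))
})

test_that("the afterdepolarization rides an attractor in the transcritical model but not in the fold model", {
  ## reset-point perturbation of +-10 percent: the transcritical ADP apex
  ## barely moves (the lower-branch attractor sets it); the fold ADP is
  ## reset-made and moves an order of magnitude more
  apex_amp <- function(tr) {
    rep_ <- signature_report(tr)
    expect_true(rep_$adp)
    rep_$adp_amplitude
  }
  base_t <- apex_amp(trace_hybrid_high())
  pp <- hybrid_defaults("fold")
  mk_fold <- function(extra = list()) {
    p <- modifyList(list(), extra)
    hybrid_model("fold", p,
                 step_protocol(pp$I_off, pp$I_on - pp$I_off, 100, 400))
  }
  base_f <- apex_amp(simulate_hybrid(mk_fold(), t_max = 600))
  rel_t <- rel_f <- numeric(0)
  for (s in c(0.9, 1.1)) {
    ht <- build_tc_hybrid("high_ca", 100, 400,
                          params = list(v_reset = -0.1 * s,
                                        d_w = 0.2 * s))
    at <- apex_amp(simulate_hybrid(ht, t_max = 700))
    rel_t <- c(rel_t, abs(at - base_t) / base_t)
    af <- apex_amp(simulate_hybrid(
      mk_fold(list(v_reset = pp$v_reset * s, d_w = pp$d_w * s)),
      t_max = 600))
    rel_f <- c(rel_f, abs(af - base_f) / base_f)
  }
  expect_lt(max(rel_t), 0.05)
  expect_gt(min(rel_f), 3 * max(rel_t))
})
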