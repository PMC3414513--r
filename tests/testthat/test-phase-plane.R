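test_that("nullclines and equilibria of a linear system match the closed form", {
  pm <- toy_linear()
  nc <- compute_nullclines(pm, 0)
  expect_length(nc$v_nullcline, 1)
  expect_length(nc$n_nullcline, 1)
  ## f = -V + n: the branch is the line n = V
  pts <- nc$v_nullcline[[1]]$points
  expect_lt(max(abs(pts[, 2] - pts[, 1])), 1e-6)
  eqs <- find_equilibria(pm, 0)
  expect_length(eqs, 1)
  expect_lt(max(abs(eqs[[1]]$location)), 1e-8)
  expect_identical(eqs[[1]]$classification, "stable focus")
})

test_that("polished nullcline points satisfy the defining equation", {
  pm <- reduced_hh_ca()
  nc <- compute_nullclines(pm, 0)
  for (b in nc$v_nullcline) {
    res <- abs(pm$f(b$points[, 1], b$points[, 2], 0))
    expect_lt(stats::quantile(res, 0.99), 1e-8)
  }
})

test_that("nullcline topology tracks the applied current", {
  pm <- reduced_hh_ca()
  expect_identical(nullcline_topology(pm, 0)$topology, "hourglass")
  expect_identical(nullcline_topology(pm, 10)$topology, "two_branch")
  expect_identical(nullcline_topology(reduced_hh(), 0)$topology,
                   "single_branch")
})

test_that("equilibria match an independent one-dimensional root oracle", {
  ## at an equilibrium n = n_inf(V) and the steady-state current
  ## vanishes: scan V, solve the scalar problem, compare locations
  for (I in c(0, 5)) {
    pm <- reduced_hh_ca()
    n_inf <- function(V) hourglass:::hh_n_inf(V)
    fV <- function(V) pm$f(V, n_inf(V), I)
    Vg <- seq(-50, 119.9, length.out = 8000)
    y <- fV(Vg)
    idx <- which(diff(sign(y)) != 0)
    oracle <- vapply(idx, function(i)
      uniroot(fV, c(Vg[i], Vg[i + 1]), tol = 1e-12)$root, numeric(1))
    found <- vapply(find_equilibria(pm, I), function(e) e$location[1],
                    numeric(1))
    expect_equal(sort(found), sort(oracle), tolerance = 1e-6)
  }
})

test_that("with three equilibria the middle one is the saddle", {
  eqs <- find_equilibria(reduced_hh_ca(), 0)
  expect_length(eqs, 3)
  cls <- vapply(eqs, `[[`, "", "classification")
  expect_identical(cls[2], "saddle")
})

test_that("saddle manifolds obey the flow and funnel relaxation", {
  pm <- reduced_hh_ca()
  eqs <- find_equilibria(pm, 0)
  sad <- Filter(function(e) e$classification == "saddle", eqs)[[1]]
  man <- saddle_manifolds(pm, 0, sad)
  ## both unstable branches terminate at the resting node below the
  ## homoclinic current
  node <- eqs[[1]]$location
  for (b in man$unstable) {
    endp <- b[nrow(b), ]
    expect_lt(abs(endp[1] - node[1]), 0.5)
    expect_lt(abs(endp[2] - node[2]), 0.01)
  }
  ## flow property: re-integrating from a mid-manifold point stays on
  ## the polyline
  b <- man$unstable[[1]]
  i0 <- nrow(b) %/% 3
  tr <- simulate_planar(pm, initial = c(v = b[i0, 1], n = b[i0, 2]),
                        t_max = 5, dt = 0.01, I = 0)
  s <- hourglass:::box_scale(pm$box)
  for (k in seq(1, nrow(tr), by = 50)) {
    d <- min(sqrt(((tr$v[k] - b[, 1]) / s[1])^2 +
                  ((tr$n[k] - b[, 2]) / s[2])^2))
    expect_lt(d, 1e-3)
  }
  ## a non-saddle input is refused
  expect_error(saddle_manifolds(pm, 0, eqs[[1]]), "not a saddle")
})

test_that("the toy X-field has its transcritical point at the origin", {
  pm <- toy_transcritical()
  tc <- detect_transcritical(pm, c(-0.5, 0.5), extend = 0.2, n_starts = 5)
  expect_lt(max(abs(tc$location)), 1e-6)
  expect_lt(abs(tc$critical_current), 1e-6)
  q <- tc$quadratic_coefficients
  expect_equal(unname(q["vv"]), 1, tolerance = 1e-4)
  expect_equal(unname(q["nn"]), -1, tolerance = 1e-4)
  nf <- normal_form_coefficients(pm, tc)
  expect_identical(nf$label, "transcritical")
})

test_that("the toy fold field is labelled fold with unit coefficients", {
  pm <- toy_fold()
  fc <- find_fold_candidate(pm, 0, start = c(0.1, -0.1))
  expect_lt(max(abs(fc$location)), 1e-6)
  nf <- normal_form_coefficients(pm, fc)
  expect_identical(nf$label, "fold")
  expect_equal(unname(nf$coefficients["vv"]), 1, tolerance = 1e-4)
  expect_equal(unname(nf$coefficients["fn"]), 1, tolerance = 1e-4)
})

test_that("the calcium model's singularity is physiological, the classical one is not", {
  tc1 <- cached("tc_point_ca",
                detect_transcritical(reduced_hh_ca(), c(-30, 30)))
  expect_true(tc1$inside_box)
  expect_lt(tc1$hessian_det, 0)
  expect_identical(normal_form_coefficients(reduced_hh_ca(), tc1)$label,
                   "transcritical")
  tc0 <- cached("tc_point_hh",
                detect_transcritical(reduced_hh(), c(-30, 30)))
  expect_false(tc0$inside_box)
  expect_lt(tc0$location[2], 0)   # recovery variable below its range
  ## the classical model's physiological singular transition is a fold
  nf0 <- normal_form_coefficients(reduced_hh(),
                                  find_fold_candidate(reduced_hh(), 0))
  expect_identical(nf0$label, "fold")
})

test_that("the nullcline components pinch together as the critical current is approached", {
  pm <- reduced_hh_ca()
  tc <- cached("tc_point_ca", detect_transcritical(pm, c(-30, 30)))
  Is <- tc$critical_current - c(2, 1, 0.5, 0.25)
  gaps <- vapply(Is, function(I) nullcline_topology(pm, I)$min_gap,
                 numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 0.02)
})
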