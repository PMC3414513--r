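## One-parameter bifurcation analysis in the applied current for planar
## models: equilibrium branches with stability, fold/Hopf events, limit
## cycle extent by simulation + peak analysis, homoclinic location by
## bisection on cycle existence.

## Newton refinement of a fold: f = g = det(J) = 0 in (V, n, I)
refine_fold <- function(pm, x0) {
  s <- box_scale(pm$box)
  fn <- function(x) {
    J <- planar_jacobian(pm, x[1], x[2], x[3])
    c(pm$f(x[1], x[2], x[3]), pm$g(x[1], x[2]), det(J))
  }
  newton_solve(fn, x0, h = c(1e-6 * s, 1e-5), tol = 1e-8, maxit = 60)
}

## Newton refinement of a Hopf: f = g = tr(J) = 0 in (V, n, I)
refine_hopf <- function(pm, x0) {
  s <- box_scale(pm$box)
  fn <- function(x) {
    J <- planar_jacobian(pm, x[1], x[2], x[3])
    c(pm$f(x[1], x[2], x[3]), pm$g(x[1], x[2]), sum(diag(J)))
  }
  newton_solve(fn, x0, h = c(1e-6 * s, 1e-5), tol = 1e-8, maxit = 60)
}

#' Continuation of equilibrium branches in the applied current
#'
#' Tracks every equilibrium across a current sweep: at each step,
#' equilibria are predicted from the previous step by Newton iteration,
#' and a full nullcline-intersection scan is run periodically (and at the
#' endpoints) to pick up newly born branches. Points are linked into
#' branches by proximity. Folds are detected where two branches meet with
#' a vanishing real eigenvalue and refined by solving
#' \code{f = g = det(J) = 0}; Hopf points where a complex pair crosses
#' the imaginary axis, refined by solving \code{f = g = tr(J) = 0}.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_range current interval \code{c(lo, hi)}.
#' @param n_steps sweep resolution.
#' @param rescan_every full re-scan period (steps).
#' @param resolution nullcline grid for the full scans.
#' @return list with \code{branches} (each a data frame \code{I, V, n,
#'   re1, im1, re2, im2, stable}) and \code{events} (data frame
#'   \code{type, I, V, n}).
#' @export
continue_equilibria <- function(pm, I_range, n_steps = 161,
                                rescan_every = 10, resolution = 300) {
  stopifnot(all(is.finite(I_range)))
  s <- box_scale(pm$box)
  Is <- seq(I_range[1], I_range[2], length.out = n_steps)
  branches <- list()   # each: list(rows = list of point-rows, open = TRUE)
  live <- list()       # indices into branches of currently tracked ones
  point_row <- function(I, x) {
    J <- planar_jacobian(pm, x[1], x[2], I)
    ev <- eigen(J)$values
    data.frame(I = I, V = x[1], n = x[2],
               re1 = Re(ev[1]), im1 = Im(ev[1]),
               re2 = Re(ev[2]), im2 = Im(ev[2]),
               stable = all(Re(ev) < 0))
  }
  full_scan <- function(I) {
    eqs <- find_equilibria(pm, I, resolution = resolution)
    lapply(eqs, function(e) unname(e$location))
  }
  newton_track <- function(I, x0) {
    fn <- function(x) c(pm$f(x[1], x[2], I), pm$g(x[1], x[2]))
    r <- newton_solve(fn, x0, h = 1e-7 * s, tol = 1e-9, maxit = 40)
    if (r$converged &&
        r$x[1] >= pm$box[1] && r$x[1] <= pm$box[2] &&
        r$x[2] >= pm$box[3] && r$x[2] <= pm$box[4] &&
        sqrt(sum(((r$x - x0) / s)^2)) < 0.2) r$x else NULL
  }
  for (k in seq_along(Is)) {
    I <- Is[k]
    found <- list()
    for (bi in live) {
      last <- branches[[bi]]$rows[[length(branches[[bi]]$rows)]]
      x <- newton_track(I, c(last$V, last$n))
      if (!is.null(x)) found[[length(found) + 1]] <- list(bi = bi, x = x)
    }
    ## collapse branches that converged to the same point (fold passage)
    keep <- list()
    for (fz in found) {
      dup <- any(vapply(keep, function(kz)
        sqrt(sum(((kz$x - fz$x) / s)^2)) < 1e-5, logical(1)))
      if (!dup) keep[[length(keep) + 1]] <- fz
    }
    found <- keep
    if (k %% rescan_every == 1L || k == length(Is)) {
      for (x in full_scan(I)) {
        dup <- any(vapply(found, function(fz)
          sqrt(sum(((fz$x - x) / s)^2)) < 1e-4, logical(1)))
        if (!dup) found[[length(found) + 1]] <- list(bi = NA, x = x)
      }
    }
    new_live <- integer(0)
    for (fz in found) {
      if (is.na(fz$bi)) {
        branches[[length(branches) + 1]] <- list(rows = list())
        fz$bi <- length(branches)
      }
      branches[[fz$bi]]$rows[[length(branches[[fz$bi]]$rows) + 1]] <-
        point_row(I, fz$x)
      new_live <- c(new_live, fz$bi)
    }
    live <- new_live
  }
  branch_dfs <- lapply(branches, function(b) do.call(rbind, b$rows))
  branch_dfs <- branch_dfs[vapply(branch_dfs, nrow, 1L) >= 2]
  events <- detect_branch_events(pm, branch_dfs, s)
  list(branches = branch_dfs, events = events)
}

detect_branch_events <- function(pm, branch_dfs, s) {
  ev <- list()
  for (b in branch_dfs) {
    ## Hopf: complex pair with real part crossing zero
    cplx <- abs(b$im1) > 1e-9
    re <- b$re1
    for (i in which(diff(sign(re)) != 0 & cplx[-1] & cplx[-nrow(b)])) {
      r <- refine_hopf(pm, c(b$V[i], b$n[i], b$I[i]))
      if (r$converged) {
        J <- planar_jacobian(pm, r$x[1], r$x[2], r$x[3])
        if (det(J) > 0)
          ev[[length(ev) + 1]] <- data.frame(type = "hopf", I = r$x[3],
                                             V = r$x[1], n = r$x[2])
      }
    }
    ## fold: real eigenvalue hitting zero at a branch extremity of I
    mineig <- pmin(abs(b$re1), abs(b$re2))
    ends <- c(1L, nrow(b))
    for (i in ends) {
      near_zero <- mineig[i] < 0.5
      interior <- b$I[i] > min(b$I) + 1e-12 || b$I[i] < max(b$I) - 1e-12
      if (near_zero) {
        r <- refine_fold(pm, c(b$V[i], b$n[i], b$I[i]))
        if (r$converged)
          ev[[length(ev) + 1]] <- data.frame(type = "fold", I = r$x[3],
                                             V = r$x[1], n = r$x[2])
      }
    }
  }
  if (!length(ev)) return(data.frame(type = character(0), I = numeric(0),
                                     V = numeric(0), n = numeric(0)))
  ev <- do.call(rbind, ev)
  ## dedup events
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(ev))) {
      if (j <= i || !keep[j]) next
      if (ev$type[i] == ev$type[j] && abs(ev$I[i] - ev$I[j]) < 1e-4 &&
          sqrt(sum((c(ev$V[i] - ev$V[j], ev$n[i] - ev$n[j]) / s)^2)) < 1e-3)
        keep[j] <- FALSE
    }
  }
  ev[keep, , drop = FALSE]
}

## standardized spiking initial condition: mid-depolarized state
spiking_ic <- function(pm) {
  c(v = pm$box[1] + 0.6 * (pm$box[2] - pm$box[1]), n = 0.4)
}

## slow time constant ceiling over the box (for transient discard)
slow_tau_max <- function(pm) {
  if (is.null(pm$slow_tau)) return(10)
  Vg <- seq(pm$box[1], pm$box[2], length.out = 200)
  max(pm$slow_tau(Vg)) / max(pm$eps, 1e-12)
}

#' Detect a stable limit cycle at one current value
#'
#' Integrates from an initial condition, discards ten slow time
#' constants of transient, and accepts a periodic attractor when at
#' least five consecutive inter-peak intervals agree within 1 percent.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_app applied current.
#' @param initial starting state; default is the standardized spiking
#'   initial condition.
#' @param t_measure measurement window after transient discard (ms).
#' @param ipi_tol relative inter-peak tolerance for periodicity.
#' @return list \code{present, v_min, v_max, period, peaks,
#'   final_state}.
#' @export
limit_cycle_at <- function(pm, I_app, initial = NULL, t_measure = 400,
                           ipi_tol = 0.01) {
  if (is.null(initial)) initial <- spiking_ic(pm)
  t_trans <- 10 * slow_tau_max(pm)
  tr <- simulate_planar(pm, initial = initial,
                        t_max = t_trans + t_measure, dt = 0.02, I = I_app)
  late <- tr[tr$t >= t_trans, ]
  vr <- range(late$v)
  absent <- list(present = FALSE, v_min = NA_real_, v_max = NA_real_,
                 period = NA_real_, peaks = numeric(0),
                 final_state = c(v = tail(late$v, 1), n = tail(late$n, 1)))
  if (diff(vr) < 1) return(absent)
  thr <- mean(vr)
  pk <- local_maxima(late$v, floor = thr)
  if (length(pk) < 6) return(absent)
  tp <- late$t[pk]
  ipi <- diff(tp)
  m <- length(ipi)
  if (m < 5) return(absent)
  last5 <- tail(ipi, 5)
  if (max(abs(last5 - mean(last5))) > ipi_tol * mean(last5)) return(absent)
  cyc <- late[late$t >= tp[max(1, length(tp) - 3)], ]
  list(present = TRUE, v_min = min(cyc$v), v_max = max(cyc$v),
       period = mean(last5), peaks = tp,
       final_state = c(v = tail(late$v, 1), n = tail(late$n, 1)))
}

#' Limit-cycle extent across a current sweep
#'
#' Applies \code{\link{limit_cycle_at}} on a grid of currents, following
#' the attractor by reusing the final state of each run as the next
#' initial condition (falling back to the standardized spiking state
#' when the cycle is lost).
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_values current grid (scanned in the given order).
#' @param t_measure per-current measurement window (ms).
#' @return data frame \code{I, present, v_min, v_max, period}.
#' @export
limit_cycle_scan <- function(pm, I_values, t_measure = 400) {
  state <- NULL
  rows <- lapply(I_values, function(I) {
    lc <- limit_cycle_at(pm, I, initial = state, t_measure = t_measure)
    state <<- if (lc$present) lc$final_state else NULL
    data.frame(I = I, present = lc$present, v_min = lc$v_min,
               v_max = lc$v_max, period = lc$period)
  })
  do.call(rbind, rows)
}

#' Locate a saddle-homoclinic bifurcation by bisection
#'
#' Bisection on the existence of the stable spiking cycle between a
#' current where it is present and one where it is absent, while a
#' saddle point exists throughout. Errors when the saddle is missing at
#' either endpoint (the cycle disappearance is then not homoclinic,
#' e.g. a saddle-node of limit cycles).
#'
#' @param pm a \code{\link{planar_model}}.
#' @param bracket \code{c(I_absent, I_present)} (any order).
#' @param tol bracket width tolerance in current units.
#' @param t_measure cycle-detection window (ms); periods diverge near the
#'   connection, so this should comfortably exceed the expected period.
#' @return list with \code{I_hom} (bracket midpoint), \code{bracket},
#'   and \code{saddle_distance} (box-normalized closest approach of the
#'   cycle to the saddle just above the bifurcation).
#' @export
locate_homoclinic <- function(pm, bracket, tol = 1e-4, t_measure = 800) {
  has_saddle <- function(I) {
    eqs <- find_equilibria(pm, I, resolution = 300)
    sad <- Filter(function(e) e$classification == "saddle", eqs)
    if (length(sad)) sad[[1]] else NULL
  }
  s1 <- has_saddle(bracket[1]); s2 <- has_saddle(bracket[2])
  if (is.null(s1) || is.null(s2))
    stop("no saddle at a bracket endpoint: cycle disappearance is not ",
         "homoclinic here")
  cyc <- function(I) limit_cycle_at(pm, I, t_measure = t_measure)$present
  c1 <- cyc(bracket[1]); c2 <- cyc(bracket[2])
  if (c1 == c2) stop("bracket endpoints do not straddle cycle existence")
  lo <- bracket[1]; hi <- bracket[2]
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (cyc(mid) == c1) lo <- mid else hi <- mid
  }
  I_hom <- (lo + hi) / 2
  I_above <- if (c2) hi else lo   # side where the cycle exists
  lc <- limit_cycle_at(pm, I_above + sign(I_above - I_hom) * 5 * tol,
                       t_measure = t_measure)
  sd <- NA_real_
  sad <- has_saddle(I_above)
  if (lc$present && !is.null(sad)) {
    tr <- simulate_planar(pm, initial = spiking_ic(pm),
                          t_max = 10 * slow_tau_max(pm) + 2 * lc$period,
                          dt = 0.02, I = I_above)
    late <- tr[tr$t > 10 * slow_tau_max(pm), ]
    s <- box_scale(pm$box)
    sd <- min(sqrt(((late$v - sad$location[1]) / s[1])^2 +
                   ((late$n - sad$location[2]) / s[2])^2))
  }
  list(I_hom = I_hom, bracket = sort(c(lo, hi)), saddle_distance = sd)
}

#' Criticality of a Hopf bifurcation
#'
#' Classifies a Hopf point as sub- or supercritical. The primary method
#' evaluates the first Lyapunov coefficient of the planar field at the
#' bifurcation (third-order finite differences in eigen-coordinates,
#' Guckenheimer-Holmes normal form formula); when the coefficient is
#' below resolution the fallback simulates just past the Hopf point and
#' inspects the amplitude of the resulting attractor.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param hopf_event one row of the \code{events} table from
#'   \code{\link{continue_equilibria}} (or a list with \code{I, V, n}).
#' @param method \code{"lyapunov"}, \code{"simulation"} or
#'   \code{"auto"}.
#' @return list with \code{criticality} (\code{"subcritical"},
#'   \code{"supercritical"} or \code{"undetermined"}),
#'   \code{lyapunov_coefficient} and \code{method}.
#' @export
hopf_criticality <- function(pm, hopf_event,
                             method = c("auto", "lyapunov",
                                        "simulation")) {
  method <- match.arg(method)
  I <- hopf_event$I; x0 <- c(hopf_event$V, hopf_event$n)
  a <- NA_real_
  if (method %in% c("auto", "lyapunov")) {
    a <- first_lyapunov(pm, x0, I)
    if (is.finite(a) && abs(a) > 1e-10)
      return(list(criticality = if (a > 0) "subcritical"
                  else "supercritical",
                  lyapunov_coefficient = a, method = "lyapunov"))
    if (method == "lyapunov")
      return(list(criticality = "undetermined",
                  lyapunov_coefficient = a, method = "lyapunov"))
  }
  ## simulation fallback: step slightly past the Hopf on the unstable
  ## side and measure the attractor amplitude from a near-equilibrium
  ## start
  s <- box_scale(pm$box)
  probe <- function(I_probe) {
    eqs <- find_equilibria(pm, I_probe, resolution = 300)
    if (!length(eqs)) return(NA_real_)
    d <- vapply(eqs, function(e)
      sqrt(sum(((e$location - x0) / s)^2)), numeric(1))
    e <- eqs[[which.min(d)]]
    init <- e$location + c(0.01 * s[1], 0)
    lc <- limit_cycle_at(pm, I_probe, initial = init, t_measure = 600)
    if (!lc$present) 0 else (lc$v_max - lc$v_min) / s[1]
  }
  J <- planar_jacobian(pm, x0[1], x0[2], I)
  dI <- 1e-3 * max(1, abs(I))
  ## find the side where the equilibrium is unstable
  unstable_side <- NULL
  for (sgn in c(1, -1)) {
    eqs <- find_equilibria(pm, I + sgn * dI, resolution = 300)
    if (!length(eqs)) next
    d <- vapply(eqs, function(e)
      sqrt(sum(((e$location - x0) / s)^2)), numeric(1))
    e <- eqs[[which.min(d)]]
    if (all(Re(e$eigenvalues) > 0)) { unstable_side <- sgn; break }
  }
  if (is.null(unstable_side))
    return(list(criticality = "undetermined", lyapunov_coefficient = a,
                method = "simulation"))
  amp <- probe(I + unstable_side * 5 * dI)
  crit <- if (!is.finite(amp)) "undetermined"
          else if (amp > 0.25) "subcritical" else "supercritical"
  list(criticality = crit, lyapunov_coefficient = a,
       method = "simulation")
}

## first Lyapunov coefficient at a planar Hopf point
## (Guckenheimer & Holmes, eq. 3.4.11, in eigen-normalized coordinates)
first_lyapunov <- function(pm, x0, I) {
  J <- planar_jacobian(pm, x0[1], x0[2], I)
  detJ <- det(J)
  if (detJ <= 0) return(NA_real_)
  w <- sqrt(detJ)
  eg <- eigen(J)
  iw_idx <- which.max(Im(eg$values))
  v <- eg$vectors[, iw_idx]
  P <- cbind(Im(v), Re(v))
  if (abs(det(P)) < 1e-12) return(NA_real_)
  Pinv <- solve(P)
  s <- box_scale(pm$box)
  F2 <- function(u) {
    y <- x0 + as.numeric(P %*% u)
    as.numeric(Pinv %*% c(pm$f(y[1], y[2], I),
                          pm$eps * pm$g(y[1], y[2])))
  }
  ## scale of the eigen-coordinates
  h <- 1e-3 * mean(sqrt(colSums((P / rbind(s, s))^2)))^0 # unit step scale
  h <- 1e-3
  fu <- function(i, j) {   # second partials of both components
    (F2(c(i, j) * h))
  }
  g2 <- function(di, dj) F2(c(di, dj) * h)
  ## second derivatives
  f00 <- F2(c(0, 0))
  d2 <- list(
    uu = (g2(1, 0) - 2 * f00 + g2(-1, 0)) / h^2,
    vv = (g2(0, 1) - 2 * f00 + g2(0, -1)) / h^2,
    uv = (g2(1, 1) - g2(1, -1) - g2(-1, 1) + g2(-1, -1)) / (4 * h^2))
  ## third derivatives
  d3 <- list(
    uuu = (g2(2, 0) - 2 * g2(1, 0) + 2 * g2(-1, 0) - g2(-2, 0)) /
      (2 * h^3),
    vvv = (g2(0, 2) - 2 * g2(0, 1) + 2 * g2(0, -1) - g2(0, -2)) /
      (2 * h^3),
    uvv = ((g2(1, 1) + g2(1, -1) - 2 * g2(1, 0)) -
           (g2(-1, 1) + g2(-1, -1) - 2 * g2(-1, 0))) / (2 * h^3),
    uuv = ((g2(1, 1) + g2(-1, 1) - 2 * g2(0, 1)) -
           (g2(1, -1) + g2(-1, -1) - 2 * g2(0, -1))) / (2 * h^3))
  fx <- function(d) d[1]; gx <- function(d) d[2]
  a <- (fx(d3$uuu) + fx(d3$uvv) + gx(d3$uuv) + gx(d3$vvv)) / 16 +
    (fx(d2$uv) * (fx(d2$uu) + fx(d2$vv)) -
     gx(d2$uv) * (gx(d2$uu) + gx(d2$vv)) -
     fx(d2$uu) * gx(d2$uu) + fx(d2$vv) * gx(d2$vv)) / (16 * w)
  a
}

#' Time to first spike above a fold of equilibria
#'
#' Measures the divergence of spike latency as the current approaches
#' the fold from above (the "ghost" of the resting state): from the
#' pre-fold rest location, the time to the first voltage peak is
#' recorded for a set of current offsets.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_fold fold current.
#' @param deltas positive current offsets (scanned as
#'   \code{I_fold + deltas}).
#' @param v_spike voltage threshold defining the spike.
#' @param t_max per-run horizon (ms).
#' @return data frame \code{delta, latency}.
#' @export
latency_above_fold <- function(pm, I_fold, deltas, v_spike = 50,
                               t_max = 2000) {
  eqs <- find_equilibria(pm, I_fold - 2 * min(deltas), resolution = 300)
  if (!length(eqs)) stop("no pre-fold equilibrium found")
  stab <- Filter(function(e) grepl("stable", e$classification) &&
                   !grepl("un", e$classification), eqs)
  rest <- if (length(stab)) stab[[which.min(vapply(stab, function(e)
    e$location[1], numeric(1)))]] else eqs[[1]]
  rows <- lapply(deltas, function(d) {
    tr <- simulate_planar(pm, initial = rest$location,
                          t_max = t_max, dt = 0.05, I = I_fold + d)
    st <- upcross_times(tr$t, tr$v, v_spike)
    data.frame(delta = d,
               latency = if (length(st)) st[1] else NA_real_)
  })
  do.call(rbind, rows)
}

#' One-parameter bifurcation diagram
#'
#' Combines \code{\link{continue_equilibria}} and
#' \code{\link{limit_cycle_scan}} into a labelled diagram.
#'
#' @inheritParams continue_equilibria
#' @param n_cycle_steps resolution of the limit-cycle sweep.
#' @param classify_hopf also classify each Hopf event's criticality.
#' @return object of class \code{bifurcation_diagram}: list with
#'   \code{branches}, \code{cycles}, \code{events}.
#' @export
bifurcation_diagram <- function(pm, I_range, n_steps = 161,
                                n_cycle_steps = 41,
                                classify_hopf = TRUE) {
  ce <- continue_equilibria(pm, I_range, n_steps)
  Ic <- seq(I_range[2], I_range[1], length.out = n_cycle_steps)
  cyc <- limit_cycle_scan(pm, Ic)
  ev <- ce$events
  if (classify_hopf && nrow(ev)) {
    crit <- character(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      crit[i] <- if (ev$type[i] == "hopf")
        hopf_criticality(pm, ev[i, ])$criticality else ""
    }
    ev$criticality <- crit
    ev$type <- ifelse(ev$type == "hopf" & ev$criticality != "",
                      paste0("hopf_", substr(ev$criticality, 1, 3)),
                      ev$type)
  }
  structure(list(branches = ce$branches, cycles = cyc, events = ev),
            class = "bifurcation_diagram")
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram>", length(x$branches), "equilibrium",
      "branch(es)\n")
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("   %-10s I = %.4f at (%.2f, %.3f)\n",
                  x$events$type[i], x$events$I[i], x$events$V[i],
                  x$events$n[i]))
  }
  pr <- x$cycles[x$cycles$present, ]
  if (nrow(pr))
    cat(sprintf("  stable cycle on I in [%.3f, %.3f]\n", min(pr$I),
                max(pr$I)))
  invisible(x)
}
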