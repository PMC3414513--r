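## Phase-plane machinery for planar models: nullclines, equilibria,
## saddle manifolds, transcritical singularity, local normal forms.
## Tolerances follow the package defaults: polished nullcline residual
## 1e-8, equilibrium residual 1e-9, dedup radius 1e-5 in box-normalized
## units.

box_scale <- function(box) c(box[2] - box[1], box[4] - box[3])

## 2x2 Jacobian of (f, eps*g) at a point, central differences scaled to box
planar_jacobian <- function(pm, V, n, I, rel_h = 1e-6) {
  s <- box_scale(pm$box)
  hV <- rel_h * s[1]; hn <- rel_h * s[2]
  matrix(c((pm$f(V + hV, n, I) - pm$f(V - hV, n, I)) / (2 * hV),
           (pm$f(V, n + hn, I) - pm$f(V, n - hn, I)) / (2 * hn),
           pm$eps * (pm$g(V + hV, n) - pm$g(V - hV, n)) / (2 * hV),
           pm$eps * (pm$g(V, n + hn) - pm$g(V, n - hn)) / (2 * hn)),
         2, 2, byrow = TRUE)
}

classify_jacobian <- function(J, tol_hyp = 1e-6) {
  ev <- eigen(J)$values
  re <- Re(ev); im <- Im(ev)
  cls <- if (max(abs(re)) < tol_hyp) "non-hyperbolic"
  else if (any(abs(im) > 1e-9)) {
    if (all(re < 0)) "stable focus" else "unstable focus"
  } else if (prod(re) < 0) "saddle"
  else if (all(re < 0)) "stable node"
  else "unstable node"
  list(eigenvalues = ev, classification = cls)
}

#' Nullclines of a planar model
#'
#' Extracts all connected components of \code{\{f = 0\}} and
#' \code{\{g = 0\}} inside the physiological box by marching-squares
#' contour tracing on a fine grid, followed by one-dimensional Newton
#' polishing of every vertex (along the coordinate with the larger
#' partial derivative) to residual below \code{tol_null}. Branch labels
#' (left/right/upper/lower) are assigned from the component centroid
#' relative to the transcritical point when one is supplied, else
#' relative to the mean of all components.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_app applied current.
#' @param resolution grid points per axis.
#' @param tol_null target residual for polished points.
#' @param reference optional \code{c(V, n)} used for branch labelling.
#' @return list with \code{v_nullcline} and \code{n_nullcline}, each a
#'   list of branches \code{list(variable, branch_id, points)} where
#'   \code{points} is a two-column (V, n) matrix.
#' @export
compute_nullclines <- function(pm, I_app = 0, resolution = 400,
                               tol_null = 1e-8, reference = NULL) {
  box <- pm$box
  Vg <- seq(box[1], box[2], length.out = resolution)
  ng <- seq(box[3], box[4], length.out = resolution)
  out <- list()
  for (which in c("v", "n")) {
    fun <- if (which == "v") function(V, n) pm$f(V, n, I_app)
           else function(V, n) pm$g(V, n)
    z <- outer(Vg, ng, fun)
    cl <- grDevices::contourLines(Vg, ng, z, levels = 0)
    branches <- lapply(cl, function(b) {
      pts <- polish_nullcline(fun, b$x, b$y, box, tol_null)
      list(variable = which, points = pts)
    })
    branches <- branches[vapply(branches, function(b) nrow(b$points) > 1,
                                logical(1))]
    out[[paste0(which, "_nullcline")]] <- branches
  }
  out$v_nullcline <- label_branches(out$v_nullcline, reference)
  out
}

## vectorized 1D Newton along the steeper coordinate
polish_nullcline <- function(fun, x, y, box, tol, maxit = 8) {
  s <- box_scale(box)
  hV <- 1e-7 * s[1]; hn <- 1e-7 * s[2]
  for (it in seq_len(maxit)) {
    f0 <- fun(x, y)
    if (max(abs(f0)) < tol) break
    fx <- (fun(x + hV, y) - fun(x - hV, y)) / (2 * hV)
    fy <- (fun(x, y + hn) - fun(x, y - hn)) / (2 * hn)
    ## move along the coordinate with larger normalized slope
    useV <- abs(fx * s[1]) >= abs(fy * s[2])
    dx <- ifelse(useV & abs(fx) > 0, -f0 / fx, 0)
    dy <- ifelse(!useV & abs(fy) > 0, -f0 / fy, 0)
    ## cap the step to stay near the traced curve
    dx <- pmax(pmin(dx, 0.01 * s[1]), -0.01 * s[1])
    dy <- pmax(pmin(dy, 0.01 * s[2]), -0.01 * s[2])
    x <- pmin(pmax(x + dx, box[1]), box[2])
    y <- pmin(pmax(y + dy, box[3]), box[4])
  }
  cbind(V = x, n = y)
}

label_branches <- function(branches, reference = NULL) {
  if (!length(branches)) return(branches)
  cents <- t(vapply(branches, function(b) colMeans(b$points), numeric(2)))
  if (is.null(reference)) reference <- colMeans(cents)
  for (i in seq_along(branches)) {
    dV <- cents[i, 1] - reference[1]
    dn <- cents[i, 2] - reference[2]
    ## n-extent decides whether the branch reads as lateral or stacked
    span_n <- diff(range(branches[[i]]$points[, 2]))
    branches[[i]]$branch_id <-
      if (span_n > 0.5) { if (dV < 0) "left" else "right" }
      else { if (dn < 0) "lower" else "upper" }
  }
  branches
}

#' Classify the voltage-nullcline topology
#'
#' Distinguishes the resting "hourglass" configuration (two lateral lobes
#' spanning a wide range of the recovery variable, pinched at a funnel)
#' from the stimulated configuration in which a compact lower branch
#' detaches below the N-shaped branch, and from a single-branch portrait.
#'
#' @inheritParams compute_nullclines
#' @return list with \code{topology} (one of \code{"single_branch"},
#'   \code{"hourglass"}, \code{"two_branch"}), \code{n_components}, and
#'   \code{min_gap} (smallest box-normalized distance between the two
#'   main components, \code{NA} for a single component).
#' @export
nullcline_topology <- function(pm, I_app = 0, resolution = 400) {
  nc <- compute_nullclines(pm, I_app, resolution)
  br <- nc$v_nullcline
  ncomp <- length(br)
  if (ncomp < 2)
    return(list(topology = "single_branch", n_components = ncomp,
                min_gap = NA_real_))
  sizes <- vapply(br, function(b) nrow(b$points), numeric(1))
  main <- br[order(sizes, decreasing = TRUE)[1:2]]
  s <- box_scale(pm$box)
  a <- main[[1]]$points; b <- main[[2]]$points
  ## subsample for the gap computation
  a <- a[seq(1, nrow(a), length.out = min(400, nrow(a))), , drop = FALSE]
  b <- b[seq(1, nrow(b), length.out = min(400, nrow(b))), , drop = FALSE]
  d2 <- outer(a[, 1], b[, 1], "-")^2 / s[1]^2 +
        outer(a[, 2], b[, 2], "-")^2 / s[2]^2
  min_gap <- sqrt(min(d2))
  spans <- vapply(main, function(x) diff(range(x$points[, 2])), numeric(1))
  topo <- if (all(spans > 0.5 * (pm$box[4] - pm$box[3]))) "hourglass"
          else "two_branch"
  list(topology = topo, n_components = ncomp, min_gap = min_gap)
}

#' Equilibria of a planar model
#'
#' Locates all intersections of the two nullclines inside the box:
#' candidates are sign changes of \code{g} along the polished voltage
#' nullcline, refined by damped two-dimensional Newton iteration to
#' residual below \code{tol_eq}, deduplicated within \code{dedup} (box
#' normalized). Each equilibrium is classified from the eigenvalues of
#' the finite-difference Jacobian.
#'
#' @inheritParams compute_nullclines
#' @param tol_eq equilibrium residual tolerance.
#' @param dedup dedup radius in box-normalized units.
#' @return list of equilibria, each \code{list(location, jacobian,
#'   eigenvalues, classification)}, ordered by voltage.
#' @export
find_equilibria <- function(pm, I_app = 0, resolution = 400,
                            tol_eq = 1e-9, dedup = 1e-5) {
  nc <- compute_nullclines(pm, I_app, resolution)
  s <- box_scale(pm$box)
  fn <- function(x) c(pm$f(x[1], x[2], I_app), pm$g(x[1], x[2]))
  cands <- list()
  for (b in nc$v_nullcline) {
    gv <- pm$g(b$points[, 1], b$points[, 2])
    idx <- which(diff(sign(gv)) != 0)
    for (i in idx) {
      w <- abs(gv[i + 1]) / (abs(gv[i]) + abs(gv[i + 1]))
      cands[[length(cands) + 1]] <-
        w * b$points[i, ] + (1 - w) * b$points[i + 1, ]
    }
  }
  sols <- list()
  for (x0 in cands) {
    r <- newton_solve(fn, as.numeric(x0), h = 1e-7 * s, tol = tol_eq,
                      maxit = 60)
    if (!r$converged) next  # candidate dropped
    x <- r$x
    if (x[1] < pm$box[1] - 1e-9 || x[1] > pm$box[2] + 1e-9 ||
        x[2] < pm$box[3] - 1e-9 || x[2] > pm$box[4] + 1e-9) next
    dup <- any(vapply(sols, function(sx)
      sqrt(sum(((sx$location - x) / s)^2)) < dedup, logical(1)))
    ## also collapse near-identical equilibria found from coarse contour
    ## segments on opposite sides of a tangency
    dup <- dup || any(vapply(sols, function(sx)
      sqrt(sum(((sx$location - x) / s)^2)) < 5e-4, logical(1)))
    if (dup) next
    J <- planar_jacobian(pm, x[1], x[2], I_app)
    cl <- classify_jacobian(J)
    sols[[length(sols) + 1]] <- list(location = c(V = x[1], n = x[2]),
                                     jacobian = J,
                                     eigenvalues = cl$eigenvalues,
                                     classification = cl$classification)
  }
  sols[order(vapply(sols, function(e) e$location[1], numeric(1)))]
}

#' Stable and unstable manifolds of a saddle
#'
#' Integrates the planar flow forward from small perturbations of the
#' saddle along its unstable eigenvector (both signs), and backward along
#' the stable eigenvector, truncating the polylines at the box boundary
#' or at a fixed arc-length cap.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_app applied current.
#' @param saddle an equilibrium from \code{\link{find_equilibria}} with
#'   classification \code{"saddle"}.
#' @param delta eigenvector perturbation in box-normalized units.
#' @param t_max integration horizon (ms) per branch.
#' @param arc_cap arc-length cap in box-normalized units.
#' @return list with \code{stable} and \code{unstable}, each a list of
#'   two polylines (two-column matrices).
#' @export
saddle_manifolds <- function(pm, I_app, saddle, delta = 1e-4,
                             t_max = 500, arc_cap = 20) {
  if (saddle$classification != "saddle")
    stop("equilibrium is not a saddle")
  s <- box_scale(pm$box)
  eg <- eigen(saddle$jacobian)
  lam <- Re(eg$values)
  vu <- Re(eg$vectors[, which.max(lam)])
  vs <- Re(eg$vectors[, which.min(lam)])
  margin <- 0.02
  trace_from <- function(dir_vec, sgn, backward) {
    y0 <- saddle$location + sgn * delta * dir_vec * s
    rhs <- function(t, y, p) {
      d <- c(pm$f(y[1], y[2], I_app), pm$eps * pm$g(y[1], y[2]))
      if (backward) d <- -d
      list(d)
    }
    ## terminate at an expanded box boundary to avoid integrating the
    ## (backward-unstable) flow to infinity
    rootfun <- function(t, y, p)
      c(y[1] - (pm$box[1] - margin * s[1]),
        (pm$box[2] + margin * s[1]) - y[1],
        y[2] - (pm$box[3] - margin * s[2]),
        (pm$box[4] + margin * s[2]) - y[2])
    times <- seq(0, t_max, length.out = 4000)
    out <- suppressWarnings(
      deSolve::lsodar(unname(y0), times, rhs, NULL, rtol = 1e-8,
                      atol = 1e-8, rootfunc = rootfun))
    pts <- out[, 2:3, drop = FALSE]
    inside <- pts[, 1] >= pm$box[1] & pts[, 1] <= pm$box[2] &
              pts[, 2] >= pm$box[3] & pts[, 2] <= pm$box[4] &
              is.finite(pts[, 1]) & is.finite(pts[, 2])
    stop_at <- if (any(!inside)) which(!inside)[1] else nrow(pts)
    pts <- pts[seq_len(stop_at), , drop = FALSE]
    if (nrow(pts) > 2) {
      arc <- cumsum(c(0, sqrt(diff(pts[, 1] / s[1])^2 +
                              diff(pts[, 2] / s[2])^2)))
      pts <- pts[arc <= arc_cap, , drop = FALSE]
    }
    colnames(pts) <- c("V", "n")
    pts
  }
  list(stable = list(trace_from(vs, +1, TRUE), trace_from(vs, -1, TRUE)),
       unstable = list(trace_from(vu, +1, FALSE),
                       trace_from(vu, -1, FALSE)))
}

## second-order expansion of f at a point, box-scaled central differences
fast_hessian <- function(pm, V, n, I, smooth = TRUE, rel_h = 1e-4) {
  s <- box_scale(pm$box)
  hV <- rel_h * s[1]; hn <- rel_h * s[2]
  f <- function(dV, dn) pm$f(V + dV, n + dn, I, smooth = smooth)
  f0 <- f(0, 0)
  list(
    f = f0,
    fV = (f(hV, 0) - f(-hV, 0)) / (2 * hV),
    fn = (f(0, hn) - f(0, -hn)) / (2 * hn),
    fVV = (f(hV, 0) - 2 * f0 + f(-hV, 0)) / hV^2,
    fnn = (f(0, hn) - 2 * f0 + f(0, -hn)) / hn^2,
    fVn = (f(hV, hn) - f(hV, -hn) - f(-hV, hn) + f(-hV, -hn)) /
      (4 * hV * hn))
}

#' Locate the transcritical singularity of a planar family
#'
#' Solves the three-equation system \code{f = df/dV = df/dn = 0} in
#' \code{(V, n, I)} by damped Newton iteration from a grid of starting
#' points, using the smooth (unclipped) extension of the static gate
#' relations. Solutions whose fast-dynamics Hessian is indefinite are
#' nullcline self-intersections (X shape); among them the one inside the
#' physiological box is returned when it exists, else the one nearest the
#' box. Solutions with a definite Hessian (isolated lobe births/deaths)
#' are discarded.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_bracket current interval to search.
#' @param extend fractional box extension for the search region (the
#'   classical singularity lies outside the physiological box).
#' @param n_starts starting points per axis.
#' @return list with \code{location} \code{c(V, n)},
#'   \code{critical_current}, \code{quadratic_coefficients}
#'   (\code{c(fVV/2, fVn, fnn/2)}), \code{hessian_det} and
#'   \code{inside_box}; \code{NULL}-safe error if no solution is found.
#' @export
detect_transcritical <- function(pm, I_bracket = c(-30, 30), extend = 0.6,
                                 n_starts = 7) {
  box <- pm$box
  s <- box_scale(box)
  lo <- c(box[1] - extend * s[1], box[3] - extend * s[2])
  hi <- c(box[2] + extend * s[1], box[4] + extend * s[2])
  fn <- function(x) {
    hs <- fast_hessian(pm, x[1], x[2], x[3], smooth = TRUE, rel_h = 1e-6)
    c(hs$f, hs$fV, hs$fn)
  }
  sols <- list()
  for (V0 in seq(lo[1], hi[1], length.out = n_starts))
    for (n0 in seq(lo[2], hi[2], length.out = n_starts))
      for (I0 in seq(I_bracket[1], I_bracket[2], length.out = 5)) {
        r <- newton_solve(fn, c(V0, n0, I0),
                          h = c(1e-6 * s, 1e-6 * max(abs(I_bracket), 1)),
                          tol = 1e-8, maxit = 60)
        if (!r$converged) next
        x <- r$x
        if (x[3] < I_bracket[1] - 1 || x[3] > I_bracket[2] + 1) next
        if (x[1] < lo[1] || x[1] > hi[1] || x[2] < lo[2] || x[2] > hi[2])
          next
        if (any(vapply(sols, function(sx)
          max(abs((sx$raw - x) / c(s, 10))) < 1e-3, logical(1)))) next
        hs <- fast_hessian(pm, x[1], x[2], x[3])
        det_h <- hs$fVV * hs$fnn - hs$fVn^2
        norm_h <- hs$fVV * s[1]^2 + abs(hs$fVn) * s[1] * s[2] +
          abs(hs$fnn) * s[2]^2
        if (abs(norm_h) < 1e-8) next    # degenerate expansion
        if (det_h >= 0) next            # definite: not a self-intersection
        inside <- x[1] >= box[1] && x[1] <= box[2] &&
                  x[2] >= box[3] && x[2] <= box[4]
        sols[[length(sols) + 1]] <- list(
          raw = x,
          location = c(V = x[1], n = x[2]),
          critical_current = x[3],
          quadratic_coefficients = c(vv = hs$fVV / 2, vn = hs$fVn,
                                     nn = hs$fnn / 2),
          hessian_det = det_h,
          inside_box = inside)
      }
  if (!length(sols))
    stop("no transcritical point found in the given bracket")
  inside <- vapply(sols, `[[`, logical(1), "inside_box")
  pick <- if (any(inside)) which(inside)[1] else {
    dist_box <- vapply(sols, function(sx) {
      dV <- max(box[1] - sx$location[1], 0, sx$location[1] - box[2])
      dn <- max(box[3] - sx$location[2], 0, sx$location[2] - box[4])
      sqrt((dV / s[1])^2 + (dn / s[2])^2)
    }, numeric(1))
    which.min(dist_box)
  }
  sols[[pick]]$raw <- NULL
  sols[[pick]]
}

#' Fold point of the fast dynamics at fixed current
#'
#' Solves \code{f = df/dV = 0} at fixed \code{I} (a knee of the voltage
#' nullcline, the organizing fold of the fast subsystem). Used to supply
#' fold candidates to \code{\link{normal_form_coefficients}}.
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_app applied current.
#' @param start optional starting point \code{c(V, n)}; by default knees
#'   are sought along the computed voltage nullcline and the one at the
#'   lowest voltage is returned.
#' @return list with \code{location} and \code{current}.
#' @export
find_fold_candidate <- function(pm, I_app = 0, start = NULL) {
  s <- box_scale(pm$box)
  fn <- function(x) {
    hs <- fast_hessian(pm, x[1], x[2], I_app, smooth = TRUE, rel_h = 1e-6)
    c(hs$f, hs$fV)
  }
  starts <- if (!is.null(start)) list(start) else {
    nc <- compute_nullclines(pm, I_app, 300)
    st <- list()
    for (b in nc$v_nullcline) {
      pts <- b$points
      hV <- 1e-5 * s[1]
      fV <- (pm$f(pts[, 1] + hV, pts[, 2], I_app) -
             pm$f(pts[, 1] - hV, pts[, 2], I_app)) / (2 * hV)
      for (i in which(diff(sign(fV)) != 0))
        st[[length(st) + 1]] <- pts[i, ]
    }
    st
  }
  sols <- list()
  for (x0 in starts) {
    r <- newton_solve(fn, as.numeric(x0), h = 1e-6 * s, tol = 1e-9,
                      maxit = 60)
    if (r$converged)
      sols[[length(sols) + 1]] <- list(location = c(V = r$x[1],
                                                    n = r$x[2]),
                                       current = I_app)
  }
  if (!length(sols)) stop("no fold of the fast dynamics found")
  sols[[which.min(vapply(sols, function(sx) sx$location[1], numeric(1)))]]
}

#' Local normal form of the fast dynamics at a singular point
#'
#' Second-order Taylor expansion of \code{f} in coordinates centered at
#' the supplied point. The singularity is labelled
#' \code{"transcritical"} when the gradient vanishes and the quadratic
#' form is indefinite (the v^2 - w^2 structure whose zero set is an X),
#' and \code{"fold"} when the expansion is \code{fV = 0} but
#' \code{fn != 0} with a non-degenerate curvature (the v^2 + w
#' structure).
#'
#' @param pm a \code{\link{planar_model}}.
#' @param point a result of \code{\link{detect_transcritical}} or
#'   \code{\link{find_fold_candidate}} (needs \code{location} plus
#'   \code{critical_current} or \code{current}).
#' @param tol degeneracy tolerance on box-normalized derivatives.
#' @return list with \code{label}, \code{coefficients} (linear slope in
#'   n and the three quadratic coefficients), and the raw derivatives.
#' @export
normal_form_coefficients <- function(pm, point, tol = 1e-5) {
  I <- if (!is.null(point$critical_current)) point$critical_current
       else point$current
  loc <- point$location
  hs <- fast_hessian(pm, loc[1], loc[2], I)
  s <- box_scale(pm$box)
  ## box-normalized magnitudes for degeneracy decisions
  gV <- hs$fV * s[1]; gn <- hs$fn * s[2]
  qVV <- hs$fVV * s[1]^2; qnn <- hs$fnn * s[2]^2; qVn <- hs$fVn * s[1] * s[2]
  qnorm <- abs(qVV) + abs(qVn) + abs(qnn)
  if (qnorm < tol && abs(gn) < tol)
    stop("degenerate expansion: all second-order terms below tolerance")
  det_h <- hs$fVV * hs$fnn - hs$fVn^2
  label <- if (abs(gV) < 1e-3 * qnorm && abs(gn) < 1e-3 * qnorm &&
               det_h < 0) "transcritical"
  else if (abs(gV) < 1e-3 * qnorm && abs(gn) >= 1e-3 * qnorm &&
           abs(qVV) >= tol) "fold"
  else "undetermined"
  list(label = label,
       coefficients = c(fn = unname(hs$fn), vv = unname(hs$fVV) / 2,
                        vn = unname(hs$fVn), nn = unname(hs$fnn) / 2),
       derivatives = hs)
}

#' Agreement between traced nullclines and a brute-force sign grid
#'
#' Compares the polylines from \code{\link{compute_nullclines}} with the
#' set of sign-change cells of \code{f} on a fine regular grid: every
#' point of the (densely resampled) polylines must fall within one grid
#' cell of a sign change, and every sign-change cell must have a
#' polyline point within one cell (a discrete two-sided Hausdorff check
#' at the grid scale).
#'
#' @param pm a \code{\link{planar_model}}.
#' @param I_app applied current.
#' @param grid_res brute-force grid resolution per axis.
#' @param trace_res resolution handed to \code{compute_nullclines}.
#' @return list with \code{points_off_grid} (polyline points farther
#'   than one cell from any sign change), \code{cells_missed}
#'   (sign-change cells with no nearby polyline), and the totals
#'   \code{n_points}, \code{n_cells}.
#' @export
nullcline_grid_agreement <- function(pm, I_app = 0, grid_res = 2000,
                                     trace_res = 500) {
  Vg <- seq(pm$box[1], pm$box[2], length.out = grid_res)
  ng <- seq(pm$box[3], pm$box[4], length.out = grid_res)
  sgn <- sign(outer(Vg, ng, function(V, n) pm$f(V, n, I_app)))
  cell <- (sgn[-grid_res, -grid_res] * sgn[-1, -grid_res] < 0) |
          (sgn[-grid_res, -grid_res] * sgn[-grid_res, -1] < 0)
  nc <- compute_nullclines(pm, I_app, resolution = trace_res)
  dV <- Vg[2] - Vg[1]; dn <- ng[2] - ng[1]
  P <- matrix(FALSE, grid_res - 1, grid_res - 1)
  for (b in nc$v_nullcline) {
    x <- b$points[, 1]; y <- b$points[, 2]
    seglen <- pmax(abs(diff(x)) / dV, abs(diff(y)) / dn)
    xs <- ys <- vector("list", length(seglen))
    for (k in seq_along(seglen)) {
      m <- max(2, ceiling(seglen[k] * 2))
      xs[[k]] <- seq(x[k], x[k + 1], length.out = m)
      ys[[k]] <- seq(y[k], y[k + 1], length.out = m)
    }
    xx <- unlist(xs); yy <- unlist(ys)
    i <- pmin(pmax(findInterval(xx, Vg), 1L), grid_res - 1L)
    j <- pmin(pmax(findInterval(yy, ng), 1L), grid_res - 1L)
    P[cbind(i, j)] <- TRUE
  }
  dilate <- function(M) {
    D <- M; n <- nrow(M)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      D <- D | M[pmin(pmax(seq_len(n) + di, 1L), n),
                 pmin(pmax(seq_len(n) + dj, 1L), n)]
    }
    D
  }
  list(points_off_grid = sum(!dilate(cell)[P]),
       cells_missed = sum(!dilate(P)[cell]),
       n_points = sum(P), n_cells = sum(cell))
}

#' Assemble a phase portrait
#'
#' Convenience wrapper collecting nullclines, classified equilibria and,
#' when a saddle is present, its invariant manifolds at one value of the
#' applied current.
#'
#' @inheritParams compute_nullclines
#' @param manifolds also compute saddle manifolds.
#' @return list of class \code{phase_portrait}.
#' @export
phase_portrait <- function(pm, I_app = 0, resolution = 400,
                           manifolds = TRUE) {
  eqs <- find_equilibria(pm, I_app, resolution)
  nc <- compute_nullclines(pm, I_app, resolution)
  sad <- Filter(function(e) e$classification == "saddle", eqs)
  man <- if (manifolds && length(sad))
    saddle_manifolds(pm, I_app, sad[[1]]) else NULL
  structure(list(model = pm$name, I_app = I_app, nullclines = nc,
                 equilibria = eqs, manifolds = man),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat("<phase_portrait>", x$model, "at I =", x$I_app, "\n")
  cat(" ", length(x$nullclines$v_nullcline), "V-nullcline branch(es),",
      length(x$equilibria), "equilibria:\n")
  for (e in x$equilibria)
    cat(sprintf("   (%.3f, %.4f)  %s\n", e$location[1], e$location[2],
                e$classification))
  invisible(x)
}
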