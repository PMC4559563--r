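# Jacobians, eigenvalues and classification ---------------------------------

#' Jacobian matrix of the dynamics at a state
#'
#' Partial derivatives of the right-hand side with respect to every state
#' component, in the canonical layout (consumers first, resources second).
#' The analytic form uses the active branch of Liebig-minimum growth; states
#' exactly on an isocline corner are handled with the lower-index branch
#' convention and flagged via attribute `on_corner`. The finite-difference
#' form uses central differences with per-component step
#' `h = h_scale * max(1, |x|)` and no branch bookkeeping, and is the fallback
#' for non-smooth checks.
#'
#' @param system A [cr_system()] object.
#' @param state State vector (canonical layout, see [cr_state()]).
#' @param method `"analytic"` (default) or `"finite_diff"`.
#' @param h_scale Relative step for the finite-difference method.
#' @return Square numeric matrix of rates \[1/time\], with dimnames; attribute
#'   `on_corner` is `TRUE` when some Liebig consumer sits exactly on its
#'   isocline corner (analytic method only).
#' @examples
#' sys <- example_system_1c1r()
#' cr_jacobian(sys, cr_state(sys, B = 0, R = 1))
#' @export
cr_jacobian <- function(system, state, method = c("analytic", "finite_diff"),
                        h_scale = 1e-6) {
  stopifnot(inherits(system, "cr_system"))
  method <- match.arg(method)
  state <- as_state(system, state)
  nm <- state_names(system)
  d <- length(nm)
  if (method == "finite_diff") {
    f <- make_rhs(system, check = FALSE)
    J <- matrix(0, d, d, dimnames = list(nm, nm))
    for (j in seq_len(d)) {
      h <- h_scale * max(1, abs(state[j]))
      xp <- state; xp[j] <- xp[j] + h
      xm <- state; xm[j] <- xm[j] - h
      J[, j] <- (f(xp) - f(xm)) / (2 * h)
    }
    return(J)
  }
  nc <- n_consumers(system); nr <- n_resources(system)
  cids <- names(system$consumers); rids <- names(system$resources)
  N <- state[cids]; R <- state[rids]
  a <- vapply(system$resources, `[[`, numeric(1), "a")
  m <- vapply(system$consumers, `[[`, numeric(1), "m")
  Q <- q_matrix(system)
  fvals <- vapply(system$consumers, growth_rate, numeric(1), R = R)
  grads <- lapply(system$consumers, growth_gradient, R = R, rids = rids)
  G <- do.call(rbind, lapply(grads, as.numeric))       # nc x nr, rows consumers
  dimnames(G) <- list(cids, rids)
  corner <- any(vapply(grads, function(g) isTRUE(attr(g, "on_corner")), logical(1)))

  J <- matrix(0, d, d, dimnames = list(nm, nm))
  # consumer rows: d(dN_i)/dN_i = f_i - m_i; d(dN_i)/dR_j = N_i df_i/dR_j
  for (i in seq_len(nc)) {
    J[i, i] <- fvals[i] - m[i]
    J[i, nc + seq_len(nr)] <- N[i] * G[i, ]
  }
  # resource rows: d(dR_j)/dN_i = -q_ji f_i; d(dR_j)/dR_l = -a_j 1(j=l) - sum_i q_ji N_i df_i/dR_l
  for (j in seq_len(nr)) {
    J[nc + j, seq_len(nc)] <- -Q[j, ] * fvals
    J[nc + j, nc + seq_len(nr)] <- -colSums(Q[j, ] * N * G)
    J[nc + j, nc + j] <- J[nc + j, nc + j] - a[j]
  }
  structure(J, on_corner = corner)
}

#' Closed-form eigenvalues at the one-consumer/one-resource coexistence point
#'
#' Evaluates
#' \deqn{\lambda_\pm = -\tfrac12 a_R - \tfrac12 q B^* f'(R^*)
#'   \pm \tfrac12\sqrt{(a_R + q B^* f'(R^*))^2 - 4 m q B^* f'(R^*)}}
#' at the feasible coexistence point of a Holling II consumer on one
#' chemostat resource. Both eigenvalues always have negative real part: the
#' point is a stable node (real pair) or a stable vortex (complex pair).
#'
#' @param system A [cr_system()] with one consumer (holling2) and one resource.
#' @return Complex vector of length 2, ordered by decreasing real part.
#' @examples
#' eigen_coexistence_1c1r(example_system_1c1r())  # -0.3, -1
#' @export
eigen_coexistence_1c1r <- function(system) {
  stopifnot(inherits(system, "cr_system"))
  pt <- coexistence_1c1r(system)
  if (!pt$feasible)
    stop("coexistence point is not feasible for this system", call. = FALSE)
  co <- system$consumers[[1L]]
  res <- system$resources[[1L]]
  rstar <- pt$state[[res$id]]
  bstar <- pt$state[[co$id]]
  g <- co$growth
  fp <- g$f_max * g$k[[1L]] / (rstar + g$k[[1L]])^2   # f'(R*)
  w <- co$q[[res$id]] * bstar * fp
  disc <- as.complex((res$a + w)^2 - 4 * co$m * w)
  lam <- -0.5 * res$a - 0.5 * w + c(0.5, -0.5) * sqrt(disc)
  lam[order(-Re(lam), -Im(lam))]
}

#' Classify a stationary point by its Jacobian eigenvalues
#'
#' Computes the eigenvalues of the (analytic) Jacobian at the point and
#' classifies by the sign pattern of their real parts, with a scale-aware
#' hyperbolicity tolerance `tol_re = 1e-8 * max(a_j, m_i, f_max_i)`: any real
#' part within the tolerance of zero yields `"non_hyperbolic"` (no guess).
#' Complex parts beyond `tol_im` make a node a vortex. Timescales
#' \eqn{1/|Re \lambda|} are reported because transient dynamics is governed
#' by the magnitudes of the eigenvalues, not only their signs.
#'
#' @param system A [cr_system()] object.
#' @param point A `stationary_point` (or a bare state vector).
#' @param tol_re Hyperbolicity tolerance; default `1e-8 * rate scale`.
#' @param tol_im Imaginary-part tolerance for vortex detection.
#' @return A `cr_classification`: eigenvalues (decreasing real part), class
#'   (one of `stable_node`, `stable_vortex`, `saddle`, `unstable_node`,
#'   `unstable_vortex`, `non_hyperbolic`), timescales, and the slowest
#'   unstable rate (smallest positive real part, `NA` if none).
#' @examples
#' sys <- example_system_1c1r()
#' classify(sys, supply_point(sys))  # saddle: 0.25, -1
#' @export
classify <- function(system, point, tol_re = NULL, tol_im = 1e-10) {
  stopifnot(inherits(system, "cr_system"))
  state <- if (inherits(point, "stationary_point")) point$state else as_state(system, point)
  J <- cr_jacobian(system, state)
  ev <- eigen(unclass(J), only.values = TRUE)$values
  ev <- as.complex(ev)
  ev <- ev[order(-Re(ev), -Im(ev))]
  if (is.null(tol_re)) tol_re <- 1e-8 * rate_scale(system)
  re <- Re(ev); im <- Im(ev)
  cls <- if (any(abs(re) <= tol_re)) "non_hyperbolic"
  else if (any(re > 0) && any(re < 0)) "saddle"
  else {
    vortex <- any(abs(im) > tol_im)
    if (all(re < 0)) if (vortex) "stable_vortex" else "stable_node"
    else if (vortex) "unstable_vortex" else "unstable_node"
  }
  pos <- re[re > tol_re]
  structure(
    list(point = if (inherits(point, "stationary_point")) point else NULL,
         state = state,
         eigenvalues = ev,
         class = cls,
         timescales = 1 / abs(re),
         slowest_unstable_rate = if (length(pos)) min(pos) else NA_real_,
         on_corner = isTRUE(attr(J, "on_corner")),
         tol_re = tol_re, tol_im = tol_im),
    class = "cr_classification")
}

#' @export
print.cr_classification <- function(x, ...) {
  cat("<cr_classification> ", x$class,
      if (isTRUE(x$on_corner)) "  (Liebig corner: active-branch Jacobian)" else "",
      "\n", sep = "")
  ev <- signif(x$eigenvalues, 6)
  cat("  eigenvalues:", paste(format(ev), collapse = ", "), "\n")
  cat("  timescales :", paste(signif(x$timescales, 4), collapse = ", "), "\n")
  if (!is.na(x$slowest_unstable_rate))
    cat("  slowest unstable rate:", signif(x$slowest_unstable_rate, 6), "\n")
  invisible(x)
}

#' Determinant sign criterion for two-consumer/two-resource coexistence
#'
#' Compares the sign of \eqn{\det Q} (conversion matrix) with the sign of the
#' determinant of the growth-gradient matrix
#' \eqn{(\partial f_i / \partial R_j)} evaluated at the coexistence resource
#' pair. Opposite signs give a saddle; equal signs a stable point (node or
#' vortex). Geometrically: the consumption vectors must cross the isoclines
#' in the same rotational order -- each consumer must consume mostly the
#' resource that limits its own growth at the intersection.
#'
#' @param system A [cr_system()] with 2 consumers and 2 resources.
#' @param point A feasible coexistence `stationary_point` from
#'   [coexistence_2c2r()].
#' @return `"stable"`, `"saddle"`, or `"degenerate"` (either determinant
#'   below `1e-12` in magnitude: no verdict).
#' @export
coexistence_sign_criterion <- function(system, point) {
  stopifnot(inherits(system, "cr_system"), inherits(point, "stationary_point"))
  if (point$kind != "coexistence" || length(point$present) != 2L)
    stop_config("expected a two-consumer coexistence point")
  rids <- names(system$resources)
  R <- point$state[rids]
  dQ <- det(q_matrix(system))
  G <- do.call(rbind, lapply(system$consumers, function(co)
    as.numeric(growth_gradient(co, R, rids))))
  dG <- det(G)
  if (abs(dQ) < 1e-12 || abs(dG) < 1e-12) return("degenerate")
  if (sign(dQ) * sign(dG) < 0) "saddle" else "stable"
}

#' Stability report for every stationary point of a system
#'
#' Runs [find_all_equilibria()] and [classify()] and tabulates densities,
#' classes, eigenvalues and timescales -- ready for `write.csv()` or
#' `jsonlite::toJSON()`.
#'
#' @param system A [cr_system()] object.
#' @return A data frame with one row per stationary point.
#' @examples
#' stability_report(example_system_1c1r())
#' @export
stability_report <- function(system) {
  eq <- find_all_equilibria(system)
  df <- as.data.frame(eq)
  cls <- lapply(eq, function(p) classify(system, p))
  df$class <- vapply(cls, `[[`, character(1), "class")
  df$eigen_re <- vapply(cls, function(cc) paste(signif(Re(cc$eigenvalues), 6), collapse = ";"),
                        character(1))
  df$eigen_im <- vapply(cls, function(cc) paste(signif(Im(cc$eigenvalues), 6), collapse = ";"),
                        character(1))
  df$timescales <- vapply(cls, function(cc) paste(signif(cc$timescales, 6), collapse = ";"),
                          character(1))
  df
}

#' Equilibria report as a flat table
#'
#' Convenience wrapper: `as.data.frame(find_all_equilibria(system))`.
#'
#' @param system A [cr_system()] object.
#' @return A data frame with one row per stationary point.
#' @export
equilibria_report <- function(system) {
  as.data.frame(find_all_equilibria(system))
}
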