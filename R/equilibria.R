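# Stationary points ---------------------------------------------------------
#
# Closed-form enumeration of the stationary points of systems with at most
# two consumers and two resources: the supply point (all consumers absent,
# resources at their stable levels), boundary points with a single consumer
# present, and interior coexistence points. Feasibility means all densities
# non-negative (tolerance -1e-12 for float noise at thresholds).

FEAS_TOL <- 1e-12

new_stationary_point <- function(system, state, kind, present,
                                 limiting = NULL, on_corner = FALSE,
                                 note = NULL) {
  state <- stats::setNames(as.numeric(state), state_names(system))
  feasible <- all(state >= -FEAS_TOL)
  structure(
    list(state = state, kind = kind, present = present, feasible = feasible,
         limiting = limiting, on_corner = on_corner, note = note),
    class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat("<stationary_point> ", x$kind,
      if (length(x$present)) paste0(" [", paste(x$present, collapse = ","), "]") else "",
      if (!x$feasible) "  (infeasible)" else "",
      if (isTRUE(x$on_corner)) "  (on isocline corner)" else "", "\n", sep = "")
  print(signif(x$state, 6))
  if (!is.null(x$limiting))
    cat("  limiting:", paste(names(x$limiting), x$limiting, sep = "->", collapse = ", "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

point_label <- function(p) {
  switch(p$kind,
         supply = "supply",
         single_consumer = paste0(p$present, "-point"),
         coexistence = "coexistence",
         p$kind)
}

#' Supply point (trivial equilibrium)
#'
#' The stationary state with every consumer absent and every resource at its
#' stable level \eqn{s_j}. Always feasible.
#'
#' @param system A [cr_system()] object.
#' @return A `stationary_point`.
#' @examples
#' supply_point(example_system_1c1r())
#' @export
supply_point <- function(system) {
  stopifnot(inherits(system, "cr_system"))
  s <- vapply(system$resources, `[[`, numeric(1), "s")
  new_stationary_point(system,
                       c(numeric(n_consumers(system)), s),
                       kind = "supply", present = character(0))
}

stop_no_solution <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("chemocomp_no_positive_solution", "error", "condition")))
}

#' Critical resource level (R*) of a consumer
#'
#' The resource density at which growth exactly balances mortality on one
#' resource branch of the consumer's growth model:
#' \eqn{R^* = k m / (f_{max} - m)}. No positive solution exists when
#' \eqn{f_{max} \le m} (the consumer cannot persist at any resource level);
#' this raises an error of class `chemocomp_no_positive_solution`.
#'
#' @param consumer A [consumer()] object.
#' @param resource_id Which resource branch to evaluate; defaults to the sole
#'   resource of a `holling2` growth model (required for `liebig_min`).
#' @return Critical density \[density\].
#' @examples
#' b <- consumer("B", m = 1, growth = growth_holling2(2, c(R = 1)), q = c(R = 1))
#' critical_resource_level(b)  # 1
#' @export
critical_resource_level <- function(consumer, resource_id = NULL) {
  stopifnot(inherits(consumer, "cr_consumer"))
  g <- consumer$growth
  if (is.null(resource_id)) {
    if (length(g$k) != 1L)
      stop_config("'resource_id' is required for a multi-resource growth model")
    resource_id <- names(g$k)
  }
  if (!resource_id %in% names(g$k))
    stop_config("consumer '", consumer$id, "' has no half-saturation constant for resource '",
                resource_id, "'")
  if (g$f_max <= consumer$m)
    stop_no_solution("consumer '", consumer$id, "': maximal growth rate f_max = ",
                     g$f_max, " does not exceed mortality m = ", consumer$m,
                     "; no positive critical resource level exists")
  g$k[[resource_id]] * consumer$m / (g$f_max - consumer$m)
}

# Critical levels for all (consumer, resource) branches of a liebig consumer;
# named numeric over resource ids. Errors if f_max <= m.
critical_levels <- function(consumer) {
  vapply(names(consumer$growth$k),
         function(r) critical_resource_level(consumer, r), numeric(1))
}

#' Coexistence point of one consumer and one resource
#'
#' Solves growth = mortality for \eqn{R^*} and the resource balance for
#' \eqn{B^* = a_R (s_R - R^*) / (q_{RB} m_B)}. Feasible iff
#' \eqn{0 < R^* < s_R}; when the stable level falls short of the critical
#' level the point is returned with a negative consumer density and
#' `feasible = FALSE`.
#'
#' @param system A [cr_system()] with exactly one consumer (holling2 growth)
#'   and one resource.
#' @return A `stationary_point` of kind `"coexistence"`.
#' @examples
#' coexistence_1c1r(example_system_1c1r())  # B* = 1/3, R* = 2/3
#' @export
coexistence_1c1r <- function(system) {
  stopifnot(inherits(system, "cr_system"))
  if (n_consumers(system) != 1L || n_resources(system) != 1L)
    stop_config("coexistence_1c1r() needs exactly 1 consumer and 1 resource")
  single_consumer_point_1r(system, names(system$consumers)[1L])
}

#' Single-consumer boundary point with one resource
#'
#' The stationary point of a one-resource system in which only the named
#' consumer is present: resource at that consumer's critical level, consumer
#' density from the resource balance, every other consumer exactly zero.
#'
#' @param system A [cr_system()] with one resource; all consumers `holling2`.
#' @param consumer_id Id of the consumer present at the point.
#' @return A `stationary_point`.
#' @export
single_consumer_point_1r <- function(system, consumer_id) {
  stopifnot(inherits(system, "cr_system"))
  if (n_resources(system) != 1L)
    stop_config("single_consumer_point_1r() needs exactly 1 resource")
  co <- system$consumers[[consumer_id]]
  if (is.null(co)) stop_config("unknown consumer '", consumer_id, "'")
  if (co$growth$variant != "holling2")
    stop_config("closed form for one resource requires holling2 growth")
  res <- system$resources[[1L]]
  rstar <- critical_resource_level(co)              # may raise no-positive-solution
  qv <- co$q[[res$id]]
  if (is.na(qv) || qv <= 0)
    stop_config("consumer '", co$id, "': conversion factor for resource '",
                res$id, "' must be > 0 for a closed-form boundary point")
  bstar <- res$a * (res$s - rstar) / (qv * co$m)
  state <- cr_state(system)
  state[co$id] <- bstar
  state[res$id] <- rstar
  kind <- if (n_consumers(system) == 1L) "coexistence" else "single_consumer"
  new_stationary_point(system, state, kind, present = co$id,
                       limiting = stats::setNames(res$id, co$id))
}

#' Single-consumer stationary point with two essential resources
#'
#' For a consumer with Liebig-minimum growth the zero-growth isocline is
#' L-shaped: two semi-lines starting at the corner of the critical levels.
#' Consumption constrains the resources to the supply line through the
#' supply point \eqn{(s_P, s_R)} with slope \eqn{a_R q_{P}/(a_P q_{R})}; the
#' stationary resource pair is the intersection of that line with whichever
#' semi-line contains it (the other coordinate strictly above its critical
#' level). The consumer density follows from either resource balance. All
#' other consumers are exactly absent.
#'
#' @param system A [cr_system()] with two resources; the named consumer must
#'   have `liebig_min` growth.
#' @param consumer_id Id of the consumer present at the point.
#' @return A `stationary_point`; `limiting` records the active resource.
#'   A supply line with positive slope always meets exactly one arm of the
#'   L-shaped isocline (or its corner, flagged `on_corner`); when the supply
#'   point lies below the isocline the intersection carries a negative
#'   consumer density and the point is returned with `feasible = FALSE`.
#' @export
single_consumer_point_2r <- function(system, consumer_id) {
  stopifnot(inherits(system, "cr_system"))
  if (n_resources(system) != 2L)
    stop_config("single_consumer_point_2r() needs exactly 2 resources")
  co <- system$consumers[[consumer_id]]
  if (is.null(co)) stop_config("unknown consumer '", consumer_id, "'")
  if (co$growth$variant != "liebig_min")
    stop_config("closed form for two resources requires liebig_min growth")
  rids <- names(system$resources)
  a <- vapply(system$resources, `[[`, numeric(1), "a")
  s <- vapply(system$resources, `[[`, numeric(1), "s")
  crit <- critical_levels(co)[rids]                 # may raise no-positive-solution
  qv <- stats::setNames(numeric(2), rids)
  qv[names(co$q)] <- co$q
  if (any(qv <= 0))
    stop_config("consumer '", co$id,
                "': both conversion factors must be > 0 for the supply-line construction")

  # Candidate with resource `act` on its critical level; the other resource
  # follows from the supply line through (s_P, s_R).
  candidate <- function(act) {
    oth <- setdiff(rids, act)
    r <- stats::setNames(numeric(2), rids)
    r[act] <- crit[[act]]
    r[oth] <- s[[oth]] - (a[[act]] * qv[[oth]] / (a[[oth]] * qv[[act]])) *
      (s[[act]] - crit[[act]])
    list(act = act, oth = oth, r = r, slack = r[[oth]] - crit[[oth]])
  }
  cands <- lapply(rids, candidate)
  # a positive-slope line meets exactly one arm (or the corner): the candidate
  # with the larger slack is the consistent one
  slacks <- vapply(cands, `[[`, numeric(1), "slack")
  pick <- cands[[which.max(slacks)]]
  corner <- any(slacks == 0)
  act <- pick$act
  dens <- a[[act]] * (s[[act]] - pick$r[[act]]) / (qv[[act]] * co$m)
  state <- cr_state(system)
  state[co$id] <- dens
  state[rids] <- pick$r
  kind <- if (n_consumers(system) == 1L) "coexistence" else "single_consumer"
  new_stationary_point(system, state, kind, present = co$id,
                       limiting = stats::setNames(act, co$id),
                       on_corner = corner)
}

#' Coexistence points of two consumers on two essential resources
#'
#' Enumerates the branch pairings of the two L-shaped zero-growth isoclines,
#' keeps resource intersections consistent with both consumers' active-branch
#' conditions, and solves the linear resource balance
#' \eqn{Q (m_A A, m_B B)^T = (a_P(s_P - P^*), a_R(s_R - R^*))^T} for the
#' consumer densities. A point is feasible iff both consumer densities are
#' positive, equivalently iff the supply point lies in the wedge spanned by
#' the consumption vectors.
#'
#' @param system A [cr_system()] with two consumers and two resources, both
#'   consumers with `liebig_min` growth.
#' @return A list of `stationary_point`s (possibly empty). Intersections at
#'   an isocline corner are returned flagged `on_corner`, not resolved.
#' @export
coexistence_2c2r <- function(system) {
  stopifnot(inherits(system, "cr_system"))
  if (n_consumers(system) != 2L || n_resources(system) != 2L)
    stop_config("coexistence_2c2r() needs exactly 2 consumers and 2 resources")
  if (!all(vapply(system$consumers, function(co) co$growth$variant, character(1)) == "liebig_min"))
    stop_config("closed form for two resources requires liebig_min growth")
  cids <- names(system$consumers)
  rids <- names(system$resources)
  a <- vapply(system$resources, `[[`, numeric(1), "a")
  s <- vapply(system$resources, `[[`, numeric(1), "s")
  m <- vapply(system$consumers, `[[`, numeric(1), "m")
  crit <- sapply(system$consumers, critical_levels)[rids, , drop = FALSE]  # res x cons
  Q <- q_matrix(system)
  dQ <- det(Q)
  if (abs(dQ) < 1e-12)
    stop(errorCondition("conversion matrix Q is singular; coexistence densities are not determined",
                        class = c("chemocomp_singular_q", "error", "condition")))

  pts <- list()
  # consumer 1 limited by resource u, consumer 2 by the other resource
  for (u in rids) {
    v <- setdiff(rids, u)
    rstar <- stats::setNames(numeric(2), rids)
    rstar[u] <- crit[u, cids[1L]]
    rstar[v] <- crit[v, cids[2L]]
    # each consumer's non-active resource must sit at or above its own critical level
    slack1 <- rstar[[v]] - crit[v, cids[1L]]
    slack2 <- rstar[[u]] - crit[u, cids[2L]]
    if (slack1 < 0 || slack2 < 0) next
    dens <- solve(Q, a * (s - rstar)) / m
    state <- cr_state(system)
    state[cids] <- dens
    state[rids] <- rstar
    pts[[length(pts) + 1L]] <-
      new_stationary_point(system, state, "coexistence", present = cids,
                           limiting = stats::setNames(c(u, v), cids),
                           on_corner = (slack1 == 0 || slack2 == 0))
  }
  pts
}

#' Enumerate all stationary points of a system
#'
#' Dispatches over the four supported configurations (1 or 2 consumers by 1
#' or 2 resources) and returns the supply point, every single-consumer
#' boundary point whose critical resource level exists, and every coexistence
#' point, each with its feasibility flag. Consumers whose maximal growth rate
#' does not exceed their mortality contribute no boundary point.
#'
#' @param system A [cr_system()] object.
#' @return An object of class `cr_equilibria`: a list of `stationary_point`s
#'   with the system attached as an attribute. Coerce with `as.data.frame()`.
#' @examples
#' find_all_equilibria(example_system_1c1r())
#' @export
find_all_equilibria <- function(system) {
  stopifnot(inherits(system, "cr_system"))
  nc <- n_consumers(system); nr <- n_resources(system)
  if (nc > 2L || nr > 2L)
    stop(errorCondition(
      paste0("closed-form equilibria are implemented for at most 2 consumers and 2 resources (got ",
             nc, "x", nr, "); generic simulation remains available"),
      class = c("chemocomp_unsupported", "error", "condition")))
  pts <- list(supply_point(system))
  skip_no_solution <- function(expr) tryCatch(expr, chemocomp_no_positive_solution = function(e) NULL)
  single_fun <- if (nr == 1L) single_consumer_point_1r else single_consumer_point_2r
  for (cid in names(system$consumers)) {
    p <- skip_no_solution(single_fun(system, cid))
    if (!is.null(p)) pts[[length(pts) + 1L]] <- p
  }
  if (nc == 2L && nr == 2L) {
    cx <- skip_no_solution(coexistence_2c2r(system))
    if (length(cx)) pts <- c(pts, cx)
  }
  structure(pts, class = "cr_equilibria", system = system)
}

#' @export
print.cr_equilibria <- function(x, ...) {
  cat("<cr_equilibria> ", length(x), " stationary point(s)\n", sep = "")
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' @export
as.data.frame.cr_equilibria <- function(x, ...) {
  sys <- attr(x, "system")
  nm <- state_names(sys)
  rows <- lapply(x, function(p) {
    df <- data.frame(point = point_label(p), kind = p$kind,
                     feasible = p$feasible, on_corner = isTRUE(p$on_corner),
                     limiting = if (is.null(p$limiting)) NA_character_ else
                       paste(names(p$limiting), p$limiting, sep = ":", collapse = ";"),
                     stringsAsFactors = FALSE)
    cbind(df, as.data.frame(as.list(p$state)))
  })
  do.call(rbind, rows)
}

#' Feasibility threshold for the maximal growth rate
#'
#' For a Holling II consumer on one chemostat resource the coexistence point
#' lies in the positive quadrant iff \eqn{R^* < s_R}, i.e. iff
#' \eqn{f_{max} > m (1 + k/s)}. This returns that threshold value of
#' \eqn{f_{max}}.
#'
#' @param m Mortality rate \[1/time\].
#' @param k Half-saturation constant \[density\].
#' @param s Stable resource level (> 0) \[density\].
#' @return Threshold maximal growth rate \[1/time\].
#' @examples
#' coexistence_threshold_f_max(m = 1, k = 1, s = 1)  # 2
#' @export
coexistence_threshold_f_max <- function(m, k, s) {
  check_scalar(m, "m"); check_scalar(k, "k"); check_scalar(s, "s")
  if (m <= 0 || k <= 0 || s <= 0) stop("'m', 'k' and 's' must be positive", call. = FALSE)
  m * (1 + k / s)
}
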