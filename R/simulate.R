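# Forward-Euler integration and transient-visit detection -------------------

# Default horizon: 100 times the slowest timescale among the stable feasible
# stationary points (so even the slowest relaxation completes); falls back to
# 100 / (smallest rate parameter) when no closed form or no stable point is
# available.
default_t_end <- function(system) {
  ts <- tryCatch({
    eq <- find_all_equilibria(system)
    stable <- Filter(function(p) p$feasible, eq)
    cls <- lapply(stable, function(p) classify(system, p))
    keep <- vapply(cls, function(cc) cc$class %in% c("stable_node", "stable_vortex"),
                   logical(1))
    tt <- unlist(lapply(cls[keep], `[[`, "timescales"))
    tt <- tt[is.finite(tt)]
    if (length(tt)) max(tt) else NA_real_
  }, error = function(e) NA_real_)
  if (is.na(ts)) {
    slow <- min(vapply(system$resources, `[[`, numeric(1), "a"),
                vapply(system$consumers, `[[`, numeric(1), "m"))
    ts <- 1 / slow
  }
  100 * ts
}

#' Fixed-step forward-Euler integration
#'
#' Integrates the system with the explicit first-order update
#' \eqn{x_{n+1} = x_n + \Delta t \, f(x_n)}. The step is fixed and fully
#' deterministic; densities are never clamped. Tiny negative excursions (down
#' to `-1e-6`, Euler round-off) are tolerated and treated as zero inside the
#' growth functions; anything more negative stops the integration early with
#' a diagnostic (the step size is too large for the dynamics). Consumer
#' components that start at exactly zero remain exactly zero.
#'
#' @param system A [cr_system()] object.
#' @param x0 Non-negative initial state (canonical layout, see [cr_state()]).
#' @param dt Time step; default `0.01 / max(a_j, m_i, f_max_i)`.
#' @param t_end Integration horizon; default 100 times the slowest stable
#'   timescale of the system's classified equilibria.
#' @param record_every Record every n-th state (thinning); the step itself is
#'   unaffected.
#' @return A `cr_trajectory`: `times`, `states` (rows = recorded time points,
#'   columns = state layout), `dt`, `termination` (`"completed"` or
#'   `"negative_state"`) and a diagnostic `message`.
#' @examples
#' sys <- example_system_1c1r()
#' tr <- integrate_euler(sys, cr_state(sys, B = 0.01, R = 0), dt = 0.01, t_end = 200)
#' tail(as.data.frame(tr), 1)  # near B* = 1/3, R* = 2/3
#' @export
integrate_euler <- function(system, x0, dt = NULL, t_end = NULL, record_every = 1L) {
  stopifnot(inherits(system, "cr_system"))
  x0 <- as_state(system, x0)
  if (any(x0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  if (is.null(dt)) dt <- 0.01 / rate_scale(system)
  check_scalar(dt, "dt")
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (is.null(t_end)) t_end <- default_t_end(system)
  check_scalar(t_end, "t_end")
  if (t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  record_every <- max(1L, as.integer(record_every))

  f <- make_rhs(system, neg_tol = 1e-6, check = TRUE)
  n_steps <- ceiling(t_end / dt)
  n_rec <- n_steps %/% record_every + 1L
  nm <- state_names(system)
  states <- matrix(NA_real_, n_rec, length(nm), dimnames = list(NULL, nm))
  times <- numeric(n_rec)
  x <- x0
  states[1L, ] <- x
  ri <- 1L
  termination <- "completed"
  msg <- NULL
  for (n in seq_len(n_steps)) {
    xn <- x + dt * f(x)
    if (any(!is.finite(xn)))
      stop(errorCondition(
        paste0("state diverged (non-finite) at step ", n, " (t = ",
               format(n * dt), "); reduce dt"),
        class = c("chemocomp_divergence", "error", "condition")))
    if (any(xn < -1e-6)) {
      bad <- nm[which.min(xn)]
      termination <- "negative_state"
      msg <- paste0("component '", bad, "' fell below -1e-6 at step ", n,
                    " (t = ", format(n * dt), "); step too large, retry with smaller dt")
      break
    }
    x <- xn
    if (n %% record_every == 0L) {
      ri <- ri + 1L
      states[ri, ] <- x
      times[ri] <- n * dt
    }
  }
  states <- states[seq_len(ri), , drop = FALSE]
  times <- times[seq_len(ri)]
  structure(list(times = times, states = states, dt = dt, t_end = t_end,
                 system = system, termination = termination, message = msg),
            class = "cr_trajectory")
}

#' @export
print.cr_trajectory <- function(x, ...) {
  cat("<cr_trajectory> ", nrow(x$states), " recorded states, dt = ", format(x$dt),
      ", t in [0, ", format(x$times[length(x$times)]), "], termination: ",
      x$termination, "\n", sep = "")
  if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  cat("final state:\n")
  print(signif(x$states[nrow(x$states), ], 6))
  invisible(x)
}

#' @export
as.data.frame.cr_trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' @export
plot.cr_trajectory <- function(x, which = c("time", "phase"), vars = NULL, ...) {
  which <- match.arg(which)
  nm <- colnames(x$states)
  if (which == "time") {
    graphics::matplot(x$times, x$states, type = "l", lty = 1,
                      xlab = "time", ylab = "density", ...)
    graphics::legend("topright", legend = nm, col = seq_along(nm), lty = 1, bty = "n")
  } else {
    if (is.null(vars)) vars <- utils::tail(nm, 2L)
    graphics::plot(x$states[, vars[1L]], x$states[, vars[2L]], type = "l",
                   xlab = vars[1L], ylab = vars[2L], ...)
  }
  invisible(x)
}

#' Detect transient visits to stationary points
#'
#' Trajectories of these systems travel between saddle points and can linger
#' near an unstable equilibrium for a long time before escaping along its
#' unstable direction. A visit is a maximal time interval during which the
#' Euclidean distance between the trajectory and a stationary point stays
#' below `eps` for at least `min_dur` time units. By default the distance is
#' measured in the resource subspace -- the phase plane in which the
#' saddle-visiting narrative of these models is usually told; an invader
#' density growing from a tiny inoculum does not end a visit before the
#' resources have moved on. Set `space = "full"` to include the consumer
#' components. When several points are simultaneously within `eps`, the
#' nearest one claims the time step, so visits never overlap.
#'
#' @param traj A `cr_trajectory` from [integrate_euler()].
#' @param points List of `stationary_point`s (e.g. from
#'   [find_all_equilibria()]).
#' @param eps Distance threshold \[density\].
#' @param min_dur Minimal duration \[time\].
#' @param space `"resource"` (default) to measure distance over the resource
#'   densities only, or `"full"` for the complete state vector.
#' @return A data frame with columns `point` (label), `t_enter`, `t_exit`,
#'   `min_distance`, in chronological order.
#' @export
detect_visits <- function(traj, points, eps = 0.1, min_dur = 2,
                          space = c("resource", "full")) {
  stopifnot(inherits(traj, "cr_trajectory"))
  space <- match.arg(space)
  if (inherits(points, "stationary_point")) points <- list(points)
  empty <- data.frame(point = character(0), t_enter = numeric(0),
                      t_exit = numeric(0), min_distance = numeric(0))
  if (!length(points)) return(empty)
  if (eps <= 0 || min_dur <= 0) stop("'eps' and 'min_dur' must be > 0", call. = FALSE)
  cols <- if (space == "resource") names(traj$system$resources) else colnames(traj$states)
  S <- traj$states[, cols, drop = FALSE]
  n <- nrow(S)
  D <- vapply(points, function(p)
    sqrt(rowSums((S - matrix(p$state[cols], n, length(cols), byrow = TRUE))^2)),
    numeric(n))
  D <- matrix(D, nrow = n)
  nearest <- max.col(-D, ties.method = "first")
  d_near <- D[cbind(seq_len(n), nearest)]
  lab <- ifelse(d_near < eps, nearest, 0L)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L
  out <- empty
  for (i in which(keep)) {
    t_enter <- traj$times[starts[i]]
    t_exit <- traj$times[ends[i]]
    if (t_exit - t_enter < min_dur) next
    pi <- r$values[i]
    out <- rbind(out, data.frame(
      point = point_label(points[[pi]]),
      t_enter = t_enter, t_exit = t_exit,
      min_distance = min(D[starts[i]:ends[i], pi])))
  }
  out[order(out$t_enter), , drop = FALSE]
}
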