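# Worked example scenarios and the random-system sampler --------------------
#
# Each preset bundles a parameter set, an initial state and a note on the
# expected qualitative outcome. The four 2c2r presets share one parameter
# table (half-saturations k_PA = 0.9, k_PB = 0.7, k_RA = 0.8, k_RB = 1 give
# isocline corners P_A = 0.45, P_B = 0.35, R_A = 0.4, R_B = 0.5).

sys_1c1r <- function(f_mB = 2.5, k_RB = 1, m_B = 1, a_R = 1, s_R = 1, q_RB = 1) {
  cr_system(
    resources = list(resource("R", a = a_R, s = s_R)),
    consumers = list(consumer("B", m = m_B,
                              growth = growth_holling2(f_mB, c(R = k_RB)),
                              q = c(R = q_RB))))
}

sys_2c1r <- function(s_R, a_R = 1,
                     m_A = 1, q_RA = 1, k_RA = 1, f_mA = 3,
                     m_B = 1, q_RB = 1, k_RB = 1, f_mB = 2) {
  cr_system(
    resources = list(resource("R", a = a_R, s = s_R)),
    consumers = list(
      consumer("A", m = m_A, growth = growth_holling2(f_mA, c(R = k_RA)), q = c(R = q_RA)),
      consumer("B", m = m_B, growth = growth_holling2(f_mB, c(R = k_RB)), q = c(R = q_RB))))
}

sys_1c2r <- function(s_P, s_R = 1, a_P = 1, a_R = 1,
                     m_B = 1, f_mB = 3, k_PB = 1, k_RB = 1,
                     q_PB = 1, q_RB = 1) {
  cr_system(
    resources = list(resource("P", a = a_P, s = s_P),
                     resource("R", a = a_R, s = s_R)),
    consumers = list(consumer("B", m = m_B,
                              growth = growth_liebig(f_mB, c(P = k_PB, R = k_RB)),
                              q = c(P = q_PB, R = q_RB))))
}

sys_2c2r <- function(s_P = 1, s_R = 1, a_P = 1, a_R = 1,
                     q_PA = 1, q_RA = 0.8, q_PB = 0.8, q_RB = 1,
                     m_A = 1, f_mA = 3, k_PA = 0.9, k_RA = 0.8,
                     m_B = 1, f_mB = 3, k_PB = 0.7, k_RB = 1) {
  cr_system(
    resources = list(resource("P", a = a_P, s = s_P),
                     resource("R", a = a_R, s = s_R)),
    consumers = list(
      consumer("A", m = m_A, growth = growth_liebig(f_mA, c(P = k_PA, R = k_RA)),
               q = c(P = q_PA, R = q_RA)),
      consumer("B", m = m_B, growth = growth_liebig(f_mB, c(P = k_PB, R = k_RB)),
               q = c(P = q_PB, R = q_RB))))
}

scenario_defs <- function() {
  list(
    fig2a = list(system = sys_1c1r(), x0 = c(B = 0.01, R = 0),
                 notes = "stable coexistence node at (B, R) = (1/3, 2/3) after lingering at the trivial saddle"),
    fig2c = list(system = sys_1c1r(a_R = 0.1, q_RB = 0.1), x0 = c(B = 0.01, R = 0),
                 notes = "same stationary densities, slow supply: stable vortex, oscillatory approach"),
    fig3a = list(system = sys_2c1r(s_R = 0.8), x0 = c(A = 0.001, B = 1, R = 0),
                 notes = "B dies out (s_R below its critical level), A grows to its boundary point"),
    fig3b = list(system = sys_2c1r(s_R = 1.2), x0 = c(A = 0.001, B = 1, R = 0),
                 notes = "B holds a transient level near B' = 0.2 before A takes over"),
    fig4a = list(system = sys_1c2r(s_P = 0.9), x0 = c(B = 0.01, P = 0, R = 0),
                 notes = "one consumer, two essential resources: stable coexistence, P-limited"),
    fig4b = list(system = sys_1c2r(s_P = 0.7), x0 = c(B = 0.01, P = 0, R = 0),
                 notes = "lower s_P: same stationary P, lower B, higher R"),
    fig4c = list(system = sys_1c2r(s_P = 0.9, a_P = 0.1, a_R = 0.1, q_PB = 0.1, q_RB = 0.1),
                 x0 = c(B = 0.01, P = 0, R = 0),
                 notes = "a and q divided by ten: same stationary point, stable vortex"),
    fig5a = list(system = sys_2c2r(), x0 = c(A = 0.001, B = 0.01, P = 0, R = 0.5),
                 notes = "supply point -> B-point -> stable coexistence (A* = 0.4167, B* = 0.1667)"),
    fig5c = list(system = sys_2c2r(), x0 = c(A = 0, B = 0.01, P = 0, R = 0.5),
                 notes = "A strictly absent: ends at the B-point (0.5, 0.6, 0.5)"),
    fig5e = list(system = sys_2c2r(), x0 = c(A = 0.001, B = 0, P = 0, R = 0.5),
                 notes = "B strictly absent: ends at the A-point (0.55, 0.45, 0.56)"),
    fig6a = list(system = sys_2c2r(s_R = 0.8), x0 = c(A = 1e-4, B = 0.01, P = 0.8, R = 1),
                 notes = "supply point outside the wedge: supply -> B-point -> stable A-point (0.5, 0.5, 0.4)"),
    fig6c = list(system = sys_2c2r(s_P = 0.8), x0 = c(A = 1e-4, B = 0.01, P = 0.8, R = 1),
                 notes = "mirrored case: ends at the stable B-point (0.5, 0.4, 0.5)"),
    fig7a = list(system = sys_2c2r(q_PA = 0.8, q_RA = 1, q_PB = 1, q_RB = 0.8),
                 x0 = c(A = 0.01, B = 0.05, P = 0, R = 0.5),
                 notes = "consumption ratios favour own limiting resource: coexistence is a saddle; this start ends at the B-point"),
    fig7c = list(system = sys_2c2r(q_PA = 0.8, q_RA = 1, q_PB = 1, q_RB = 0.8),
                 x0 = c(A = 0.01, B = 0.03, P = 0.8, R = 0),
                 notes = "other basin: ends at the A-point"),
    fig8 = list(system = sys_2c2r(a_P = 0.1, a_R = 0.1,
                                  q_PA = 0.1, q_RA = 0.08, q_PB = 0.08, q_RB = 0.1),
                x0 = c(A = 0.001, B = 0.01, P = 0, R = 0.5),
                notes = "a and q divided by ten: same stationary points, oscillatory approach to a stable vortex")
  )
}

#' Names of the bundled scenarios
#' @return Character vector of preset names.
#' @export
scenario_names <- function() names(scenario_defs())

#' Retrieve a bundled scenario
#'
#' Each scenario is a fully specified system plus initial state reproducing
#' one of the classical worked examples of the model family (keyed by the
#' figure panels they correspond to: one consumer/one resource `fig2*`, two
#' consumers/one resource `fig3*`, one consumer/two resources `fig4*`, two
#' consumers/two resources `fig5*`--`fig8`).
#'
#' @param name One of [scenario_names()].
#' @return A list with elements `name`, `system`, `x0` and `notes`.
#' @examples
#' scenario("fig2a")$system
#' @export
scenario <- function(name) {
  defs <- scenario_defs()
  if (!is.character(name) || length(name) != 1L || !name %in% names(defs))
    stop_config("unknown scenario '", paste(name, collapse = ","),
                "'; available: ", paste(names(defs), collapse = ", "))
  d <- defs[[name]]
  d$x0 <- as_state(d$system, d$x0[state_names(d$system)])
  c(list(name = name), d)
}

#' Run the full analysis for a bundled scenario
#'
#' Enumerates equilibria, classifies every feasible point, integrates the
#' trajectory from the scenario's initial state, and detects transient
#' visits to the feasible stationary points.
#'
#' @param name One of [scenario_names()].
#' @param dt,t_end Overrides for [integrate_euler()] (defaults as there).
#' @param eps,min_dur,space Visit-detection parameters, see [detect_visits()].
#' @return A `cr_report`: the scenario, the equilibria table (with classes),
#'   the classification objects, the trajectory and the visit table.
#' @examples
#' \donttest{
#' rep <- run_scenario("fig2a")
#' rep$visits
#' }
#' @export
run_scenario <- function(name, dt = NULL, t_end = NULL, eps = 0.1, min_dur = 2,
                         space = c("resource", "full")) {
  sc <- scenario(name)
  eq <- find_all_equilibria(sc$system)
  cls <- lapply(eq, function(p) classify(sc$system, p))
  traj <- integrate_euler(sc$system, sc$x0, dt = dt, t_end = t_end)
  feas <- Filter(function(p) p$feasible, eq)
  visits <- detect_visits(traj, feas, eps = eps, min_dur = min_dur, space = space)
  tab <- as.data.frame(eq)
  tab$class <- vapply(cls, `[[`, character(1), "class")
  structure(list(scenario = sc, equilibria = eq, table = tab,
                 classifications = cls, trajectory = traj, visits = visits),
            class = "cr_report")
}

#' @export
print.cr_report <- function(x, ...) {
  cat("<cr_report> scenario '", x$scenario$name, "': ", x$scenario$notes, "\n\n", sep = "")
  print(x$table, digits = 4)
  cat("\nfinal state at t =", format(x$trajectory$times[length(x$trajectory$times)]), ":\n")
  print(signif(x$trajectory$states[nrow(x$trajectory$states), ], 4))
  if (nrow(x$visits)) {
    cat("\ntransient visits:\n")
    print(x$visits, digits = 4)
  }
  invisible(x)
}

#' Sample a random system for property testing
#'
#' Draws positive parameters log-uniformly from fixed ranges (rates `a`, `m`,
#' `f_max` from \[0.05, 5\]; densities `k`, `s` from \[0.1, 5\]; conversion
#' factors `q` from \[0.1, 2\]) for one of the four supported configurations.
#' One-resource consumers get Holling II growth, two-resource consumers
#' Liebig-minimum growth, matching the closed-form machinery. Fully
#' reproducible: the same `seed` yields the same system.
#'
#' @param seed Optional integer seed (sets the RNG locally via [set.seed()]).
#' @param shape `"any"` (uniformly among the four) or one of `"1c1r"`,
#'   `"2c1r"`, `"1c2r"`, `"2c2r"`.
#' @return A [cr_system()] object.
#' @examples
#' sample_system(seed = 1, shape = "2c2r")
#' @export
sample_system <- function(seed = NULL, shape = c("any", "1c1r", "2c1r", "1c2r", "2c2r")) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  if (shape == "any") shape <- sample(c("1c1r", "2c1r", "1c2r", "2c2r"), 1L)
  nc <- if (substr(shape, 1, 1) == "1") 1L else 2L
  nr <- if (substr(shape, 3, 3) == "1") 1L else 2L
  rids <- if (nr == 1L) "R" else c("P", "R")
  cids <- if (nc == 1L) "B" else c("A", "B")
  resources <- lapply(rids, function(id)
    resource(id, a = runif_log(1, 0.05, 5), s = runif_log(1, 0.1, 5)))
  consumers <- lapply(cids, function(id) {
    f_max <- runif_log(1, 0.05, 5)
    k <- stats::setNames(runif_log(nr, 0.1, 5), rids)
    growth <- if (nr == 1L) growth_holling2(f_max, k) else growth_liebig(f_max, k)
    consumer(id, m = runif_log(1, 0.05, 5), growth = growth,
             q = stats::setNames(runif_log(nr, 0.1, 2), rids))
  })
  cr_system(resources, consumers)
}
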