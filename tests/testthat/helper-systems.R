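# Shared fixtures: all built in code, no files.

fig2a_sys <- function() scenario("fig2a")$system
fig5_sys <- function() scenario("fig5a")$system

# A random non-negative state for a system (components in [0, 2.5]).
rand_state <- function(sys) {
  nm <- c(names(sys$consumers), names(sys$resources))
  stats::setNames(stats::runif(length(nm), 0, 2.5), nm)
}

# A random strictly positive state away from Liebig corners with
# probability 1 (continuous draws).
rand_smooth_state <- function(sys) {
  nm <- c(names(sys$consumers), names(sys$resources))
  stats::setNames(stats::runif(length(nm), 0.2, 2), nm)
}

# Draw 2c2r systems until `n` of them have a feasible coexistence point.
# Returns list(systems, points). `max_tries` guards against a degenerate run.
sample_feasible_2c2r <- function(n, max_tries = 400 * n) {
  systems <- vector("list", n)
  points <- vector("list", n)
  found <- 0L
  for (i in seq_len(max_tries)) {
    sys <- sample_system(shape = "2c2r")
    pts <- tryCatch(coexistence_2c2r(sys),
                    error = function(e) list())
    feas <- Filter(function(p) p$feasible && !p$on_corner, pts)
    if (length(feas)) {
      found <- found + 1L
      systems[[found]] <- sys
      points[[found]] <- feas[[1L]]
      if (found == n) break
    }
  }
  list(systems = systems[seq_len(found)], points = points[seq_len(found)])
}

max_abs <- function(x) max(abs(x))
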