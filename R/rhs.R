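# Build a fast right-hand-side evaluator for a system.
#
# The returned closure maps a state vector (consumers first, resources
# second) to its time derivative
#   dN_i/dt = (f_i(R) - m_i) N_i
#   dR_j/dt = a_j (s_j - R_j) - sum_i q_ji f_i(R) N_i
# Entries in [-neg_tol, 0) are treated as exactly 0 inside the growth
# functions (Euler round-off); more negative entries raise an error when
# check = TRUE. check = FALSE skips all domain checks (used by the
# finite-difference Jacobian, where tiny negative excursions are deliberate).
make_rhs <- function(system, neg_tol = 1e-9, check = TRUE) {
  rs <- system$resources; cs <- system$consumers
  n_r <- length(rs); n_c <- length(cs)
  a <- vapply(rs, `[[`, numeric(1), "a")
  s <- vapply(rs, `[[`, numeric(1), "s")
  m <- vapply(cs, `[[`, numeric(1), "m")
  f_max <- vapply(cs, function(co) co$growth$f_max, numeric(1))
  variant <- vapply(cs, function(co) co$growth$variant, character(1))
  rid <- names(rs)
  Q <- q_matrix(system)
  K <- matrix(NA_real_, n_r, n_c, dimnames = list(rid, names(cs)))
  hol <- integer(n_c)
  for (ci in seq_len(n_c)) {
    kk <- cs[[ci]]$growth$k
    K[names(kk), ci] <- kk
    if (variant[ci] == "holling2") hol[ci] <- match(names(kk), rid)
  }
  is_hol <- variant == "holling2"
  ic <- seq_len(n_c); ir <- n_c + seq_len(n_r)
  d <- n_c + n_r

  function(state) {
    if (length(state) != d)
      stop("state has length ", length(state), " but system dimension is ", d,
           call. = FALSE)
    if (check) {
      if (any(!is.finite(state))) stop("state entries must be finite", call. = FALSE)
      if (any(state < -neg_tol))
        stop(errorCondition(
          paste0("state entry below -", format(neg_tol), "; not a valid density"),
          class = c("chemocomp_negative_state", "error", "condition")))
    }
    N <- state[ic]
    R <- state[ir]
    Rg <- R
    if (check && any(Rg < 0)) Rg[Rg < 0] <- 0  # round-off negatives: no growth
    f <- numeric(n_c)
    for (ci in seq_len(n_c)) {
      if (is_hol[ci]) {
        r <- Rg[hol[ci]]
        f[ci] <- f_max[ci] * r / (r + K[hol[ci], ci])
      } else {
        f[ci] <- f_max[ci] * min(Rg / (Rg + K[, ci]))
      }
    }
    c((f - m) * N, a * (s - R) - as.vector(Q %*% (f * N)))
  }
}

#' Right-hand side of the consumer--resource ODE system
#'
#' Time derivative of a state under the model dynamics: consumers grow at
#' their resource-dependent rate minus mortality, resources follow chemostat
#' supply minus consumption (growth times conversion factor, summed over
#' consumers).
#'
#' @param system A [cr_system()] object.
#' @param state State vector in the canonical layout (see [cr_state()]).
#'   Entries must be `>= -1e-9`; values in `[-1e-9, 0)` are treated as zero
#'   inside the growth functions.
#' @return Named derivative vector with the same layout as `state`.
#' @examples
#' sys <- example_system_1c1r()
#' cr_rhs(sys, cr_state(sys, B = 0, R = 1))  # supply point: zero vector
#' @export
cr_rhs <- function(system, state) {
  stopifnot(inherits(system, "cr_system"))
  state <- as_state(system, state)
  stats::setNames(make_rhs(system)(state), state_names(system))
}
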