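#' Holling type II functional response
#'
#' Relative growth rate on a single resource, \eqn{f(R) = f_{max} R/(R + k)}:
#' zero at zero resource, monotone increasing, saturating below `f_max`.
#'
#' @param R Resource density, non-negative (vectorised).
#' @param f_max Maximal relative growth rate (> 0) \[1/time\].
#' @param k Half-saturation constant (> 0) \[density\].
#' @return Growth rate(s) in `[0, f_max)` \[1/time\].
#' @examples
#' holling_growth(1, f_max = 2.5, k = 1)  # 1.25
#' @export
holling_growth <- function(R, f_max, k) {
  if (!is.numeric(R) || any(!is.finite(R))) stop("'R' must be finite numeric", call. = FALSE)
  if (any(R < 0)) stop("resource density must be non-negative", call. = FALSE)
  check_scalar(f_max, "f_max"); check_scalar(k, "k")
  if (f_max <= 0 || k <= 0) stop("'f_max' and 'k' must be positive", call. = FALSE)
  f_max * R / (R + k)
}

#' Liebig minimum growth on essential resources
#'
#' Growth limited by the scarcest essential resource:
#' \eqn{f = f_{max} \min_j R_j/(R_j + k_j)}. The return value carries an
#' attribute `limiting` naming the active (minimising) resource; exact ties
#' are resolved towards the lowest-index resource and flagged with attribute
#' `on_corner = TRUE`.
#'
#' @param R Named numeric vector of resource densities (non-negative); must
#'   contain every resource named in `k`.
#' @param f_max Maximal relative growth rate (> 0) \[1/time\].
#' @param k Named numeric vector of half-saturation constants (> 0).
#' @return Growth rate \[1/time\] with attributes `limiting` and `on_corner`.
#' @examples
#' liebig_growth(c(P = 0.45, R = 1), f_max = 3, k = c(P = 0.9, R = 0.8))
#' @export
liebig_growth <- function(R, f_max, k) {
  if (!is.numeric(k) || is.null(names(k))) stop_config("'k' must be a named numeric vector")
  if (!is.numeric(R) || is.null(names(R))) stop_config("'R' must be a named numeric vector")
  missing_r <- setdiff(names(k), names(R))
  if (length(missing_r))
    stop_config("missing resource densities: ", paste(missing_r, collapse = ", "))
  check_scalar(f_max, "f_max")
  if (f_max <= 0 || any(k <= 0)) stop("'f_max' and 'k' must be positive", call. = FALSE)
  R <- R[names(k)]
  if (any(R < 0)) stop("resource densities must be non-negative", call. = FALSE)
  ratio <- R / (R + k)
  i <- which.min(ratio)          # ties resolve to the lowest index
  corner <- sum(ratio == ratio[i]) > 1L
  structure(f_max * ratio[[i]], limiting = names(k)[i], on_corner = corner)
}

#' Chemostat supply term
#'
#' Net resource replenishment \eqn{g(R) = a (s - R)}: positive below the
#' stable level `s`, zero exactly at it, negative above.
#'
#' @param R Resource density, non-negative (vectorised).
#' @param spec A [resource()] object (or any list with elements `a` and `s`).
#' @return Supply rate(s) \[density/time\].
#' @examples
#' chemostat_supply(0.5, resource("R", a = 1, s = 1))  # 0.5
#' @export
chemostat_supply <- function(R, spec) {
  if (!is.numeric(R) || any(!is.finite(R))) stop("'R' must be finite numeric", call. = FALSE)
  if (any(R < 0)) stop("resource density must be non-negative", call. = FALSE)
  if (!is.list(spec) || is.null(spec$a) || is.null(spec$s))
    stop_config("'spec' must provide supply rate 'a' and stable level 's'")
  spec$a * (spec$s - R)
}

# Growth rate of one consumer at resource densities R (named, full system).
# Internal; no domain checks beyond what the variants enforce.
growth_rate <- function(consumer, R) {
  g <- consumer$growth
  if (g$variant == "holling2") {
    r <- R[[names(g$k)]]
    g$f_max * r / (r + g$k[[1L]])
  } else {
    as.numeric(liebig_growth(R, g$f_max, g$k))
  }
}

# Gradient of a consumer's growth rate with respect to every resource density,
# evaluated on the active branch for liebig_min. Returns a named vector over
# all resources in `rids`; attribute `on_corner` flags an exact Liebig tie.
growth_gradient <- function(consumer, R, rids) {
  g <- consumer$growth
  grad <- stats::setNames(numeric(length(rids)), rids)
  corner <- FALSE
  if (g$variant == "holling2") {
    rid <- names(g$k)
    r <- R[[rid]]
    grad[rid] <- g$f_max * g$k[[1L]] / (r + g$k[[1L]])^2
  } else {
    kk <- g$k
    ratio <- R[names(kk)] / (R[names(kk)] + kk)
    i <- which.min(ratio)
    corner <- sum(ratio == ratio[i]) > 1L
    rid <- names(kk)[i]
    grad[rid] <- g$f_max * kk[[i]] / (R[[rid]] + kk[[i]])^2
  }
  structure(grad, on_corner = corner)
}
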