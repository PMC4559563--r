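#' Define a chemostat resource
#'
#' A resource replenished by chemostat supply \eqn{g(R) = a (s - R)}:
#' exponential relaxation towards the stable level `s` at dilution rate `a`.
#'
#' @param id Short character label, e.g. `"R"` or `"P"`.
#' @param a Supply/dilution rate, must be positive \[1/time\].
#' @param s Stable supply level, must be non-negative \[density\].
#' @return An object of class `cr_resource`.
#' @seealso [consumer()], [cr_system()]
#' @examples
#' resource("R", a = 1, s = 1)
#' @export
resource <- function(id, a, s) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_scalar(a, "a")
  check_scalar(s, "s")
  if (a <= 0) stop_config("resource '", id, "': supply rate 'a' must be > 0")
  if (s < 0) stop_config("resource '", id, "': stable level 's' must be >= 0")
  structure(list(id = id, a = a, s = s), class = "cr_resource")
}

#' Holling type II growth model
#'
#' Saturating growth on a single resource, \eqn{f(R) = f_{max} R / (R + k)}.
#'
#' @param f_max Maximal relative growth rate (> 0) \[1/time\].
#' @param k Named length-1 numeric: half-saturation constant (> 0) for the
#'   single resource the consumer feeds on, e.g. `c(R = 1)`.
#' @return An object of class `cr_growth`.
#' @examples
#' growth_holling2(f_max = 2.5, k = c(R = 1))
#' @export
growth_holling2 <- function(f_max, k) {
  check_scalar(f_max, "f_max")
  if (f_max <= 0) stop_config("'f_max' must be > 0")
  if (!is.numeric(k) || length(k) != 1L || is.null(names(k)) || !nzchar(names(k)))
    stop_config("holling2 growth needs exactly one named half-saturation constant, e.g. k = c(R = 1)")
  if (k <= 0) stop_config("half-saturation constant must be > 0")
  structure(list(variant = "holling2", f_max = f_max, k = k), class = "cr_growth")
}

#' Liebig minimum growth model for essential resources
#'
#' Growth limited by the scarcest of several essential resources:
#' \eqn{f(R_1, R_2, \ldots) = f_{max} \min_j R_j / (R_j + k_j)}.
#'
#' @param f_max Maximal relative growth rate (> 0) \[1/time\].
#' @param k Named numeric vector of half-saturation constants, one per
#'   essential resource, e.g. `c(P = 0.9, R = 0.8)`. All must be positive.
#' @return An object of class `cr_growth`.
#' @examples
#' growth_liebig(f_max = 3, k = c(P = 0.9, R = 0.8))
#' @export
growth_liebig <- function(f_max, k) {
  check_scalar(f_max, "f_max")
  if (f_max <= 0) stop_config("'f_max' must be > 0")
  if (!is.numeric(k) || length(k) < 1L || is.null(names(k)) || any(!nzchar(names(k))))
    stop_config("liebig_min growth needs a named vector of half-saturation constants")
  if (anyDuplicated(names(k))) stop_config("duplicate resource ids in 'k'")
  if (any(k <= 0)) stop_config("all half-saturation constants must be > 0")
  structure(list(variant = "liebig_min", f_max = f_max, k = k), class = "cr_growth")
}

#' Define a consumer
#'
#' @param id Short character label, e.g. `"A"` or `"B"`.
#' @param m Mortality rate, must be positive \[1/time\].
#' @param growth A growth model from [growth_holling2()] or [growth_liebig()].
#' @param q Named numeric vector of conversion factors (resource removed per
#'   unit consumer produced); all non-negative, at least one positive.
#' @return An object of class `cr_consumer`.
#' @examples
#' consumer("B", m = 1, growth = growth_holling2(2.5, c(R = 1)), q = c(R = 1))
#' @export
consumer <- function(id, m, growth, q) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  check_scalar(m, "m")
  if (m <= 0) stop_config("consumer '", id, "': mortality 'm' must be > 0")
  if (!inherits(growth, "cr_growth")) stop_config("'growth' must be a cr_growth object")
  if (!is.numeric(q) || length(q) < 1L || is.null(names(q)) || any(!nzchar(names(q))))
    stop_config("consumer '", id, "': 'q' must be a named numeric vector")
  if (anyDuplicated(names(q))) stop_config("consumer '", id, "': duplicate resource ids in 'q'")
  if (any(q < 0)) stop_config("consumer '", id, "': conversion factors must be >= 0")
  if (all(q == 0)) stop_config("consumer '", id, "': at least one conversion factor must be > 0")
  structure(list(id = id, m = m, growth = growth, q = q), class = "cr_consumer")
}

#' Assemble a consumer--resource system
#'
#' Bundles resources and consumers into a validated system object. Resource
#' and consumer ids must be unique; every half-saturation and conversion key
#' must refer to a declared resource; a `holling2` consumer references exactly
#' one resource while a `liebig_min` consumer must reference every resource.
#'
#' @param resources List of [resource()] objects (order defines the state
#'   layout of the resource block).
#' @param consumers List of [consumer()] objects (order defines the state
#'   layout of the consumer block).
#' @return An object of class `cr_system`.
#' @examples
#' sys <- cr_system(
#'   resources = list(resource("R", a = 1, s = 1)),
#'   consumers = list(consumer("B", m = 1,
#'     growth = growth_holling2(2.5, c(R = 1)), q = c(R = 1)))
#' )
#' sys
#' @export
cr_system <- function(resources, consumers) {
  if (inherits(resources, "cr_resource")) resources <- list(resources)
  if (inherits(consumers, "cr_consumer")) consumers <- list(consumers)
  if (!length(resources) || !all(vapply(resources, inherits, logical(1), "cr_resource")))
    stop_config("'resources' must be a non-empty list of cr_resource objects")
  if (!length(consumers) || !all(vapply(consumers, inherits, logical(1), "cr_consumer")))
    stop_config("'consumers' must be a non-empty list of cr_consumer objects")
  rid <- vapply(resources, `[[`, character(1), "id")
  cid <- vapply(consumers, `[[`, character(1), "id")
  if (anyDuplicated(c(rid, cid)))
    stop_config("resource/consumer ids must be unique, got: ",
                paste(c(rid, cid), collapse = ", "))
  for (co in consumers) {
    kk <- names(co$growth$k)
    bad <- setdiff(kk, rid)
    if (length(bad))
      stop_config("consumer '", co$id, "': half-saturation key(s) ",
                  paste(bad, collapse = ", "), " do not match any declared resource")
    if (co$growth$variant == "liebig_min" && !setequal(kk, rid))
      stop_config("consumer '", co$id, "': liebig_min growth must reference every resource (",
                  paste(rid, collapse = ", "), ")")
    badq <- setdiff(names(co$q), rid)
    if (length(badq))
      stop_config("consumer '", co$id, "': conversion key(s) ",
                  paste(badq, collapse = ", "), " do not match any declared resource")
  }
  names(resources) <- rid
  names(consumers) <- cid
  structure(list(resources = resources, consumers = consumers), class = "cr_system")
}

#' Conversion matrix of a system
#'
#' The matrix Q with one row per resource and one column per consumer holding
#' the conversion factors q (zero where a consumer does not use a resource).
#' Its determinant decides solvability of the two-consumer/two-resource
#' coexistence equations and enters the determinant stability criterion.
#'
#' @param system A [cr_system()] object.
#' @return Numeric matrix, `length(resources)` x `length(consumers)`.
#' @export
q_matrix <- function(system) {
  stopifnot(inherits(system, "cr_system"))
  rid <- names(system$resources)
  cid <- names(system$consumers)
  Q <- matrix(0, length(rid), length(cid), dimnames = list(rid, cid))
  for (co in system$consumers) Q[names(co$q), co$id] <- co$q
  Q
}

# Canonical state layout: consumers first, resources second, declaration order.
state_names <- function(system) {
  c(names(system$consumers), names(system$resources))
}

#' Build a state vector for a system
#'
#' States are named numeric vectors laid out as all consumer densities (in
#' declaration order) followed by all resource densities. Components omitted
#' from `...` default to zero.
#'
#' @param system A [cr_system()] object.
#' @param ... Named densities, e.g. `B = 0.01, R = 0`.
#' @return Named numeric state vector.
#' @examples
#' sys <- example_system_1c1r()
#' cr_state(sys, B = 0.01)  # R defaults to 0
#' @export
cr_state <- function(system, ...) {
  stopifnot(inherits(system, "cr_system"))
  vals <- c(...)
  nm <- state_names(system)
  x <- stats::setNames(numeric(length(nm)), nm)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!names(vals) %in% nm))
      stop_config("state components must be named after declared ids: ",
                  paste(nm, collapse = ", "))
    x[names(vals)] <- vals
  }
  x
}

# Coerce/validate a user-supplied state against the system layout.
as_state <- function(system, x) {
  nm <- state_names(system)
  if (length(x) != length(nm))
    stop("state has length ", length(x), " but system dimension is ",
         length(nm), call. = FALSE)
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    if (!setequal(names(x), nm)) stop_config("state names do not match system ids")
    x <- x[nm]
  } else names(x) <- nm
  if (any(!is.finite(x))) stop("state entries must be finite", call. = FALSE)
  x
}

n_consumers <- function(system) length(system$consumers)
n_resources <- function(system) length(system$resources)

# Largest rate parameter in the system; sets the scale for step sizes and
# hyperbolicity tolerances.
rate_scale <- function(system) {
  max(vapply(system$resources, `[[`, numeric(1), "a"),
      vapply(system$consumers, `[[`, numeric(1), "m"),
      vapply(system$consumers, function(co) co$growth$f_max, numeric(1)))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("chemocomp_config_error", "error", "condition")))
}

check_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'", what, "' must be a finite numeric scalar")
  invisible(x)
}

#' @export
print.cr_system <- function(x, ...) {
  cat("<cr_system> ", n_consumers(x), " consumer(s), ",
      n_resources(x), " resource(s)\n", sep = "")
  for (r in x$resources)
    cat(sprintf("  resource %-3s a = %g, s = %g\n", r$id, r$a, r$s))
  for (co in x$consumers) {
    g <- co$growth
    cat(sprintf("  consumer %-3s m = %g, %s(f_max = %g, k: %s), q: %s\n",
                co$id, co$m, g$variant, g$f_max,
                paste(sprintf("%s=%g", names(g$k), g$k), collapse = " "),
                paste(sprintf("%s=%g", names(co$q), co$q), collapse = " ")))
  }
  invisible(x)
}

#' A ready-made one-consumer/one-resource example system
#'
#' Holling II consumer with `f_max = 2.5`, `k = 1`, `m = 1` on a chemostat
#' resource with `a = 1`, `s = 1`, `q = 1` -- the canonical stable-coexistence
#' configuration used throughout the documentation.
#'
#' @return A [cr_system()] object.
#' @export
example_system_1c1r <- function() {
  cr_system(
    resources = list(resource("R", a = 1, s = 1)),
    consumers = list(consumer("B", m = 1,
                              growth = growth_holling2(2.5, c(R = 1)),
                              q = c(R = 1)))
  )
}
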