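# System configuration I/O --------------------------------------------------
#
# Schema (JSON or YAML): top-level keys
#   resources: list of {id, a, s}
#   consumers: list of {id, m, growth: {variant, f_max, k: {rid: value}},
#               q: {rid: value}}
# Validation happens in the constructors, so malformed documents fail with
# informative chemocomp_config_error messages.

system_to_list <- function(system) {
  list(
    resources = lapply(unname(system$resources), function(r)
      list(id = r$id, a = r$a, s = r$s)),
    consumers = lapply(unname(system$consumers), function(co)
      list(id = co$id, m = co$m,
           growth = list(variant = co$growth$variant,
                         f_max = co$growth$f_max,
                         k = as.list(co$growth$k)),
           q = as.list(co$q)))
  )
}

list_to_system <- function(x) {
  if (!is.list(x) || is.null(x$resources) || is.null(x$consumers))
    stop_config("configuration must have top-level keys 'resources' and 'consumers'")
  need <- function(el, key, where) {
    if (is.null(el[[key]])) stop_config("missing key '", key, "' in ", where)
    el[[key]]
  }
  resources <- lapply(x$resources, function(r)
    resource(need(r, "id", "a resource entry"),
             a = as.numeric(need(r, "a", "a resource entry")),
             s = as.numeric(need(r, "s", "a resource entry"))))
  as_dbl <- function(v) stats::setNames(as.numeric(v), names(v))
  consumers <- lapply(x$consumers, function(co) {
    g <- need(co, "growth", "a consumer entry")
    kv <- as_dbl(unlist(need(g, "k", "a growth entry")))
    variant <- need(g, "variant", "a growth entry")
    growth <- switch(variant,
                     holling2 = growth_holling2(as.numeric(need(g, "f_max", "a growth entry")), kv),
                     liebig_min = growth_liebig(as.numeric(need(g, "f_max", "a growth entry")), kv),
                     stop_config("unknown growth variant '", variant,
                                 "' (expected holling2 or liebig_min)"))
    consumer(need(co, "id", "a consumer entry"),
             m = as.numeric(need(co, "m", "a consumer entry")),
             growth = growth,
             q = as_dbl(unlist(need(co, "q", "a consumer entry"))))
  })
  cr_system(resources, consumers)
}

#' Write a system configuration to JSON or YAML
#'
#' @param system A [cr_system()] object.
#' @param path Output file; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return `path`, invisibly.
#' @seealso [read_system()]
#' @export
write_system <- function(system, path) {
  stopifnot(inherits(system, "cr_system"))
  x <- system_to_list(system)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("the 'yaml' package is required for YAML output")
    writeLines(yaml::as.yaml(x, precision = 17L), path)
  } else stop_config("unsupported configuration format '.", ext,
                     "' (use .json, .yaml or .yml)")
  invisible(path)
}

#' Read a system configuration from JSON or YAML
#'
#' @param path Configuration file; format chosen by extension.
#' @return A validated [cr_system()] object.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_system(example_system_1c1r(), f)
#' read_system(f)
#' @export
read_system <- function(path) {
  if (!file.exists(path)) stop_config("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_config("the 'yaml' package is required for YAML input")
    yaml::read_yaml(path)
  } else stop_config("unsupported configuration format '.", ext,
                     "' (use .json, .yaml or .yml)")
  list_to_system(x)
}
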