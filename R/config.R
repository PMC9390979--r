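#' Read a model configuration file
#'
#' Parses a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file into
#' a plain list.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop(sprintf("unsupported config extension '%s' (use yaml or json)", ext),
         call. = FALSE)
  }
}

check_keys <- function(x, valid, where) {
  bad <- setdiff(names(x), valid)
  if (length(bad)) {
    stop(sprintf("unknown key(s) in %s: %s (valid: %s)", where,
                 paste(bad, collapse = ", "),
                 paste(valid, collapse = ", ")), call. = FALSE)
  }
}

#' Build a circuit network from a configuration list or file
#'
#' The configuration holds a `mode` (see [resource_context()]), resource
#' capacities, either explicit per-module rate constants (`modules`, a list
#' of two blocks with keys `g`, `k_m`, `k_p`, `d_m`, `d_p`) or a
#' `calibration` block (`target_m`, `target_p`) that rescales the constants
#' via [match_means()], and an optional `controller` block with the
#' [controller_spec()] fields.
#'
#' @param config List or path accepted by [read_config()].
#' @return A `reaction_network`.
#' @examples
#' circuit_from_config(list(mode = "competitive", J_p = 10, J_g = 20,
#'                          calibration = list(target_m = 10, target_p = 100)))
#' @export
circuit_from_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  check_keys(config, c("mode", "J_p", "J_g", "frozen_means", "modules",
                       "calibration", "controller"), "config")
  if (is.null(config$mode)) stop("config needs a 'mode'", call. = FALSE)
  ctx <- resource_context(config$mode,
                          J_p = config$J_p %||% 10,
                          J_g = config$J_g %||% 20,
                          frozen_means = unlist(config$frozen_means))
  mods <- if (!is.null(config$modules)) {
    if (length(config$modules) != 2L) {
      stop("'modules' must list exactly two modules", call. = FALSE)
    }
    lapply(config$modules, function(m) {
      check_keys(m, c("g", "k_m", "k_p", "d_m", "d_p"), "module block")
      do.call(gene_module, m)
    })
  } else {
    list(gene_module(), gene_module())
  }
  if (!is.null(config$calibration)) {
    cal <- config$calibration
    check_keys(cal, c("target_m", "target_p"), "calibration block")
    mods <- match_means(mods, ctx,
                        target_m = unlist(cal$target_m),
                        target_p = unlist(cal$target_p))
  }
  ctrl <- NULL
  if (!is.null(config$controller)) {
    cb <- config$controller
    check_keys(cb, c("ctype", "placement", "S_c", "K_e", "K_b",
                     "dcas_total"), "controller block")
    ctrl <- do.call(controller_spec, cb)
  }
  build_network(mods, ctx, controller = ctrl)
}

#' Serialise network provenance to JSON
#'
#' Writes the network's provenance record (mode, capacities, module
#' parameters, controller) so that result files can be traced back to the
#' exact model that produced them.
#'
#' @param network A `reaction_network`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_provenance <- function(network, path = NULL) {
  js <- jsonlite::toJSON(network$provenance, auto_unbox = TRUE,
                         null = "null", digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(as.character(js), path)
  invisible(path)
}
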