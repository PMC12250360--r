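# Structured configuration: YAML files overriding rate constants, initial
# concentrations, drug definitions, solver options and the top-level seed.

.config_keys <- c("rates", "initial", "drugs", "solver", "seed",
                  "release_ligand_on_unbind", "pulse_release")
.drug_fields <- c("name", "Kd", "dose", "kdegOL", "koff", "kon",
                  "dose_compartment")

#' Load a run configuration
#'
#' Reads a YAML file and merges it over the built-in defaults.  Recognised
#' top-level keys: `rates` (any entry of [default_rates()]), `initial`
#' (any species of [default_initial_state()]), `drugs` (named blocks with
#' fields `Kd`, `dose`, `kdegOL`, `koff`, `kon`, `dose_compartment`,
#' merged over [default_drugs()] or defining new drugs), `solver`
#' (fields of [solver_options()]), `seed`, `release_ligand_on_unbind`,
#' `pulse_release`.  Unknown keys at any level are an error naming the
#' offending key.  An empty file yields the full defaults.
#'
#' @param path YAML file path.
#' @return object of class `run_config` with fully resolved components
#'   and a `hash` of the resolved configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), .config_keys)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rates <- default_rates(if (is.null(raw$rates)) list() else raw$rates)
  initial <- default_initial_state(raw$initial)
  drugs <- default_drugs()
  if (!is.null(raw$drugs)) {
    for (nm in names(raw$drugs)) {
      blk <- raw$drugs[[nm]]
      badf <- setdiff(names(blk), .drug_fields)
      if (length(badf)) {
        stop("unknown drug field(s) in '", nm, "': ",
             paste(badf, collapse = ", "), call. = FALSE)
      }
      base <- if (nm %in% names(drugs)) {
        d <- drugs[[nm]]
        list(name = d$name, Kd = d$Kd, dose = d$dose, kdegOL = d$kdegOL,
             koff = d$koff, dose_compartment = d$dose_compartment)
      } else list(name = nm)
      merged <- modifyList(base, blk)
      if (is.null(merged$Kd) || is.null(merged$dose)) {
        stop("drug '", nm, "' needs at least Kd and dose", call. = FALSE)
      }
      drugs[[nm]] <- do.call(drug_spec, merged)
    }
  }
  solver <- do.call(solver_options,
                    if (is.null(raw$solver)) list() else raw$solver)
  cfg <- structure(list(
    rates = rates, initial = initial, drugs = drugs, solver = solver,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    release_ligand_on_unbind = isTRUE(raw$release_ligand_on_unbind),
    pulse_release = raw$pulse_release
  ), class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

#' Hash of a resolved configuration
#'
#' MD5 of the serialised configuration, embedded in result artifacts for
#' provenance.
#'
#' @param config a `run_config` (or any serialisable object).
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  config$hash <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  seed %d, hash %s\n", x$seed, substr(x$hash, 1, 8)))
  cat(sprintf("  drugs: %s\n", paste(names(x$drugs), collapse = ", ")))
  invisible(x)
}

#' Write a fully resolved configuration as YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  drugs <- lapply(config$drugs, function(d) {
    list(name = d$name, Kd = d$Kd, dose = d$dose, kdegOL = d$kdegOL,
         koff = d$koff, kon = d$kon, dose_compartment = d$dose_compartment)
  })
  yaml::write_yaml(list(
    rates = config$rates,
    initial = as.list(config$initial),
    drugs = drugs,
    solver = unclass(config$solver),
    seed = config$seed,
    hash = config$hash
  ), path)
  invisible(path)
}

#' Write a recovery report (or any result list) as JSON
#'
#' @param x a `recovery_report`, `hill_fit`, `camp_fit` or plain list.
#' @param path output path.
#' @param config optional `run_config` whose hash is embedded.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, config = NULL) {
  obj <- if (inherits(x, "hill_fit")) {
    list(bottom = x$bottom, top = x$top, midpoint = x$midpoint,
         hill_slope = x$hill_slope, se = as.list(x$se),
         direction = x$direction)
  } else if (inherits(x, "camp_fit")) {
    c(as.list(coef(x)), list(amplitude = x$amplitude))
  } else {
    lapply(unclass(x), function(v) if (is.numeric(v)) unname(v) else v)
  }
  if (!is.null(config)) obj$config_hash <- config$hash
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
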