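#' Load a parameter bundle from a YAML or JSON config file
#'
#' Reads a structured config document into validated, typed parameter
#' objects.  The schema mirrors the bundled fixtures under
#' `inst/extdata/`: a top-level `arms` mapping (each arm carrying the
#' [arm_parameters()] fields), and optional `mortality` (list of
#' `age_low`/`age_high`/`p_death` bands), `utilities`
#' (`disease_free`/`local_recurrence`/`metastasis`) and `config` blocks.
#' Unknown keys anywhere in the document are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A parameter bundle of class `apbi_parameters`: a list with
#'   elements `arms` (named list of [arm_parameters()]), `mortality`,
#'   `utilities` and `config` (the latter three may be `NULL` for partial
#'   documents such as sensitivity-variant files).
#' @export
load_parameters <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  parse_parameter_doc(doc, source = path)
}

ARM_FIELDS <- c("p_local_recurrence", "p_bc_death",
                "p_metastasis_from_disease_free",
                "p_metastasis_from_local_recurrence",
                "cost_treatment", "cost_other_direct",
                "cost_annual_maintenance")

reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stopf("unknown key(s) in %s: %s", where, paste(extra, collapse = ", "))
}

parse_parameter_doc <- function(doc, source = "config") {
  reject_unknown(doc, c("arms", "mortality", "utilities", "config"), source)
  if (is.null(doc$arms) || !length(doc$arms))
    stopf("%s: config must define at least one arm under 'arms'", source)
  horizon <- doc$config$horizon %||% 10
  arms <- lapply(names(doc$arms), function(lab) {
    a <- doc$arms[[lab]]
    reject_unknown(a, ARM_FIELDS, paste0("arms$", lab))
    missing <- setdiff(setdiff(ARM_FIELDS, "cost_annual_maintenance"), names(a))
    if (length(missing))
      stopf("arms$%s: missing field(s): %s", lab, paste(missing, collapse = ", "))
    arm_parameters(arm_label = lab,
                   p_local_recurrence = a$p_local_recurrence,
                   p_bc_death = a$p_bc_death,
                   p_metastasis_from_disease_free = a$p_metastasis_from_disease_free,
                   p_metastasis_from_local_recurrence = a$p_metastasis_from_local_recurrence,
                   cost_treatment = a$cost_treatment,
                   cost_other_direct = a$cost_other_direct,
                   cost_annual_maintenance = a$cost_annual_maintenance %||% 0,
                   horizon = horizon)
  })
  names(arms) <- names(doc$arms)

  mortality <- NULL
  if (!is.null(doc$mortality)) {
    m <- doc$mortality
    if (is.data.frame(m)) m <- split(m, seq_len(nrow(m)))
    for (band in m) reject_unknown(band, c("age_low", "age_high", "p_death"),
                                   "mortality band")
    mortality <- mortality_table(
      age_low = vapply(m, function(b) as.numeric(b$age_low), 1),
      age_high = vapply(m, function(b) as.numeric(b$age_high), 1),
      p_death = vapply(m, function(b) as.numeric(b$p_death), 1))
  }

  utilities <- NULL
  if (!is.null(doc$utilities)) {
    reject_unknown(doc$utilities,
                   c("disease_free", "local_recurrence", "metastasis"),
                   "utilities")
    utilities <- utility_set(doc$utilities$disease_free,
                             doc$utilities$local_recurrence,
                             doc$utilities$metastasis)
  }

  config <- NULL
  if (!is.null(doc$config)) {
    cf <- doc$config
    reject_unknown(cf, c("cohort_size", "start_age", "horizon", "cycle_length",
                         "discount_rate_benefits", "discount_rate_costs",
                         "include_maintenance", "maintenance_divisor",
                         "conventions"), "config")
    conv <- if (is.null(cf$conventions)) model_conventions() else {
      cv <- cf$conventions
      reject_unknown(cv, c("bc_death_sources", "death_combination",
                           "discount_timing", "half_cycle_correction"),
                     "config$conventions")
      model_conventions(
        bc_death_sources = cv$bc_death_sources %||% "metastasis",
        death_combination = cv$death_combination %||% "independent",
        discount_timing = cv$discount_timing %||% "first_cycle_undiscounted",
        half_cycle_correction = cv$half_cycle_correction %||% FALSE)
    }
    config <- model_config(
      cohort_size = cf$cohort_size %||% 100,
      start_age = cf$start_age %||% 60,
      horizon = cf$horizon %||% 10,
      cycle_length = cf$cycle_length %||% 1,
      discount_rate_benefits = cf$discount_rate_benefits %||% 0.03,
      discount_rate_costs = cf$discount_rate_costs %||% 0.03,
      include_maintenance = cf$include_maintenance %||% TRUE,
      maintenance_divisor = cf$maintenance_divisor,
      conventions = conv)
  }

  structure(list(arms = arms, mortality = mortality,
                 utilities = utilities, config = config),
            class = "apbi_parameters")
}

#' Serialize a parameter bundle back to YAML
#'
#' Exact inverse of [load_parameters()] on bundles it produced:
#' `load_parameters(write_parameters(p, f))` reproduces `p`.
#'
#' @param params An `apbi_parameters` bundle.
#' @param path Output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  doc <- list(arms = lapply(params$arms, function(a)
    a[setdiff(ARM_FIELDS, character(0))]))
  if (!is.null(params$mortality))
    doc$mortality <- lapply(seq_len(nrow(params$mortality$bands)), function(i)
      as.list(params$mortality$bands[i, ]))
  if (!is.null(params$utilities))
    doc$utilities <- list(disease_free = params$utilities$u_disease_free,
                          local_recurrence = params$utilities$u_local_recurrence,
                          metastasis = params$utilities$u_metastasis)
  if (!is.null(params$config)) {
    cf <- params$config
    doc$config <- list(cohort_size = cf$cohort_size, start_age = cf$start_age,
                       horizon = cf$horizon, cycle_length = cf$cycle_length,
                       discount_rate_benefits = cf$discount_rate_benefits,
                       discount_rate_costs = cf$discount_rate_costs,
                       include_maintenance = cf$include_maintenance,
                       conventions = unclass(cf$conventions))
    if (!is.null(cf$maintenance_divisor))
      doc$config$maintenance_divisor <- cf$maintenance_divisor
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

.param_cache <- new.env(parent = emptyenv())

#' The bundled IORT vs IMRT parameter set
#'
#' Loads (and caches) the published model inputs shipped with the
#' package: base-case IORT and IMRT arms, the two one-way sensitivity
#' variants of the IORT arm (`IORT_lower_recurrence` replaces only the
#' annual local-recurrence vector; `IORT_lower_metastasis` replaces only
#' the disease-free metastasis probability, 0.004), the Chilean
#' all-cause mortality bands, the health-state utilities, and the default
#' configuration (cohort of 100 women aged 60, 10 annual cycles, 3%
#' discounting of benefits and costs).
#'
#' @return An `apbi_parameters` bundle with six arms-and-tables elements;
#'   see [load_parameters()] for the structure.
#' @examples
#' p <- apbi_parameters()
#' p$arms$IORT$p_local_recurrence[3]   # annual P(LR), year 3
#' @export
apbi_parameters <- function() {
  if (!is.null(.param_cache$bundle)) return(.param_cache$bundle)
  base <- load_parameters(system.file("extdata", "params_base.yaml",
                                      package = "apbicea", mustWork = TRUE))
  sens <- load_parameters(system.file("extdata", "params_sensitivity.yaml",
                                      package = "apbicea", mustWork = TRUE))
  base$arms <- c(base$arms, sens$arms)
  .param_cache$bundle <- base
  base
}

#' Read/write a time-dependent probability table as CSV
#'
#' CSV alternative to the YAML vectors: columns `year`, `p_lr`,
#' `p_bc_death`.
#'
#' @param path CSV file path.
#' @return `read_transition_csv`: a list with numeric vectors
#'   `p_local_recurrence` and `p_bc_death` ordered by year.
#' @export
read_transition_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("year", "p_lr", "p_bc_death") %in% names(d)))
    stopf("transition CSV must have columns year, p_lr, p_bc_death")
  d <- d[order(d$year), ]
  list(p_local_recurrence = d$p_lr, p_bc_death = d$p_bc_death)
}

#' @rdname read_transition_csv
#' @param p_local_recurrence,p_bc_death Annual probability vectors.
#' @export
write_transition_csv <- function(p_local_recurrence, p_bc_death, path) {
  utils::write.csv(data.frame(year = seq_along(p_local_recurrence),
                              p_lr = p_local_recurrence,
                              p_bc_death = p_bc_death),
                   path, row.names = FALSE)
  invisible(path)
}
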