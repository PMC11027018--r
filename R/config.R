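#' Load the model configuration
#'
#' Reads a YAML configuration holding the reference endothelin-1 kinetics,
#' cardiorenal parameters, antagonist definitions, feedback gains and solver
#' tolerances. With no arguments the reference healthy-subject
#' parameterization shipped with the package is returned.
#'
#' @param path Path to a YAML configuration file, or `NULL` for the packaged
#'   reference configuration.
#' @param overrides Named nested list merged over the loaded configuration
#'   (e.g. `list(kinetics = list(k_pt = 10))`).
#' @return A list of class `et_config` with elements `subject`, `kinetics`,
#'   `antagonists`, `cardiorenal`, `feedback`, `solver`, `protocol_defaults`.
#' @examples
#' cfg <- et_config()
#' cfg$kinetics$k_pt
#' @export
et_config <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_config.yaml", package = "etsim")
  }
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(overrides)) cfg <- merge_lists(cfg, overrides)
  class(cfg) <- "et_config"
  validate_config(cfg)
  cfg
}

merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Validate a model configuration
#'
#' Checks positivity of all rates and volumes, finiteness of the receptor
#' dissociation constants, the renal predominance of ET_B expression, and
#' antagonist selectivity orientation (Kd_B/Kd_A > 1 for ET_A-selective
#' agents, < 1 for the ET_B-selective BQ788).
#'
#' @param cfg An `et_config` object.
#' @return The configuration, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  k <- cfg$kinetics
  pos <- c("bigET1_production_rate", "k_ECE", "k_tp", "k_pt", "V_tissue",
           "V_plasma", "kon_A", "koff_A", "k_int_A", "kon_B", "koff_B",
           "k_int_B", "R_A_tissue", "R_B_tissue", "R_A_plasma", "R_B_plasma",
           "molar_mass_ET1")
  for (nm in pos) {
    if (is.null(k[[nm]]) || !is.finite(k[[nm]]) || k[[nm]] <= 0)
      stop("kinetics$", nm, " must be a positive finite number")
  }
  if (k$k_cl_plasma < 0) stop("kinetics$k_cl_plasma must be >= 0")
  kd_a <- k$koff_A / k$kon_A
  kd_b <- k$koff_B / k$kon_B
  if (!is.finite(kd_a) || kd_a <= 0 || !is.finite(kd_b) || kd_b <= 0)
    stop("receptor Kd values must be finite and positive")
  if (k$R_B_tissue <= k$R_A_tissue)
    stop("R_B_tissue must exceed R_A_tissue (renal ET_B predominance)")
  for (nm in names(cfg$antagonists)) {
    a <- cfg$antagonists[[nm]]
    sel <- a$Kd_B / a$Kd_A
    if (nm %in% c("BQ123", "VML588") && sel <= 1)
      stop(nm, ": ET_A-selective antagonist must have Kd_B/Kd_A > 1")
    if (nm == "BQ788" && sel >= 1)
      stop("BQ788: ET_B-selective antagonist must have Kd_B/Kd_A < 1")
    if (a$plasma_halflife <= 0 || a$V_distribution <= 0)
      stop(nm, ": half-life and distribution volume must be positive")
  }
  cr <- cfg$cardiorenal
  for (nm in c("R_preafferent", "R_afferent", "R_efferent", "R_peritubular",
               "K_f", "N_nephrons", "SVR_nominal", "CO_nominal", "ECF0",
               "blood_volume0")) {
    if (cr[[nm]] <= 0) stop("cardiorenal$", nm, " must be positive")
  }
  for (nm in c("eta_PT", "eta_LoH", "eta_DCT", "eta_CD")) {
    if (cr[[nm]] <= 0 || cr[[nm]] >= 1)
      stop("cardiorenal$", nm, " must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Retrieve an antagonist specification
#'
#' @param cfg An `et_config` object.
#' @param name One of `"BQ123"`, `"BQ788"`, `"VML588"`.
#' @return A list with fields `name`, `Kd_A`, `Kd_B` (pM),
#'   `plasma_halflife` (min), `V_distribution` (L), `bioavailable_fraction`,
#'   `molar_mass` (g/mol).
#' @export
antagonist_spec <- function(cfg, name) {
  a <- cfg$antagonists[[name]]
  if (is.null(a)) stop("unknown antagonist: ", name)
  c(list(name = name), a)
}
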