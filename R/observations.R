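## Observation tables: the common currency between the synthetic-data
## generator, the objective function and the selection machinery.

OBS_VARIABLES <- names(VAR_COLUMN)

#' Construct / validate an observation table
#'
#' One row per measurement: study, arm, variable, time (sampling time for
#' instantaneous variables; collection-bin end for urine variables, with the
#' bin start in `t_start`), observed value, standard error and subject
#' count.
#'
#' @param df Data frame with columns `study`, `arm`, `variable`, `time`,
#'   `t_start` (NA for instantaneous measurements), `value`, `se`, `n`.
#' @return The validated data frame with class `et_observations`.
#' @export
observation_table <- function(df) {
  need <- c("study", "arm", "variable", "time", "t_start", "value", "se",
            "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("observation table lacks columns: ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$variable), OBS_VARIABLES)
  if (length(bad)) stop("unknown observation variables: ",
                        paste(bad, collapse = ", "))
  if (any(!is.na(df$se) & df$se <= 0)) stop("se must be > 0 where provided")
  df$arm <- as.character(df$arm)
  class(df) <- c("et_observations", "data.frame")
  df
}

#' @rdname observation_table
#' @param path CSV file path.
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(arm = "character"))
  observation_table(df)
}

#' @rdname observation_table
#' @param obs An `et_observations` table.
#' @export
write_observations <- function(obs, path) {
  write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

## Baseline value of each observable (for the default residual weights).
baseline_obs_values <- function(init) {
  b <- init$baseline
  c(ET1 = unname(init$state0["ET1_plasma"]),
    MAP = unname(b["MAP"]), RBF = unname(b["RBF"]),
    RPF = unname(b["RPF"]), GFR = unname(b["GFR"]),
    RVR = unname(b["RVR"]), SVR = unname(b["SVR"]),
    urine_flow = unname(b["urine_flow"]), UNaV = unname(b["UNaV"]),
    FENa = unname(b["FENa"]), FELi = unname(b["FELi"]))
}
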