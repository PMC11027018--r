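## Weighted least-squares objective.

## Precompute everything reusable across objective evaluations for a fixed
## observation table: steady-state initializations per sodium diet and the
## residual weights.
objective_context <- function(observations, config = et_config(),
                              rtol = NULL, atol = NULL) {
  diets <- unique(vapply(seq_len(nrow(observations)), function(r)
    protocol_for(observations$study[r], observations$arm[r])$Na_diet,
    0))
  inits <- lapply(diets, function(d)
    steady_state_initialize(config, Na_intake = d))
  names(inits) <- as.character(diets)
  base <- baseline_obs_values(inits[[1]])
  w <- ifelse(!is.na(observations$se) & observations$se > 0,
              observations$se,
              0.05 * abs(base[observations$variable]))
  list(config = config, inits = inits, weights = unname(w),
       observations = observations,
       occ0 = inits[[1]]$occ0,
       rtol = if (is.null(rtol)) config$solver$rtol else rtol,
       atol = if (is.null(atol)) config$solver$atol else atol)
}

## OBJ and residuals for a mechanism set against a prepared context.
## Simulation failure yields OBJ = +Inf (keeps optimizers alive) with the
## cause attached.
objective_eval <- function(mechanisms, ctx) {
  mechanisms <- anchor_mechanisms(mechanisms, ctx$occ0)
  pred <- tryCatch(
    predict_observations(ctx$observations, mechanisms, ctx$config,
                         inits = ctx$inits, rtol = ctx$rtol,
                         atol = ctx$atol),
    error = function(e) e)
  if (inherits(pred, "error")) {
    return(structure(list(OBJ = Inf, residuals = NULL,
                          failure = conditionMessage(pred)),
                     class = "et_objective"))
  }
  resid <- (pred$pred - pred$value) / ctx$weights
  if (any(!is.finite(resid))) {
    return(structure(list(OBJ = Inf, residuals = resid,
                          failure = "non-finite residual"),
                     class = "et_objective"))
  }
  structure(list(OBJ = sum(resid^2), residuals = resid,
                 predictions = pred$pred, failure = NULL),
            class = "et_objective")
}

#' Weighted sum-of-squares objective for a mechanism set
#'
#' Simulates every study/arm present in the observation table under the
#' given mechanisms and returns the sum over observations of
#' `((sim - obs)/w)^2`, where the weight `w` is the observation's reported
#' standard error, or 5\% of the variable's baseline value where no SE is
#' available. Each study/arm is simulated once per evaluation; a simulation
#' failure returns `+Inf` rather than an error.
#'
#' @param mechanisms List of [mechanism()] objects.
#' @param observations An [observation_table()].
#' @param config An `et_config`.
#' @param context Optional precomputed internal context (reused across
#'   evaluations in fitting loops).
#' @return The objective value (non-negative scalar; 0 iff all residuals
#'   vanish).
#' @export
objective_value <- function(mechanisms, observations, config = et_config(),
                            context = NULL) {
  ctx <- if (is.null(context)) objective_context(observations, config)
         else context
  objective_eval(mechanisms, ctx)$OBJ
}
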