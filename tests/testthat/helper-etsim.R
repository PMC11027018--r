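## Shared fixtures, computed once per test run.

test_cfg <- et_config()
test_init <- steady_state_initialize(test_cfg)
refined_truth <- mechanism_preset("refined")

## Memoised synthetic observation tables (generation costs a few seconds).
.fixture_env <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

obs_all_seed1 <- function() memo("obs_all_seed1",
  generate_observations(synthetic_spec(seed = 1), test_cfg))

obs_all_noisefree <- function() memo("obs_all_noisefree",
  generate_observations(synthetic_spec(noise_cv = 0), test_cfg))

nrow_or_zero <- function(df) if (is.null(df)) 0L else nrow(df)
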