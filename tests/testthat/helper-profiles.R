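# Shared fixtures: noiseless profiles built from the model evaluators.

sched8 <- c(0.5, 1, 2, 3, 4, 5, 5.5, 6)

noiseless_profile <- function(model, params, schedule = sched8, t_lag = 0) {
  simulate_release(model, params, schedule = schedule, noise_sd = 0,
                   t_lag = t_lag, plateau_after = Inf)
}

# evaluate through the exported model functions (independent of the
# internal registry dispatch)
eval_model_public <- function(model, par, t, t_lag = 0) {
  switch(model,
    zero_order = zero_order(t, par[["a"]], par[["k"]], t_lag),
    noyes_whitney = noyes_whitney(t, par[["k"]], t_lag),
    higuchi = higuchi(t, par[["alpha"]], t_lag),
    power_law = power_law(t, par[["alpha"]], par[["beta"]], t_lag),
    weibull = weibull_release(t, par[["alpha"]], par[["beta"]], t_lag)
  )
}

# generating parameters used across recovery tests (one per model)
recovery_params <- list(
  zero_order    = list(a = 0.05, k = 0.15),
  noyes_whitney = list(k = 0.4),
  higuchi       = list(alpha = 0.37),
  power_law     = list(alpha = 0.3, beta = 0.6),
  weibull       = list(alpha = 0.2, beta = 0.8)
)
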