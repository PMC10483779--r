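# Shared small fixtures built in code.

six_group_growth <- function(mu = 0.41, n_batches = 16) {
  stats::setNames(
    replicate(6, rbale_params(mu = rep(mu, n_batches)), simplify = FALSE),
    LETTERS[1:6])
}

quiet_fit_monod <- function(...) {
  suppressWarnings(fit_monod_hierarchical(...))
}
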