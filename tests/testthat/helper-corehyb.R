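# Small scenario used where the full default study would be overkill.
tiny_config <- function(...) {
  defaults <- list(n_parents_pop1 = 6L, n_males_pop2 = 15L,
                   n_analytes = 60L, n_latent = 3L, n_causal = 10L,
                   n_nuisance_latent = 2L, seed = 101L)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

# Deterministic random matrix with named dims, for oracle tests.
rand_matrix <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("x", seq_len(p))))
  m
}

# Feature table fixture: two groups of four samples each.
two_group_table <- function(values) {
  feature_table(values,
                line_ids = rownames(values),
                groups = rep(c("A", "B"), each = 4))
}
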