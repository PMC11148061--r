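# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; nothing is read from disk.

# Named list of random CRE x time tables (no structure).
make_noise_tables <- function(n_tables = 4, n_cres = 60, n_t = 5, seed = 1) {
  set.seed(seed)
  tabs <- lapply(seq_len(n_tables), function(k) {
    matrix(rnorm(n_cres * n_t), n_cres, n_t,
           dimnames = list(sprintf("CRE%04d", seq_len(n_cres)),
                           paste0(c(0, 0.5, 1, 2, 4)[seq_len(n_t)], "h")))
  })
  names(tabs) <- c("DMSO", sprintf("INH%02d", seq_len(n_tables - 1)))
  tabs
}

# Small wired fixture run through the generator; grouped so inhibitors
# 1..n_programs, n_programs+1..2*n_programs, ... share intended targets.
small_fixture <- function(seed, n_cres = 400, n_inhibitors = 8, n_kinases = 4,
                          n_programs = 4, offtarget_rate = 0, ...) {
  w <- generate_wiring(n_cres, n_inhibitors, n_kinases, n_programs,
                       offtarget_rate = offtarget_rate, seed = seed)
  sim <- generate_counts(w, seed = seed + 1000L, ...)
  list(wiring = w, tables = sim$tables, truth = sim$truth)
}

# Minimal hand-built mfa_result carrying only what cre_distances needs.
fake_mfa <- function(partial_scores, vehicle = "DMSO", selected_dims = NULL) {
  ndim <- ncol(partial_scores[[1]])
  structure(list(partial_scores = partial_scores,
                 compromise_scores = Reduce(`+`, partial_scores) / length(partial_scores),
                 selected_dims = selected_dims %||% seq_len(ndim),
                 vehicle = vehicle,
                 conditions = names(partial_scores),
                 n_tables = length(partial_scores)),
            class = "mfa_result")
}

# Minimal perturbation_scores with a given score matrix.
fake_scores <- function(score) {
  structure(list(distance = abs(score), log_null = c(mean = 0, sd = 1),
                 ccdf = 10^(-abs(score)), delta_z = score, score = score,
                 vehicle = "DMSO", clamp = 300),
            class = "perturbation_scores")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
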