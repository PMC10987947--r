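# Shared fixtures, all generated in code at test time.

# tiny attention configuration used across the rope/model tests
tiny_attention_config <- function(L = 1L) {
  attention_config(d_model = 8, n_heads = 2, n_layers = L, mlp_hidden = 16)
}

tiny_roformer_spec <- function(...) {
  args <- utils::modifyList(
    list(family = "roformer", n_channels = 3, n_outputs = 2, d_model = 8,
         n_heads = 2, n_layers = 1, mlp_hidden = 16, head_hidden = 6),
    list(...))
  do.call(regressor_spec, args)
}

# small synthetic cohort memoized per (subjects, movements, shift, seed)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

small_cohort <- function(n_subjects = 1, n_movements = 2, shift = 0,
                         seed = 123, trial_duration_s = 4) {
  key <- sprintf("cohort_%d_%d_%g_%d_%g", n_subjects, n_movements, shift,
                 seed, trial_duration_s)
  cached(key, generate_cohort(
    cohort_spec(n_subjects = n_subjects, n_movements = n_movements,
                trial_duration_s = trial_duration_s,
                shift_magnitude = shift),
    seed))
}

# a quick feature-series pair (train/test) for one synthetic subject
small_norm_split <- function(seed = 123, normalization = "mu_law") {
  key <- sprintf("split_%d_%s", seed, normalization)
  cached(key, {
    coh <- small_cohort(seed = seed)
    ns <- asNamespace("rofemg")
    sp <- ns$prepare_split(ns$subset_recordings(coh$recordings, "s01"),
                           split_seed = 1, window_ms = 100, step_ms = 50)
    ns$normalize_split(sp$train, sp$test, normalization)
  })
}

# an "oracle" model whose predictions are looked up from a label table,
# used to check evaluation plumbing end to end
oracle_model <- function(lookup) {
  structure(list(lookup = lookup, norm_hash = NA_character_),
            class = "oracle_model")
}

predict.oracle_model <- function(object, features, ...) {
  object$lookup(as.matrix(features))
}
registerS3method("predict", "oracle_model", predict.oracle_model,
                 envir = asNamespace("stats"))

# finite-difference gradient of scalar-valued f at params[[name]][k]
fd_grad <- function(f, params, name, k, eps = 1e-6) {
  p <- params
  p[[name]][k] <- p[[name]][k] + eps
  up <- f(p)
  p[[name]][k] <- p[[name]][k] - 2 * eps
  dn <- f(p)
  (up - dn) / (2 * eps)
}
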