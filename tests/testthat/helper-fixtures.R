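# Shared fixtures. Fast unit tests use coarse pulse programs (0.02 s
# sampling); study-scale fixtures (200 samples, default programs) are
# built once per run and cached.

fast_mrpv <- function() pulse_program_mrpv(sampling_interval = 0.02)
fast_mspv <- function() pulse_program_mspv(sampling_interval = 0.02)

# Small dataset: 5 classes x n_samples, coarse e-tongue sampling.
tiny_dataset <- function(n_samples = 3, noise_sd = 0.05, seed = 11) {
  ds <- simulate_dataset(default_age_specs(n_samples, noise_sd), seed = seed,
                         program_mrpv = fast_mrpv(),
                         program_mspv = fast_mspv())
  et <- extract_etongue_features(ds$traces, fast_mrpv(), fast_mspv(),
                                 labels = ds$labels)
  en <- extract_enose_features(ds$traces, labels = ds$labels)
  list(ds = ds, etongue = et, enose = en)
}

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Full study conditions: 200 samples, default programs, default noise.
study_tables <- function() {
  cache_fixture("study", {
    ds <- simulate_dataset(seed = 101)
    et <- extract_etongue_features(ds$traces, labels = ds$labels)
    en <- extract_enose_features(ds$traces, labels = ds$labels)
    rm(ds)
    list(etongue = et, enose = en)
  })
}

# Noiseless study conditions (for exact-recovery properties).
noiseless_tables <- function() {
  cache_fixture("noiseless", {
    ds <- simulate_dataset(default_age_specs(noise_sd = 0), seed = 102)
    et <- extract_etongue_features(ds$traces, labels = ds$labels)
    en <- extract_enose_features(ds$traces, labels = ds$labels)
    rm(ds)
    list(etongue = et, enose = en)
  })
}

random_ft <- function(n, p, seed = 1, age = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
  feature_table(m, age_years = age)
}

# Leave-one-out 1-nearest-neighbour accuracy on a score matrix.
loo_1nn_accuracy <- function(scores, classes) {
  d <- as.matrix(dist(scores))
  diag(d) <- Inf
  mean(classes[apply(d, 1, which.min)] == classes)
}

# Constant-value e-nose trace over [0, 230] s at 1 Hz.
flat_enose_trace <- function(value, sensor = "S1", sample_id = "s1") {
  signal_trace(sample_id, "enose", sensor, 0:230, rep(value, 231))
}
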