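# Shared fixtures. The phantom study (60 + 60 cases at database-default
# settings) is expensive, so it is computed once per test run and cached;
# every consumer sees the identical deterministic objects.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small fast phantoms for unit-level checks
small_phantom <- function(label = "benign", seed = 7, rows = 96, cols = 128) {
  make_phantom(phantom_spec(label, rows = rows, cols = cols, seed = seed))
}

# the full two-class phantom study: default-parameter LOO evaluation plus
# the cross-contrast robustness protocol in the contrast-invariant regime
# (noise compensation off, where the phase-congruency invariance theory
# applies; benign phantom interiors are pure speckle, i.e. exactly the
# component the adaptive noise floor is designed to remove)
phantom_study <- function() {
  fixture("study", function() {
    ds <- phantom_dataset(60, 60, seed = 101)
    feats <- extract_features(ds)
    config <- grid_search_svm(feats, seed = 101)
    loo <- loo_cv(feats, config)
    cc <- cross_contrast_experiment(ds, params = pcbp_params(k_noise = 0),
                                    seed = 101)
    list(dataset = ds, origin_features = feats, config = config,
         loo = loo, cc = cc)
  })
}

# separable two-blob feature table for classifier-level tests
blob_features <- function(n_per = 30, d = 5, shift = 2.5, seed = 3) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = shift), n_per, d))
  })
  colnames(x) <- paste0("f", seq_len(d))
  dplyr::bind_cols(
    tibble::tibble(id = sprintf("s%02d", seq_len(2 * n_per)),
                   label = rep(c("benign", "malignant"), each = n_per)),
    tibble::as_tibble(x)
  )
}
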