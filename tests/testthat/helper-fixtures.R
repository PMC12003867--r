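# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code at a reduced sampling rate (the decimated working rate
# and every analysis constant are unchanged).

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

small_spec <- function(seed = 101, ...) {
  args <- list(n_drugs = 4L, datasets_per_drug = 6L, seed = seed, sf = 50,
               annotated_fraction = 1.0)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_spec, args)
}

# One noisy recording plus its preprocessed bundle (intestinal, class 1).
fx_matched <- function() {
  fixture("matched", function() {
    spec <- small_spec()
    drugs <- generate_drug_library(4, spec$adr_prevalence, 1, spec$seed)
    rec <- simulate_recording(drugs[[1]], TISSUE_CODE("duodenum"), 2L, spec,
                              901, "fx1")
    list(rec = rec, matched = preprocess_recording(rec), spec = spec)
  })
}

# Clean recording: no noise, no dropout, no artifacts, no missing values.
fx_clean_rec <- function() {
  fixture("clean_rec", function() {
    spec <- small_spec(noise_sd = 0, dropout_rate = 0, artifact_rate = 0,
                       nan_rate = 0)
    drugs <- generate_drug_library(4, spec$adr_prevalence, 1, spec$seed)
    rec <- simulate_recording(drugs[[2]], TISSUE_CODE("ileum"), 2L, spec,
                              902, "fxclean")
    list(rec = rec, spec = spec)
  })
}

TISSUE_CODE <- function(name) {
  c(stomach = 1L, duodenum = 2L, ileum = 3L, colon = 4L)[[name]]
}

# A small already-preprocessed cohort shared by labelling/ensemble tests.
fx_cohort <- function() {
  fixture("cohort", function() {
    spec <- small_spec(seed = 202, annotated_fraction = 0.75)
    preprocess_cohort(spec)
  })
}

# Deterministic toy training problem: two channel-mean-separated classes.
toy_problem <- function(n = 24, T = 80, C = 8, sep = 1, seed = 5) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  xs <- lapply(seq_len(n), function(i) {
    matrix(rnorm(T * C, mean = sep * (2 * y[i] - 1), sd = 0.5), T, C)
  })
  names(xs) <- sprintf("toy%02d", seq_len(n))
  list(xs = xs, y = y, tissues = rep(1:4, length.out = n),
       concs = rep(1:3, length.out = n),
       emb = make_embedding_table(7, n_channels = C))
}
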