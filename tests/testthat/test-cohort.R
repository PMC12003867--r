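test_that("drug library is deterministic and respects prevalence input", {
  prev <- c(nausea = 0.5, vomiting = 0.5, diarrhoea = 0.5,
            constipation = 0.5)
  a <- generate_drug_library(10, prev, 1.0, seed = 7)
  b <- generate_drug_library(10, prev, 1.0, seed = 7)
  expect_identical(lapply(a, `[[`, "adr_flags"),
                   lapply(b, `[[`, "adr_flags"))
  expect_true(all(vapply(a, `[[`, TRUE, "annotated")))
  expect_error(generate_drug_library(10, c(nausea = 1.5), 1, 1), "nausea")
  expect_error(generate_drug_library(10, c(nausea = 0), 1, 1), "nausea")
})

test_that("ADR flag prevalence matches the binomial expectation at n=1000", {
  lib <- generate_drug_library(1000, c(nausea = 0.5), 1.0, seed = 1,
                               indication_rate = 0)
  frac <- mean(vapply(lib, function(d) d$adr_flags[["nausea"]], 0L))
  # 99.7% binomial band around 0.5 at n = 1000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("annotated fraction emulates the database overlap at n=172", {
  lib <- generate_drug_library(172, c(nausea = 0.3), 95 / 172, seed = 2)
  n_ann <- sum(vapply(lib, `[[`, TRUE, "annotated"))
  expect_lt(abs(n_ann - 95), 3 * sqrt(172 * (95 / 172) * (77 / 172)) + 1)
})

test_that("indication relations are corrected to class 0", {
  lib <- generate_drug_library(300, c(nausea = 0.5), 1.0, seed = 3,
                               indication_rate = 0.3)
  for (d in lib) {
    for (a in names(d$indication_flags)) {
      if (d$indication_flags[[a]]) expect_identical(d$adr_flags[[a]], 0L)
    }
  }
})

test_that("cohort design counts datasets and drugs correctly", {
  spec <- small_spec(n_drugs = 4L, datasets_per_drug = 8L)
  design <- cohort_design(spec)
  expect_equal(nrow(design), 32)
  expect_equal(length(unique(design$drug)), 4)
  expect_false(any(duplicated(design$dataset_id)))
  # stomach only tested at medium concentration
  expect_true(all(design$conc[design$tissue == 1] == 2))
  # same spec twice -> identical design
  expect_identical(design, cohort_design(small_spec(n_drugs = 4L,
                                                    datasets_per_drug = 8L)))
})

test_that("annotation table lists only annotated drugs, deterministically", {
  spec <- small_spec(n_drugs = 8L, annotated_fraction = 0.5, seed = 11)
  d1 <- generate_drug_library(8, spec$adr_prevalence, 0.5, 11)
  d2 <- generate_drug_library(8, spec$adr_prevalence, 0.5, 11)
  a1 <- annotation_table(d1); a2 <- annotation_table(d2)
  expect_identical(a1, a2)
  expect_lt(length(unique(a1$drug_id)), 8)
  tf <- tempfile(fileext = ".tsv")
  write_annotations(a1, tf)
  expect_identical(read_annotations(tf), a1)
})

test_that("simulated recording has the declared geometry and timing", {
  rec <- fx_matched()$rec
  spec <- fx_matched()$spec
  expect_s3_class(rec, "sw_recording")
  expect_equal(dim(rec$signal), c(60, spec$sf * spec$duration))
  expect_gte(rec$t_drug, 295)
  expect_lte(rec$t_drug, 305)
  expect_equal(nrow(rec$layout), 60)
  # corners of the 8x8 grid unused
  occupied <- paste(rec$layout$row, rec$layout$col)
  expect_false(any(c("1 1", "1 8", "8 1", "8 8") %in% occupied))
})

test_that("recordings are deterministic given the seed", {
  fx <- fx_clean_rec()
  drugs <- generate_drug_library(4, fx$spec$adr_prevalence, 1, fx$spec$seed)
  rec2 <- simulate_recording(drugs[[2]], 3L, 2L, fx$spec, 902, "fxclean")
  expect_identical(fx$rec$signal, rec2$signal)
})

test_that("noiseless recording oscillates at the tissue dominant frequency", {
  fx <- fx_clean_rec()
  rec <- fx$rec
  base <- rec$signal[5, seq_len(round(290 * rec$sf))]
  ds <- downsample(base, rec$sf / 10)
  sp <- compute_dominant_frequency(ds, 10)
  expect_lt(abs(sp$DF - rec$df_baseline), 0.5)
  # intestinal band puts every clean channel above the DF filter threshold
  expect_gte(rec$df_baseline, 12)
})

test_that("with artifacts disabled all samples stay in the signal range", {
  fx <- fx_clean_rec()
  expect_lte(max(abs(fx$rec$signal)), 1200 * 1.05)
})

test_that("full dropout produces channels that all fail the DF filter", {
  spec <- small_spec(noise_sd = 0, dropout_rate = 1, artifact_rate = 0,
                     nan_rate = 0)
  drugs <- generate_drug_library(4, spec$adr_prevalence, 1, spec$seed)
  rec <- simulate_recording(drugs[[1]], 2L, 2L, spec, 55, "dead")
  dfs <- vapply(1:10, function(ch) {
    compute_dominant_frequency(downsample(rec$signal[ch, ], 5), 10)$DF
  }, 0)
  expect_true(all(is.na(dfs)))
  expect_false(any(filter_channels_by_df(dfs, 2L)))
})

test_that("class-1 drugs shift the post-drug dominant frequency", {
  spec <- small_spec(noise_sd = 0, dropout_rate = 0, artifact_rate = 0,
                     nan_rate = 0)
  drugs <- generate_drug_library(6, c(nausea = 0.4), 1.0, seed = 33,
                                 effect_shift_cpm = 3)
  cls <- vapply(drugs, function(d) any(d$adr_flags == 1L), TRUE)
  skip_if(sum(cls) == 0 || sum(!cls) == 0)
  shift_of <- function(d) {
    rec <- simulate_recording(d, 2L, 2L, spec, 77, "s")
    post <- downsample(rec$signal[1, (320 * spec$sf):(700 * spec$sf)],
                       spec$sf / 10)
    base <- downsample(rec$signal[1, 1:(290 * spec$sf)], spec$sf / 10)
    compute_dominant_frequency(post, 10)$DF -
      compute_dominant_frequency(base, 10)$DF
  }
  s1 <- shift_of(drugs[[which(cls)[1]]])
  s0 <- shift_of(drugs[[which(!cls)[1]]])
  expect_gt(s1, 1.5)    # signature shift (3 cpm nominal at medium conc)
  expect_lt(abs(s0), 1.5)  # nuisance jitter only
})

test_that("generate_cohort writes a complete container", {
  spec <- small_spec(n_drugs = 2L, datasets_per_drug = 2L, sf = 50)
  out <- file.path(tempdir(), "cohort_test")
  res <- generate_cohort(spec, out_dir = out)
  expect_equal(length(res$files), 4)
  expect_true(all(file.exists(res$files)))
  meta <- read.csv(file.path(out, "metadata.csv"))
  expect_equal(nrow(meta), 4)
  rec <- readRDS(res$files[1])
  expect_s3_class(rec, "sw_recording")
  unlink(out, recursive = TRUE)
})
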