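# synthetic_cohort module: generator, derived variables, inclusion filters.

test_that("degenerate one-class truth with emissions 1 yields all-ones cells", {
  spec <- model_spec("latent_profile", 1)
  params <- model_params(spec, 1, prob = array(1, c(1, 3, 5)))
  truth <- generative_truth(spec, params, c(A = 50), seed = 4)
  co <- generate_cohort(truth)
  y <- symptomLCA:::panel_matrix(co)
  expect_true(all(y[!is.na(y)] == 1))
})

test_that("generated prevalences match the mixture prevalence within 3 MC SEs", {
  spec <- model_spec("latent_profile", 2)
  p <- array(NA_real_, c(2, 3, 5))
  p[1, , ] <- 0.8; p[2, , ] <- 0.2
  params <- model_params(spec, c(0.5, 0.5), prob = p)
  n <- 20000
  truth <- generative_truth(spec, params, c(A = n), seed = 99)
  co <- generate_cohort(truth)
  y <- symptomLCA:::panel_matrix(co)
  mix_p <- 0.5 * 0.8 + 0.5 * 0.2
  se <- sqrt(mix_p * (1 - mix_p) / n)
  expect_true(all(abs(colMeans(y) - mix_p) < 3 * se))
})

test_that("structural cells are fully missing and only in the right cohort", {
  truth <- default_truth(seed = 12, cohort_sizes = c(A = 150, B = 200),
                         item_rate = 0)
  co <- generate_cohort(truth)
  for (a in c(1, 3)) {
    col <- co[[paste0("rhinitis_", a)]]
    expect_true(all(is.na(col[co$cohort == "B"])))
    expect_true(all(!is.na(col[co$cohort == "A"])))
  }
  expect_true(all(!is.na(co$eczema_1)))
})

test_that("seeded generation is bit-reproducible and seeds differ", {
  t1 <- default_truth(seed = 5, cohort_sizes = c(A = 40, B = 60))
  co1 <- generate_cohort(t1)
  co2 <- generate_cohort(t1)
  expect_identical(co1, co2)
  co3 <- generate_cohort(default_truth(seed = 6, cohort_sizes = c(A = 40, B = 60)))
  expect_false(identical(co1, co3))
})

test_that("invalid truth parameters are rejected", {
  spec <- model_spec("latent_profile", 2)
  expect_error(model_params(spec, c(0.7, 0.7), prob = array(0.5, c(2, 3, 5))),
               NA) # weights are normalised, not rejected
  expect_error(model_params(spec, c(0.5, 0.5), prob = array(1.5, c(2, 3, 5))),
               "outside")
  expect_error(model_params(spec, c(0.5), prob = array(0.5, c(2, 3, 5))),
               "length")
})

test_that("derive_asthma implements the two-of-three rule with NA logic", {
  expect_equal(derive_asthma(1, 1, 0), 1)
  expect_equal(derive_asthma(0, 0, 1), 0)
  expect_equal(derive_asthma(1, 1, 1), 1)
  # undecidable with one missing feature and one positive
  expect_true(is.na(derive_asthma(1, 0, NA)))
  # decidable despite a missing feature
  expect_equal(derive_asthma(1, NA, 1), 1)
  expect_equal(derive_asthma(0, 0, NA), 0)
  # symmetry in the three features
  combos <- expand.grid(a = c(0, 1, NA), b = c(0, 1, NA), c = c(0, 1, NA))
  for (i in seq_len(nrow(combos))) {
    v <- unlist(combos[i, ])
    base <- derive_asthma(v[1], v[2], v[3])
    expect_identical(derive_asthma(v[2], v[3], v[1]), base)
    expect_identical(derive_asthma(v[3], v[1], v[2]), base)
  }
})

test_that("derive_sensitised thresholds at 3 mm over the negative control", {
  expect_equal(derive_sensitised(c(5.0, 1.0), 2.0), 1)  # 5.0 - 2.0 = 3.0 qualifies
  expect_equal(derive_sensitised(c(4.9), 2.0), 0)
  expect_equal(derive_sensitised(c(0, 0), 0), 0)
  expect_true(is.na(derive_sensitised(numeric(0), 1.0)))
  expect_error(derive_sensitised(c(-1), 0), ">= 0")
})

test_that("filter_min_timepoints keeps children with >= k observed ages per symptom", {
  # 10-child fixture with hand-set masks, T = 2 so k = 2 means fully observed
  set.seed(3)
  panels <- matrix(rbinom(60, 1, 0.5), 10, 6)
  panels[1, 1:2] <- NA           # child 1: eczema never observed
  panels[2, 1] <- NA             # child 2: eczema observed once
  panels[3, 3] <- NA             # child 3: wheeze observed once
  panels[4, c(1, 3, 5)] <- NA    # child 4: one observation per symptom
  co <- toy_cohort(panels)
  kept <- filter_min_timepoints(co, k = 2, exempt_structural = FALSE)
  expect_setequal(kept$child_id, sprintf("t%03d", 5:10))
  kept1 <- filter_min_timepoints(co, k = 1, exempt_structural = FALSE)
  expect_setequal(kept1$child_id, sprintf("t%03d", 2:10))
})

test_that("structurally unobserved symptoms are exempt from the inclusion rule", {
  truth <- default_truth(seed = 21, cohort_sizes = c(A = 80, B = 120),
                         item_rate = 0)
  co <- generate_cohort(truth)
  # cohort B rhinitis is only collectable at 3 ages; with k = 2 everyone whose
  # remaining cells are complete must survive
  expect_equal(nrow(filter_min_timepoints(co, k = 2)), nrow(co))
  # at k = 4 cohort B can still qualify: rhinitis requirement caps at the 3
  # collectable ages
  k4 <- filter_min_timepoints(co, k = 4)
  expect_true(any(k4$cohort == "B"))
  # disabling the exemption with k = 4 kills all of cohort B (only 3 rhinitis ages)
  k4s <- filter_min_timepoints(co, k = 4, exempt_structural = FALSE)
  expect_false(any(k4s$cohort == "B"))
})

test_that("filter_mild_eczema drops mild / unconfirmable / missing-early-eczema children", {
  panels <- matrix(1, 6, 6)
  panels[5, 1:2] <- 0            # child 5: no early eczema
  panels[6, 1:2] <- NA           # child 6: early eczema missing entirely
  co <- toy_cohort(panels, steroidrx3 = c(0, 1, NA, 1, NA, 1))
  kept <- filter_mild_eczema(co)
  # child 1: eczema + no steroid -> dropped (mild)
  # child 2: eczema + steroid -> kept
  # child 3: eczema + missing flag -> dropped (unconfirmable)
  # child 5: no early eczema, flag irrelevant -> kept
  # child 6: early eczema unknown -> dropped
  expect_setequal(kept$child_id, c("t002", "t004", "t005"))
})

test_that("filters are idempotent", {
  truth <- default_truth(seed = 31, cohort_sizes = c(A = 120, B = 150),
                         item_rate = 0.2)
  co <- generate_cohort(truth)
  f1 <- filter_min_timepoints(co, k = 2)
  expect_identical(as.data.frame(filter_min_timepoints(f1, k = 2)),
                   as.data.frame(f1))
  m1 <- filter_mild_eczema(f1)
  expect_identical(as.data.frame(filter_mild_eczema(m1)), as.data.frame(m1))
})

test_that("cohort CSV round-trips", {
  truth <- default_truth(seed = 8, cohort_sizes = c(A = 25, B = 30))
  co <- generate_cohort(truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back)[names(as.data.frame(co))],
               as.data.frame(co), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("asthma variant replaces wheeze columns by the derived rule", {
  truth <- default_truth(seed = 9, cohort_sizes = c(A = 40, B = 40))
  co <- generate_cohort(truth)
  va <- use_asthma_variant(co)
  expected <- derive_asthma(co$wheeze_5, co$meduse_5, co$dxasthma_5)
  expect_identical(va$wheeze_5, expected)
  expect_identical(va$eczema_5, co$eczema_5)
})
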