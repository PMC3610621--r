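test_that("the four stain-count conversions reproduce hand evaluations", {
  # proliferation: lambda_M <n> = (f/20 h) * 24 h/day
  expect_equal(proliferation_rate(0, 1), 0)
  expect_equal(proliferation_rate(0.5, 1), 0.6)
  expect_equal(proliferation_rate(0.5, 0.5), 1.2)
  expect_error(proliferation_rate(0.5, 0), "mean_n")
  # apoptosis: lambda_A = (f/5 h) * 24 h/day
  expect_equal(apoptosis_rate(0), 0)
  expect_equal(apoptosis_rate(0.1), 0.48)
  expect_equal(apoptosis_rate(1), 4.8)
  # vascular support (1-f)^{3/2}
  expect_equal(vascular_support_fraction(0), 1)
  expect_equal(vascular_support_fraction(1), 0)
  expect_equal(vascular_support_fraction(0.75), 0.125)
  # hypoxic fraction f^{3/2}
  expect_equal(hypoxic_cell_fraction(0), 0)
  expect_equal(hypoxic_cell_fraction(1), 1)
  expect_equal(hypoxic_cell_fraction(0.25), 0.125)
})

test_that("conversions are monotone with bounded ranges over a fraction grid", {
  f <- seq(0, 1, by = 0.01)
  lm <- proliferation_rate(f, 1)
  la <- apoptosis_rate(f)
  vs <- vascular_support_fraction(f)
  hf <- hypoxic_cell_fraction(f)
  expect_true(all(diff(lm) > 0)); expect_true(all(lm >= 0 & lm <= 1.2 + 1e-9))
  expect_true(all(diff(la) > 0)); expect_true(all(la >= 0 & la <= 4.8 + 1e-9))
  expect_true(all(diff(vs) < 0)); expect_true(all(vs >= 0 & vs <= 1))
  expect_true(all(diff(hf) > 0)); expect_true(all(hf >= 0 & hf <= 1))
})

test_that("IHC tables validate their schema", {
  tab <- synth_ihc(noise = FALSE)
  expect_s3_class(tab, "ihc_table")
  expect_equal(nrow(tab), 5 * 5 * 2)
  expect_true(all(tab$stained + tab$unstained > 0))
  bad <- as.data.frame(tab); bad$stained[1] <- -1
  expect_error(ihc_table(bad), "non-negative")
  bad <- as.data.frame(tab); bad$marker[1] <- "CD99"
  expect_error(ihc_table(bad), "marker")
})

test_that("synthetic tables concentrate around targets and are seed-stable", {
  big <- synth_ihc(total = 1e6, rng_seed = 4)
  f <- lymphosim:::stained_fraction(big, "Casp3", "periphery")
  expect_equal(f, 0.12, tolerance = 0.01)
  zero <- synth_ihc(targets = list(Ki67 = c(core = 0, periphery = 0)),
                    total = 500)
  expect_true(all(zero$stained == 0))
  t1 <- synth_ihc(rng_seed = 42)
  t2 <- synth_ihc(rng_seed = 42)
  expect_identical(t1, t2)
  expect_false(identical(t1, synth_ihc(rng_seed = 43)))
})

test_that("IHC CSV round-trips through the documented schema", {
  tab <- synth_ihc(rng_seed = 8)
  path <- tempfile(fileext = ".csv")
  write_ihc(tab, path)
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, "section,marker,region,stained,unstained")
  back <- read_ihc(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("calibration recovers rates and the A ratio from a synthetic table", {
  tab <- synth_ihc(noise = FALSE)
  res <- calibrate_ihc(tab)
  f_ki <- lymphosim:::stained_fraction(tab, "Ki67")
  f_ca <- lymphosim:::stained_fraction(tab, "Casp3")
  f_cd <- lymphosim:::stained_fraction(tab, "CD31")
  expect_equal(res$lambda_A, apoptosis_rate(f_ca))
  expect_equal(res$mean_n, vascular_support_fraction(f_cd))
  expect_equal(res$lambda_M, proliferation_rate(f_ki, res$mean_n))
  expect_equal(res$A, res$lambda_A / res$lambda_M)
  # analytic round trip: A = (f_C/5) / (f_K/20) * <n>
  expect_equal(res$A, (f_ca / 5) / (f_ki / 20) * res$mean_n)
  # the baseline fixture represents the lymphoma phenotype the model is
  # built around: A near 0.4, lambda_M near the 20 h cycle rate
  expect_equal(res$A, 0.4, tolerance = 0.2)
  expect_equal(res$lambda_M, 1.2, tolerance = 0.15)
  # purity: same table, same result
  expect_identical(calibrate_ihc(tab), calibrate_ihc(tab))
})

test_that("large-count sampling reproduces the analytic A relationship", {
  tab <- synth_ihc(total = 2e5, rng_seed = 21)
  res <- calibrate_ihc(tab)
  det <- calibrate_ihc(synth_ihc(noise = FALSE))
  expect_equal(res$A, det$A, tolerance = 0.02)
})

test_that("resistant preset carries the 4-fold central endothelial enrichment", {
  tab <- synth_ihc("resistant", noise = FALSE)
  core <- lymphosim:::stained_fraction(tab, "CD31", "core")
  peri <- lymphosim:::stained_fraction(tab, "CD31", "periphery")
  expect_gt(core / peri, 2.5)
})
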