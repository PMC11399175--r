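# Plate-assay reduction: kinetic slopes, blank correction, replicate
# aggregation, protein normalisation, table assembly.

test_that("kinetic_rate recovers exact and noisy slopes", {
  flat <- kinetic_trace("W1", "s1", times = c(0, 60, 120, 180),
                        absorbances = rep(0.5, 4), wavelength = 412)
  expect_equal(kinetic_rate(flat), 0)

  line <- kinetic_trace("W1", "s1", times = c(0, 60, 120, 180),
                        absorbances = c(0.10, 0.20, 0.30, 0.40),
                        wavelength = 412)
  expect_equal(kinetic_rate(line), 0.10)

  # brute-force normal-equations oracle on a noisy 7-read trace
  withr::local_seed(11)
  t_s <- seq(0, 360, by = 60)
  ab <- 0.05 * (t_s / 60) + rnorm(7, 0, 0.001)
  tr <- kinetic_trace("W2", "s2", t_s, ab, wavelength = 412)
  X <- cbind(1, t_s / 60)
  beta <- solve(t(X) %*% X, t(X) %*% ab)
  expect_equal(kinetic_rate(tr), beta[2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(abs(kinetic_rate(tr) - 0.05), 0.003)
})

test_that("kinetic_rate is baseline-invariant and sign-reverses with the trace", {
  withr::local_seed(3)
  for (i in 1:10) {
    t_s <- sort(sample(0:400, 6))
    ab <- runif(6)
    tr <- kinetic_trace("W", "s", t_s, ab, wavelength = 340)
    shifted <- kinetic_trace("W", "s", t_s, ab + 2.5, wavelength = 340)
    expect_equal(kinetic_rate(shifted), kinetic_rate(tr), tolerance = 1e-10)
  }
  # reversing an equally spaced read sequence negates the slope
  t_s <- seq(0, 300, by = 60)
  ab <- c(0.1, 0.18, 0.22, 0.35, 0.41, 0.50)
  fwd <- kinetic_trace("W", "s", t_s, ab, wavelength = 340)
  rev_tr <- kinetic_trace("W", "s", t_s, rev(ab), wavelength = 340)
  expect_equal(kinetic_rate(rev_tr), -kinetic_rate(fwd), tolerance = 1e-12)
})

test_that("invalid traces are rejected", {
  expect_error(kinetic_trace("W", "s", times = 0, absorbances = 0.1,
                             wavelength = 412), "at least 2")
  expect_error(kinetic_trace("W", "s", times = c(0, 0), absorbances = c(1, 2),
                             wavelength = 412), "strictly increasing")
  expect_error(kinetic_trace("W", "s", times = c(0, 60),
                             absorbances = c(1, 2), wavelength = -1),
               "wavelength")
  expect_error(endpoint_read("W", "s", absorbance = Inf, wavelength = 412),
               "non-finite")
})

test_that("blank correction subtracts the mean blank and errors without blanks", {
  r <- blank_correct(c(a = 0.8, b = 0.9, bl1 = 0.1, bl2 = 0.1),
                     c("sample", "sample", "blank", "blank"))
  expect_equal(unname(r$corrected), c(0.7, 0.8))
  expect_equal(r$blank_value, 0.1)

  r2 <- blank_correct(c(a = 0.1, bl = 0.1), c("sample", "blank"))
  expect_equal(unname(r2$corrected), 0)

  # kinetic case: rates in, mean blank rate out
  r3 <- blank_correct(c(s = 0.10, b1 = 0.01, b2 = 0.03),
                      c("sample", "blank", "blank"))
  expect_equal(unname(r3$corrected), 0.08)

  expect_error(blank_correct(c(a = 1), "sample"), "blank")
})

test_that("replicate aggregation returns mean, CV and flags", {
  a <- aggregate_replicates(c(0.3, 0.3, 0.3), rep("s1", 3))
  expect_equal(a$value, 0.3)
  expect_equal(a$cv, 0)
  expect_false(a$flagged)

  b <- aggregate_replicates(c(1, 2, 3), rep("s1", 3))
  expect_equal(b$value, 2)
  expect_equal(b$cv, sd(c(1, 2, 3)) / 2)  # hand sd oracle
  expect_true(b$flagged)                  # CV = 0.5 > 0.2 default

  single <- aggregate_replicates(0.5, "s1")
  expect_equal(single$value, 0.5)
  expect_true(is.na(single$cv))
  expect_false(single$flagged)
})

test_that("blank correction and replicate aggregation commute", {
  withr::local_seed(5)
  for (i in 1:10) {
    vals <- runif(9, 0.2, 1)
    ids <- rep(c("s1", "s2", "s3"), each = 3)
    blanks <- runif(3, 0, 0.1)
    bc <- blank_correct(c(vals, blanks),
                        c(rep("sample", 9), rep("blank", 3)))
    agg_after <- aggregate_replicates(bc$corrected, ids)
    agg_first <- aggregate_replicates(vals, ids)
    expect_equal(agg_after$value, agg_first$value - mean(blanks),
                 tolerance = 1e-12)
  }
})

test_that("protein normalisation divides, guards and scales homogeneously", {
  expect_equal(normalize_to_protein(10, 2), 5)
  expect_equal(normalize_to_protein(0, 2), 0)
  expect_error(normalize_to_protein(1, 0, "fish1"), "fish1")
  withr::local_seed(9)
  raw <- runif(5); prot <- runif(5, 0.5, 2); c_scale <- 3.7
  expect_equal(normalize_to_protein(raw * c_scale, prot),
               c_scale * normalize_to_protein(raw, prot))
})

test_that("biomarker table assembly keeps missing cells and rejects bad input", {
  groups <- tibble::tibble(animal_id = c("f1", "f2", "f3"),
                           group = c("A1", "A1", "A2"))
  assays <- list(
    AChE = tibble::tibble(sample_id = c("f1", "f2", "f3"),
                          value = c(1, 2, 3)),
    CAT = tibble::tibble(sample_id = c("f1", "f2", "f3"),
                         value = c(4, 5, 6))
  )
  tb <- build_biomarker_table(assays, groups)
  expect_s3_class(tb, "biomarker_table")
  expect_equal(nrow(tb), 3)
  expect_equal(biomarker_names(tb), c("AChE", "CAT"))

  assays$CAT <- assays$CAT[-2, ]  # one animal misses one assay
  tb2 <- build_biomarker_table(assays, groups)
  expect_equal(nrow(tb2), 3)
  expect_true(is.na(tb2$CAT[tb2$animal_id == "f2"]))

  expect_error(build_biomarker_table(
    assays, tibble::tibble(animal_id = c("f1", "f1", "f3"),
                           group = c("A1", "A1", "A2"))),
    "duplicate animal_id")
  expect_error(build_biomarker_table(
    list(AChE = tibble::tibble(sample_id = "ghost", value = 1)), groups),
    "without a group")
})
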