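# MSP spectrum ingestion, peak estimation, normalization, template fitting,
# chromophore decision, classification and summaries.

test_that("read_spectrum parses, sorts, averages duplicates, and reports bad lines", {
  wl <- 350:750
  ab <- evaluate_template(template_spec("A1", 505), wl) * 0.02
  p <- write_spectrum_file(wl, ab)
  sp <- read_spectrum(p)
  expect_s3_class(sp, "msp_spectrum")
  expect_length(sp$wavelength, 401)

  # descending file gives the same spectrum as its ascending twin
  p_desc <- write_spectrum_file(rev(wl), rev(ab), header = FALSE, sep = ",")
  sp2 <- read_spectrum(p_desc)
  expect_equal(sp2$wavelength, sp$wavelength)
  expect_equal(sp2$absorbance, sp$absorbance)

  # duplicated wavelength is averaged
  p_dup <- write_spectrum_file(c(wl, 500), c(ab, ab[wl == 500] + 0.2))
  sp3 <- read_spectrum(p_dup)
  expect_length(sp3$wavelength, 401)
  expect_equal(sp3$absorbance[sp3$wavelength == 500],
               unname(ab[wl == 500] + 0.1))

  # non-numeric row -> error naming the line
  bad <- write_spectrum_file(wl, ab)
  lines <- readLines(bad)
  lines[10] <- "401\toops"
  writeLines(lines, bad)
  expect_error(read_spectrum(bad), "line 10")

  expect_error(read_spectrum(write_spectrum_file(1:10, 1:10)), "50")

  # round trip through write_spectrum
  rt <- tempfile(fileext = ".tsv")
  write_spectrum(sp, rt)
  sp4 <- read_spectrum(rt)
  expect_equal(sp4$absorbance, sp$absorbance)
})

test_that("merge_scans averages pointwise and improves noisy recovery", {
  wl <- 350:750
  ab <- evaluate_template(template_spec("A1", 505), wl)
  down <- spectrum(wl, ab, scan_direction = "down")
  up <- spectrum(wl, ab, scan_direction = "up")
  m <- merge_scans(down, up)
  expect_equal(m$absorbance, ab)
  expect_identical(m$scan_direction, "merged")

  eps <- 0.01
  m2 <- merge_scans(spectrum(wl, ab + eps), spectrum(wl, ab - eps))
  expect_equal(m2$absorbance, ab)

  expect_error(merge_scans(down, spectrum(wl + 1, ab)), "grid")

  # across 100 seeded replicate pairs the merged scan recovers the peak
  # better than either single scan
  errs <- vapply(1:100, function(i) {
    d <- gen_spectrum(lambda_max_a1 = 505, peak_absorbance = 1,
                      noise_sd = 0.02, seed = i)$spectrum
    u <- gen_spectrum(lambda_max_a1 = 505, peak_absorbance = 1,
                      noise_sd = 0.02, seed = i + 5000)$spectrum
    c(d = find_peak(d)$lambda_peak, u = find_peak(u)$lambda_peak,
      m = find_peak(merge_scans(d, u))$lambda_peak)
  }, c(d = 0, u = 0, m = 0))
  true_peak <- 350:750
  true_peak <- true_peak[which.max(
    evaluate_template(template_spec("A1", 505), 350:750))]
  mae <- rowMeans(abs(errs - true_peak))
  expect_lt(mae[["m"]], mae[["d"]])
  expect_lt(mae[["m"]], mae[["u"]])
})

test_that("find_peak recovers Gaussian and template peaks", {
  wl <- 350:750
  # exact Gaussian self-recovery
  g <- exp(-(wl - 505)^2 / (2 * 20^2)) * 0.02
  pk <- find_peak(spectrum(wl, g))
  expect_equal(pk$lambda_peak, 505, tolerance = 0.01)
  expect_equal(pk$peak_absorbance, 0.02, tolerance = 1e-6)
  expect_true(pk$reliable)
  expect_identical(pk$n_points_used, 40L)

  # noiseless A1 template: within 1 nm of the template's own peak
  tv <- evaluate_template(template_spec("A1", 505), wl)
  pk2 <- find_peak(spectrum(wl, tv))
  expect_lt(abs(pk2$lambda_peak - wl[which.max(tv)]), 1)

  # 200 seeded noisy spectra: median error under 1 nm (stated MSP accuracy)
  errs <- vapply(1:200, function(i) {
    sp <- gen_spectrum(lambda_max_a1 = 505, peak_absorbance = 1,
                       noise_sd = 0.01, seed = i)$spectrum
    find_peak(sp)$lambda_peak - 505
  }, 0)
  expect_lt(median(abs(errs)), 1)

  # contiguous-window mode works on the same data
  pkc <- find_peak(spectrum(wl, g), contiguous = TRUE)
  expect_equal(pkc$lambda_peak, 505, tolerance = 0.01)

  expect_error(find_peak(spectrum(wl, g - 0.019)), "non-positive")
})

test_that("normalization is idempotent and scale-invariant", {
  sp <- gen_spectrum(lambda_max_a1 = 505, peak_absorbance = 0.02,
                     noise_sd = 0.001, seed = 3)$spectrum
  n1 <- normalize_spectrum(sp)
  n2 <- normalize_spectrum(n1)
  expect_equal(n1$absorbance, n2$absorbance, tolerance = 1e-9)

  scaled <- spectrum(sp$wavelength, sp$absorbance * 3)
  expect_equal(normalize_spectrum(scaled)$absorbance, n1$absorbance,
               tolerance = 1e-9)
  # the fitted peak of the normalized spectrum is 1; the raw maximum exceeds
  # it only by noise
  expect_equal(find_peak(n1)$peak_absorbance, 1, tolerance = 0.02)
  expect_equal(max(n1$absorbance), 1, tolerance = 0.2)
})

test_that("fit_template self-recovers and prefers the generating chromophore", {
  wl <- 350:750
  a1 <- spectrum(wl, evaluate_template(template_spec("A1", 505), wl))
  f <- fit_template(a1, "A1")
  expect_equal(f$lambda_max, 505, tolerance = 0.5)
  expect_lt(f$sse, 1e-6)
  expect_identical(f$lambda_max_reported, 505L)

  a2 <- spectrum(wl, evaluate_template(template_spec("A2", 526), wl))
  f1 <- fit_template(a2, "A1")
  f2 <- fit_template(a2, "A2")
  expect_lt(f2$sse, f1$sse)
  expect_equal(f2$lambda_max, 526, tolerance = 0.5)
})

test_that("grid argmin matches a 0.01-nm brute-force scan on noisy spectra", {
  for (i in 1:5) {
    sp <- gen_spectrum(lambda_max_a1 = 505, peak_absorbance = 1,
                       noise_sd = 0.01, seed = 100 + i)$spectrum
    pk <- find_peak(sp)
    norm <- normalize_spectrum(sp, pk)
    f <- fit_template(norm, "A1", pk)
    brute <- oracle_fit_argmin(norm, "A1", pk$lambda_peak)
    expect_lt(abs(f$lambda_max - brute), 0.1 + 1e-9)
  }
})

test_that("chromophore decision follows SSE, the 580-nm rule, and the tie rule", {
  mkfit <- function(ch, lm, sse) {
    structure(list(chromophore = ch, lambda_max = lm,
                   lambda_max_reported = as.integer(round(lm)), sse = sse,
                   n_points_fit = 30L, fit_window = c(lm, lm + 40)),
              class = "template_fit")
  }
  d <- decide_chromophore(mkfit("A1", 505, 0.01), mkfit("A2", 509, 0.03))
  expect_identical(d$best, "A1")
  expect_false(d$a2_flag)
  expect_false(d$tie)

  # A1 best fit far in the red still flags A2 presence
  d2 <- decide_chromophore(mkfit("A1", 635, 0.01), mkfit("A2", 626, 0.03))
  expect_identical(d2$best, "A1")
  expect_true(d2$a2_flag)

  d3 <- decide_chromophore(mkfit("A1", 505, 0.02), mkfit("A2", 509, 0.02))
  expect_identical(d3$best, "A1")
  expect_true(d3$tie)

  d4 <- decide_chromophore(mkfit("A1", 505, 0.05), mkfit("A2", 509, 0.01))
  expect_identical(d4$best, "A2")
  expect_true(d4$a2_flag)
})

test_that("classify_cell uses the default ranid bins", {
  expect_identical(classify_cell(505), "RH1_rod")
  expect_identical(classify_cell(433), "SWS2_rod")
  expect_identical(classify_cell(626), "LWS_cone")
  expect_identical(classify_cell(470), "unknown")
  bad <- data.frame(cell_class = c("a", "b"), lo = c(400, 430),
                    hi = c(440, 460))
  expect_error(classify_cell(435, bad), "overlap")
})

test_that("summarize_class means, counts, and recovery on a simulated class", {
  res <- data.frame(cell_id = c("c1", "c2"), cell_class = "RH1_rod",
                    best = c("A1", "A1"), lambda_max = c(504, 506),
                    lambda_max_reported = c(504L, 506L),
                    lambda_max_a1 = c(504, 506), sse_a1 = c(0.1, 0.1),
                    lambda_max_a2 = c(508, 510), sse_a2 = c(0.2, 0.2),
                    a2_flag = FALSE, rejected = FALSE)
  s <- summarize_class(res)
  expect_identical(s$n_cells, 2L)
  expect_equal(s$mean_lambda_max, 505)
  expect_identical(s$mean_lambda_max_reported, 505L)
  expect_identical(s$n_best_a1, 2L)

  s1 <- summarize_class(res[1, ])
  expect_equal(s1$mean_lambda_max, res$lambda_max[1])

  # parameter recovery: 18 cells at true lambda-max 505 (SD 2), noise 0.01
  pop <- gen_cell_population(
    data.frame(class = "RH1_rod", lambda_mean = 505, lambda_sd = 2,
               chromophore = "A1", n = 18),
    noise_sd = 0.01, peak_absorbance = 1, seed = 9)
  fits <- fit_cells(pop$spectra)
  s2 <- summarize_class(fits)
  expect_lt(abs(s2$mean_lambda_max[s2$group == "RH1_rod"] - 505), 1.5)
})

test_that("fitted lambda-max is monotone in the true value (noiseless)", {
  wl <- 350:750
  fitted <- vapply(seq(480, 560, 10), function(lm) {
    sp <- spectrum(wl, evaluate_template(template_spec("A1", lm), wl))
    fit_template(sp, "A1")$lambda_max
  }, 0)
  expect_true(all(diff(fitted) >= 0))
})

test_that("A1-template fitted lambda-max rises with the A2 pigment fraction", {
  wl <- 350:750
  s1 <- template_spec("A1", 505)
  s2 <- template_spec("A2", 526)
  fitted <- vapply(seq(0, 1, 0.2), function(f) {
    sp <- spectrum(wl, mixture_template(s1, s2, f, wl))
    fit_template(sp, "A1")$lambda_max
  }, 0)
  expect_true(all(diff(fitted) >= 0))
  expect_gt(fitted[6] - fitted[1], 10)
})

test_that("flat spectra are rejected as pigment-free", {
  wl <- 350:750
  flat <- gen_spectrum(peak_absorbance = 1e-6, noise_sd = 0.01,
                       seed = 2)$spectrum
  r <- fit_cell(flat)
  expect_true(r$rejected)
  expect_match(r$reject_reason, "no pigment")
  tab <- fit_cells(list(flat))
  expect_true(tab$rejected)
})
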