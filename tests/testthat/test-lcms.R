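# small handmade run: 3 scans, peaks at known m/z
toy_run <- function() {
  centroided_run(
    rt = c(1.0, 1.0, 1.5, 2.0),
    mz = c(500.000, 500.002, 500.000, 700.000),
    intensity = c(10, 5, 20, 7)
  )
}

test_that("centroided runs validate their invariants", {
  expect_error(centroided_run(numeric(0), numeric(0), numeric(0)), "empty")
  expect_error(centroided_run(c(1, 1), c(500, 501), c(1, -2)), ">= 0")
  r <- toy_run()
  expect_equal(length(r$scan_rt), 3)
  expect_true(!is.unsorted(r$scan_rt, strictly = TRUE))
})

test_that("EIC extraction sums centroids inside the ppm window", {
  r <- toy_run()
  # nothing near the target: all-zero trace
  none <- extract_eic(r, 900, 10)
  expect_equal(none$intensity, c(0, 0, 0))
  # 500.002 is 4 ppm from 500.000: included at 10 ppm, excluded at 1 ppm
  wide <- extract_eic(r, 500.000, 10)
  expect_equal(wide$intensity, c(15, 20, 0))  # brute-force sum of both centroids
  narrow <- extract_eic(r, 500.000, 1)
  expect_equal(narrow$intensity, c(10, 20, 0))
  single <- extract_eic(r, 700, 10)
  expect_equal(single$intensity, c(0, 0, 7))
  expect_error(extract_eic(r, 500, 0), "tolerance")
})

test_that("peak integration is a baseline-subtracted trapezoid", {
  flat <- structure(list(target_mz = 500, tolerance_ppm = 10,
                         rt = seq(0, 1, 0.1), intensity = rep(7, 11)),
                    class = "eic_trace")
  expect_equal(integrate_peak(flat, c(0, 1)), 0)

  # triangular peak height h base b on zero baseline: area h*b/2
  rt <- seq(0, 2, by = 0.005)
  h <- 100; b <- 1
  tri <- pmax(h * (1 - abs(rt - 1) / (b / 2)), 0)
  trace <- structure(list(target_mz = 500, tolerance_ppm = 10,
                          rt = rt, intensity = tri), class = "eic_trace")
  expect_equal(integrate_peak(trace, c(0.4, 1.6)), h * b / 2, tolerance = 1e-2)

  zero <- structure(list(target_mz = 500, tolerance_ppm = 10,
                         rt = rt, intensity = rep(0, length(rt))),
                    class = "eic_trace")
  expect_equal(integrate_peak(zero, c(0, 2)), 0)
  expect_error(integrate_peak(trace, c(1.6, 0.4)), "precede")
  expect_error(integrate_peak(trace, c(5, 6)), "outside")
})

test_that("noiseless synthetic runs are matched with correct names and areas", {
  lib <- build_library()
  q <- quant_table(c("M4", "D44", "T444"), c(50, 30, 20))
  sim <- gen_lcms_run(q, lib, ppm_noise_sd = 0, peak_cv = 0, seed = 1)
  # match against the retention-time-annotated species; species that share a
  # residue multiset (e.g. D53 and D44) are isobaric and can only be told
  # apart chromatographically
  known <- sim$library[match(q$name, sim$library$name), ]
  ids <- match_run(sim$run, known)
  expect_equal(sort(ids$name), sort(q$name))
  expect_equal(ids$mass_error_ppm, rep(0, 3), tolerance = 1e-9)
  # relative areas reproduce the generated proportions within 1%
  got <- ids$area[match(q$name, ids$name)]
  expect_equal(got / sum(got), q$molar_percent / 100, tolerance = 0.01)
})

test_that("mass tolerance prevents cross-matching", {
  lib <- build_library()
  # run containing only M4: D44 (mass far away) must not be identified
  q <- quant_table("M4", 100)
  sim <- gen_lcms_run(q, lib, ppm_noise_sd = 0, peak_cv = 0, seed = 1)
  two <- sim$library[match(c("M4", "D44"), sim$library$name), ]
  two$rt[2] <- two$rt[1]  # even at the same retention time
  ids <- match_run(sim$run, two)
  expect_equal(ids$name, "M4")

  # 20 ppm mass noise against a 0.1 ppm window: everything falls outside
  sim_noisy <- gen_lcms_run(q, lib, ppm_noise_sd = 20, peak_cv = 0, seed = 2)
  ids0 <- match_run(sim_noisy$run, sim_noisy$library[sim_noisy$library$name == "M4", ],
                    tolerance_ppm = 0.1)
  expect_equal(nrow(ids0), 0)
})

test_that("molar normalization is exact, scale-invariant and conserves 100%", {
  ids <- data.frame(name = c("a", "b", "c"), area = c(1, 1, 2))
  q <- normalize_molar(ids)
  expect_equal(q$molar_percent, c(25, 25, 50))
  expect_equal(sum(q$molar_percent), 100, tolerance = 1e-6)

  expect_equal(normalize_molar(data.frame(name = "x", area = 7))$molar_percent, 100)
  expect_error(normalize_molar(data.frame(name = "x", area = 0)), "positive area")

  doubled <- normalize_molar(transform(ids, area = area * 2))
  expect_equal(doubled$molar_percent, q$molar_percent)

  # round trip: Table-proportioned percentages in, identical percentages out
  pcts <- c(45.16, 43.29, 10.54, 1.01)
  rt <- quant_table(c("m", "d", "t", "q"), pcts)
  expect_equal(sort(rt$molar_percent), sort(pcts), tolerance = 1e-6)
})

test_that("stochastic round trip recovers molar percentages within 1.5 points", {
  lib <- build_library()
  q <- quant_table(c("M4", "M3", "D44", "D43", "D44N", "T444", "Q4444",
                     "M4N", "M3N", "D43N"),
                   c(30, 7.21, 20, 15.34, 3, 10.54, 1.01, 3.5, 1.45, 7.95))
  sim <- gen_lcms_run(q, lib, ppm_noise_sd = 5, peak_cv = 0.05, seed = 11)
  known <- sim$library[match(q$name, sim$library$name), ]
  rec <- normalize_molar(match_run(sim$run, known))
  truth_pct <- 100 * sim$truth$amount / sum(sim$truth$amount)
  got <- rec$molar_percent[match(sim$truth$name, rec$name)]
  expect_lt(max(abs(got - truth_pct)), 1.5)
})

test_that("centroided mzML files load through the mzR backend", {
  r <- read_mzml(test_path("synthetic_centroided.mzML"))
  expect_s3_class(r, "centroided_run")
  expect_equal(r$scan_rt, c(0.50, 0.51, 0.52))
  expect_equal(extract_eic(r, 942.4150, 10)$intensity, c(100, 250, 120))
})

test_that("peak tables read from CSV reproduce the run", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(rt_min = c(1, 1, 2), mz = c(500, 600, 500),
                       intensity = c(5, 6, 7)), path, row.names = FALSE)
  r <- read_peak_table(path)
  expect_equal(length(r$scan_rt), 2)
  expect_equal(extract_eic(r, 500, 10)$intensity, c(5, 7))
})
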