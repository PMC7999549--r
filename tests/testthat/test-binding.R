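mklanes <- function(conc, rel_by_rep, antibiotic = "drug", ctrl = 100) {
  # rel_by_rep: list per replicate of relative values at conc
  rows <- list()
  for (r in seq_along(rel_by_rep)) {
    rows[[length(rows) + 1L]] <- data.frame(
      antibiotic = antibiotic, concentration = 0, replicate = r,
      intensity = ctrl)
    rows[[length(rows) + 1L]] <- data.frame(
      antibiotic = antibiotic, concentration = conc, replicate = r,
      intensity = ctrl * rel_by_rep[[r]])
  }
  do.call(rbind, rows)
}

test_that("relative binding normalizes each replicate to its own control", {
  conc <- c(1, 10, 100)
  tr <- relative_binding(mklanes(conc, list(c(1, 1, 1), c(1, 1, 1))))
  expect_equal(tr$curve$mean_rel, c(1, 1, 1, 1))
  expect_equal(tr$curve$sd, rep(0, 4))

  # single replicate: flagged, sd reported as 0
  tr1 <- relative_binding(mklanes(1, list(0.25)))
  expect_true(tr1$single_replicate)
  expect_equal(tr1$curve$mean_rel[tr1$curve$concentration == 1], 0.25)
  expect_equal(tr1$curve$sd, c(0, 0))

  # two replicates 0.4 and 0.6: mean 0.5, sd sqrt(0.02) = 0.1414...
  tr2 <- relative_binding(mklanes(1, list(0.4, 0.6)))
  at1 <- tr2$curve[tr2$curve$concentration == 1, ]
  expect_equal(at1$mean_rel, 0.5)
  expect_equal(at1$sd, 0.14142136, tolerance = 1e-7)

  bad <- mklanes(1, list(0.5)); bad$intensity[bad$concentration == 0] <- 0
  expect_error(relative_binding(bad), "> 0")
  expect_error(relative_binding(bad[bad$concentration > 0, ]), "control")
})

test_that("titration results are invariant to overall intensity scaling", {
  lanes <- mklanes(c(1, 10, 100), list(c(0.8, 0.5, 0.2), c(0.9, 0.45, 0.25)))
  a <- relative_binding(lanes)
  lanes2 <- transform(lanes, intensity = intensity * 37.5)
  b <- relative_binding(lanes2)
  expect_equal(a$curve, b$curve)
  expect_equal(ic50_interpolate(a), ic50_interpolate(b))
})

test_that("responses classify as inhibition, enhancement or weak", {
  descend <- relative_binding(mklanes(c(1, 10, 100),
                                      list(c(0.9, 0.4, 0.1))))
  expect_equal(classify_response(descend), "inhibition")
  rise <- relative_binding(mklanes(c(1, 10, 100),
                                   list(c(1.0, 1.2, 1.5))))
  expect_equal(classify_response(rise), "enhancement")
  mild <- relative_binding(mklanes(c(1, 10, 100),
                                   list(c(1.05, 0.95, 0.85))))
  expect_equal(classify_response(mild), "weak")

  # property: a monotone-decreasing curve that reaches the inhibition
  # threshold is never classed enhancement
  for (seed in 1:20) {
    set.seed(seed)
    rels <- sort(runif(5, 0, 1.1), decreasing = TRUE)
    rels[5] <- min(rels[5], 0.4)
    tr <- relative_binding(mklanes(10^(0:4), list(rels)))
    expect_false(classify_response(tr) == "enhancement")
  }
})

test_that("IC50 interpolation works on the log-concentration scale", {
  # 1.0 at c=1 and 0.0 at c=100 cross 0.5 at the log midpoint, 10
  tr <- relative_binding(mklanes(c(1, 100), list(c(1, 0))))
  expect_equal(ic50_interpolate(tr), 10, tolerance = 1e-9)
  # never below 0.6: undefined
  high <- relative_binding(mklanes(c(1, 10, 100), list(c(1, 0.8, 0.65))))
  expect_true(is.na(ic50_interpolate(high)))
  # dense noiseless log-logistic curve: recovered within 10%
  sim <- gen_titration(ic50 = 3, hill = 1.2, noise_cv = 0,
                       concentrations = 10^seq(-2, 2, length.out = 41),
                       replicates = 1, seed = 1)
  tr2 <- relative_binding(sim$lanes)
  expect_equal(ic50_interpolate(tr2), 3, tolerance = 0.1)
})

test_that("protein-amount linearity fits behave on exact and flat input", {
  exact <- data.frame(amount = 1:5, intensity = 2 * (1:5))
  fit <- linearity_check(exact)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1)
  flat <- data.frame(amount = 1:5, intensity = rep(3, 5))
  expect_equal(linearity_check(flat)$slope, 0)
  expect_error(linearity_check(exact[1:2, ]), "3 points")
  expect_error(linearity_check(data.frame(amount = rep(1, 4),
                                          intensity = 1:4)), "variance")
  # noisy synthetic points with slope 2: recovered within 5%
  set.seed(9)
  pts <- data.frame(amount = seq(0.5, 5, 0.5))
  pts$intensity <- 2 * pts$amount * (1 + rnorm(nrow(pts), 0, 0.01))
  expect_equal(linearity_check(pts)$slope, 2, tolerance = 0.05)
})

test_that("the titrate wrapper analyzes several antibiotics at once", {
  inh <- gen_titration("penicillinG", ic50 = 1, seed = 2)$lanes
  enh <- gen_titration("aztreonam", enhancement = TRUE, amplitude = 0.5,
                       seed = 3)$lanes
  res <- titrate(rbind(inh, enh))
  expect_setequal(names(res), c("penicillinG", "aztreonam"))
  expect_equal(res$penicillinG$response_class, "inhibition")
  expect_equal(res$aztreonam$response_class, "enhancement")
  expect_false(is.na(res$penicillinG$ic50))
})
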