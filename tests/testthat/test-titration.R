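# Competitive fast-exchange titrations: shift algebra, the slope estimator,
# and relay chaining.

test_that("fast-exchange shift algebra has the exact limiting cases", {
  dH <- -57.94; dHp <- -58.52
  expect_equal(bound_ratio_from_shift((dH + dHp) / 2, dH, dHp), 1,
               tolerance = 1e-12)
  # near the H' endpoint the ratio vanishes
  expect_equal(bound_ratio_from_shift(dHp + 1e-9, dH, dHp), 0,
               tolerance = 1e-6)
  expect_error(bound_ratio_from_shift(dH, dH, dHp), "endpoint")
  expect_error(bound_ratio_from_shift(dHp - 0.1, dH, dHp), "endpoint")
  expect_error(bound_ratio_from_shift(-58, -58.2, -58.2), "identical")
})

test_that("ideal-mixture solubility is linear in the molar fraction", {
  expect_identical(mixture_solubility(1, 2.5e-4), 2.5e-4)
  expect_identical(mixture_solubility(0, 2.5e-4), 0)
  expect_equal(mixture_solubility(0.5, 0.002), 0.001, tolerance = 1e-15)
  expect_error(mixture_solubility(1.2, 1), "\\[0, 1\\]")
  expect_error(mixture_solubility(0.5, -1), "positive")
})

test_that("titration series enforces its invariants", {
  expect_error(
    titration_series("a", "b", -57.94, -58.52, 1e-4, 2e-4,
                     x_H = c(0.3, 0.5), delta_obs = c(-58.2, -58.1),
                     x_Hprime = c(0.6, 0.5)),
    "within 1e-9")
  expect_error(
    titration_series("a", "b", -57.94, -58.52, 1e-4, 2e-4,
                     x_H = c(0.3, 0.5), delta_obs = c(-59, -58.1)),
    "between the endpoint")
  expect_error(
    titration_series("a", "b", -58, -58, 1e-4, 2e-4,
                     x_H = 0.5, delta_obs = -58),
    "differ")
})

test_that("noiseless synthetic series are fitted back exactly", {
  for (K in c(0.1, 1, 10, 448)) {
    ts <- simulate_titration(true_K_rel = K, noise_sd = 0, seed = 1)
    fit <- fit_competition(ts)
    expect_equal(fit$K_rel, K, tolerance = 1e-6 * K)
    expect_lt(abs(fit$intercept), 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("symmetric unit-affinity design gives slope 1 and zero intercept", {
  ts <- simulate_titration(true_K_rel = 1, S0_H = 2e-4, S0_Hprime = 2e-4,
                           noise_sd = 0, seed = 3)
  fit <- fit_competition(ts)
  expect_equal(fit$K_rel, 1, tolerance = 1e-9)
  expect_lt(abs(fit$intercept), 1e-9)
})

test_that("swapping the two guests yields the reciprocal affinity", {
  ts <- simulate_titration(true_K_rel = 25, noise_sd = 0.003, seed = 9)
  fwd <- fit_competition(ts)
  swapped <- titration_series(ts$guest_Hprime, ts$guest_H,
                              ts$delta_Hprime, ts$delta_H,
                              ts$S0_Hprime, ts$S0_H,
                              x_H = ts$points$x_Hprime,
                              delta_obs = ts$points$delta_obs,
                              x_Hprime = ts$points$x_H)
  rev <- fit_competition(swapped)
  # reciprocal within combined propagated uncertainty
  se_rec <- rev$K_rel_se / rev$K_rel^2
  tol <- 2 * sqrt(fwd$K_rel_se^2 + (se_rec * fwd$K_rel^2)^2) / fwd$K_rel^2 *
    fwd$K_rel^2
  expect_lt(abs(fwd$K_rel - 1 / rev$K_rel), max(tol, 0.05 * fwd$K_rel))
})

test_that("through-origin option reports both estimates, close on good data", {
  ts <- simulate_titration(true_K_rel = 50, noise_sd = 0.002, seed = 5)
  fit <- fit_competition(ts, through_origin = TRUE)
  expect_false(is.null(fit$K_rel_origin))
  expect_equal(fit$K_rel_origin / fit$K_rel, 1, tolerance = 0.1)
})

test_that("fit refuses short series and flags non-positive slopes", {
  ts <- simulate_titration(true_K_rel = 5, noise_sd = 0, seed = 2,
                           n_points = 8)
  short <- titration_series(ts$guest_H, ts$guest_Hprime, ts$delta_H,
                            ts$delta_Hprime, ts$S0_H, ts$S0_Hprime,
                            x_H = ts$points$x_H[1:2],
                            delta_obs = ts$points$delta_obs[1:2])
  expect_error(fit_competition(short), "at least 3")
  # reversing the response ordering manufactures a negative slope
  bad <- titration_series(ts$guest_H, ts$guest_Hprime, ts$delta_H,
                          ts$delta_Hprime, ts$S0_H, ts$S0_Hprime,
                          x_H = ts$points$x_H,
                          delta_obs = rev(ts$points$delta_obs))
  expect_warning(fbad <- fit_competition(bad), "non-positive")
  expect_true(fbad$flagged)
})

test_that("relay chaining composes, rescales, and reports provenance", {
  m <- data.frame(numerator_guest = c("a", "b"),
                  denominator_guest = c("b", "c"),
                  K_rel = c(2, 3), K_rel_se = c(0.1, 0.1))
  res <- chain_affinities(m, "c")
  expect_equal(res$K_rel[res$guest == "a"], 6, tolerance = 1e-12)
  expect_equal(res$K_rel[res$guest == "c"], 1, tolerance = 1e-12)
  # log-space error propagation: (se/K)^2 adds along the path
  rel_var <- (0.1 / 2)^2 + (0.1 / 3)^2
  expect_equal(res$K_rel_se[res$guest == "a"], 6 * sqrt(rel_var),
               tolerance = 1e-12)
  expect_match(res$provenance[res$guest == "a"], "a/b")
  # identity: a guest measured directly against the reference
  single <- data.frame(numerator_guest = "x", denominator_guest = "ref",
                       K_rel = 7, K_rel_se = 0.2)
  out <- chain_affinities(single, "ref")
  expect_equal(out$K_rel[out$guest == "x"], 7, tolerance = 1e-12)
})

test_that("rescaling the packaged ladder from cycloheptene to benzene", {
  t1 <- cb_table("table1")
  m <- data.frame(numerator_guest = t1$id,
                  denominator_guest = "19",
                  K_rel = t1$K_cycloheptene_P3 / 1000,
                  K_rel_se = 0)
  m <- m[m$numerator_guest != "19", ]
  res <- chain_affinities(m, "18")
  # published normalization used unrounded data; rounded-column ratios
  # agree within 2.5%
  for (id in t1$id) {
    expect_lt(abs(res$K_rel[res$guest == id] /
                    t1$K_benzene_P3[t1$id == id] - 1), 0.025,
              label = paste("guest", id))
  }
  expect_equal(res$K_rel[res$guest == "14"], 110, tolerance = 110 * 0.02)
})

test_that("chaining rejects disconnected guests and inconsistent cycles", {
  m <- data.frame(numerator_guest = c("a", "x"),
                  denominator_guest = c("b", "y"),
                  K_rel = c(2, 3), K_rel_se = c(0.01, 0.01))
  expect_error(chain_affinities(m, "b"), "not connected")
  # a 3-cycle whose product is far from 1
  cyc <- data.frame(numerator_guest = c("a", "b", "a"),
                    denominator_guest = c("b", "c", "c"),
                    K_rel = c(2, 3, 60), K_rel_se = c(0.01, 0.01, 0.01))
  expect_error(chain_affinities(cyc, "c"), "inconsistent cycle")
  # consistent cycle passes
  ok <- data.frame(numerator_guest = c("a", "b", "a"),
                   denominator_guest = c("b", "c", "c"),
                   K_rel = c(2, 3, 6.001), K_rel_se = c(0.05, 0.05, 0.05))
  expect_silent(chain_affinities(ok, "c"))
})
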