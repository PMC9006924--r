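# Cavity characterization: the pre-formed cavity regressions, mixture
# optimization, descriptor correlations, outlier flagging, prediction.

test_that("dispersion terms combine solvation and cavitation per guest", {
  g <- toy_guests()
  sv <- cb_solvents()
  x <- dispersion_terms(g, sv$benzene)
  expect_equal(unname(x), g$solv_benzene - g$cav_benzene, tolerance = 1e-12)
  mix <- solvent_mixture(list(sv$pfh, sv$benzene), c(0.68, 0.32))
  xm <- dispersion_terms(g, mix)
  expect_equal(unname(xm),
               0.68 * (g$solv_pfh - g$cav_pfh) +
                 0.32 * (g$solv_benzene - g$cav_benzene),
               tolerance = 1e-12)
  expect_error(dispersion_terms(g, sv$benzene, ids = "zz"), "unknown guest")
  # missing cavitation cells are filled from the solvent model
  g2 <- g; g2$cav_benzene[2] <- NA
  x2 <- dispersion_terms(g2, sv$benzene)
  expect_equal(unname(x2[2]),
               g$solv_benzene[2] -
                 solvent_cavitation(g$sigma_prime[2], sv$benzene),
               tolerance = 1e-12)
})

test_that("a host equal to its mimic terms fits the identity line", {
  g <- toy_guests()
  sv <- cb_solvents()
  x <- dispersion_terms(g, sv$benzene)
  hd <- host_data("self", x)
  cf <- characterize_cavity(hd, g, sv$benzene)
  expect_equal(cf$fit$slope, 1, tolerance = 1e-10)
  expect_lt(abs(cf$fit$intercept), 1e-10)
  expect_equal(cf$fit$r_squared, 1, tolerance = 1e-12)
})

test_that("headline characterizations reproduce the published fits", {
  sv <- cb_solvents()
  p3 <- characterize_cavity(cb_host("CB8.P3"), mimic = sv$benzene)
  expect_equal(p3$fit$slope, 1.00, tolerance = 0.005)
  expect_equal(p3$fit$r_squared, 0.97, tolerance = 0.005)
  expect_lt(abs(p3$fit$slope_se - 0.07), 0.005)
  expect_equal(p3$fit$n, 9)

  cb6 <- characterize_cavity(cb_host("CB6"), mimic = sv$pfh)
  expect_equal(cb6$fit$slope, 0.95, tolerance = 0.005)
  expect_equal(cb6$fit$n, 7)

  cb7 <- characterize_cavity(cb_host("CB7"), mimic = sv$pfh)
  expect_equal(cb7$fit$slope, 1.14, tolerance = 0.005)
  expect_equal(cb7$fit$n, 14)  # methane curated out by default

  cb5 <- characterize_cavity(cb_host("CB5"), mimic = sv$pfh)
  expect_equal(cb5$fit$slope, 1.30, tolerance = 0.005)
  expect_equal(cb5$fit$n, 6)   # ethane curated out
})

test_that("the 68:32 mixture gives the published unity-slope fit", {
  sv <- cb_solvents()
  mix <- solvent_mixture(list(sv$pfh, sv$benzene), c(0.68, 0.32))
  cf <- characterize_cavity(cb_host("CB5"), mimic = mix)
  expect_equal(cf$fit$slope, 1.00, tolerance = 0.005)
  expect_lt(abs(cf$fit$intercept - (-0.68)), 0.005)
  expect_lt(abs(cf$fit$intercept_se - 0.17), 0.005)
})

test_that("mixture-fraction optimization finds the unity-slope composition", {
  sv <- cb_solvents()
  opt <- optimize_mixture_fraction(cb_host("CB5"), cb_guests(),
                                   sv$pfh, sv$benzene)
  expect_equal(opt$fraction, 0.68, tolerance = 0.005)
  expect_equal(opt$characterization$fit$slope, 1, tolerance = 1e-3)
  # endpoints reproduce the pure-solvent characterizations
  pure <- characterize_cavity(cb_host("CB5"), mimic = sv$pfh)
  at1 <- optimize_mixture_fraction(cb_host("CB5"), cb_guests(), sv$pfh,
                                   sv$benzene,
                                   target_slope = pure$fit$slope)
  expect_equal(at1$fraction, 1, tolerance = 1e-3)
  # a host built from pure solvent A terms roots at fraction 1
  g <- toy_guests()
  hd <- host_data("pureA", dispersion_terms(g, sv$pfh))
  optA <- optimize_mixture_fraction(hd, g, sv$pfh, sv$benzene)
  expect_equal(optA$fraction, 1, tolerance = 1e-3)
  # unreachable target reports the bracketing slopes
  expect_error(optimize_mixture_fraction(cb_host("CB5"), cb_guests(),
                                         sv$pfh, sv$benzene,
                                         target_slope = 5),
               "no root")
})

test_that("descriptor correlations match the published coefficients", {
  alpha_fit <- correlate_descriptor(cb_host("CB8.P3"), descriptor = "alpha")
  expect_equal(alpha_fit$r_squared, 0.97, tolerance = 0.005)
  # two guests always give a perfect line
  hd <- host_data("two", c(`1` = -3, `18` = -6))
  expect_equal(correlate_descriptor(hd, descriptor = "alpha")$r_squared, 1,
               tolerance = 1e-12)
  # CB7 polarizability correlation is good but weaker than the mimic fit
  cb7a <- correlate_descriptor(cb_host("CB7"), descriptor = "alpha",
                               exclusions = character())
  expect_gt(cb7a$r_squared, 0.85)
  expect_lt(cb7a$r_squared, 0.95)
  expect_error(correlate_descriptor(cb_host("CB7"), descriptor = "sasa"),
               "lacks column")
})

test_that("relative datasets shift both axes to the reference guest", {
  g <- toy_guests()
  sv <- cb_solvents()
  x <- dispersion_terms(g, sv$benzene)
  y_abs <- 1.3 * x - 2
  hd_abs <- host_data("abs", y_abs)
  hd_rel <- host_data("rel", y_abs - y_abs[["b"]], reference_guest = "b")
  f_abs <- characterize_cavity(hd_abs, g, sv$benzene)
  f_rel <- characterize_cavity(hd_rel, g, sv$benzene)
  expect_equal(f_rel$fit$slope, f_abs$fit$slope, tolerance = 1e-10)
  expect_equal(f_rel$fit$r_squared, f_abs$fit$r_squared, tolerance = 1e-10)
  # intercept becomes reference-relative: 0 for an exact line
  expect_lt(abs(f_rel$fit$intercept), 1e-10)
})

test_that("outlier flagging combines the statistical rule with curation", {
  # the probe-P1 vs probe-P3 comparison: cyclooctatetraene stands out
  t1 <- cb_table("table1")
  f <- ols(t1$ddG_gas_P1, t1$ddG_gas_P3, ids = t1$id)
  flagged <- flag_outliers(f, curated = data.frame(
    id = "21", reason = "binds probe P3 far better than P1",
    stringsAsFactors = FALSE))
  expect_true("21" %in% flagged$id)
  st <- studentized_residuals(f)
  expect_gt(abs(st[["21"]]), 2.5)
  # refit without it reproduces the published probe-comparison slope
  keep <- t1$id != "21"
  f2 <- ols(t1$ddG_gas_P1[keep], t1$ddG_gas_P3[keep])
  expect_equal(f2$slope, 1.3, tolerance = 0.05)
  # perfect-line data yield no statistical flags
  clean <- ols(1:6, 2 * (1:6) + 1, ids = letters[1:6])
  expect_equal(nrow(flag_outliers(clean)), 0)
  expect_error(flag_outliers(ols(1:3, c(1, 2, 2.5))), "at least 4")
})

test_that("unity-slope screen surfaces the curated CB[8]P2 outliers", {
  sv <- cb_solvents()
  cf <- characterize_cavity(cb_host("CB8.P2"), mimic = sv$benzene,
                            exclusions = character(), slope = 1)
  flagged <- flag_outliers(cf)
  expect_true(all(c("14", "12") %in% flagged$id))
  expect_true("too large to fit" %in%
                flagged$reason[flagged$id %in% c("14", "12")])
  # after removing the two oversized guests the free fit is satisfactory
  cf2 <- characterize_cavity(cb_host("CB8.P2"), mimic = sv$benzene,
                             exclusions = c("14", "12"))
  expect_gt(cf2$fit$r_squared, 0.85)
})

test_that("prediction interpolates the fit and guards extrapolation", {
  g <- toy_guests()
  sv <- cb_solvents()
  x <- dispersion_terms(g, sv$benzene)
  hd <- host_data("lin", 2 * x + 1)
  cf <- characterize_cavity(hd, g, sv$benzene)
  pr <- predict(cf, g, ids = c("a", "c"))
  expect_equal(pr$predicted, unname(2 * x[c("a", "c")] + 1),
               tolerance = 1e-9)
  # identity characterization predicts x itself
  hd_id <- host_data("id", x)
  cf_id <- characterize_cavity(hd_id, g, sv$benzene)
  expect_equal(predict(cf_id, g, ids = "b")$predicted,
               unname(x["b"]), tolerance = 1e-9)
  # guest larger than any fitted guest triggers the size warning
  big <- rbind(g, data.frame(id = "big", name = "big", volume = 400,
                             sigma_prime = effective_diameter(400),
                             alpha = 20, solv_water = 0, solv_benzene = -8,
                             solv_pfh = -4, cav_benzene = 18, cav_pfh = 5))
  expect_warning(predict(cf, big, ids = "big"), "largest fitted guest")
  expect_error(predict(cf, g[1:3, ], ids = "d"), "unknown guest")
})

test_that("leave-one-out prediction lands near the held-out guest", {
  sv <- cb_solvents()
  cb6 <- cb_host("CB6")
  loo <- characterize_cavity(cb6, mimic = sv$pfh, exclusions = "12")
  # cyclopentane is larger than any guest left in the fit: size guard fires
  expect_warning(pr <- predict(loo, ids = "12"), "largest fitted guest")
  expect_equal(pr$predicted, -7.26, tolerance = 0.5)
  expect_true(pr$se > 0)
})

test_that("characterize validates coverage of the guest table", {
  sv <- cb_solvents()
  g <- toy_guests()
  hd <- host_data("h", c(a = 1, b = 2, zz = 3))
  expect_error(characterize_cavity(hd, g, sv$benzene), "unknown guest")
  g2 <- g; g2$solv_benzene[1] <- NA; g2$sigma_prime[1] <- NA
  hd2 <- host_data("h", stats::setNames(1:4, g$id))
  expect_error(characterize_cavity(hd2, g2, sv$benzene), "missing")
})
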