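# straight-line arithmetic oracle: each correlation written out in one
# expression directly from raw inputs, sharing no code with the package
oracle <- function(sigma, rho, f, We, Oh, IN, n = NULL, a = NULL) {
  b33 <- (pi * sigma / (rho * f^2))^0.33
  b13 <- (pi * sigma / (rho * f^2))^(1 / 3)
  list(
    lang = 0.34 * (8 * pi * sigma / (rho * f^2))^(1 / 3),
    rajan_pandit = b33 * (1 + a * We^0.22 * Oh^0.166 * IN^(-0.0277)),
    ramisetty = 0.00154 * b33 *
      (1 + (pi * sigma / (rho * f^2))^(-0.2) * We^0.154 * Oh^(-0.111) * IN^(-0.033)),
    avvaru = b13 + 0.0013 * We^0.008 * Oh^(-0.14 / n) * IN^0.28,
    barba = 0.058 * b33 * We^0.151 * Oh^0.192 * IN^(-0.02)
  )
}

test_that("Lang diameter matches its closed form and base-term identity", {
  d <- lang_diameter(0.07, 1004, 25000)
  expect_equal(d, 4.8e-5, tolerance = 0.01)
  # 0.34 * 8^(1/3) = 0.68 times the exponent-1/3 base term, for any inputs
  expect_equal(d / correlation_base_term(0.07, 1004, 25000, exponent = 1 / 3),
               0.68, tolerance = 1e-12)
  # frequency scaling d ~ f^(-2/3)
  expect_equal(lang_diameter(0.07, 1004, 50000), d * 2^(-2 / 3),
               tolerance = 1e-12)
})

test_that("Rajan-Pandit collapses to the base term at a_rp = 0 and needs a_rp", {
  base <- rajan_pandit_diameter(0.07, 1004, 25000, We = 25.1, Oh = 8.96e3,
                                I_N = 9.14e-13, a_rp = 0)
  expect_equal(base, correlation_base_term(0.07, 1004, 25000, 0.33))
  expect_equal(base, 7.75e-5, tolerance = 0.005)
  expect_error(rajan_pandit_diameter(0.07, 1004, 25000, 25.1, 8.96e3, 9.14e-13),
               "a_rp", class = "sonodrop_config_error")
  # monotone increasing in a_rp
  a <- seq(0, 2, by = 0.25)
  d <- vapply(a, function(ai) rajan_pandit_diameter(0.07, 1004, 25000, 25.1,
                                                    8.96e3, 9.14e-13, a_rp = ai),
              numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("Ramisetty prediction sits near the published 58 um under both policies", {
  for (pol in c("apparent", "zero_shear")) {
    ds <- ref_dims(pol)
    d <- ramisetty_diameter(0.07, 1004, 25000, ds$We, ds$Oh, ds$I_N)
    expect_equal(d * 1e6, 58, tolerance = 0.10)
  }
  # bracket floor: second term suppressed leaves 0.00154 * base
  expect_equal(0.00154 * correlation_base_term(0.07, 1004, 25000, 0.33),
               1.194676e-7, tolerance = 1e-5)
})

test_that("Ramisetty validity envelope flags the alginate case on Oh only", {
  ds <- ref_dims("zero_shear")
  vio <- check_validity(list(f = 25000, rho = 1004, sigma = 0.07,
                             Oh = ds$Oh, We = ds$We, I_N = ds$I_N))
  expect_equal(vio$quantity, "Oh")
  expect_gt(vio$value, 161.64)
  # We = 25.1 is inside [14.8, 571] so must not appear
  expect_false("We" %in% vio$quantity)
})

test_that("validity intervals are closed and midpoints always pass", {
  env <- ramisetty_envelope()
  mid <- lapply(env, mean)
  expect_equal(nrow(check_validity(mid, env)), 0L)
  # exactly on a bound: no violation
  at_bounds <- list(f = 20e3, rho = 1151, sigma = 0.0029, Oh = 161.64,
                    We = 14.8, I_N = 1.92e-9)
  expect_equal(nrow(check_validity(at_bounds, env)), 0L)
  just_out <- list(Oh = 161.64 * (1 + 1e-9))
  expect_equal(check_validity(just_out, env)$quantity, "Oh")
})

test_that("Avvaru prediction reproduces the published 71 um with exponent 1/3", {
  ds <- ref_dims("apparent")
  d <- avvaru_diameter(0.07, 1004, 25000, ds$We, ds$Oh, ds$I_N, n = 0.854)
  expect_equal(d * 1e6, 71, tolerance = 0.05)
  # vanishing correction: I_N -> 0 leaves the base term
  tiny <- avvaru_diameter(0.07, 1004, 25000, ds$We, ds$Oh, 1e-300, n = 0.854)
  expect_equal(tiny, correlation_base_term(0.07, 1004, 25000, 1 / 3))
  # Newtonian limit of the Oh exponent
  expect_equal(
    avvaru_diameter(0.07, 1004, 25000, ds$We, ds$Oh, ds$I_N, n = 1),
    correlation_base_term(0.07, 1004, 25000, 1 / 3) +
      0.0013 * ds$We^0.008 * ds$Oh^(-0.14) * ds$I_N^0.28)
  expect_error(avvaru_diameter(0.07, 1004, 25000, 25, 9e3, 9e-13, n = 1.2),
               class = "sonodrop_input_error")
})

test_that("Barba prediction sits near the published 76 um under both policies", {
  for (pol in c("apparent", "zero_shear")) {
    ds <- ref_dims(pol)
    d <- barba_diameter(0.07, 1004, 25000, ds$We, ds$Oh, ds$I_N)
    expect_equal(d * 1e6, 76, tolerance = 0.10)
  }
  # unit dimensionless numbers leave 0.058 * base exactly
  expect_equal(barba_diameter(0.07, 1004, 25000, 1, 1, 1),
               0.058 * correlation_base_term(0.07, 1004, 25000, 0.33))
  # monotone increasing in Oh (exponent +0.192)
  ds <- ref_dims("apparent")
  Ohs <- c(10, 100, 1000, 1e4)
  d <- vapply(Ohs, function(oh) barba_diameter(0.07, 1004, 25000, ds$We, oh,
                                               ds$I_N), numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("all diameters fall with frequency over 20-130 kHz", {
  f <- seq(20e3, 130e3, length.out = 23)
  Am <- vibration_amplitude(power_intensity(10, 1.38e-3), 1004, 1497, f)
  We <- weber_us(f, 7e-8, 1004, 0.07)
  Oh <- ohnesorge_us(0.088, f, Am, 1004)
  IN <- intensity_number(f, Am, 1497, 7e-8)
  expect_true(all(diff(lang_diameter(0.07, 1004, f)) < 0))
  barba <- mapply(function(fi, w, o, i) barba_diameter(0.07, 1004, fi, w, o, i),
                  f, We, Oh, IN)
  expect_true(all(diff(barba) < 0))
})

test_that("package correlations match the straight-line oracle on 100 draws", {
  d <- draw_inputs(100, seed = 31)
  Am <- vibration_amplitude(power_intensity(d$P, d$A), d$rho, d$C, d$f)
  We <- weber_us(d$f, d$Q, d$rho, d$sigma)
  Oh <- ohnesorge_us(d$mu, d$f, Am, d$rho)
  IN <- intensity_number(d$f, Am, d$C, d$Q)
  a <- runif(100, 0, 2)
  for (i in seq_len(100)) {
    o <- oracle(d$sigma[i], d$rho[i], d$f[i], We[i], Oh[i], IN[i],
                n = d$n_idx[i], a = a[i])
    expect_equal(lang_diameter(d$sigma[i], d$rho[i], d$f[i]),
                 o$lang, tolerance = 1e-10)
    expect_equal(rajan_pandit_diameter(d$sigma[i], d$rho[i], d$f[i], We[i],
                                       Oh[i], IN[i], a_rp = a[i]),
                 o$rajan_pandit, tolerance = 1e-10)
    expect_equal(ramisetty_diameter(d$sigma[i], d$rho[i], d$f[i], We[i],
                                    Oh[i], IN[i]),
                 o$ramisetty, tolerance = 1e-10)
    expect_equal(avvaru_diameter(d$sigma[i], d$rho[i], d$f[i], We[i], Oh[i],
                                 IN[i], n = d$n_idx[i]),
                 o$avvaru, tolerance = 1e-10)
    expect_equal(barba_diameter(d$sigma[i], d$rho[i], d$f[i], We[i], Oh[i],
                                IN[i]),
                 o$barba, tolerance = 1e-10)
  }
})
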