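test_that("power intensity reproduces the reference nozzle value", {
  expect_equal(power_intensity(10, 1.38e-3), 7.25e3, tolerance = 0.005)
  expect_equal(power_intensity(0, 1.38e-3), 0)
  expect_equal(power_intensity(20, 1.38e-3), 2 * power_intensity(10, 1.38e-3))
  expect_error(power_intensity(10, 0), class = "sonodrop_input_error")
})

test_that("vibration amplitude has the right value and scalings", {
  Am <- vibration_amplitude(7246.377, 1004, 1497, 25000)
  # frozen independent arithmetic: (1/(2*pi*25000))*sqrt(2*7246.377/(1004*1497))
  expect_equal(Am, 6.251408e-7, tolerance = 1e-6)
  expect_equal(vibration_amplitude(0, 1004, 1497, 25000), 0)
  # square-root scaling in intensity, inverse in frequency
  expect_equal(vibration_amplitude(4 * 7246.377, 1004, 1497, 25000), 2 * Am)
  expect_equal(vibration_amplitude(7246.377, 1004, 1497, 50000), Am / 2)
  expect_error(vibration_amplitude(100, 0, 1497, 25000),
               class = "sonodrop_input_error")
})

test_that("amplitude is homogeneous of degree 1/2 in delivered power", {
  A <- 1.38e-3
  Am1 <- vibration_amplitude(power_intensity(10, A), 1004, 1497, 25000)
  Am9 <- vibration_amplitude(power_intensity(90, A), 1004, 1497, 25000)
  expect_equal(Am9, 3 * Am1)
})

test_that("vibrating area sums two cone laterals and an annulus", {
  # degenerate cones (equal bases) are cylinders of lateral area pi*D*h
  g_cyl <- nozzle_geometry(D_i_nozzle = 2e-3, D_f_nozzle = 2e-3,
                           D_tip = 3e-3, D_o = 3e-3,
                           L_act = 5e-3, H_tip = 2e-3)
  expected <- pi * 2e-3 * 5e-3 + pi * 3e-3 * 2e-3 +
    pi / 4 * ((3e-3)^2 - (2e-3)^2)
  expect_equal(vibrating_area(g_cyl), expected)

  # zero annulus when D_tip == D_f_nozzle
  g0 <- nozzle_geometry(2e-3, 1e-3, 1e-3, 5e-4, 5e-3, 2e-3)
  cone <- function(D1, D2, h) pi * (D1 + D2) / 2 * sqrt(h^2 + ((D1 - D2) / 2)^2)
  expect_equal(vibrating_area(g0), cone(2e-3, 1e-3, 5e-3) + cone(1e-3, 5e-4, 2e-3))

  # full three-term hand computation (independent geometric oracle)
  g <- nozzle_geometry(D_i_nozzle = 2e-3, D_f_nozzle = 1e-3,
                       D_tip = 3e-3, D_o = 1e-3, L_act = 5e-3, H_tip = 2e-3)
  by_hand <- cone(2e-3, 1e-3, 5e-3) + cone(3e-3, 1e-3, 2e-3) +
    pi / 4 * ((3e-3)^2 - (1e-3)^2)
  expect_equal(vibrating_area(g), by_hand)

  expect_error(nozzle_geometry(2e-3, 2e-3, 1e-3, 1e-3, 5e-3, 2e-3),
               "annulus", class = "sonodrop_input_error")
})

test_that("critical flow rate matches the published value and We_c = 1", {
  Qc <- critical_flow_rate(0.07, 1004, 25000)
  expect_equal(Qc, 2.8e-9, tolerance = 0.005)
  expect_equal(critical_flow_rate(0.072, 1000, 25000), 2.88e-9, tolerance = 0.001)
  expect_error(critical_flow_rate(0, 1004, 25000), class = "sonodrop_input_error")
})

test_that("maximum flow rate is the surface displacement rate", {
  Am <- vibration_amplitude(power_intensity(10, 1.38e-3), 1004, 1497, 25000)
  Qmax <- max_flow_rate(25000, Am, 1.38e-3)
  expect_equal(Qmax, 2.2e-5, tolerance = 0.05)
  expect_equal(max_flow_rate(25000, 0, 1.38e-3), 0)
  expect_equal(max_flow_rate(25000, Am, 2 * 1.38e-3), 2 * Qmax)
})

test_that("operating window classifies flow rates and echoes bounds", {
  w <- operating_window(7e-8, 2.8e-9, 2.2e-5)
  expect_equal(w$verdict, "good_atomization")
  expect_equal(w$Q_c, 2.8e-9)
  expect_equal(operating_window(1e-10, 2.8e-9, 2.2e-5)$verdict, "below_critical")
  expect_equal(operating_window(1e-4, 2.8e-9, 2.2e-5)$verdict, "dripping")
  expect_error(operating_window(7e-8, 1e-5, 1e-6), "inconsistent",
               class = "sonodrop_input_error")
})

test_that("the reference case sits inside its own operating window", {
  Qc <- critical_flow_rate(ref$fluid$surface_tension, ref$fluid$density,
                           ref$setup$frequency)
  Qmax <- max_flow_rate(ref$setup$frequency, ref$setup$amplitude, ref$setup$area)
  expect_lt(Qc, Qmax)
  expect_equal(operating_window(ref$flow$Q_core, Qc, Qmax)$verdict,
               "good_atomization")
  expect_equal(operating_window(ref$flow$Q_shell, Qc, Qmax)$verdict,
               "good_atomization")
})

test_that("flow_config applies the effective-flow policy", {
  fc <- flow_config(Q_core = 1.83e-8, Q_shell = 7e-8)
  expect_equal(fc$Q_effective, 7e-8)          # shell is the default policy
  expect_equal(flow_config(1.83e-8, 7e-8, "core")$Q_effective, 1.83e-8)
  expect_equal(flow_config(1.83e-8, 7e-8, "total")$Q_effective, 8.83e-8)
  expect_error(flow_config(0, 0), class = "sonodrop_input_error")
  expect_error(flow_config(1e-8, 1e-8, "sideways"))
})

test_that("ultrasonic_setup derives intensity and amplitude and accepts geometry", {
  us <- ultrasonic_setup(25000, 10, area = 1.38e-3, sound_speed = 1497,
                         coupling_density = 1004)
  expect_equal(us$intensity, 10 / 1.38e-3)
  expect_equal(us$amplitude,
               vibration_amplitude(10 / 1.38e-3, 1004, 1497, 25000))
  g <- nozzle_geometry(2e-3, 1e-3, 3e-3, 1e-3, 5e-3, 2e-3)
  us_g <- ultrasonic_setup(25000, 10, geometry = g, sound_speed = 1497,
                           coupling_density = 1004)
  expect_equal(us_g$area, vibrating_area(g))
  expect_error(ultrasonic_setup(25000, 10, sound_speed = 1497,
                                coupling_density = 1004),
               "area.*geometry", class = "sonodrop_input_error")
})
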