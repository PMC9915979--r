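test_that("tissue uptake curve matches hand substitution and its limits", {
  comp <- tiny_comp(Q = 1, V = 10, P = 2)
  # (1*2*1*20) / (10*2 + 1*20) = 40/40 = 1
  expect_equal(compartment_concentration(comp, c_art = 1, t = 20), 1.0)
  expect_equal(compartment_concentration(comp, c_art = 1, t = 0), 0.0)
  # asymptote P * c_art
  expect_equal(compartment_concentration(comp, c_art = 1, t = 1e12), 2.0,
               tolerance = 1e-9)
  expect_error(compartment_concentration(comp, c_art = -1, t = 1),
               class = "benzrisk_domain_error")
  expect_error(compartment_concentration(comp, c_art = 1, t = -1),
               class = "benzrisk_domain_error")
})

test_that("uptake curve stays strictly between 0 and P*c_art and is nondecreasing in t", {
  set.seed(11)
  for (i in 1:100) {
    lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
    comp <- tiny_comp(Q = lu(0.05, 5), V = lu(0.1, 40), P = lu(0.3, 60))
    c_art <- lu(1e-4, 1)
    t <- sort(lu(1, 1e6) * runif(8))
    vals <- compartment_concentration(comp, c_art, t)
    brute <- (comp$Q * comp$P * c_art * t) / (comp$V * comp$P + comp$Q * t)
    expect_equal(vals, brute)  # closed form == direct evaluation
    expect_true(all(vals > 0 & vals < comp$P * c_art))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("steady-state time puts the curve within the requested tolerance", {
  comp <- tiny_comp(Q = 0.75, V = 0.85, P = 1.7)
  t_ss <- steady_state_time(comp, 1e-6)
  val <- compartment_concentration(comp, c_art = 1, t = t_ss)
  expect_lte((comp$P - val) / comp$P, 1e-6 * (1 + 1e-9))
  expect_gt(comp$P - val, 0)
  # just before t_ss the shortfall still exceeds the tolerance
  expect_gt(comp$P - compartment_concentration(comp, 1, t_ss * 0.9),
            1e-6 * comp$P * 0.99)
})

test_that("arterial concentration is linear in air concentration with the m3->L factor", {
  ph <- physiology(P_blood_air = 8.0)
  expect_equal(arterial_concentration(0, ph), 0)
  expect_equal(arterial_concentration(5.85, ph), 5.85 / 1000 * 8.0)
  expect_equal(arterial_concentration(11.7, ph),
               2 * arterial_concentration(5.85, ph))
  # mass-balance alternative is also linear and below blood:air equilibrium
  mb <- arterial_concentration(5.85, ph, mode = "mass_balance")
  expect_equal(arterial_concentration(11.7, ph, mode = "mass_balance"), 2 * mb)
  expect_lt(mb, arterial_concentration(5.85, ph))
  expect_error(arterial_concentration(-1, ph),
               class = "benzrisk_domain_error")
})

test_that("Michaelis-Menten rate: half-saturation, bounds, monotone concavity", {
  met <- metabolism_params(Vmax = 1, Km = 0.5)
  expect_equal(metabolic_rate(0.5, met), 0.5)
  expect_equal(metabolic_rate(0, met), 0)
  expect_equal(metabolic_rate(1.5, met), 0.75)
  grid <- seq(0, 50, length.out = 400)
  r <- metabolic_rate(grid, met)
  expect_true(all(r < met$Vmax))
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(diff(r)) <= 1e-12))  # concave
  expect_error(metabolic_rate(-0.1, met), class = "benzrisk_domain_error")
})

test_that("forward chain: zero in zero out, monotone, saturating, linear at low dose", {
  p <- default_pbpk_parameters()
  ph <- physiology()
  expect_equal(ttma_urine_forward(0, p, ph)$ttma_conc, 0)
  cs <- c(0.01, 0.1, 1, 5.85, 50, 500, 5e4)
  ys <- vapply(cs, function(c) ttma_urine_forward(c, p, ph)$ttma_conc,
               numeric(1))
  expect_true(all(diff(ys) > 0))
  bound <- ttma_saturation_bound(p, ph)
  expect_true(all(ys < bound))
  expect_equal(ttma_urine_forward(1e9, p, ph)$ttma_conc, bound,
               tolerance = 1e-3)
  # first-order regime: forward(eps*c)/eps converges as eps -> 0
  base <- 1
  slopes <- vapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    ttma_urine_forward(eps * base, p, ph)$ttma_conc / eps
  }, numeric(1))
  expect_equal(slopes[2], slopes[3], tolerance = 1e-4)
  expect_gt(abs(slopes[1] - slopes[3]) / slopes[3],
            abs(slopes[2] - slopes[3]) / slopes[3])
})

test_that("tt-MA mass per void respects the stoichiometric ceiling", {
  set.seed(21)
  for (i in 1:25) {
    p <- random_pbpk_parameters()
    ph <- random_physiology()
    out <- ttma_urine_forward(10^runif(1, -1, 3), p, ph)
    mass <- out$ttma_conc * ph$urine_void_volume
    ceiling_mass <- p$metabolism$f_ttma * (142.11 / 78.11) *
      p$metabolism$Vmax * ph$micturition_interval
    expect_lt(mass, ceiling_mass)
    expect_equal(out$ttma_per_creatinine,
                 out$ttma_conc / ph$urinary_creatinine)
  }
})

test_that("quadrature mode agrees with the steady-state product once at steady state", {
  p <- default_pbpk_parameters()
  ph <- physiology()
  ss <- ttma_urine_forward(5.85, p, ph)$ttma_conc
  quad <- ttma_urine_forward(5.85, p, ph, integrate = TRUE)$ttma_conc
  expect_equal(quad, ss, tolerance = 1e-6)
  # a void window starting right at exposure onset collects less metabolite
  early <- ttma_urine_forward(5.85, p, ph, integrate = TRUE,
                              void_start = 0)$ttma_conc
  expect_lt(early, ss)
})

test_that("mg/m^3 to ppm conversion uses molar volume over molecular weight", {
  expect_equal(round(mg_m3_to_ppm(5.85), 2), 1.83)
  expect_equal(mg_m3_to_ppm(0), 0)
  expect_equal(round(mg_m3_to_ppm(1), 4), 0.3130)
  expect_error(mg_m3_to_ppm(1, mw = 0), class = "benzrisk_domain_error")
})
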