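test_that("effective modulus reproduces its algebraic limits", {
  m <- material(100, 0.5)
  expect_equal(effective_modulus(m, m), (2 / 3) * 100, tolerance = 1e-12)
  rigid <- material(1e15, 0)
  soft <- material(73.32, 0.5)
  expect_equal(effective_modulus(rigid, soft), 73.32 / (1 - 0.25),
               tolerance = 1e-6)
  # glass vs soft PDMS is dominated by the PDMS
  md <- material_defaults()
  es <- effective_modulus(md$glass, md$pdms)
  expect_lt(abs(es / (73.32 / 0.75) - 1), 1e-4)
})

test_that("zero force gives zero contact radius, indentation and pressure", {
  hc <- hertz_contact(0, sphere_probe(1), 100)
  expect_equal(hc$a_um, 0)
  expect_equal(hc$delta_um, 0)
  expect_equal(hc$p0_kPa, 0)
})

test_that("contact radius and pressure follow the cube-root scaling exactly", {
  hc <- hertz_contact(c(10, 80), sphere_probe(1), 3.27e6)
  expect_equal(hc$a_um[2] / hc$a_um[1], 2, tolerance = 1e-12)
  expect_equal(hc$p0_kPa[2] / hc$p0_kPa[1], 2, tolerance = 1e-12)
  expect_equal(hc$delta_um[2] / hc$delta_um[1], 4, tolerance = 1e-12)
})

test_that("closed forms satisfy the Hertz self-consistency relations", {
  hc <- hertz_contact(c(1, 10, 80), sphere_probe(1), 1e6)
  a_m <- hc$a_um * 1e-6
  expect_equal(hc$p0_kPa * 1e3, 3 * hc$F_mN * 1e-3 / (2 * pi * a_m^2),
               tolerance = 1e-12)
  expect_equal(hc$delta_um, hc$a_um^2 / 1e3, tolerance = 1e-12)
})

test_that("closed forms agree with a numerical simultaneous solve", {
  set.seed(7)
  for (i in 1:100) {
    F_mN <- runif(1, 0.5, 100)
    R_mm <- runif(1, 0.2, 5)
    E_star <- 10^runif(1, 2, 7)
    hc <- hertz_contact(F_mN, sphere_probe(R_mm), E_star)
    # independent route: solve F = (4/3) E* sqrt(R) delta^(3/2) for a
    f <- function(a) (4 / 3) * (E_star * 1e3) * a^3 / (R_mm * 1e-3) -
      F_mN * 1e-3
    a_num <- stats::uniroot(f, c(1e-9, 1), tol = 1e-15)$root
    expect_equal(hc$a_um, a_num * 1e6, tolerance = 1e-7)
  }
})

test_that("the pressure table covers every force-pairing combination", {
  md <- material_defaults()
  pairings <- list(
    pdms_glass = list(probe = md$probe, m1 = md$glass, m2 = md$pdms),
    ps_glass = list(probe = md$probe, m1 = md$glass, m2 = md$ps)
  )
  tab <- pressure_sweep(c(10, 20, 40, 80), pairings)
  expect_equal(nrow(tab), 8)
  # Hertz scaling across pairings at equal force
  p_ps <- tab$p0_kPa[tab$pairing == "ps_glass" & tab$F_mN == 10]
  p_pdms <- tab$p0_kPa[tab$pairing == "pdms_glass" & tab$F_mN == 10]
  es_ps <- effective_modulus(md$glass, md$ps)
  es_pdms <- effective_modulus(md$glass, md$pdms)
  expect_equal(p_ps / p_pdms, (es_ps / es_pdms)^(2 / 3), tolerance = 1e-9)
  expect_error(pressure_sweep(numeric(0), pairings), "non-empty")
})

test_that("negative forces and invalid materials are rejected", {
  expect_error(hertz_contact(-1, sphere_probe(1), 100), ">= 0")
  expect_error(material(-5, 0.3), "> 0")
  expect_error(material(100, 0.7), "<=")
  expect_error(sphere_probe(0), "> 0")
})
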