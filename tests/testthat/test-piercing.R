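md <- material_defaults()

test_that("on a rigid substrate the track width is load-independent", {
  pm <- piercing_model(material(1e12, 0.3), md$probe,
                       probe_material = material(1e12, 0), h_crit = 0.76)
  w <- pierced_track_width(c(10, 80), pm)
  target <- 2 * sqrt(2 * 1000 * 0.76)  # um
  expect_equal(w$width_um, rep(target, 2), tolerance = 1e-4)
})

test_that("no compression tolerance reduces to the monolayer-contact chord", {
  pm <- piercing_model(md$ps, md$probe, h_cell = 3, h_crit = 3)
  w <- pierced_track_width(10, pm)
  expect_equal(w$width_um, 2 * sqrt(2 * 1000 * (3 + w$delta_um)),
               tolerance = 1e-9)
  expect_equal(w$width_um, w$r_touch_um * 2, tolerance = 1e-9)
})

test_that("width, indentation and kill radius are non-decreasing in force", {
  pm <- piercing_model(md$ps, md$probe, h_crit = 0.76)
  w <- pierced_track_width(c(5, 10, 20, 40, 80), pm)
  expect_true(all(diff(w$width_um) > 0))
  expect_true(all(diff(w$delta_um) > 0))
  expect_true(all(diff(w$a_um) > 0))
})

test_that("track width grows far slower with load than the Hertz contact radius", {
  pm <- piercing_model(md$ps, md$probe, h_crit = 0.76)
  w <- pierced_track_width(c(10, 80), pm)
  width_ratio <- w$width_um[2] / w$width_um[1]
  hertz_ratio <- w$a_um[2] / w$a_um[1]
  expect_equal(hertz_ratio, 2, tolerance = 1e-12)
  expect_lt(width_ratio, 1.4)
  expect_gt(width_ratio, 1)
})

test_that("the implied critical thickness inverts the width prediction", {
  h <- implied_h_crit(77.8, sphere_probe(1))
  expect_equal(h, (77.8 / 2)^2 / 2000, tolerance = 1e-12)
  # numerical inversion oracle: h_crit such that the rigid-limit width is 77.8
  f <- function(hc) 2 * sqrt(2 * 1000 * hc) - 77.8
  h_num <- stats::uniroot(f, c(0.01, 5), tol = 1e-12)$root
  expect_equal(h, h_num, tolerance = 1e-9)
  # elastic-substrate variant subtracts the Hertz indentation
  es <- effective_modulus(md$glass, md$ps)
  h_el <- implied_h_crit(77.8, sphere_probe(1), F = 10, E_star = es)
  expect_lt(h_el, h)
})

test_that("model invariants are enforced", {
  expect_error(piercing_model(md$ps, md$probe, h_cell = 3, h_crit = 4),
               "<=")
  expect_error(piercing_model(md$ps, md$probe, h_crit = 0), "> 0")
})
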