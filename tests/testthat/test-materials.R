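## material definitions, cross sections, sampling and the source spectrum

test_that("material constructor enforces its invariants", {
  expect_error(material("m", -1, c(H = 1)), "density")
  expect_error(material("m", 1, c(H = 0.5, O = 0.6)), "sum to 1")
  expect_error(material("m", 1, c(Xx = 1)), "unknown element")
  m <- material("m", 1, c(H = 0.111894, O = 0.888106))
  expect_s3_class(m, "tte_material")
})

test_that("mixture rule reproduces a pure element and classic anchors", {
  xs <- xs_tables()
  ti <- tte_material("titanium")
  j <- match("Ti", xs$elements)
  for (e in c(0.1, 1.25, 6)) {
    i <- which(abs(xs$energies - e) < 1e-9)
    expect_equal(mixture_mu_rho(ti, e), unname(xs$total[i, j]), tolerance = 1e-12)
  }
  ## classic attenuation values (coherent excluded), 2% tolerance
  expect_equal(mixture_mu_rho(tte_material("water"), 2.0), 0.0493,
               tolerance = 0.02)
  ## hand mixture over the element tables for the magnet alloy
  nd <- tte_material("ndfeb")
  i2 <- which(abs(xs$energies - 2) < 1e-9)
  byhand <- 0.266838 * xs$total[i2, "Nd"] + 0.723162 * xs$total[i2, "Fe"] +
    0.01 * xs$total[i2, "B"]
  expect_equal(mixture_mu_rho(nd, 2.0), unname(byhand), tolerance = 1e-10)
  expect_error(mixture_mu_rho(nd, 50), "out of table range")
})

test_that("channel partition sums to the total within 1% everywhere", {
  xs <- xs_tables()
  for (mat in c("water", "wax", "titanium", "ndfeb", "peek", "silicone")) {
    m <- tte_material(mat)
    tot <- mixture_mu_rho(m, xs$energies, "total")
    parts <- mixture_mu_rho(m, xs$energies, "photoelectric") +
      mixture_mu_rho(m, xs$energies, "compton") +
      mixture_mu_rho(m, xs$energies, "pair")
    expect_lt(max(abs(parts / tot - 1)), 0.01)
  }
})

test_that("transmission follows Beer-Lambert and is monotone", {
  w <- tte_material("water")
  expect_equal(transmission(w, 0, 2), 1.0)
  expect_equal(transmission(w, 10, 2), exp(-mixture_mu_rho(w, 2) * 10),
               tolerance = 1e-12)
  expect_equal(transmission(w, 10, 2), exp(-0.493), tolerance = 0.01)
  expect_error(transmission(w, -1, 2), ">= 0")
  ## monotone in thickness and in density, over a grid
  th <- seq(0, 20, 2)
  expect_true(all(diff(transmission(w, th, 1.25)) < 0))
  nd <- lapply(c(6, 7, 7.4, 7.6), function(r) tte_material("ndfeb", r))
  tr <- vapply(nd, transmission, 0, thickness = 0.25, energy = 2)
  expect_true(all(diff(tr) < 0))
})

test_that("interaction channel sampling matches the table ratios", {
  nd <- tte_material("ndfeb")
  p <- interaction_probabilities(0.03, nd)
  expect_equal(sum(p), 1)
  expect_gt(p[["photoelectric"]], 0.5)   # photoelectric dominates at 30 keV
  ## empirical frequencies over 1e5 draws within 3 sigma binomial
  set.seed(42)
  draws <- sample_interaction(2.0, nd, 1e5)
  p2 <- interaction_probabilities(2.0, nd)
  for (ch in names(p2)) {
    phat <- mean(draws == ch)
    se <- sqrt(p2[[ch]] * (1 - p2[[ch]]) / 1e5)
    expect_lt(abs(phat - p2[[ch]]), 3 * se + 1e-12)
  }
})

test_that("Compton sampling obeys the Compton relation and Klein-Nishina", {
  E <- 2
  a <- E / 0.51099895
  set.seed(7)
  s <- sample_compton(E, 2e4)
  ## kinematics: E' = E / (1 + a (1 - cos theta)) at every sample
  expect_equal(s$energy, E / (1 + a * (1 - cos(s$angle))), tolerance = 1e-12)
  expect_equal(s$electron, E - s$energy, tolerance = 1e-12)
  ## closed forms: forward scatter keeps E, backscatter formula at theta = pi
  expect_equal(E / (1 + a * (1 - cos(0))), E)
  back <- min(s$energy)
  expect_gte(back, E / (1 + 2 * a))
  ## chi-squared against direct numerical integration of Klein-Nishina
  brk <- seq(0, pi, length.out = 21)
  obs <- table(cut(s$angle, brk))
  pdf <- function(th) klein_nishina_pdf(E, th) * sin(th)
  probs <- vapply(seq_len(20), function(i)
    stats::integrate(pdf, brk[i], brk[i + 1])$value, 0)
  probs <- probs / sum(probs)
  chi <- suppressWarnings(stats::chisq.test(as.vector(obs), p = probs))
  expect_gt(chi$p.value, 0.001)
})

test_that("6 MV spectrum is normalized with a plausible effective energy", {
  s <- spectrum_6mv()
  expect_equal(sum(s$weights), 1, tolerance = 1e-12)
  expect_true(all(s$weights >= 0))
  expect_lte(max(s$energy), 6)
  expect_gt(s$effective_energy, 1.6)
  expect_lt(s$effective_energy, 2.2)
  mono <- spectrum_6mv(mono = 2)
  expect_equal(mono$effective_energy, 2)
  expect_equal(mono$weights, 1)
})
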