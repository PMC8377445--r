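test_that("relaxation time sums per-reaction times", {
  # Ea = 0, A = 1/min: tau = 1 min at any temperature
  one <- reaction_network(0, 1)
  expect_equal(network_tau(one, c(5, 25, 45)), rep(1, 3))
  # two identical reactions double tau
  two <- reaction_network(c(40, 40), c(1e5, 1e5))
  expect_equal(network_tau(two, 25), 2 * network_tau(reaction_network(40, 1e5), 25))
  # scalar oracle: Ea = 64 kJ/mol, A = e^26 at 25 C
  net <- reaction_network(64, exp(26))
  expect_equal(
    network_tau(net, 25),
    exp(64000 / (8.314 * 298.15) - 26),
    tolerance = 1e-12
  )
})

test_that("tau is additive under network concatenation", {
  set.seed(14)
  a <- random_network(4)
  b <- random_network(3)
  ab <- reaction_network(
    c(a$Ea_kJ_per_mol, b$Ea_kJ_per_mol),
    c(a$A_per_min, b$A_per_min)
  )
  for (tmp in c(8, 22, 40)) {
    expect_equal(network_tau(ab, tmp), network_tau(a, tmp) + network_tau(b, tmp))
  }
})

test_that("single-reaction composite reduces exactly to the Arrhenius line", {
  net <- reaction_network(64, exp(5))
  temps <- seq(5, 45, by = 0.5)
  closed <- 5 - 64000 / (8.314 * (temps + 273.15))
  expect_equal(composite_lnk(net, temps), closed, tolerance = 1e-12)
})

test_that("the slowest step bounds the composite rate", {
  set.seed(15)
  for (rep in 1:10) {
    net <- random_network(5)
    for (tmp in c(10, 22, 35)) {
      lnk_each <- vapply(seq_len(nrow(net)), function(i) {
        composite_lnk(reaction_network(net$Ea_kJ_per_mol[i], net$A_per_min[i]), tmp)
      }, numeric(1))
      expect_lte(composite_lnk(net, tmp), min(lnk_each))
    }
  }
})

test_that("equal per-reaction times at T* halve the composite rate", {
  # two reactions engineered to share tau at T* = 25 C
  Ea <- c(50, 90)
  t_star <- 30 # minutes each at T*
  A <- exp(Ea * 1000 / 8.314 / 298.15 - log(t_star))
  net <- reaction_network(Ea, A)
  lnk1 <- composite_lnk(reaction_network(Ea[1], A[1]), 25)
  expect_equal(composite_lnk(net, 25), lnk1 - log(2), tolerance = 1e-10)
})

test_that("reactions sharing one Ea collapse into a single reaction at all temperatures", {
  A <- c(2e7, 5e7, 1e8)
  chain <- reaction_network(rep(55, 3), A)
  collapsed <- reaction_network(55, 1 / sum(1 / A))
  temps <- seq(5, 45, by = 5)
  expect_equal(
    composite_lnk(chain, temps),
    composite_lnk(collapsed, temps),
    tolerance = 1e-12
  )
})

test_that("composite rate increases strictly with temperature for positive Ea", {
  set.seed(16)
  net <- random_network(8)
  lnk <- composite_lnk(net, seq(5, 45, by = 1))
  expect_true(all(diff(lnk) > 0))
})

test_that("analytic derivatives match central finite differences", {
  set.seed(17)
  for (rep in 1:20) {
    net <- random_network(2)
    tmp <- stats::runif(1, 8, 40)
    x0 <- 1 / (tmp + 273.15)
    # step balances truncation ((b h)^2) against roundoff (eps / h^2)
    h <- 1e-6
    f <- function(x) composite_lnk(net, 1 / x - 273.15)
    d1_num <- (f(x0 + h) - f(x0 - h)) / (2 * h)
    d2_num <- (f(x0 + h) - 2 * f(x0) + f(x0 - h)) / h^2
    d <- composite_lnk_derivs(net, tmp)
    expect_equal(d$dy_dx, d1_num, tolerance = 1e-6)
    expect_equal(d$d2y_dx2, d2_num, tolerance = 1e-3)
    kappa_num <- abs(d2_num) / (1 + d1_num^2)^1.5
    expect_equal(curvature_at(net, tmp), kappa_num, tolerance = 1e-3)
  }
})

test_that("a single reaction has zero curvature everywhere", {
  net <- reaction_network(64, exp(20))
  expect_equal(curvature_at(net, seq(5, 45, 5)), rep(0, 9))
})

test_that("composite curves are concave downward in 1/T for any network", {
  set.seed(18)
  for (rep in 1:25) {
    net <- random_network(sample(2:10, 1))
    d <- composite_lnk_derivs(net, seq(5, 45, by = 2))
    expect_true(all(d$d2y_dx2 <= 0))
  }
})

test_that("composite prediction from a single fit reproduces that fit's line", {
  d <- exact_arrhenius_points(64, 5, seq(14, 28, 2))
  fit <- fit_arrhenius(d, start_code = "A", end_code = "B")
  pred <- predict_composite(list(fit), seq(14, 28, 2), core_range = c(14, 28))
  expect_equal(
    pred$prediction$lnk,
    fit$intercept + fit$slope_K / (seq(14, 28, 2) + 273.15),
    tolerance = 1e-9
  )
  expect_equal(pred$tangent_Ea_kJ, 64, tolerance = 1e-9)
})

test_that("sub-intervals with equal Ea compose to an exact Arrhenius line with that Ea", {
  f1 <- fit_arrhenius(exact_arrhenius_points(64, 5, seq(14, 28, 2)),
                      start_code = "A", end_code = "B")
  f2 <- fit_arrhenius(exact_arrhenius_points(64, 6, seq(14, 28, 2)),
                      start_code = "B", end_code = "C")
  pred <- predict_composite(list(f1, f2), seq(5, 45, 1), core_range = c(14, 28))
  expect_equal(pred$tangent_Ea_kJ, 64, tolerance = 1e-6)
  # exact line: curvature of the composite is 0
  expect_equal(curvature_at(pred$network, 22), 0, tolerance = 1e-12)
})

test_that("non-contiguous sub-interval fits warn but still compose", {
  f1 <- fit_arrhenius(exact_arrhenius_points(60, 5, seq(14, 28, 2)),
                      start_code = "A", end_code = "B")
  f3 <- fit_arrhenius(exact_arrhenius_points(80, 9, seq(14, 28, 2)),
                      start_code = "C", end_code = "D")
  expect_warning(
    pred <- predict_composite(list(f1, f3), seq(14, 28, 2)),
    "contiguous"
  )
  expect_s3_class(pred, "composite_prediction")
})

test_that("reaction expansion preserves tau exactly at the reference temperature only", {
  Ea <- 66.74
  A <- 1e10
  expanded <- expand_reaction(Ea, A, m = 999, T_ref_K = 295.15)
  expect_equal(
    expanded$Ea_kJ_per_mol[1],
    66.74 - 8.314 * 295.15 * log(999) / 1000
  )
  tau_orig <- network_tau(reaction_network(Ea, A), 295.15 - 273.15)
  tau_exp <- network_tau(expanded, 295.15 - 273.15)
  expect_equal(tau_exp, tau_orig, tolerance = 1e-9)
  # away from T_ref the chain and the original disagree
  for (dT in c(-10, 10)) {
    tmp <- 295.15 - 273.15 + dT
    expect_gt(
      abs(network_tau(expanded, tmp) - network_tau(reaction_network(Ea, A), tmp)) /
        network_tau(reaction_network(Ea, A), tmp),
      1e-3
    )
  }
  # m = 1 leaves the reaction unchanged
  same <- expand_reaction(Ea, A, m = 1)
  expect_equal(same$Ea_kJ_per_mol, Ea)
  expect_equal(same$A_per_min, A)
})

test_that("networks round-trip through JSON", {
  net <- reaction_network(c(33.5, 72.25), c(1e6, 1e11))
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$Ea_kJ_per_mol, net$Ea_kJ_per_mol)
  expect_equal(back$A_per_min, net$A_per_min)
})
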