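cm_real_system <- function() {
  m <- load_model("cm_subtype")
  net <- m$network
  net$clamps <- setNames(integer(), character())  # inputs become parameters
  transform_to_real(net, inputs = m$inputs)
}

test_that("the relaxation rules transform example gates correctly", {
  mul <- cardiobn:::poly_mul
  one_minus <- cardiobn:::poly_one_minus
  pv <- cardiobn:::poly_var
  # AND with negation -> product with complement
  p <- poly_from_expr(parse_boolean_rule("IRX4 & !NR2F2"))
  expect_true(poly_equal(p, mul(pv("IRX4"), one_minus(pv("NR2F2")))))
  # OR -> probabilistic sum
  p2 <- poly_from_expr(parse_boolean_rule("IRX4 | GATA4_6"))
  expect_equal(poly_eval(p2, c(IRX4 = 0.5, GATA4_6 = 0.5)), 0.75)
  # constants survive
  expect_true(poly_equal(poly_from_expr(parse_boolean_rule("1")),
                         cardiobn:::poly_const(1)))
})

test_that("continuous trajectories from binary corners equal Boolean ones", {
  set.seed(17)
  nets <- c(list(load_model("cm_subtype")$network),
            lapply(1:6, function(i) random_boolean_network(sample(2:5, 1L), 3L)))
  for (net in nets) {
    net$clamps <- setNames(integer(), character())
    sys <- transform_to_real(net, inputs = character())
    for (rep in 1:5) {
      s <- setNames(as.integer(runif(length(net$nodes)) < 0.5), net$nodes)
      class(s) <- "network_state"
      x <- as.numeric(s); names(x) <- net$nodes
      for (step in 1:6) {
        s <- sync_step(net, s)
        x <- vapply(net$nodes, function(nm) poly_eval(sys$polys[[nm]], x),
                    numeric(1))
        expect_equal(unname(x), as.numeric(unname(unclass(s))), tolerance = 1e-12)
      }
    }
  }
})

test_that("iterates stay inside the unit cube and converge to the closed form", {
  sys <- cm_real_system()
  set.seed(23)
  for (i in 1:10) {
    rho <- runif(1); gam <- runif(1, 0.05, 1); nu <- runif(1)
    fp <- iterate_to_fixed_point(sys, c(RA = rho, GATA4_6 = gam, NOTCH = nu))
    expect_true(all(fp >= -1e-12 & fp <= 1 + 1e-12))
    cf <- closed_form_cm_steady_state(rho, gam, nu)
    expect_equal(unclass(fp)[names(cf)], cf, tolerance = 1e-8)
  }
  # the worked midpoint: rho = 0.5, full GATA4/6 and NOTCH
  fp <- iterate_to_fixed_point(sys, c(RA = 0.5, GATA4_6 = 1, NOTCH = 1))
  expect_equal(unclass(fp)[c("NR2F2", "HAND2", "IRX4", "MYL2", "HEY2", "MYL7")],
               c(NR2F2 = 0.5, HAND2 = 1, IRX4 = 0.5, MYL2 = 0.25,
                 HEY2 = 0.5, MYL7 = 0.25), tolerance = 1e-8)
})

test_that("binary corners reproduce the Boolean steady states", {
  sys <- cm_real_system()
  acm <- iterate_to_fixed_point(sys, c(RA = 1, GATA4_6 = 1, NOTCH = 1))
  expect_equal(unclass(acm)[c("MYL7", "MYL2", "NR2F2", "HEY2", "IRX4", "HAND2")],
               c(MYL7 = 1, MYL2 = 0, NR2F2 = 1, HEY2 = 0, IRX4 = 0, HAND2 = 1),
               tolerance = 1e-8)
  vcm <- iterate_to_fixed_point(sys, c(RA = 0, GATA4_6 = 1, NOTCH = 1))
  expect_equal(unclass(vcm)[c("MYL7", "MYL2", "NR2F2", "HEY2", "IRX4", "HAND2")],
               c(MYL7 = 0, MYL2 = 1, NR2F2 = 0, HEY2 = 1, IRX4 = 1, HAND2 = 1),
               tolerance = 1e-8)
  cf0 <- closed_form_cm_steady_state(0, 1, 1)
  expect_equal(unname(cf0[c("HAND2", "IRX4", "MYL2")]), c(1, 1, 1))
})

test_that("the coupled-block denominator reading is the steady-state solution", {
  # from H' = I + g - g*I and I' = H*(1-r), steady state requires
  # H - [H*(1-r) + g - g*H*(1-r)] = 0, which expands to H*(r+g-r*g) - g = 0:
  # hence H = g / (r + g - r*g), fixing the fraction's reading
  add <- cardiobn:::poly_add; mul <- cardiobn:::poly_mul
  sc <- cardiobn:::poly_scale; pv <- cardiobn:::poly_var
  one_minus <- cardiobn:::poly_one_minus
  H <- pv("H"); g <- pv("g"); r <- pv("r")
  hand2_update <- add(add(pv("I"), g), sc(mul(g, pv("I")), -1))
  lhs <- add(H, sc(poly_substitute(hand2_update, "I", mul(H, one_minus(r))), -1))
  den <- add(add(r, g), sc(mul(r, g), -1))
  expect_true(poly_equal(lhs, add(mul(H, den), sc(g, -1))))
  # and the closed form satisfies both recurrences numerically
  for (rv in c(0.1, 0.5, 0.9)) for (gv in c(0.2, 1)) {
    cf <- closed_form_cm_steady_state(rv, gv, 1)
    expect_equal(cf[["HAND2"]],
                 cf[["IRX4"]] + gv - gv * cf[["IRX4"]], tolerance = 1e-12)
    expect_equal(cf[["IRX4"]], cf[["HAND2"]] * (1 - rv), tolerance = 1e-12)
  }
})

test_that("the degenerate corner is refused, not papered over", {
  expect_error(closed_form_cm_steady_state(0, 0, 1), "degenerate")
  sys <- cm_real_system()
  init <- setNames(rep(0.5, length(sys$nodes)), sys$nodes)
  init["HAND2"] <- 0.3; init["IRX4"] <- 0.7   # asymmetric start -> 2-cycle
  expect_error(iterate_to_fixed_point(sys, c(RA = 0, GATA4_6 = 0, NOTCH = 1),
                                      init = init, max_iter = 500),
               "did not converge")
})

test_that("the RA sweep recovers the dose-response curves and threshold", {
  sys <- cm_real_system()
  sweep <- ra_sweep_and_threshold(sys, gamma = 1, nu = 1, grid_size = 41L)
  g <- sweep$grid
  # closed forms at full GATA4/6 and NOTCH: MYL2 = (1-rho)^2, MYL7 = rho^2
  expect_equal(g$MYL2, (1 - g$rho)^2, tolerance = 1e-6)
  expect_equal(g$MYL7, g$rho^2, tolerance = 1e-6)
  expect_true(all(diff(g$MYL2) <= 1e-9))       # ventricular marker falls with RA
  expect_equal(g$MYL2[1L], 1, tolerance = 1e-8)  # rho = 0 corner is ventricular
  expect_equal(sweep$crossover, 0.5, tolerance = 1e-6)
  # a system whose markers never cross reports the absence of a threshold
  toy <- boolean_network(c(RA = "RA", MYL2 = "1", MYL7 = "0"))
  flat <- ra_sweep_and_threshold(transform_to_real(toy, inputs = "RA"),
                                 grid_size = 11L)
  expect_true(is.na(flat$crossover))
})
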