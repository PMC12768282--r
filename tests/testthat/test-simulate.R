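# helper: Monte-Carlo absorption frequencies of a network whose attractors
# are all fixed points, from uniform random initial states
mc_absorption <- function(net, atts, runs) {
  sigs <- lapply(atts, function(a) {
    s <- a$states[[1L]]
    setNames(as.integer(s), names(s))
  })
  names(sigs) <- paste0("att", seq_along(sigs))
  counts <- simulate_population(net, runs = runs, signatures = sigs)
  unlist(counts[1L, names(sigs)]) / runs
}

test_that("a cell started at a fixed point is returned immediately", {
  net <- set_clamps(toy_orchain(), c(B = 0))
  fp <- network_state(net, c(A = 1))
  res <- simulate_cell(net, fp)
  expect_true(res$converged)
  expect_identical(res$steps, 0)
  expect_identical(res$state, fp)
})

test_that("absorption from a bistable start hits one of the two sinks", {
  net <- toy_orchain()
  set.seed(1)
  terminals <- replicate(50, {
    res <- simulate_cell(net, network_state(net, c(A = 0, B = 1)))
    expect_true(res$converged)
    state_key(res$state)
  })
  expect_setequal(unique(terminals), c("10", "00"))
})

test_that("non-convergence is flagged, never silently dropped", {
  net <- toy_negation()  # pure 2-cycle, no fixed point
  set.seed(1)
  res <- simulate_cell(net, network_state(net), max_steps = 100)
  expect_false(res$converged)
  counts <- simulate_population(net, runs = 50, signatures = list(x1 = c(X = 1)),
                                max_steps = 100, seed = 1)
  expect_identical(counts$non_converged, 50L)
})

test_that("population simulation is reproducible from the master seed", {
  m <- load_model("unified")
  a <- simulate_population(m, runs = 500, seed = 123)
  b <- simulate_population(m, runs = 500, seed = 123)
  expect_identical(a, b)
  c <- simulate_population(m, runs = 500, seed = 124)
  expect_false(identical(a, c))
})

test_that("Monte-Carlo frequencies match the exact absorption solve", {
  # hand-solvable chain: from (A=0,B=1) the 4-state chain splits 1/2 - 1/2
  net <- toy_orchain()
  ex <- exact_absorption_probabilities(net, network_state(net, c(A = 0, B = 1)))
  expect_equal(ex$probabilities, c(0.5, 0.5), tolerance = 1e-12)

  # uniform-start oracle vs simulation on random fixed-point-only networks
  set.seed(31)
  tested <- 0L
  while (tested < 4L) {
    net <- random_boolean_network(n = sample(3:5, 1L), k = 2L)
    atts <- find_attractors(net)
    if (!all(vapply(atts, function(a) a$is_steady, logical(1)))) next
    tested <- tested + 1L
    ex <- exact_absorption_probabilities(net)
    runs <- 20000L
    freq <- mc_absorption(net, atts, runs)
    for (j in seq_along(atts)) {
      p <- ex$probabilities[j]
      sigma <- sqrt(max(p * (1 - p), 1e-12) / runs)
      expect_lt(abs(freq[j] - p), 4 * sigma + 1e-9)
    }
  }
})

test_that("WNT-on conditions absorb deterministically on the unified model", {
  m <- load_model("unified")
  counts <- simulate_population(m, runs = 3000, seed = 99,
    conditions = signaling_conditions(m)[c("WNT=1,RA=0", "WNT=1,RA=1")])
  expect_identical(counts$null, c(0L, 0L))
  expect_identical(counts$non_converged, c(0L, 0L))
  expect_identical(counts$SHF_vCM, c(3000L, 0L))
  expect_identical(counts$SHF_aCM, c(0L, 3000L))
})

test_that("lineage fraction pools expected-cell counts with a binomial SE", {
  # the published efficiency table as fixed counts
  counts <- data.frame(
    condition = c("WNT=0,RA=0", "WNT=1,RA=0", "WNT=0,RA=1", "WNT=1,RA=1"),
    FHF_aCM = c(0L, 0L, 81858L, 0L), FHF_vCM = c(81937L, 0L, 0L, 0L),
    SHF_aCM = c(0L, 0L, 0L, 100000L), SHF_vCM = c(0L, 100000L, 0L, 0L),
    null = c(18063L, 0L, 18142L, 0L), runs = 100000L)
  lf <- lineage_fraction(counts)
  expect_equal(lf$expected_cells, 363795)
  expect_equal(lf$fraction, 363795 / 400000, tolerance = 1e-12)
  expect_equal(lf$se, sqrt(lf$fraction * (1 - lf$fraction) / 4e5), tolerance = 1e-9)
  # all-expected corner
  counts$null <- 0L
  counts$FHF_vCM[1] <- 100000L
  counts$FHF_aCM[3] <- 100000L
  expect_equal(lineage_fraction(counts)$fraction, 1)
})

test_that("random initial states are fair coin flips over free nodes", {
  m <- load_model("unified")
  net <- set_clamps(m$network, c(EX_WNT = 0, RA = 1))
  set.seed(2)
  draws <- t(replicate(4000, unclass(random_initial_state(net))))
  frees <- setdiff(colnames(draws), names(net$clamps))
  means <- colMeans(draws[, frees])
  expect_true(all(abs(means - 0.5) < 0.03))
  expect_true(all(draws[, "RA"] == 1L))
  # determinism under a fixed seed
  set.seed(77); s1 <- random_initial_state(net)
  set.seed(77); s2 <- random_initial_state(net)
  expect_identical(s1, s2)
})
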