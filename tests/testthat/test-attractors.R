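test_that("fixed-point enumeration matches hand-derived sets", {
  # brute force over 8 states: (0,0,0), (0,0,1), (1,1,1)
  net <- toy_chain3()
  fps <- enumerate_fixed_points(net)
  expect_identical(lapply(fps, function(s) unname(unclass(s))),
                   list(c(0L, 0L, 0L), c(0L, 0L, 1L), c(1L, 1L, 1L)))

  # subtype model under full input clamps has the single atrial fixed point
  m <- load_model("cm_subtype")
  fps <- enumerate_fixed_points(set_clamps(m$network, c(RA = 1)))
  expect_length(fps, 1L)
  s <- fps[[1L]]
  expect_identical(unname(s[c("NR2F2", "HAND2", "IRX4", "HEY2", "MYL2", "MYL7")]),
                   c(1L, 1L, 0L, 0L, 0L, 1L))

  # fully clamped network: the single clamped state
  allc <- set_clamps(toy_swap(), c(X = 1, Y = 0))
  expect_identical(enumerate_fixed_points(allc),
                   list(network_state(allc)))
})

test_that("attractor search finds steady and cyclic attractors", {
  m <- load_model("cm_subtype")
  atts <- find_attractors(m$network)  # RA left free
  expect_length(atts, 2L)
  expect_true(all(vapply(atts, function(a) a$is_steady, logical(1))))
  labs <- sort(vapply(atts, function(a)
    classify_attractor(a$states[[1L]], m$signatures), ""))
  expect_identical(labs, c("aCM", "vCM"))

  cyc <- find_attractors(toy_negation())
  expect_length(cyc, 1L)
  expect_false(cyc[[1L]]$is_steady)
  expect_length(cyc[[1L]]$states, 2L)
})

test_that("the unified model has exactly the five expected steady states", {
  m <- load_model("unified")
  seen <- character()
  for (cond in signaling_conditions(m)) {
    atts <- find_attractors(set_clamps(m$network, cond))
    expect_true(all(vapply(atts, function(a) a$is_steady, logical(1))))
    seen <- c(seen, vapply(atts, function(a)
      classify_attractor(a$states[[1L]], m$signatures), ""))
  }
  expect_identical(sort(unique(seen)),
                   sort(c("FHF_aCM", "FHF_vCM", "SHF_aCM", "SHF_vCM", "null")))
  expect_length(seen, 6L)  # null appears under both WNT=0 conditions
})

test_that("attractors equal the brute-force mutual-reachability oracle", {
  set.seed(11)
  for (rep in 1:30) {
    net <- random_boolean_network(n = sample(3:6, 1L), k = 3L)
    expect_identical(attractor_key_sets(find_attractors(net)),
                     brute_attractors(net))
  }
})

test_that("every state reaches at least one attractor", {
  set.seed(13)
  for (rep in 1:10) {
    net <- random_boolean_network(n = 5L, k = 2L)
    atts <- find_attractors(net)
    for (s in all_states(net))
      expect_gte(length(reachable_attractors(net, s)), 1L)
  }
})

test_that("reachability restricts the attractor set correctly", {
  m <- load_model("unified")
  # a fixed point reaches only itself
  net <- set_clamps(m$network, c(EX_WNT = 1, RA = 0))
  atts <- find_attractors(net)
  expect_length(atts, 1L)
  fp <- atts[[1L]]$states[[1L]]
  r <- reachable_attractors(net, fp)
  expect_length(r, 1L)
  expect_identical(r[[1L]]$states[[1L]], fp)
  expect_identical(classify_attractor(fp, m$signatures), "SHF_vCM")

  # under WNT=1, RA=0 every random start reaches only the SHF ventricular state
  set.seed(5)
  for (i in 1:5) {
    start <- random_initial_state(net)
    r <- reachable_attractors(net, start)
    expect_length(r, 1L)
    expect_identical(classify_attractor(r[[1L]]$states[[1L]], m$signatures),
                     "SHF_vCM")
  }

  # the atrial marker pattern of the subtype model flows to the ventricular
  # fixed point once RA is withdrawn
  cm <- load_model("cm_subtype")
  net0 <- set_clamps(cm$network, c(RA = 0))
  start <- network_state(net0, c(NR2F2 = 1, HAND2 = 1, MYL7 = 1))
  r <- reachable_attractors(net0, start)
  expect_length(r, 1L)
  expect_identical(classify_attractor(r[[1L]]$states[[1L]], cm$signatures), "vCM")
})

test_that("the STG has 2^f vertices with self-loops recorded", {
  net <- toy_chain3()
  stg <- build_stg(net)
  expect_equal(igraph::vcount(stg$graph), 8)
  # fixed points carry a self-loop
  el <- igraph::as_edgelist(stg$graph, names = FALSE)
  selfs <- el[el[, 1L] == el[, 2L], 1L]
  expect_true(1L %in% selfs)  # code 0 = (0,0,0) is a fixed point

  neg <- build_stg(toy_negation())
  el <- igraph::as_edgelist(neg$graph, names = FALSE)
  expect_equal(igraph::vcount(neg$graph), 2)
  expect_identical(nrow(el[el[, 1L] != el[, 2L], , drop = FALSE]), 2L)
})

test_that("state-space guards refuse oversized requests", {
  net <- random_boolean_network(8, 2)
  expect_error(enumerate_fixed_points(net, max_free = 4L), "clamp")
  expect_error(find_attractors(net, max_free = 4L), "at most 4")
  expect_warning(find_attractors(net, scc_limit = 4L), "cyclic")
})
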