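test_that("precision matrix encodes the requested partial correlations", {
  nodes3 <- c("X1", "X2", "X3")
  # independence: empty edge list gives the identity
  K0 <- precision_from_structure(structure_spec(nodes3))
  expect_equal(unname(K0), diag(3))

  # the partial-correlation formula applied to the implied correlation
  # matrix must give back the requested weights (computed inline, not via
  # the package's estimator)
  recover <- function(spec) {
    R <- correlation_from_structure(spec)
    Kr <- solve(R)
    pc <- -Kr / sqrt(outer(diag(Kr), diag(Kr)))
    diag(pc) <- 0
    pc
  }
  s1 <- structure_spec(nodes3, data.frame(from = "X1", to = "X2", rho = 0.4472))
  pc1 <- recover(s1)
  expect_equal(pc1["X1", "X2"], 0.4472, tolerance = 1e-10)
  expect_equal(pc1["X1", "X3"], 0, tolerance = 1e-12)
  expect_equal(pc1["X2", "X3"], 0, tolerance = 1e-12)

  chain <- structure_spec(nodes3, data.frame(from = c("X1", "X2"),
                                             to = c("X2", "X3"),
                                             rho = c(0.5, 0.5)))
  pc2 <- recover(chain)
  expect_equal(pc2["X1", "X2"], 0.5, tolerance = 1e-10)
  expect_equal(pc2["X2", "X3"], 0.5, tolerance = 1e-10)
  expect_equal(pc2["X1", "X3"], 0, tolerance = 1e-12)
})

test_that("jointly infeasible edge weights are rejected", {
  nodes3 <- c("X1", "X2", "X3")
  expect_error(
    structure_spec(nodes3, data.frame(from = c("X1", "X1", "X2"),
                                      to = c("X2", "X3", "X3"),
                                      rho = c(0.9, 0.9, 0.9))),
    "NotPositiveDefinite")
  expect_error(structure_spec(nodes3, data.frame(from = "X1", to = "X1",
                                                 rho = 0.2)), "self-edges")
  expect_error(
    structure_spec(nodes3, data.frame(from = c("X1", "X2"), to = c("X2", "X1"),
                                      rho = c(0.2, 0.3))), "duplicate")
})

test_that("estimating on the population correlation matrix round-trips any structure", {
  nodes <- sc_measure_names()
  specs <- list(
    td_like_structure(),
    asd_like_structure(),
    structure_spec(nodes, data.frame(
      from = nodes[1:6], to = nodes[2:7],
      rho = c(0.35, -0.25, 0.3, -0.4, 0.2, 0.45)))
  )
  for (spec in specs) {
    net <- partial_correlations(correlation_from_structure(spec))
    expected <- matrix(0, 7, 7, dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(spec$edges))) {
      expected[spec$edges$from[r], spec$edges$to[r]] <- spec$edges$rho[r]
      expected[spec$edges$to[r], spec$edges$from[r]] <- spec$edges$rho[r]
    }
    expect_lt(max(abs(net$W - expected)), 1e-10)
  }
})

test_that("generated cohorts are deterministic under seed and track target marginals", {
  cfg <- default_scenarios()$td_like
  t1 <- suppressWarnings(generate_group(65, cfg$structure, cfg$measures, seed = 11))
  t2 <- suppressWarnings(generate_group(65, cfg$structure, cfg$measures, seed = 11))
  t3 <- suppressWarnings(generate_group(65, cfg$structure, cfg$measures, seed = 12))
  expect_identical(t1, t2)
  expect_false(isTRUE(all.equal(t1$A_TOM, t3$A_TOM)))

  # A-ToM marginal matches its target within 3 sd / sqrt(n)
  m <- cfg$measures$A_TOM
  expect_lt(abs(mean(t1$A_TOM) - m$mean), 3 * m$sd / sqrt(65))

  # independence structure: two measures nearly uncorrelated at large n
  ind <- structure_spec(c("u", "v"), label = "null")
  meas <- list(measure_spec("u", 0, 1), measure_spec("v", 0, 1))
  big <- generate_group(1e5, ind, meas, seed = 5)
  expect_lt(abs(cor(big$u, big$v)), 0.02)
})

test_that("range handling reports rather than truncates, unless asked", {
  spec <- structure_spec(c("a", "b"), label = "g")
  meas <- list(measure_spec("a", 12.5, 1, range = c(0, 13)),
               measure_spec("b", 5, 1))
  expect_warning(generate_group(200, spec, meas, seed = 3),
                 "outside admissible range")
  tr <- generate_group(200, spec, meas, seed = 3, truncate = TRUE)
  expect_lte(max(tr$a), 13)
  expect_error(measure_spec("a", 50, 1, range = c(0, 36)), "InvalidRange")
})

test_that("default scenarios have the stated topology and valid precision matrices", {
  sc <- default_scenarios()
  expect_equal(sc$td_like$n, 61L)
  expect_equal(sc$asd_like$n, 65L)
  expect_equal(structure_components(sc$td_like$structure), 1L)
  expect_gt(structure_components(sc$asd_like$structure), 1L)
  expect_lte(nrow(sc$asd_like$structure$edges), 4L)
  expect_true(all(abs(sc$asd_like$structure$edges$rho) <= 0.3))
  # both precision matrices positive definite
  for (cfg in sc) {
    ev <- eigen(precision_from_structure(cfg$structure), only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  # A-ToM is the highest-strength node of the generating TD-like network
  gen <- partial_correlations(correlation_from_structure(sc$td_like$structure))
  ks <- node_strength(gen)
  expect_equal(names(which.max(ks)), "A_TOM")
})

test_that("simulate_study stacks both scenarios reproducibly", {
  tab <- suppressWarnings(simulate_study(99))
  expect_equal(nrow(tab), 126)
  expect_setequal(unique(tab$group), c("TD", "ASD"))
  expect_identical(tab, suppressWarnings(simulate_study(99)))
})
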