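test_that("population layout matches the worked two-group example", {
  d <- simulation_design(2, 100, delta = 0.8, s = 0.05)
  pop <- make_population(d)
  # group 1 subgroups at 0 and 0.05; group 2 at 0.8 and 0.75, all predictors
  expect_equal(unname(pop$means[1, ]), rep(0, 5))
  expect_equal(unname(pop$means[2, ]), rep(0.05, 5))
  expect_equal(unname(pop$means[3, ]), rep(0.8, 5))
  expect_equal(unname(pop$means[4, ]), rep(0.75, 5))
  expect_equal(sum(pop$weights), 1)
  expect_identical(pop$covariance, d$correlation)
})

test_that("zero subgroup separation collapses to homogeneous groups", {
  pop <- make_population(simulation_design(3, 150, delta = 0.5, s = 0))
  for (g in 1:3)
    expect_equal(pop$means[pop$group == g, ][1, ],
                 pop$means[pop$group == g, ][2, ])
})

test_that("delta = s = 0.2 gives complete distributional overlap of 2 groups", {
  pop <- make_population(simulation_design(2, 100, delta = 0.2, s = 0.2))
  g1 <- sort(unname(pop$means[pop$group == 1, 1]))
  g2 <- sort(unname(pop$means[pop$group == 2, 1]))
  expect_equal(g1, g2)   # {0, 0.2} both
})

test_that("middle-group displacement points toward the higher group", {
  pop <- make_population(simulation_design(3, 150, delta = 0.5, s = 0.1))
  expect_equal(unname(pop$means[pop$group == 2, 1]), c(0.5, 0.6))
  # end groups displace inward
  expect_equal(unname(pop$means[pop$group == 1, 1]), c(0, 0.1))
  expect_equal(unname(pop$means[pop$group == 3, 1]), c(1.0, 0.9))
})

test_that("population invariants hold across design cells", {
  for (ng in 2:3) for (del in c(0.2, 0.8)) for (s in c(0, 0.15)) {
    pop <- make_population(simulation_design(ng, 300, delta = del, s = s))
    for (g in seq_len(ng)) {
      mg <- pop$means[pop$group == g, , drop = FALSE]
      expect_equal(unname(abs(mg[1, ] - mg[2, ])), rep(s, 5))
    }
    base <- pop$means[pop$subgroup == 1, 1]
    expect_equal(unname(diff(base)), rep(del, ng - 1))
  }
})

test_that("invalid designs are rejected with validation errors", {
  expect_error(simulation_design(3, 150, delta = -0.1), "delta")
  expect_error(simulation_design(3, 150, s = -0.05), "`s`")
  expect_error(simulation_design(4, 150), "n_groups")
  expect_error(simulation_design(3, 150, group_proportions = c(0.5, 0.5)),
               "group_proportions")
  expect_error(simulation_design(3, 150, subgroup_proportions = c(0.9, 0.2)),
               "subgroup_proportions")
  bad <- wais_correlations(); bad[1, 2] <- 0.9
  expect_error(simulation_design(3, 150, correlation = bad), "symmetric")
  indef <- matrix(0.99, 3, 3); diag(indef) <- 1; indef[1, 2] <- indef[2, 1] <- -0.99
  expect_error(simulation_design(3, 150, n_predictors = 3,
                                 correlation = indef), "eigenvalue")
})

test_that("size allocation is exact with largest-remainder tie resolution", {
  d <- simulation_design(3, 150)
  expect_equal(unname(allocate_sizes(d)), matrix(25L, 3, 2))
  d2 <- simulation_design(3, 150, group_proportions = c(0.6, 0.2, 0.2),
                          subgroup_proportions = c(0.75, 0.25))
  a2 <- allocate_sizes(d2)
  expect_equal(unname(a2[1, ]), c(68L, 22L))   # 90 * 0.75 = 67.5, tie -> larger
  expect_equal(sum(a2), 150L)
  d3 <- simulation_design(2, 100, subgroup_proportions = c(0.75, 0.25))
  a3 <- allocate_sizes(d3)
  expect_equal(unname(a3), matrix(c(38L, 38L, 12L, 12L), 2, 2))
  expect_warning(allocate_sizes(
    simulation_design(2, 4, subgroup_proportions = c(0.9, 0.1))), "zero")
})
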