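test_that("identical seeds reproduce the identical train/cv pair", {
  d <- simulation_design(3, 150, delta = 0.5, s = 0.1)
  p1 <- simulate_pair(d, 123)
  p2 <- simulate_pair(d, 123)
  expect_identical(p1$train$X, p2$train$X)
  expect_identical(p1$cv$X, p2$cv$X)
  expect_identical(p1$train$group, p2$train$group)
  expect_identical(p1$train$subgroup, p2$train$subgroup)
  p3 <- simulate_pair(d, 124)
  expect_false(identical(p1$train$X, p3$train$X))
  # train and cv are distinct draws
  expect_false(identical(p1$train$X, p1$cv$X))
})

test_that("per-cell counts match the allocation exactly in every replicate", {
  d <- simulation_design(3, 151, group_proportions = c(0.6, 0.2, 0.2),
                         subgroup_proportions = c(0.75, 0.25))
  counts <- allocate_sizes(d)
  for (seed in 1:5) {
    pair <- simulate_pair(d, seed)
    for (ds in pair) {
      tab <- table(ds$group, ds$subgroup)
      expect_equal(unname(as.matrix(tab)), unname(counts),
                   ignore_attr = TRUE)
    }
  }
})

test_that("pooled within-subgroup correlations recover the population matrix", {
  n <- 200000
  d <- simulation_design(2, n, delta = 0.8, s = 0.1)
  pair <- simulate_pair(d, 99)
  X <- pair$train$X
  cell <- interaction(pair$train$group, pair$train$subgroup)
  resid <- X - apply(X, 2, function(col) ave(col, cell))
  emp <- stats::cor(resid)
  expect_lt(max(abs(emp - wais_correlations())), 3 / sqrt(n / 4))
})

test_that("subgroup sample means converge to their population values", {
  n <- 200000
  d <- simulation_design(2, n, delta = 0.8, s = 0.2)
  pop <- make_population(d)
  pair <- simulate_pair(d, 7)
  ds <- pair$train
  for (i in seq_along(pop$group)) {
    idx <- ds$group == pop$group[i] & ds$subgroup == pop$subgroup[i]
    expect_lt(max(abs(colMeans(ds$X[idx, ]) - pop$means[i, ])), 0.01)
  }
  # mean-layout identity: within-group subgroup mean difference ~ s
  for (g in 1:2) {
    m1 <- colMeans(ds$X[ds$group == g & ds$subgroup == 1, ])
    m2 <- colMeans(ds$X[ds$group == g & ds$subgroup == 2, ])
    expect_lt(max(abs(abs(m1 - m2) - d$s)), 0.02)
  }
})

test_that("simulation preserves the caller's random-number state", {
  set.seed(555)
  before <- .Random.seed
  invisible(simulate_pair(simulation_design(2, 50), 1))
  expect_identical(.Random.seed, before)
})

test_that("datasets round-trip through CSV", {
  d <- simulation_design(2, 40, delta = 0.5, s = 0.1)
  pair <- simulate_pair(d, 5)
  path <- tempfile(fileext = ".csv")
  write_dataset_csv(pair$cv, path)
  back <- utils::read.csv(path)
  expect_equal(as.matrix(back[paste0("x", 1:5)]), pair$cv$X,
               ignore_attr = TRUE)
  expect_equal(back$group, pair$cv$group)
  expect_equal(back$subgroup, pair$cv$subgroup)
  expect_true(all(back$role == "cv"))
  unlink(path)
})
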