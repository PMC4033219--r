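test_that("row accounting: cells x replicates x methods x roles", {
  g <- experiment_grid(total_n = 150, group_ratio = "equal",
                       subgroup_ratio = "equal", delta = 0.5, overlap = 0.1,
                       methods = c("lda", "cart"), replicates = 2, seed = 4)
  r <- run_grid(g)
  expect_equal(nrow(r), 8)   # 1 cell x 2 reps x 2 methods x 2 roles
  expect_setequal(r$role, c("train", "cv"))
  expect_setequal(r$method, c("lda", "cart"))
})

test_that("the same master seed reproduces results bit-identically", {
  g <- experiment_grid(total_n = c(150, 300), group_ratio = "equal",
                       subgroup_ratio = "75/25", delta = 0.8,
                       overlap = c(0, 0.2), methods = c("lda", "mixda"),
                       replicates = 2, seed = 99)
  r1 <- run_grid(g)
  r2 <- run_grid(g)
  expect_identical(r1, r2)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  utils::write.csv(r1, p1, row.names = FALSE)
  utils::write.csv(r2, p2, row.names = FALSE)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
})

test_that("child seeds are deterministic, bounded and collision-free", {
  seeds <- outer(1:180, 1:50, function(ci, ri)
    mapply(child_seed, 7, ci, ri))
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
  expect_equal(anyDuplicated(as.vector(seeds)), 0)
  expect_identical(child_seed(7, 12, 3), child_seed(7, 12, 3))
})

test_that("an s = 0 cell equals an independent homogeneous-group simulation", {
  design <- simulation_design(3, 120, delta = 0.5, s = 0)
  seed <- child_seed(31, 1, 1)
  pair <- simulate_pair(design, seed)
  # independently coded homogeneous draw: no subgroup structure at all
  u <- chol(wais_correlations())
  mu <- rep(c(0, 0.5, 1.0), each = 40)
  set.seed(seed)
  for (ds in list(pair$train, pair$cv)) {
    Z <- matrix(rnorm(120 * 5), 120, 5) %*% u + mu
    expect_equal(unname(ds$X), unname(Z))
    expect_equal(ds$group, rep(1:3, each = 40))
  }
})

test_that("a failing method is recorded as missing without voiding others", {
  g <- experiment_grid(n_groups = 2, total_n = 8, group_ratio = "equal",
                       subgroup_ratio = "equal", delta = 0.8, overlap = 0,
                       methods = c("lda", "cart"), replicates = 1, seed = 2)
  r <- suppressWarnings(run_grid(g))   # cart: n below the minimum node size
  expect_true(all(is.na(r$overall[r$method == "cart"])))
  expect_true(all(!is.na(r$overall[r$method == "lda"])))
})

test_that("summaries have the condition-table shapes", {
  g <- experiment_grid(total_n = 150, group_ratio = "equal",
                       subgroup_ratio = "equal", delta = 0.5,
                       replicates = 1, seed = 5)
  r <- run_grid(g)
  s <- summarize_results(r, by = "overlap")
  expect_equal(nrow(s), 5 * 5)          # 5 overlaps x 5 methods
  wide <- pivot_methods(s)
  expect_equal(dim(wide), c(5L, 6L))    # overlap + 5 method columns
  expect_equal(wide$overlap, c(0, 0.05, 0.10, 0.15, 0.20))
  sg <- summarize_results(r, by = c("subgroup_ratio", "overlap"),
                          by_group = TRUE)
  expect_equal(nrow(sg), 1 * 5 * 5 * 3) # sratio x overlap x method x group
  m <- marginal_stats(r, factors = "overlap")
  expect_equal(sort(m$method), sort(unique(r$method)))
  expect_true(all(m$min <= m$median & m$median <= m$max))
  cellmeans <- summarize_results(r, by = "overlap")
  for (meth in m$method) {
    rates <- cellmeans$rate[cellmeans$method == meth]
    expect_true(all(m$mean[m$method == meth] >= min(rates) &
                      m$mean[m$method == meth] <= max(rates)))
  }
})

test_that("summary CSVs round-trip through report_summaries", {
  g <- experiment_grid(total_n = 150, group_ratio = "equal",
                       subgroup_ratio = "equal", delta = 0.8, overlap = 0,
                       methods = c("lda", "lr"), replicates = 2, seed = 6)
  s <- summarize_results(run_grid(g), by = "overlap")
  dir <- file.path(tempdir(), "sgs-report")
  paths <- report_summaries(list(tab = s), dir, text = TRUE)
  back <- utils::read.csv(file.path(dir, "tab.csv"))
  expect_equal(back$rate, s$rate)
  expect_equal(back$method, s$method)
  expect_true(file.exists(file.path(dir, "tab.txt")))
  unlink(dir, recursive = TRUE)
})

test_that("experiment configs load from YAML and JSON", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("n_groups: 3", "total_n: [150, 300]",
               "group_ratio: [equal]", "subgroup_ratio: [equal, 75/25]",
               "delta: [0.5]", "overlap: [0, 0.1]",
               "methods: [lda, cart]", "replicates: 5", "seed: 42",
               "config:", "  cart:", "    min_node_size: 12"), yml)
  g <- read_experiment_config(yml)
  expect_equal(nrow(g$cells), 2 * 1 * 2 * 1 * 2)
  expect_equal(g$replicates, 5L)
  expect_equal(g$config$cart$min_node_size, 12)
  # mixed int/float YAML sequences must flatten to numeric vectors that
  # survive a simulation run
  expect_type(g$cells$overlap, "double")
  g$replicates <- 1L
  g$cells <- g$cells[1, , drop = FALSE]
  expect_s3_class(run_grid(g), "data.frame")
  jsn <- tempfile(fileext = ".json")
  writeLines('{"n_groups": 2, "total_n": [100], "delta": [0.2],
               "overlap": [0], "methods": ["lda"], "replicates": 1}', jsn)
  g2 <- read_experiment_config(jsn)
  expect_equal(g2$n_groups, 2L)
  bad <- tempfile(fileext = ".yaml")
  writeLines("bogus_field: 3", bad)
  expect_error(read_experiment_config(bad), "unknown")
  expect_error(experiment_grid(methods = "svm"), "unknown method")
  unlink(c(yml, jsn, bad))
})
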