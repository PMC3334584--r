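test_that("strict-clock trees recover true node ages for any lambda", {
  cfg <- clean_config(rate_sigma = 0, seed = 3)
  set.seed(3)
  sim <- simulate_orthogroup(cfg, "0001")
  gt <- sim$tree
  cal <- transfer_calibrations(gt, default_panel)
  truth <- true_clock_ages(gt$phy, cfg$rate_base)
  for (lam in c(0.1, 10, 1000)) {
    fit <- penalized_likelihood_date(gt, cal, lambda = lam, nstart = 2)
    rel <- abs(fit$node_ages - truth) / pmax(truth, 1)
    expect_lt(max(rel), 1e-3)
  }
})

test_that("smoothing monotonically reduces rate heterogeneity", {
  cfg <- clean_config(rate_sigma = 0.5, seed = 8)
  set.seed(8)
  sim <- simulate_orthogroup(cfg, "0001")
  cal <- transfer_calibrations(sim$tree, default_panel)
  v0 <- var(penalized_likelihood_date(sim$tree, cal, lambda = 0.01,
                                      nstart = 2)$branch_rates)
  spread <- vapply(c(0.01, 1, 100, 1e4), function(lam) {
    f <- penalized_likelihood_date(sim$tree, cal, lambda = lam, nstart = 2)
    diff(range(f$branch_rates))
  }, numeric(1))
  vL <- var(penalized_likelihood_date(sim$tree, cal, lambda = 1e4,
                                      nstart = 2)$branch_rates)
  expect_lt(vL, v0)
  # rates converge to a common clock as lambda grows by orders of magnitude
  expect_lt(spread[4], spread[1] / 50)
})

test_that("fit matches a brute-force grid search over ages", {
  nwk <- paste0("((A|a:0.8,B|b:0.4)90:0.6,((C|c:0.5,D|d:0.3)90:0.4,",
                "E|e:1.1)90:0.5);")
  gt <- read_gene_tree(nwk)
  root <- length(gt$phy$tip.label) + 1L
  cal <- calibration_set(root, 10, 10)
  lam <- 1; ns <- 100
  fit <- penalized_likelihood_date(gt, cal, lambda = lam, nsites = ns,
                                   nstart = 5)
  grid <- oracle_pl_grid(fit$phy, root_age = 10, lambda = lam, nsites = ns)
  obj_fit <- oracle_pl_objective(fit$phy, fit$node_ages,
                                 log(fit$branch_rates * ns), lam, ns)
  # the optimizer must do at least as well as the grid (up to grid noise)
  expect_gte(obj_fit, grid$obj - 1e-2)
  # and land within one grid step of the grid optimum
  step <- 10 * (0.96 - 0.04) / 11
  free <- setdiff((root):(root + gt$phy$Nnode - 1), root)
  expect_lt(max(abs(fit$node_ages[free] - grid$ages[free])), step)
})

test_that("solution beats random feasible age/rate configurations", {
  cfg <- clean_config(rate_sigma = 0.3, seed = 12)
  set.seed(12)
  sim <- simulate_orthogroup(cfg, "0001")
  cal <- transfer_calibrations(sim$tree, default_panel)
  lam <- 5; ns <- 1000
  fit <- penalized_likelihood_date(sim$tree, cal, lambda = lam, nsites = ns)
  obj_fit <- oracle_pl_objective(fit$phy, fit$node_ages,
                                 log(fit$branch_rates * ns), lam, ns)
  phy <- fit$phy
  ntip <- length(phy$tip.label)
  set.seed(99)
  for (i in 1:100) {
    # random feasible ages: perturb the fitted ages, clamped to ordering
    ages <- fit$node_ages
    ord <- order(ages[(ntip + 1):(ntip + phy$Nnode)])
    ages[(ntip + 1):(ntip + phy$Nnode)] <-
      sort(ages[(ntip + 1):(ntip + phy$Nnode)] *
             runif(phy$Nnode, 0.9, 1.1))[order(ord)]
    if (any(ages[phy$edge[, 1]] <= ages[phy$edge[, 2]])) next
    lr <- log(fit$branch_rates * ns) + rnorm(nrow(phy$edge), 0, 0.3)
    expect_gte(obj_fit, oracle_pl_objective(phy, ages, lr, lam, ns) - 1e-6)
  }
})

test_that("calibrations bind: fixed exactly, bounds at boundaries only", {
  cfg <- clean_config(rate_sigma = 0.3, seed = 5)
  set.seed(5)
  sim <- simulate_orthogroup(cfg, "0001")
  gt <- sim$tree
  cal <- transfer_calibrations(gt, default_panel)
  fit <- penalized_likelihood_date(gt, cal, lambda = 1)
  fixed <- cal$node[!is.na(cal$min) & !is.na(cal$max) & cal$min == cal$max]
  expect_true(all(abs(fit$node_ages[fixed] - 125) < 1e-9))
  root <- length(gt$phy$tip.label) + 1L
  expect_gte(fit$node_ages[root], 131)
  expect_lte(fit$node_ages[root], 309)
  # ultrametric by construction: every parent older than child, tips at 0
  expect_true(all(fit$node_ages[fit$phy$edge[, 1]] >
                    fit$node_ages[fit$phy$edge[, 2]]))
  expect_true(all(fit$node_ages[seq_len(root - 1)] == 0))
  # unidentifiable scale: only a minimum constraint
  expect_error(penalized_likelihood_date(
    gt, calibration_set(root, min = 131), lambda = 1), "unidentifiable")
})

test_that("cross-validation selects sensible smoothing", {
  calib <- function(g) transfer_calibrations(g, default_panel)
  # grid of one value is returned untouched
  cfg <- clean_config(rate_sigma = 0, seed = 21)
  set.seed(21)
  sim <- simulate_orthogroup(cfg, "0001")
  expect_equal(cross_validate_smoothing(sim$tree, calib, 7)$lambda, 7)
  # clock data: flat curve within noise; tie goes to the smallest lambda
  cv <- cross_validate_smoothing(sim$tree, calib, c(0.1, 1, 10, 100, 1000),
                                 seed = 1)
  expect_true(all(is.finite(cv$cv$score)))
  expect_equal(cv$lambda, 0.1)
  # lineage-wide rate shift plus branch noise: an interior optimum
  cfg2 <- clean_config(rate_sigma = 0.2, seed = 21)
  set.seed(21)
  sim2 <- simulate_orthogroup(cfg2, "0001")
  phy <- sim2$tree$phy
  sets <- lapply(seq_len(length(phy$tip.label) + phy$Nnode), function(v)
    if (v <= length(phy$tip.label)) v else
      which(phy$tip.label %in% ape::extract.clade(phy, v)$tip.label))
  mono <- grep("Acorus|Typha", phy$tip.label)
  shifted <- which(vapply(seq_len(nrow(phy$edge)), function(e)
    all(sets[[phy$edge[e, 2]]] %in% mono), logical(1)))
  phy$edge.length[shifted] <- phy$edge.length[shifted] * 4
  sim2$tree$phy <- phy
  cv2 <- cross_validate_smoothing(sim2$tree, calib,
                                  c(0.1, 1, 10, 100, 1000), seed = 1)
  expect_gt(cv2$lambda, min(c(0.1, 1, 10, 100, 1000)))
  expect_lt(cv2$lambda, max(c(0.1, 1, 10, 100, 1000)))
  expect_error(cross_validate_smoothing(sim$tree, calib, c(10, 1)),
               "ascending")
})

test_that("duplication ages are read off the dated tree", {
  cfg <- clean_config(rate_sigma = 0, seed = 31)
  set.seed(31)
  sim <- simulate_orthogroup(cfg, "0001")
  gt <- sim$tree
  cal <- transfer_calibrations(gt, default_panel)
  fit <- penalized_likelihood_date(gt, cal, lambda = 1)
  cl <- classify_pair(gt, "0001", sim$pair$gene_a, sim$pair$gene_b,
                      default_panel)
  expect_equal(duplication_age(fit, cl), 122, tolerance = 1e-3)
  # a calibrated fixed node dates exactly at its constraint
  fixed <- cal$node[cal$min == cal$max & !is.na(cal$min)]
  expect_identical(duplication_age(fit, fixed[1]), 125)
  # unresolved calls cannot be dated
  bad <- cl; bad$placement <- "unresolved"
  expect_error(duplication_age(fit, bad), "unresolved")
  expect_error(duplication_age(fit, 10000L), "missing")
})
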