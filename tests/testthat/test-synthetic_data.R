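test_that("default chronogram carries the calibration anchors", {
  ch <- default_chronogram()
  expect_equal(ch$ages[["eudicot_crown"]], 125)
  expect_equal(unname(branch_age_span(ch, "BR3")), c(120, 125))
  expect_equal(unname(branch_age_span(ch, "BR2")), c(125, 150))
  expect_equal(unname(branch_age_span(ch, "BR1")), c(150, 155))
  # anchors configurable
  ch2 <- default_chronogram(root = 170)
  expect_equal(ch2$ages[["root"]], 170)
  expect_error(default_chronogram(core_eudicot = 130),
               "strictly decrease")
})

test_that("infeasible duplication ages are rejected up front", {
  expect_error(synthetic_config(wgd_branch = "BR3", wgd_age = 117),
               "outside the BR3 span")
  expect_error(synthetic_config(wgd_branch = "BR3", wgd_age = 122,
                                loss_rate = 1), "infeasible")
  # the shifted chronogram used for 117-mya cohorts makes it feasible
  expect_s3_class(synthetic_config(wgd_branch = "BR3", wgd_age = 117,
                                   chronogram = chron117()),
                  "synthetic_config")
})

test_that("lossless triplication duplicates every core eudicot species", {
  cfg <- synthetic_config(wgd_branch = "BR3", wgd_age = 122,
                          duplicate_multiplicity = 2, loss_rate = 0,
                          sampling_prob = 1, rate_sigma = 0, seed = 1)
  set.seed(1)
  sim <- simulate_orthogroup(cfg, "0007")
  counts <- table(sim$tree$species)
  core <- c("Beta_vulgaris", "Mesembryanthemum_crystallinum",
            "Solanum_tuberosum", "Helianthus_annuus", "Vitis_vinifera",
            "Populus_trichocarpa", "Arabidopsis_thaliana")
  for (sp in names(counts)) {
    expect_equal(unname(counts[sp]), if (sp %in% core) 2 else 1,
                 info = sp)
  }
  # multiplicity 3 (hexaploidy-style triplication)
  cfg3 <- synthetic_config(wgd_branch = "BR3", wgd_age = 122,
                           duplicate_multiplicity = 3, loss_rate = 0,
                           sampling_prob = 1, rate_sigma = 0, seed = 1)
  set.seed(1)
  sim3 <- simulate_orthogroup(cfg3, "0008")
  expect_equal(unname(table(sim3$tree$species)["Vitis_vinifera"]), 3)
})

test_that("focal pairs are always retained and their MRCA sits at wgd_age", {
  cfg <- synthetic_config(wgd_branch = "BR3", wgd_age = 122,
                          loss_rate = 0.02, sampling_prob = 0.7,
                          rate_sigma = 0, seed = 2)
  set.seed(2)
  for (i in 1:20) {
    sim <- simulate_orthogroup(cfg, sprintf("%04d", i))
    focal <- sum(sim$tree$species == "Vitis_vinifera")
    expect_gte(focal, 2)
    expect_false(is.null(sim$pair))
    # truth conservation: with a strict clock the pair MRCA depth equals
    # wgd_age * rate_base exactly
    loc <- locate_duplication_node(sim$tree, sim$pair$gene_a,
                                   sim$pair$gene_b)
    depth <- true_depth <- NULL
    phy <- sim$tree$phy
    d <- numeric(length(phy$tip.label) + phy$Nnode)
    for (e in ape::postorder(phy)) {
      d[phy$edge[e, 1]] <- max(d[phy$edge[e, 1]],
                               d[phy$edge[e, 2]] + phy$edge.length[e])
    }
    expect_equal(d[loc$node] / cfg$rate_base, 122, tolerance = 1e-9)
  }
})

test_that("per-species survival of the extra copy matches the hazard", {
  # expected copies per non-focal duplicated species: 1 + exp(-rate * age)
  cfg <- synthetic_config(wgd_branch = "BR3", wgd_age = 122,
                          loss_rate = 0.004, sampling_prob = 1,
                          rate_sigma = 0, seed = 3)
  set.seed(3)
  n <- 800
  copies <- numeric(n)
  for (i in seq_len(n)) {
    sim <- simulate_orthogroup(cfg, "x")
    copies[i] <- sum(sim$tree$species == "Solanum_tuberosum")
  }
  p <- exp(-0.004 * 122)
  expected <- 1 + p
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(copies) - expected), 2 * se + 1e-12)
})

test_that("cohorts are reproducible and demand at least one orthogroup", {
  cfg <- synthetic_config(seed = 9, rate_sigma = 0.3,
                          support_model = support_noisy())
  c1 <- simulate_cohort(cfg, 5)
  c2 <- simulate_cohort(cfg, 5)
  expect_identical(vapply(c1$trees, write_gene_tree, ""),
                   vapply(c2$trees, write_gene_tree, ""))
  expect_identical(c1$pairs, c2$pairs)
  expect_error(simulate_cohort(cfg, 0), ">= 1")
  # written cohorts round-trip through the directory loader
  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  trees <- load_gene_trees(dir)
  expect_setequal(names(trees), names(c1$trees))
  expect_identical(write_gene_tree(trees[["0001"]]),
                   write_gene_tree(c1$trees[["0001"]]))
  pairs <- read_pairs(file.path(dir, "pairs.tsv"))
  expect_equal(nrow(pairs), nrow(c1$pairs))
})

test_that("noisy supports fall with branch duration", {
  sm <- support_noisy(slope = 1.5, midpoint = 1, noise = 0)
  set.seed(4)
  long <- wgdphylo:::.draw_support(sm, 5)
  short <- wgdphylo:::.draw_support(sm, 0.1)
  expect_gt(long, 90)
  expect_lt(short, 50)
})
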