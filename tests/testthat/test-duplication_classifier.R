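test_that("duplication node location separates the duplicates", {
  gt <- fig2_tree()
  loc <- locate_duplication_node(gt, "Vv1", "Vv2")
  expect_false(loc$multifurcating)
  phy <- gt$phy
  # MRCA subtends exactly the two duplicate clades (4 tips here)
  tips <- which(phy$tip.label %in%
                  ape::extract.clade(phy, loc$node)$tip.label)
  expect_setequal(gt$gene[tips], c("Vv1", "St1", "Vv2", "Ha1"))
  # cherry pair: clades are single leaves
  gt2 <- read_gene_tree(paste0(
    "((Vitis_vinifera|a:0.1,Vitis_vinifera|b:0.1)90:0.1,",
    "Eschscholzia_californica|e:0.2);"))
  loc2 <- locate_duplication_node(gt2, "a", "b")
  expect_lte(loc2$clade2, 3)
  expect_lte(loc2$clade3, 3)
  expect_error(locate_duplication_node(gt, "Vv1", "nope"), "not found")
})

test_that("support rule: bootstrap1 and at least one duplicate clade", {
  expect_true(passes_support(c(81, 30, 85), 80))
  expect_false(passes_support(c(79, 100, 100), 80))
  expect_true(passes_support(c(79, 100, 100), 50))
  expect_true(passes_support(c(50, 50, 0), 50))    # boundary inclusive
  expect_false(passes_support(c(49, 100, 100), 50))
  expect_false(passes_support(c(NA, 100, 100), 50))  # missing fails
  expect_false(passes_support(c(90, NA, NA), 50))
})

test_that("core eudicot-wide duplications classify as BR3 at both tiers", {
  # all supports high: BR3 at the 80% tier
  cl <- classify_pair(fig2_tree(), "og", "Vv1", "Vv2", default_panel)
  expect_identical(cl$placement, "BR3")
  expect_identical(cl$tier, "ge80")
  expect_true(all(c("asterid") %in% names(cl$inside)))
  expect_true("basal_eudicot" %in% names(cl$sister))
  # bootstrap1 in [50, 80): same call, lower tier
  cl2 <- classify_pair(fig2_tree(b1 = 65), "og", "Vv1", "Vv2",
                       default_panel)
  expect_identical(cl2$placement, "BR3")
  expect_identical(cl2$tier, "ge50")
  # bootstrap1 < 50: unresolved
  cl3 <- classify_pair(fig2_tree(b1 = 40), "og", "Vv1", "Vv2",
                       default_panel)
  expect_identical(cl3$placement, "unresolved")
  expect_identical(cl3$tier, "none")
  # missing sister witness (basal eudicot attachment unsupported) degrades
  cl4 <- classify_pair(fig2_tree(b1 = 95, b_be = 10, inner2 = 10,
                                 inner3 = 10),
                       "og", "Vv1", "Vv2", default_panel)
  expect_identical(cl4$placement, "unresolved")
})

test_that("rosid-only duplicate clades with an asterid sister give BR4", {
  cl <- classify_pair(br4_tree(), "og", "Vv1", "Vv2", default_panel)
  expect_identical(cl$placement, "BR4")
  expect_identical(cl$tier, "ge80")
  # no supported bipartition certifies any sister lineage: unresolved
  cl2 <- classify_pair(br4_tree(b_sis = 30, b_be = 30, b_mono = 30,
                                b1 = 95, join_sis = 30, join_be = 30,
                                join_mono = 30),
                       "og", "Vv1", "Vv2", default_panel)
  expect_identical(cl2$placement, "unresolved")
})

test_that("placement is invariant to relabeling species within a lineage", {
  gt <- fig2_tree()
  base <- classify_placement(gt, "Vv1", "Vv2", default_panel, 50)$placement
  swap <- gt
  swap$species[swap$species == "Solanum_tuberosum"] <- "Panax_quinquefolius"
  swap$species[swap$species == "Acorus_americanus"] <- "Typha_angustifolia"
  expect_identical(
    classify_placement(swap, "Vv1", "Vv2", default_panel, 50)$placement,
    base)
})

test_that("classifier agrees with the literal-rule brute-force oracle", {
  set.seed(77)
  mismatches <- 0
  for (rep in 1:120) {
    gt <- random_gene_tree(sample(6:12, 1))
    vv <- gt$gene[gt$species == "Vitis_vinifera"]
    pair <- sample(vv, 2)
    for (thr in c(50, 80)) {
      mine <- classify_placement(gt, pair[1], pair[2], default_panel,
                                 thr)$placement
      ref <- oracle_classify(gt, pair[1], pair[2], default_panel, thr)
      if (!identical(mine, ref)) mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("grass monocots can be excluded as evidence", {
  nwk <- paste0(
    "(Amborella_trichopoda|Am1:0.3,",
    "((Eschscholzia_californica|Es1:0.15,Aquilegia_formosa|Aq1:0.16)90:0.05,",
    "((Vitis_vinifera|Vv1:0.1,Oryza_sativa|Or1:0.2)90:0.03,",
    "(Vitis_vinifera|Vv2:0.1,Solanum_tuberosum|St1:0.1)90:0.03)90:0.02",
    ")90:0.1);")
  gt <- read_gene_tree(nwk)
  # with grasses: rice inside a duplicate clade pushes the call toward BR1
  with_g <- classify_placement(gt, "Vv1", "Vv2", default_panel, 50,
                               use_grasses = TRUE)
  expect_true("monocot" %in% names(with_g$inside))
  without_g <- classify_placement(gt, "Vv1", "Vv2", default_panel, 50,
                                  use_grasses = FALSE)
  expect_false("monocot" %in% names(without_g$inside))
  expect_identical(without_g$placement, "BR3")
})

test_that("call summaries reproduce tiered counts and percentages", {
  counts <- list(ge50 = c(BR1 = 7, BR2 = 70, BR3 = 168, BR4 = 6),
                 ge80 = c(BR1 = 0, BR2 = 19, BR3 = 80, BR4 = 4))
  sm <- summarize_calls(counts = counts)
  expect_equal(sm$pct_ge50, c(2.8, 27.9, 66.9, 2.4))
  expect_equal(sm$pct_ge80, c(0, 18.4, 77.7, 3.9))
  expect_equal(unname(attr(sm, "totals")), c(103, 251))
  expect_equal(headline_share(sm, "ge50"), 95)
  # empty input gives an all-zero table
  sm0 <- summarize_calls(list())
  expect_true(all(sm0$dup_ge50 == 0))
  expect_equal(headline_share(sm0), 0)
  # calls route: a ge80 call is counted at both tiers
  cl <- classify_pair(fig2_tree(), "og", "Vv1", "Vv2", default_panel)
  sm1 <- summarize_calls(list(cl))
  expect_equal(sm1$dup_ge50[sm1$branch == "BR3"], 1)
  expect_equal(sm1$dup_ge80[sm1$branch == "BR3"], 1)
})
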