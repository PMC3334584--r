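test_that("newick gene trees parse with supports and leaf metadata", {
  gt <- read_gene_tree("((A|g1:0.1,A|g2:0.1)95:0.2,B|g3:0.3);")
  expect_equal(n_tips(gt), 3)
  expect_equal(sort(gt$gene), c("g1", "g2", "g3"))
  expect_equal(gt$species, c("A", "A", "B"))
  expect_true(95 %in% gt$support)
  # no internal labels -> supports missing
  gt2 <- read_gene_tree("((A|g1,B|g2),C|g3);")
  expect_true(all(is.na(gt2$support)))
  expect_error(read_gene_tree("((A,B);"), "unclosed")
  expect_error(read_gene_tree("((A|g1:0.1,B|g2:0.1)high:0.2,C|g3:0.3);"),
               "non-numeric")
  expect_error(read_gene_tree("((A|g1:0.1,B|g2:0.1)150:0.2,C|g3:0.3);"),
               "\\[0, 100\\]")
})

test_that("read-write-read round trip preserves topology, supports, lengths", {
  set.seed(42)
  for (rep in 1:5) {
    gt <- random_gene_tree(sample(6:12, 1))
    txt <- write_gene_tree(gt)
    gt2 <- read_gene_tree(txt)
    expect_equal(ape::dist.topo(ape::unroot(gt2$phy),
                                ape::unroot(gt$phy))[1], 0)
    expect_equal(sort(round(gt2$phy$edge.length, 6)),
                 sort(round(gt$phy$edge.length, 6)))
    expect_equal(sort(gt2$support, na.last = TRUE),
                 sort(gt$support, na.last = TRUE))
  }
})

test_that("rooting picks the deepest lineage and preserves bipartitions", {
  nwk <- paste0("((Vitis_vinifera|v1:0.1,Solanum_tuberosum|s1:0.1)80:0.1,",
                "(Amborella_trichopoda|a1:0.2,",
                "(Acorus_americanus|m1:0.1,",
                "Eschscholzia_californica|e1:0.1)70:0.1)60:0.1);")
  gt <- read_gene_tree(nwk)
  rt <- root_by_deepest_outgroup(gt, default_panel)
  # basal angiosperm clade sister to everything else
  phy <- rt$phy
  root_kids <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2]
  out_side <- vapply(root_kids, function(k) {
    tips <- if (k <= length(phy$tip.label)) k else
      which(phy$tip.label %in% ape::extract.clade(phy, k)$tip.label)
    all(grepl("Amborella", phy$tip.label[tips]))
  }, logical(1))
  expect_true(any(out_side))
  # bipartition supports preserved: the asterid+vitis clade still carries 80
  v <- ape::getMRCA(phy, grep("Vitis|Solanum", phy$tip.label))
  expect_equal(node_support(rt, v), 80)

  # monocot priority when no basal angiosperm or magnoliid present
  nwk2 <- paste0("((Vitis_vinifera|v1:0.1,Solanum_tuberosum|s1:0.1)90:0.1,",
                 "(Acorus_americanus|m1:0.1,",
                 "Eschscholzia_californica|e1:0.1)75:0.1);")
  rt2 <- root_by_deepest_outgroup(read_gene_tree(nwk2), default_panel)
  phy2 <- rt2$phy
  kids2 <- phy2$edge[phy2$edge[, 1] == length(phy2$tip.label) + 1L, 2]
  expect_true(any(vapply(kids2, function(k)
    k <= 4 && grepl("Acorus", phy2$tip.label[k]), logical(1))))

  # all core eudicots: no outgroup
  nwk3 <- "((Vitis_vinifera|v1,Vitis_vinifera|v2),Solanum_tuberosum|s1);"
  expect_error(root_by_deepest_outgroup(read_gene_tree(nwk3),
                                        default_panel), "no outgroup")
})

test_that("coverage filter keeps >= 70% and is boundary inclusive", {
  mk <- function(nongap, len = 100)
    paste0(paste(rep("A", nongap), collapse = ""),
           paste(rep("-", len - nongap), collapse = ""))
  aln <- c(keep70 = mk(70), drop69 = mk(69), full = mk(100),
           allgap = mk(0))
  kept <- filter_alignment_coverage(aln)
  expect_setequal(kept, c("keep70", "full"))
  # custom threshold
  expect_setequal(filter_alignment_coverage(aln, 0.5),
                  c("keep70", "drop69", "full"))
  expect_error(filter_alignment_coverage(c(a = "AC-", b = "ACGT")),
               "ragged")
})

test_that("pair lists parse, collapse duplicates, and report bad rows", {
  txt <- "og1\tva\tvb\nog1\tva\tvc\n"
  df <- read_pairs(text = txt)
  expect_equal(nrow(df), 2)
  expect_equal(df$source, c("other", "other"))
  # repeated unordered pair collapses with a warning
  expect_warning(df2 <- read_pairs(text = "og1\tva\tvb\nog1\tvb\tva\n"),
                 "1 duplicate")
  expect_equal(nrow(df2), 1)
  expect_error(read_pairs(text = "og1\tonlyone\n"), "line 1")
  expect_error(read_pairs(text = "og1\tva\tva\n"), "gene_a equals gene_b")
  # CRLF and header tolerated
  df3 <- read_pairs(text = "orthogroup\tgene_a\tgene_b\r\nog9\tx\ty\r\n")
  expect_equal(df3$orthogroup, "og9")
})
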