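# shared fixtures built in code

default_panel <- build_default_panel()

# a Fig-2-style orthogroup tree: two focal (Vitis) duplicates, each in a
# clade with an asterid, basal eudicots sister, then monocots, then a basal
# angiosperm outgroup; all supports set by arguments
fig2_tree <- function(b1 = 95, b2 = 90, b3 = 85, b_be = 92, b_mono = 88,
                      inner2 = 96, inner3 = 97) {
  nwk <- sprintf(paste0(
    "(Amborella_trichopoda|Am1:0.30,",
    "((Acorus_americanus|Ac1:0.20,Typha_angustifolia|Ty1:0.22)%d:0.05,",
    "((Eschscholzia_californica|Es1:0.15,Aquilegia_formosa|Aq1:0.16)%d:0.04,",
    "((Vitis_vinifera|Vv1:0.10,Solanum_tuberosum|St1:0.11)%d:0.03,",
    "(Vitis_vinifera|Vv2:0.12,Helianthus_annuus|Ha1:0.13)%d:0.03)%d:0.02",
    ")%d:0.02)%d:0.02);"),
    b_mono, b_be, b2, b3, b1, inner2, inner3)
  read_gene_tree(nwk)
}

# BR4-style tree: both duplicate clades rosid-only, asterid clade sister;
# join_* are the supports of the nodes joining the sister groups to the
# duplication clade (any supported ancestor can certify sister evidence)
br4_tree <- function(b1 = 95, b2 = 92, b3 = 91, b_sis = 95, b_be = 90,
                     b_mono = 89, join_sis = 94, join_be = 93,
                     join_mono = 92) {
  nwk <- sprintf(paste0(
    "(Amborella_trichopoda|Am1:0.30,",
    "((Acorus_americanus|Ac1:0.20,Typha_angustifolia|Ty1:0.21)%d:0.05,",
    "((Eschscholzia_californica|Es1:0.15,Aquilegia_formosa|Aq1:0.16)%d:0.04,",
    "((Solanum_tuberosum|St1:0.09,Helianthus_annuus|Ha1:0.10)%d:0.03,",
    "((Vitis_vinifera|Vv1:0.05,Populus_trichocarpa|Po1:0.06)%d:0.02,",
    "(Vitis_vinifera|Vv2:0.05,Arabidopsis_thaliana|At1:0.07)%d:0.02",
    ")%d:0.02)%d:0.02)%d:0.02)%d:0.02);"),
    b_mono, b_be, b_sis, b2, b3, b1, join_sis, join_be, join_mono)
  read_gene_tree(nwk)
}

# true node ages of a strict-clock tree: max substitution depth / rate
true_clock_ages <- function(phy, rate) {
  ntip <- length(phy$tip.label)
  depth <- numeric(ntip + phy$Nnode)
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    depth[p] <- max(depth[p], depth[ch] + phy$edge.length[e])
  }
  depth / rate
}

# clean clock cohort configuration helpers
clean_config <- function(br = "BR3", age = 122, rate_sigma = 0.2, seed = 1,
                         chron = default_chronogram()) {
  synthetic_config(wgd_branch = br, wgd_age = age, loss_rate = 0,
                   sampling_prob = 1, rate_sigma = rate_sigma,
                   support_model = support_clean(), chronogram = chron,
                   seed = seed)
}

# small chronogram (one exemplar per lineage) with 117 mid-branch on BR3
chron117 <- function() {
  default_chronogram(core_eudicot = 112, rosid_asterid = 109,
                     exemplars_per_lineage = 1)
}

# random gene tree over the default panel with >= 2 focal genes, random
# integer supports (some missing), for oracle-equivalence checks
random_gene_tree <- function(ntips = 10) {
  species_pool <- c("Amborella trichopoda", "Nuphar advena",
                    "Persea americana", "Acorus americanus",
                    "Typha angustifolia", "Eschscholzia californica",
                    "Aquilegia formosa", "Beta vulgaris",
                    "Solanum tuberosum", "Helianthus annuus",
                    "Vitis vinifera", "Populus trichocarpa")
  nv <- sample(2:3, 1)
  sp <- c(rep("Vitis vinifera", nv),
          sample(species_pool, ntips - nv, replace = TRUE))
  phy <- ape::rtree(ntips)
  phy$tip.label <- paste0(gsub(" ", "_", sp), "|g", seq_len(ntips))
  sup <- sample(c(NA, 0:100), phy$Nnode, replace = TRUE,
                prob = c(0.15, rep(0.85 / 101, 101)))
  phy$node.label <- ifelse(is.na(sup), "", as.character(sup))
  gene_tree_from_phylo(phy)
}
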