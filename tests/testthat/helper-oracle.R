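# Independent brute-force oracles.

# ---- literal-rule duplication classifier ------------------------------------
# Re-implements the support rule by exhaustive node enumeration using
# ape::prop.part clade sets (the package uses its own edge-postorder
# accumulation), following the textual rule step by step.

oracle_classify <- function(gt, gene_a, gene_b, panel, thr) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  lin <- vapply(gt$species, lineage_of, "", panel = panel, USE.NAMES = FALSE)
  # clade tip sets for internal nodes via prop.part
  pp <- ape::prop.part(phy)
  clade_tips <- function(node) {
    if (node <= ntip) return(node)
    pp[[node - ntip]]
  }
  sup_of <- function(node) {
    if (node <= ntip) return(100)
    gt$support[node - ntip]
  }
  ta <- which(gt$gene == gene_a | phy$tip.label == gene_a)
  tb <- which(gt$gene == gene_b | phy$tip.label == gene_b)
  stopifnot(length(ta) == 1, length(tb) == 1)
  # MRCA: smallest clade containing both tips
  allnodes <- (ntip + 1L):(ntip + phy$Nnode)
  containing <- allnodes[vapply(allnodes, function(v)
    all(c(ta, tb) %in% clade_tips(v)), logical(1))]
  mrca <- containing[which.min(lengths(lapply(containing, clade_tips)))]
  kids <- phy$edge[phy$edge[, 1] == mrca, 2]
  k2 <- kids[vapply(kids, function(k) ta %in% clade_tips(k), logical(1))]
  k3 <- kids[vapply(kids, function(k) tb %in% clade_tips(k), logical(1))]
  b1 <- if (length(kids) > 2) 0 else sup_of(mrca)
  b2 <- sup_of(k2); b3 <- sup_of(k3)
  ge <- function(x) !is.na(x) && x >= thr
  if (!(ge(b1) && (ge(b2) || ge(b3)))) return("unresolved")
  dup_tips <- c(clade_tips(k2), clade_tips(k3))
  # lineage certified inside a duplicate clade: enumerate every node of the
  # tree; a node certifies if it lies within the clade, has support >= thr,
  # and subtends the lineage together with a rosid leaf
  inside_ok <- function(L) {
    for (cl in c(k2, k3)) {
      ct <- clade_tips(cl)
      for (v in allnodes) {
        vt <- clade_tips(v)
        if (!all(vt %in% ct)) next
        if (!ge(sup_of(v))) next
        if (any(lin[vt] == L) && any(lin[vt] == "rosid")) return(TRUE)
      }
    }
    FALSE
  }
  # lineage certified sister: enumerate ancestors of the MRCA; at the root
  # the certifying support is that of the root's child on the path
  parent_of <- function(v) phy$edge[phy$edge[, 2] == v, 1]
  sister_ok <- function(Ls) {
    path <- mrca
    while (path[length(path)] != root)
      path <- c(path, parent_of(path[length(path)]))
    for (i in seq_along(path)) {
      u <- path[i]
      s <- if (u == root) {
        if (i == 1) NA_real_ else sup_of(path[i - 1])
      } else sup_of(u)
      if (!ge(s)) next
      outside <- setdiff(clade_tips(u), dup_tips)
      if (any(lin[outside] %in% Ls)) return(TRUE)
    }
    FALSE
  }
  ins <- Filter(inside_ok, c("basal_angiosperm", "magnoliid", "monocot",
                             "basal_eudicot", "caryophyllid", "asterid"))
  if (length(ins)) {
    if (any(ins %in% c("basal_angiosperm", "magnoliid", "monocot"))) {
      if (sister_ok("basal_angiosperm")) return("BR1") else
        return("unresolved")
    }
    if (any(ins == "basal_eudicot")) {
      if (sister_ok("monocot")) return("BR2") else return("unresolved")
    }
    if (sister_ok("basal_eudicot")) return("BR3") else return("unresolved")
  }
  if (sister_ok(c("asterid", "caryophyllid"))) return("BR4")
  "unresolved"
}

# ---- penalized-likelihood objective + grid search ---------------------------
# Independent evaluation of the rate-smoothing objective; rates are profiled
# by an inner concave optimization at every age grid point.

oracle_pl_objective <- function(phy, ages, logrates, lambda, nsites) {
  x <- phy$edge.length * nsites
  r <- exp(logrates)
  t <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(t <= 0)) return(-Inf)
  L <- sum(ifelse(x > 0, x * log(r * t), 0) - r * t)
  root <- length(phy$tip.label) + 1L
  pen <- 0
  for (k in seq_len(nrow(phy$edge))) {
    p <- phy$edge[k, 1]
    if (p != root) {
      pe <- which(phy$edge[, 2] == p)
      pen <- pen + (r[k] - r[pe])^2
    }
  }
  pen <- pen + stats::var(r[phy$edge[, 1] == root])
  L - lambda * pen
}

# grid over the free internal-node ages of a 5-leaf tree with the root
# fixed; returns the best objective and ages found
oracle_pl_grid <- function(phy, root_age, lambda, nsites, steps = 12) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  internals <- setdiff((ntip + 1L):(ntip + phy$Nnode), root)
  E <- nrow(phy$edge)
  parent_node <- function(v) phy$edge[phy$edge[, 2] == v, 1]
  best <- list(obj = -Inf, ages = NULL)
  grid1 <- seq(0.04, 0.96, length.out = steps) * root_age
  combos <- do.call(expand.grid, rep(list(grid1), length(internals)))
  for (ci in seq_len(nrow(combos))) {
    ages <- numeric(ntip + phy$Nnode)
    ages[root] <- root_age
    ages[internals] <- as.numeric(combos[ci, ])
    ok <- all(ages[phy$edge[, 1]] > ages[phy$edge[, 2]])
    if (!ok) next
    fit <- stats::optim(rep(0, E), function(lr)
      -oracle_pl_objective(phy, ages, lr, lambda, nsites),
      method = "BFGS", control = list(maxit = 200))
    if (-fit$value > best$obj)
      best <- list(obj = -fit$value, ages = ages)
  }
  best
}
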