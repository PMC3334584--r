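# Support-based assignment of focal paralog-pair duplication nodes to the
# candidate scaffold branches BR1-BR4.
#
# For a pair (a, b), the duplication node is their MRCA; clade2 and clade3
# are its child subtrees holding a and b, bootstrap1/2/3 their supports. A
# duplication is scored at a threshold only when bootstrap1 and at least one
# of bootstrap2/bootstrap3 reach it. The branch is then bracketed from below
# by the deepest lineage certified *inside* the duplicate clades and from
# above by the next-deeper lineage certified *sister* to the duplication
# node.

# per-tree context: descendant tip sets, parents, lineages
.tree_ctx <- function(gt, panel, use_grasses = TRUE) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  sets <- .descendant_tip_sets(phy)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  lin <- tip_lineages(gt, panel)
  if (!use_grasses) {
    grass <- vapply(gt$species, is_grass, logical(1), panel = panel,
                    USE.NAMES = FALSE)
    lin[grass] <- NA_character_
  }
  list(gt = gt, phy = phy, ntip = ntip, sets = sets, parent = parent,
       root = root, lin = lin, rosid = which(!is.na(lin) & lin == "rosid"))
}

.find_tip <- function(gt, gene_id) {
  hits <- which(gt$gene == gene_id | gt$phy$tip.label == gene_id)
  if (!length(hits)) stop("gene not found in tree: '", gene_id, "'")
  if (length(hits) > 1) stop("ambiguous gene id in tree: '", gene_id, "'")
  hits
}

#' Locate the duplication node of a paralog pair
#'
#' The duplication node is the MRCA of the two genes; \code{clade2} and
#' \code{clade3} are its child subtrees separating them. For a
#' multifurcating MRCA the two children holding the duplicates are taken and
#' the remaining children are recorded as sister evidence (the implied
#' resolution carries zero support).
#'
#' @param gt rooted \code{gene_tree}.
#' @param gene_a,gene_b gene ids (or full tip labels) of the pair.
#' @return list with \code{node} (MRCA id), \code{clade2}, \code{clade3}
#'   (child node ids), \code{extra} (other children of a multifurcating
#'   MRCA), \code{tip_a}, \code{tip_b}, \code{multifurcating}.
#' @export
locate_duplication_node <- function(gt, gene_a, gene_b) {
  stopifnot(inherits(gt, "gene_tree"))
  ta <- .find_tip(gt, gene_a)
  tb <- .find_tip(gt, gene_b)
  if (ta == tb) stop("gene_a and gene_b resolve to the same leaf")
  phy <- gt$phy
  mrca <- ape::getMRCA(phy, c(ta, tb))
  kids <- phy$edge[phy$edge[, 1] == mrca, 2]
  sets <- .descendant_tip_sets(phy)
  in_kid <- function(tip) kids[vapply(kids, function(k)
    tip %in% sets[[k]], logical(1))]
  ka <- in_kid(ta); kb <- in_kid(tb)
  if (length(ka) != 1 || length(kb) != 1 || ka == kb)
    stop("internal error: duplicates not separated at their MRCA")
  list(node = mrca, clade2 = ka, clade3 = kb,
       extra = setdiff(kids, c(ka, kb)), tip_a = ta, tip_b = tb,
       multifurcating = length(kids) > 2)
}

#' Support triplet of a duplication node
#'
#' \code{bootstrap1} is the support of the node joining the duplicate clades
#' (zero for the implied resolution of a multifurcating MRCA),
#' \code{bootstrap2}/\code{bootstrap3} the supports of the clades holding
#' each duplicate (single leaves count as 100).
#'
#' @param gt \code{gene_tree}.
#' @param loc result of \code{\link{locate_duplication_node}}.
#' @return numeric vector \code{c(bootstrap1, bootstrap2, bootstrap3)}
#'   (\code{NA} = missing).
#' @export
support_triplet <- function(gt, loc) {
  b1 <- if (loc$multifurcating) 0 else node_support(gt, loc$node)
  c(bootstrap1 = b1,
    bootstrap2 = node_support(gt, loc$clade2),
    bootstrap3 = node_support(gt, loc$clade3))
}

#' Does a support triplet pass a bootstrap threshold?
#'
#' True iff bootstrap1 >= threshold and at least one of bootstrap2,
#' bootstrap3 >= threshold (boundary inclusive). Missing supports fail any
#' threshold.
#'
#' @param triplet numeric vector (bootstrap1, bootstrap2, bootstrap3).
#' @param threshold bootstrap percentage, typically 50 or 80.
#' @return logical.
#' @export
passes_support <- function(triplet, threshold) {
  ge <- function(x) !is.na(x) & x >= threshold
  ge(triplet[[1]]) && (ge(triplet[[2]]) || ge(triplet[[3]]))
}

# lineages certified inside one duplicate clade at `thr`:
# some node v of the clade (including its root) with support >= thr subtends
# >= 1 leaf of the lineage together with >= 1 rosid leaf. Returns named
# numeric vector lineage -> best certifying support.
.inside_certified <- function(ctx, clade_root, thr) {
  found <- numeric(0)
  for (v in .subtree_internal_nodes(ctx, clade_root)) {
    sup <- node_support(ctx$gt, v)
    if (is.na(sup) || sup < thr) next
    tips <- ctx$sets[[v]]
    if (!any(tips %in% ctx$rosid)) next
    for (L in unique(ctx$lin[tips])) {
      if (is.na(L) || L == "rosid") next
      if (is.na(found[L]) || sup > found[L]) found[L] <- sup
    }
  }
  found[!is.na(found)]
}

# internal nodes within the subtree rooted at `node`, including `node`
# itself when internal (a tip subtends nothing beyond itself)
.subtree_internal_nodes <- function(ctx, node) {
  if (node <= ctx$ntip) return(integer(0))
  tips <- ctx$sets[[node]]
  cand <- (ctx$ntip + 1L):(ctx$ntip + ctx$phy$Nnode)
  cand[vapply(cand, function(v) all(ctx$sets[[v]] %in% tips), logical(1))]
}

# lineages certified sister to the duplication node at `thr`: walking from
# the MRCA toward the root, an ancestor u whose bipartition support >= thr
# subtends a leaf of the lineage outside the two duplicate clades. At the
# root the certifying support is the bipartition entered from (the root's
# child on the path), since a rooted tree's root carries no bipartition of
# its own.
.sister_certified <- function(ctx, loc, thr) {
  dup_tips <- c(ctx$sets[[loc$clade2]], ctx$sets[[loc$clade3]])
  path <- loc$node
  u <- loc$node
  while (u != ctx$root) {
    u <- ctx$parent[u]
    path <- c(path, u)
  }
  found <- numeric(0)
  for (i in seq_along(path)) {
    u <- path[i]
    sup <- if (u == ctx$root) {
      if (i == 1) NA_real_ else node_support(ctx$gt, path[i - 1])
    } else {
      node_support(ctx$gt, u)
    }
    if (is.na(sup) || sup < thr) next
    outside <- setdiff(ctx$sets[[u]], dup_tips)
    for (L in unique(ctx$lin[outside])) {
      if (is.na(L) || L == "rosid") next
      if (is.na(found[L]) || sup > found[L]) found[L] <- sup
    }
  }
  found[!is.na(found)]
}

#' Classify the placement of one paralog pair at a single threshold
#'
#' Applies the support rule at one bootstrap threshold: the pair must pass
#' \code{\link{passes_support}}; the deepest lineage certified inside the
#' duplicate clades sets the candidate branch (monocot or deeper: BR1; basal
#' eudicot: BR2; asterid/caryophyllid: BR3; rosids only with an
#' asterid/caryophyllid certified sister: BR4); the corresponding sister
#' witness (basal angiosperm for BR1, monocot for BR2, basal eudicot for
#' BR3) must also be certified, else the call is unresolved.
#'
#' @param gt rooted \code{gene_tree}.
#' @param gene_a,gene_b the focal paralog pair (gene ids).
#' @param panel \code{lineage_panel}.
#' @param threshold bootstrap threshold (typically 50 or 80).
#' @param use_grasses if \code{FALSE}, grass monocots are ignored as
#'   evidence.
#' @return list with \code{placement} (\code{"BR1"}..\code{"BR4"} or
#'   \code{"unresolved"}), \code{triplet}, \code{inside} and \code{sister}
#'   evidence (named support vectors), \code{threshold}.
#' @export
classify_placement <- function(gt, gene_a, gene_b, panel, threshold,
                               use_grasses = TRUE) {
  loc <- locate_duplication_node(gt, gene_a, gene_b)
  ctx <- .tree_ctx(gt, panel, use_grasses = use_grasses)
  for (tp in c(loc$tip_a, loc$tip_b)) {
    if (is.na(ctx$lin[tp]) || ctx$lin[tp] != "rosid")
      stop("paralog pair gene is not from the focal (rosid) lineage: ",
           gt$phy$tip.label[tp])
  }
  trip <- support_triplet(gt, loc)
  inside <- numeric(0); sister <- numeric(0)
  placement <- "unresolved"
  if (passes_support(trip, threshold)) {
    i2 <- .inside_certified(ctx, loc$clade2, threshold)
    i3 <- .inside_certified(ctx, loc$clade3, threshold)
    inside <- tapply(c(i2, i3), names(c(i2, i3)), max)
    inside <- if (length(inside)) {
      stats::setNames(as.numeric(inside), names(inside))
    } else numeric(0)
    sister <- .sister_certified(ctx, loc, threshold)
    sc <- function(L) any(names(sister) %in% L)
    if (length(inside)) {
      deepest <- min(.lineage_depth[names(inside)])
      if (deepest <= .lineage_depth[["monocot"]]) {
        if (sc("basal_angiosperm")) placement <- "BR1"
      } else if (deepest == .lineage_depth[["basal_eudicot"]]) {
        if (sc("monocot")) placement <- "BR2"
      } else {
        if (sc("basal_eudicot")) placement <- "BR3"
      }
    } else {
      if (sc(c("asterid", "caryophyllid"))) placement <- "BR4"
    }
  }
  list(placement = placement, triplet = trip, inside = inside,
       sister = sister, threshold = threshold, node = loc$node,
       multifurcating = loc$multifurcating)
}

#' Classify one paralog pair at both support tiers
#'
#' Produces a tiered duplication call: the placement is the 50\%-threshold
#' call; the tier is \code{ge80} when the 80\%-threshold call yields the
#' same branch, \code{ge50} when only the lower tier resolves, and
#' \code{none} when unresolved.
#'
#' @param gt rooted \code{gene_tree}.
#' @param orthogroup orthogroup id (carried through to reports).
#' @param gene_a,gene_b the focal pair.
#' @param panel \code{lineage_panel}.
#' @param thresholds ascending pair of thresholds, default \code{c(50, 80)}.
#' @param use_grasses see \code{\link{classify_placement}}.
#' @return object of class \code{duplication_call}.
#' @export
classify_pair <- function(gt, orthogroup, gene_a, gene_b, panel,
                          thresholds = c(50, 80), use_grasses = TRUE) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  lo <- classify_placement(gt, gene_a, gene_b, panel, thresholds[1],
                           use_grasses = use_grasses)
  hi <- classify_placement(gt, gene_a, gene_b, panel, thresholds[2],
                           use_grasses = use_grasses)
  placement <- lo$placement
  tier <- if (placement == "unresolved") {
    "none"
  } else if (hi$placement == placement) {
    "ge80"
  } else {
    "ge50"
  }
  structure(list(orthogroup = orthogroup, gene_a = gene_a, gene_b = gene_b,
                 node = lo$node,
                 triplet = lo$triplet, placement = placement, tier = tier,
                 inside = lo$inside, sister = lo$sister,
                 inside_hi = hi$inside, sister_hi = hi$sister,
                 thresholds = thresholds),
            class = "duplication_call")
}

#' @export
print.duplication_call <- function(x, ...) {
  cat(sprintf("<duplication_call> %s %s/%s -> %s (%s); bs=(%s)\n",
              x$orthogroup, x$gene_a, x$gene_b, x$placement, x$tier,
              paste(ifelse(is.na(x$triplet), "NA", x$triplet),
                    collapse = ",")))
  invisible(x)
}

#' Convert a list of duplication calls to a data.frame
#'
#' @param calls list of \code{duplication_call}.
#' @return data.frame, one row per call.
#' @export
calls_to_df <- function(calls) {
  if (!length(calls))
    return(data.frame(orthogroup = character(), gene_a = character(),
                      gene_b = character(), bootstrap1 = numeric(),
                      bootstrap2 = numeric(), bootstrap3 = numeric(),
                      placement = character(), tier = character(),
                      inside = character(), sister = character(),
                      stringsAsFactors = FALSE))
  ev <- function(v) if (length(v))
    paste(names(v), v, sep = ":", collapse = ",") else ""
  data.frame(
    orthogroup = vapply(calls, `[[`, "", "orthogroup"),
    gene_a = vapply(calls, `[[`, "", "gene_a"),
    gene_b = vapply(calls, `[[`, "", "gene_b"),
    bootstrap1 = vapply(calls, function(c) c$triplet[[1]], 0),
    bootstrap2 = vapply(calls, function(c) c$triplet[[2]], 0),
    bootstrap3 = vapply(calls, function(c) c$triplet[[3]], 0),
    placement = vapply(calls, `[[`, "", "placement"),
    tier = vapply(calls, `[[`, "", "tier"),
    inside = vapply(calls, function(c) ev(c$inside), ""),
    sister = vapply(calls, function(c) ev(c$sister), ""),
    stringsAsFactors = FALSE
  )
}

#' Deterministic half-up rounding
#'
#' Rounds halves away from zero (for positive values), as used for the
#' printed percentage tables; base \code{round} rounds halves to even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Summarize duplication calls per branch and tier
#'
#' Counts calls per candidate branch at each support tier; a \code{ge80}
#' call is counted in both its \code{ge80} and \code{ge50} columns.
#' Percentages are computed per tier over the BR1--BR4 total of that tier,
#' at one decimal.
#'
#' @param calls list of \code{duplication_call}, or \code{NULL} when
#'   \code{counts} is given.
#' @param counts optional list with numeric vectors \code{ge50} and
#'   \code{ge80}, each named BR1..BR4, to summarize printed counts directly.
#' @return data.frame with columns \code{branch}, \code{dup_ge80},
#'   \code{dup_ge50}, \code{pct_ge80}, \code{pct_ge50}; tier totals in
#'   attribute \code{totals}.
#' @export
summarize_calls <- function(calls = NULL, counts = NULL) {
  brs <- c("BR1", "BR2", "BR3", "BR4")
  if (is.null(counts)) {
    n50 <- n80 <- stats::setNames(numeric(4), brs)
    for (cl in calls) {
      if (cl$placement == "unresolved") next
      n50[cl$placement] <- n50[cl$placement] + 1
      if (cl$tier == "ge80") n80[cl$placement] <- n80[cl$placement] + 1
    }
  } else {
    n50 <- counts$ge50[brs]; n80 <- counts$ge80[brs]
  }
  t50 <- sum(n50); t80 <- sum(n80)
  pct <- function(n, tot) if (tot > 0) round_half_up(100 * n / tot, 1) else
    rep(0, length(n))
  out <- data.frame(branch = brs,
                    dup_ge80 = as.numeric(n80), dup_ge50 = as.numeric(n50),
                    pct_ge80 = pct(as.numeric(n80), t80),
                    pct_ge50 = pct(as.numeric(n50), t50),
                    stringsAsFactors = FALSE)
  attr(out, "totals") <- c(ge80 = t80, ge50 = t50)
  out
}

#' Headline share of pre-rosid/asterid placements
#'
#' The share of resolved duplications placed before the rosid-asterid split
#' and after the monocot-eudicot split, i.e. (BR2 + BR3) / (BR1..BR4 total)
#' at one tier, rounded half-up to an integer percentage.
#'
#' @param summary output of \code{\link{summarize_calls}}.
#' @param tier \code{"ge50"} or \code{"ge80"}.
#' @return integer percentage.
#' @export
headline_share <- function(summary, tier = "ge50") {
  col <- paste0("dup_", tier)
  tot <- attr(summary, "totals")[[tier]]
  if (tot == 0) return(0)
  n <- sum(summary[[col]][summary$branch %in% c("BR2", "BR3")])
  round_half_up(100 * n / tot, 0)
}
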