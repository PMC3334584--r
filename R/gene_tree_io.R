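# Reading, writing and rooting gene trees; paralog pair lists; the
# per-sequence alignment-coverage filter.

#' Read a gene tree from newick text
#'
#' Internal node labels are interpreted as bootstrap supports (integers
#' 0--100; missing labels record as \code{NA}). Leaf labels are split into
#' (species, gene id) at the first occurrence of \code{delim}; a label with
#' no delimiter is used as both. Branch lengths, when present, must be finite
#' and non-negative.
#'
#' @param newick_text newick string (one tree).
#' @param delim delimiter between species and gene id in leaf labels.
#' @return An object of class \code{gene_tree}: list with \code{phy}
#'   (ape \code{phylo}), \code{species}, \code{gene} (per-tip character
#'   vectors), \code{support} (numeric per internal node, \code{NA} =
#'   missing).
#' @export
read_gene_tree <- function(newick_text, delim = "|") {
  stopifnot(is.character(newick_text), length(newick_text) == 1)
  txt <- gsub("\r", "", newick_text)
  .check_newick_balance(txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("newick parse error in: ", substr(txt, 1, 60))
  gene_tree_from_phylo(phy, delim = delim)
}

# balanced-parenthesis scan giving a character offset on failure
.check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth,
         " unclosed '(' by character ", length(chars))
  invisible(TRUE)
}

#' Construct a gene_tree from an ape phylo object
#'
#' @param phy rooted or unrooted \code{phylo}; node labels are bootstrap
#'   supports.
#' @param delim species/gene delimiter in tip labels.
#' @return \code{gene_tree}.
#' @export
gene_tree_from_phylo <- function(phy, delim = "|") {
  labs <- phy$tip.label
  pos <- regexpr(delim, labs, fixed = TRUE)
  species <- ifelse(pos > 0, substr(labs, 1, pos - 1), labs)
  gene <- ifelse(pos > 0, substr(labs, pos + nchar(delim), nchar(labs)), labs)
  support <- .parse_supports(phy$node.label, phy$Nnode)
  if (!is.null(phy$edge.length)) {
    if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
      stop("branch lengths must be finite and non-negative")
  }
  structure(list(phy = phy, species = species, gene = gene,
                 support = support, delim = delim),
            class = "gene_tree")
}

.parse_supports <- function(node.label, nnode) {
  if (is.null(node.label)) return(rep(NA_real_, nnode))
  lab <- trimws(node.label)
  sup <- rep(NA_real_, nnode)
  has <- nzchar(lab) & !is.na(lab) & tolower(lab) != "root"
  if (any(has)) {
    val <- suppressWarnings(as.numeric(lab[has]))
    if (any(is.na(val)))
      stop("non-numeric bootstrap support label(s): ",
           paste(unique(lab[has][is.na(val)]), collapse = ", "))
    if (any(val < 0 | val > 100))
      stop("bootstrap supports must lie in [0, 100]")
    if (any(abs(val - round(val)) > 1e-9))
      stop("bootstrap supports must be integers")
    sup[has] <- round(val)
  }
  sup
}

#' Write a gene tree to newick text
#'
#' Supports are written as internal node labels; missing supports are written
#' as empty labels.
#'
#' @param gt \code{gene_tree}.
#' @return newick string.
#' @export
write_gene_tree <- function(gt) {
  stopifnot(inherits(gt, "gene_tree"))
  phy <- gt$phy
  phy$node.label <- ifelse(is.na(gt$support), "", as.character(gt$support))
  ape::write.tree(phy)
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree>", length(x$phy$tip.label), "tips,",
      sum(!is.na(x$support)), "supported nodes\n")
  invisible(x)
}

#' Number of tips of a gene tree
#' @param gt \code{gene_tree}.
#' @return integer.
#' @export
n_tips <- function(gt) length(gt$phy$tip.label)

#' Effective support of a node
#'
#' Internal nodes return their bootstrap label (\code{NA} if missing); tips
#' count as trivially supported clades (support 100).
#'
#' @param gt \code{gene_tree}.
#' @param node node id (ape numbering: tips 1..n, internals n+1..).
#' @return numeric support.
#' @export
node_support <- function(gt, node) {
  ntip <- n_tips(gt)
  ifelse(node <= ntip, 100, gt$support[node - ntip])
}

#' Lineage of every tip
#'
#' @param gt \code{gene_tree}.
#' @param panel \code{lineage_panel}.
#' @return character vector of lineages, one per tip.
#' @export
tip_lineages <- function(gt, panel) {
  vapply(gt$species, lineage_of, "", panel = panel, USE.NAMES = FALSE)
}

#' Root a gene tree on its phylogenetically deepest lineage
#'
#' Roots on the leaves of the deepest lineage present, in priority order
#' basal angiosperm > magnoliid > monocot > basal eudicot. If those leaves
#' are not monophyletic in the unrooted tree, the largest subset that forms a
#' clade is used. Bootstrap supports stay attached to the bipartitions they
#' annotate.
#'
#' @param gt \code{gene_tree}.
#' @param panel \code{lineage_panel}.
#' @param scaffold \code{species_scaffold} (reserved for non-default
#'   focal lineages; the default priority order is scaffold-implied).
#' @return rooted \code{gene_tree}.
#' @export
root_by_deepest_outgroup <- function(gt, panel,
                                     scaffold = build_default_scaffold()) {
  stopifnot(inherits(gt, "gene_tree"))
  lin <- tip_lineages(gt, panel)
  for (target in c("basal_angiosperm", "magnoliid", "monocot",
                   "basal_eudicot")) {
    if (any(lin == target)) {
      out_tips <- which(lin == target)
      grp <- .largest_outgroup_clade(gt$phy, out_tips)
      phy2 <- ape::root(gt$phy, outgroup = grp, resolve.root = TRUE,
                        edgelabel = TRUE)
      return(gene_tree_from_phylo(phy2, delim = gt$delim))
    }
  }
  stop("no outgroup: all leaves are core eudicots")
}

# largest subset of `tips` forming a clade of the unrooted tree (tip indices)
.largest_outgroup_clade <- function(phy, tips) {
  ntip <- length(phy$tip.label)
  if (length(tips) == 1) return(phy$tip.label[tips])
  uphy <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  desc <- .descendant_tip_sets(uphy)
  target <- logical(ntip); target[tips] <- TRUE
  best <- tips[1]
  # each node's descendant set, and its complement, is one side of an edge
  for (s in desc) {
    for (side in list(s, setdiff(seq_len(ntip), s))) {
      if (length(side) > length(best) && all(target[side]) &&
          length(side) <= length(tips))
        best <- side
    }
  }
  phy$tip.label[best]
}

# list over all nodes (tips + internals) of descendant tip index sets
.descendant_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Filter aligned sequences by coverage
#'
#' Retains sequences whose non-gap character count is at least
#' \code{min_fraction} of the alignment length (boundary inclusive: a
#' sequence covering exactly the threshold is kept; only sequences covering
#' less are removed). Gap characters are \code{-} and \code{.}.
#'
#' @param alignment named character vector of equal-length aligned sequences.
#' @param min_fraction minimum retained coverage (default 0.70).
#' @return character vector of retained sequence names.
#' @export
filter_alignment_coverage <- function(alignment, min_fraction = 0.70) {
  if (!length(alignment)) return(character())
  if (is.null(names(alignment)))
    names(alignment) <- paste0("seq", seq_along(alignment))
  len <- unique(nchar(alignment))
  if (length(len) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(nchar(alignment))), collapse = ", "))
  nongap <- vapply(alignment,
                   function(s) len - lengths(regmatches(
                     s, gregexpr("[-.]", s))),
                   numeric(1))
  names(alignment)[nongap >= min_fraction * len]
}

#' Read a paralog-pair list
#'
#' Tab-separated rows: orthogroup id, gene id A, gene id B, optional source
#' (\code{syntenic_block} or \code{other}). Duplicate unordered pairs within
#' an orthogroup are collapsed with a warning giving the count. CRLF and a
#' header row (first field \code{orthogroup}) are tolerated.
#'
#' @param file path to a TSV file (alternative to \code{text}).
#' @param text TSV content as a single string.
#' @return data.frame with columns \code{orthogroup}, \code{gene_a},
#'   \code{gene_b}, \code{source}, preserving input order.
#' @export
read_pairs <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("^orthogroup\\b", tolower(lines[1]))) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  if (!length(lines))
    return(data.frame(orthogroup = character(), gene_a = character(),
                      gene_b = character(), source = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop("pair list line ", lineno[which(nf < 3)[1]],
         ": expected >= 3 tab-separated fields, found ", nf[which(nf < 3)[1]])
  df <- data.frame(
    orthogroup = vapply(parts, function(p) trimws(p[1]), ""),
    gene_a = vapply(parts, function(p) trimws(p[2]), ""),
    gene_b = vapply(parts, function(p) trimws(p[3]), ""),
    source = vapply(parts, function(p)
      if (length(p) >= 4 && nzchar(trimws(p[4]))) trimws(p[4]) else "other",
      ""),
    stringsAsFactors = FALSE
  )
  if (any(df$gene_a == df$gene_b))
    stop("pair list line ", lineno[which(df$gene_a == df$gene_b)[1]],
         ": gene_a equals gene_b")
  key <- paste(df$orthogroup,
               pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b),
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) collapsed")
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
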