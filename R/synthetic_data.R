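# Synthetic orthogroup generator: gene trees spanning the lineage panel with
# a whole-genome duplication seeded on a chosen scaffold branch, plus
# per-branch rate heterogeneity, gene loss, species dropout and bootstrap
# noise. Every downstream stage of the pipeline is testable against the
# recorded truth.

#' Default lineage-level chronogram
#'
#' A dated exemplar species tree over the seven lineages. Anchor ages
#' (million years ago, all configurable): angiosperm crown (root) 160,
#' magnoliid split 155, monocot-eudicot split 150, eudicot crown 125, core
#' eudicot crown 120, rosid-asterid split 118. Within-lineage crowns are
#' fixed shallow defaults. Exemplar species are drawn from the default
#' lineage panel.
#'
#' @param root,magnoliid_split,monocot_split,eudicot_crown,core_eudicot,rosid_asterid
#'   anchor node ages in mya (must decrease in this order).
#' @param exemplars_per_lineage 1, 2 or 3 exemplar species per lineage
#'   (rosids always include the focal species first).
#' @param focal_species focal genome (a rosid).
#' @return object of class \code{chronogram}.
#' @export
default_chronogram <- function(root = 160, magnoliid_split = 155,
                               monocot_split = 150, eudicot_crown = 125,
                               core_eudicot = 120, rosid_asterid = 118,
                               exemplars_per_lineage = 2,
                               focal_species = "Vitis vinifera") {
  ages <- c(root = root, magnoliid_split = magnoliid_split,
            monocot_split = monocot_split, eudicot_crown = eudicot_crown,
            core_eudicot = core_eudicot, rosid_asterid = rosid_asterid)
  if (any(diff(ages) >= 0))
    stop("chronogram anchor ages must strictly decrease from root to ",
         "rosid-asterid split")
  ex <- list(
    basal_angiosperm = c("Amborella trichopoda", "Nuphar advena"),
    magnoliid = c("Persea americana", "Liriodendron tulipifera"),
    monocot = c("Acorus americanus", "Typha angustifolia"),
    basal_eudicot = c("Eschscholzia californica", "Aquilegia formosa"),
    caryophyllid = c("Beta vulgaris", "Mesembryanthemum crystallinum"),
    asterid = c("Solanum tuberosum", "Helianthus annuus"),
    rosid = c(focal_species, "Populus trichocarpa", "Arabidopsis thaliana")
  )
  k <- exemplars_per_lineage
  stopifnot(k >= 1, k <= 3)
  ex <- lapply(ex, function(s) s[seq_len(min(k, length(s)))])
  crowns <- c(basal_angiosperm = 130, magnoliid = 100, monocot = 110,
              basal_eudicot = 100, caryophyllid = 60, asterid = 90,
              rosid = min(110, rosid_asterid - 5))
  clade <- function(lin) .ladder_clade(ex[[lin]], lin, crowns[[lin]])
  node <- function(age, children) list(age = age, children = children)
  tree <- node(root, list(
    clade("basal_angiosperm"),
    node(magnoliid_split, list(
      clade("magnoliid"),
      node(monocot_split, list(
        clade("monocot"),
        node(eudicot_crown, list(
          clade("basal_eudicot"),
          node(core_eudicot, list(
            clade("caryophyllid"),
            node(rosid_asterid, list(
              clade("asterid"),
              clade("rosid")
            ))
          ))
        ))
      ))
    ))
  ))
  structure(list(root = tree, ages = ages, exemplars = ex,
                 focal_species = focal_species),
            class = "chronogram")
}

# pectinate clade over exemplar species with evenly shrinking split ages
.ladder_clade <- function(species, lineage, crown) {
  tip <- function(sp) list(age = 0, species = sp, lineage = lineage,
                           children = NULL)
  if (length(species) == 1) return(tip(species))
  node <- tip(species[length(species)])
  depth_ages <- crown * 0.65^(seq_len(length(species) - 1) - 1)
  for (i in rev(seq_len(length(species) - 1)))
    node <- list(age = depth_ages[i],
                 children = list(tip(species[i]), node))
  node
}

#' @export
print.chronogram <- function(x, ...) {
  cat("<chronogram> root", x$ages[["root"]], "mya;",
      sum(lengths(x$exemplars)), "exemplar species\n")
  invisible(x)
}

# lineage set subtended by a node
.node_lineages <- function(node) {
  if (is.null(node$children)) return(node$lineage)
  sort(unique(unlist(lapply(node$children, .node_lineages))))
}

# age span (child_age, parent_age) of the scaffold branch `br` on the
# chronogram; also returns a path locator to the subtended node
.branch_span <- function(chron, br, scaffold = build_default_scaffold()) {
  taxa <- sort(branch_taxa(scaffold, br))
  find <- function(node, parent_age, path) {
    if (identical(.node_lineages(node), taxa))
      return(list(child_age = node$age, parent_age = parent_age,
                  path = path))
    if (is.null(node$children)) return(NULL)
    for (i in seq_along(node$children)) {
      hit <- find(node$children[[i]], node$age, c(path, i))
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  hit <- find(chron$root, Inf, integer(0))
  if (is.null(hit)) stop("branch ", br, " not found on chronogram")
  hit
}

#' Age span of a candidate duplication branch
#'
#' @param chron \code{chronogram}.
#' @param br \code{"BR1"}..\code{"BR4"}.
#' @return numeric vector \code{c(lower, upper)} in mya.
#' @export
branch_age_span <- function(chron, br) {
  hit <- .branch_span(chron, br)
  c(lower = hit$child_age, upper = hit$parent_age)
}

#' Clean and noisy bootstrap-support models
#'
#' \code{support_clean} assigns every internal node support 100.
#' \code{support_noisy} assigns \code{round(100 * plogis(slope * (duration -
#' midpoint)))} plus bounded uniform integer noise, clamped to [0, 100]:
#' short branches (rapid radiations) receive low support.
#'
#' @param slope logistic slope per my.
#' @param midpoint branch duration (my) with expected support 50.
#' @param noise half-width of the uniform integer noise.
#' @return support model object.
#' @export
support_clean <- function() {
  structure(list(type = "clean"), class = "support_model")
}

#' @rdname support_clean
#' @export
support_noisy <- function(slope = 1.5, midpoint = 1, noise = 5) {
  structure(list(type = "noisy", slope = slope, midpoint = midpoint,
                 noise = noise), class = "support_model")
}

.draw_support <- function(model, duration) {
  if (model$type == "clean") return(100)
  base <- round(100 * stats::plogis(model$slope * (duration - model$midpoint)))
  s <- base + sample.int(2 * model$noise + 1, 1) - model$noise - 1
  max(0, min(100, s))
}

#' Configuration for the synthetic orthogroup generator
#'
#' Defaults emulate the study conditions: a duplication seeded on the core
#' eudicot stem (BR3), two retained copies, moderate post-duplication gene
#' loss, incomplete transcriptome sampling, and lognormal among-branch rate
#' heterogeneity around a typical angiosperm nuclear substitution rate.
#'
#' @param wgd_branch \code{"BR1"}..\code{"BR4"} or \code{"none"}.
#' @param wgd_age duplication age in mya; must lie within the age span of
#'   \code{wgd_branch} on \code{chronogram}.
#' @param duplicate_multiplicity 2 (duplication) or 3 (triplication).
#' @param loss_rate per-lineage per-my exponential loss hazard applied to
#'   post-duplication extra copies.
#' @param sampling_prob per-species presence probability (the focal species
#'   is always sampled).
#' @param rate_base substitutions/site/my.
#' @param rate_sigma stdev of lognormal per-branch rate multipliers
#'   (mean-one parameterization).
#' @param support_model \code{\link{support_clean}()} or
#'   \code{\link{support_noisy}()}.
#' @param chronogram dated species tree, see
#'   \code{\link{default_chronogram}}.
#' @param seed integer seed used by \code{\link{simulate_cohort}}.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(wgd_branch = "BR3", wgd_age = 122,
                             duplicate_multiplicity = 2, loss_rate = 0.008,
                             sampling_prob = 0.8, rate_base = 0.002,
                             rate_sigma = 0.2,
                             support_model = support_clean(),
                             chronogram = default_chronogram(),
                             seed = 1L) {
  stopifnot(wgd_branch %in% c("BR1", "BR2", "BR3", "BR4", "none"),
            duplicate_multiplicity %in% c(2, 3),
            loss_rate >= 0, sampling_prob >= 0, sampling_prob <= 1,
            rate_base > 0, rate_sigma >= 0,
            inherits(support_model, "support_model"),
            inherits(chronogram, "chronogram"))
  if (wgd_branch != "none") {
    span <- branch_age_span(chronogram, wgd_branch)
    if (wgd_age <= span[["lower"]] || wgd_age >= span[["upper"]])
      stop("wgd_age ", wgd_age, " outside the ", wgd_branch, " span (",
           span[["lower"]], ", ", span[["upper"]], ") of the chronogram")
    p_pair <- 1 - (1 - exp(-loss_rate * wgd_age))^(duplicate_multiplicity - 1)
    if (p_pair < 1e-4)
      stop("infeasible config: focal pair retention probability ",
           signif(p_pair, 3), " < 1e-4")
  }
  structure(list(wgd_branch = wgd_branch, wgd_age = wgd_age,
                 duplicate_multiplicity = duplicate_multiplicity,
                 loss_rate = loss_rate, sampling_prob = sampling_prob,
                 rate_base = rate_base, rate_sigma = rate_sigma,
                 support_model = support_model, chronogram = chronogram,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deep-copy a subtree assigning copy numbers to tips
.assign_copy <- function(node, copy) {
  node$copy <- copy
  if (!is.null(node$children))
    node$children <- lapply(node$children, .assign_copy, copy = copy)
  node
}

# graft the WGD node onto the chronogram at `path` (child indices from root)
.graft_wgd <- function(root, path, wgd_age, multiplicity) {
  splice <- function(node, depth) {
    if (depth > length(path)) {
      copies <- lapply(seq_len(multiplicity), function(m)
        .assign_copy(node, m))
      return(list(age = wgd_age, children = copies, wgd = TRUE))
    }
    i <- path[depth]
    node$children[[i]] <- splice(node$children[[i]], depth + 1)
    node
  }
  splice(root, 1)
}

# drop tips failing `keep(tip)`; splice unary nodes; NULL when empty
.prune <- function(node, keep) {
  if (is.null(node$children)) {
    if (keep(node)) return(node) else return(NULL)
  }
  kids <- Filter(Negate(is.null), lapply(node$children, .prune, keep = keep))
  if (!length(kids)) return(NULL)
  if (length(kids) == 1) return(kids[[1]])
  node$children <- kids
  node
}

.collect_tips <- function(node) {
  if (is.null(node$children)) return(list(node))
  do.call(c, lapply(node$children, .collect_tips))
}

# serialize to newick with drawn branch rates and supports; gene ids are
# <SpeciesCode><og>.<copy>
.serialize_gene_tree <- function(root, config, orthogroup) {
  code <- function(sp) {
    w <- strsplit(sp, " ", fixed = TRUE)[[1]]
    paste0(toupper(substr(w[1], 1, 1)),
           if (length(w) > 1) substr(w[2], 1, 1) else "x")
  }
  edge_len <- function(duration) {
    mult <- if (config$rate_sigma > 0)
      exp(stats::rnorm(1, -config$rate_sigma^2 / 2, config$rate_sigma))
    else 1
    duration * config$rate_base * mult
  }
  rec <- function(node, parent_age) {
    dur <- parent_age - node$age
    if (is.null(node$children)) {
      cp <- if (is.null(node$copy)) 0L else node$copy
      lab <- paste0(gsub(" ", "_", node$species), "|",
                    code(node$species), orthogroup, ".", cp)
      return(sprintf("%s:%.8f", lab, edge_len(dur)))
    }
    inner <- paste(vapply(node$children, rec, "", parent_age = node$age),
                   collapse = ",")
    sup <- .draw_support(config$support_model, dur)
    if (is.finite(dur)) {
      sprintf("(%s)%d:%.8f", inner, sup, edge_len(dur))
    } else {
      sprintf("(%s);", inner)
    }
  }
  rec(root, Inf)
}

#' Simulate one orthogroup gene tree with a seeded duplication
#'
#' Clones the chronogram clade below the duplication point into
#' \code{duplicate_multiplicity} copies at \code{wgd_age}; one copy per
#' species is protected and each extra copy survives the exponential loss
#' hazard with probability \code{exp(-loss_rate * wgd_age)}; species outside
#' the focal genome are sampled with \code{sampling_prob}; branch durations
#' are converted to substitutions/site with mean-one lognormal rate
#' multipliers around \code{rate_base}; supports follow the support model.
#' Simulation is resampled until the focal species retains at least two
#' copies, mirroring conditioning on syntenic focal pairs.
#'
#' @param config \code{\link{synthetic_config}}.
#' @param orthogroup orthogroup id used in gene names.
#' @return list with \code{tree} (\code{gene_tree}), \code{pair}
#'   (orthogroup, gene_a, gene_b), \code{truth} (branch, age, retained and
#'   lost gene counts).
#' @export
simulate_orthogroup <- function(config, orthogroup = "0001") {
  stopifnot(inherits(config, "synthetic_config"))
  chron <- config$chronogram
  focal <- normalize_species(chron$focal_species)
  if (config$wgd_branch == "none") {
    root <- chron$root
  } else {
    hit <- .branch_span(chron, config$wgd_branch)
    if (config$wgd_age <= hit$child_age || config$wgd_age >= hit$parent_age)
      stop("wgd_age outside branch span")
    root <- .graft_wgd(chron$root, hit$path, config$wgd_age,
                       config$duplicate_multiplicity)
  }
  all_tips <- .collect_tips(root)
  species <- vapply(all_tips, `[[`, "", "species")
  p_keep <- exp(-config$loss_rate * config$wgd_age)
  for (attempt in seq_len(1000)) {
    # gene loss: copies > 1 face the exponential hazard
    lost <- vapply(all_tips, function(tp) {
      cp <- if (is.null(tp$copy)) 0L else tp$copy
      cp > 1 && stats::runif(1) > p_keep
    }, logical(1))
    # species dropout (never the focal species)
    sampled_sp <- unique(species)
    present <- stats::runif(length(sampled_sp)) <= config$sampling_prob
    present[normalize_species(sampled_sp) == focal] <- TRUE
    sp_ok <- stats::setNames(present, sampled_sp)
    keep_tip <- !lost & sp_ok[species]
    focal_kept <- sum(keep_tip & normalize_species(species) == focal)
    if (config$wgd_branch == "none" || focal_kept >= 2) break
    if (attempt == 1000)
      stop("could not retain a focal pair in 1000 attempts")
  }
  idx <- 0L
  keeper <- function(tp) {
    idx <<- idx + 1L
    keep_tip[idx]
  }
  pruned <- .prune(root, keeper)
  if (is.null(pruned) || is.null(pruned$children))
    stop("simulation lost all informative tips")
  nwk <- .serialize_gene_tree(pruned, config, orthogroup)
  gt <- read_gene_tree(nwk)
  focal_genes <- gt$gene[normalize_species(gt$species) == focal]
  focal_genes <- sort(focal_genes)
  pair <- if (config$wgd_branch != "none" && length(focal_genes) >= 2) {
    data.frame(orthogroup = orthogroup, gene_a = focal_genes[1],
               gene_b = focal_genes[2], source = "syntenic_block",
               stringsAsFactors = FALSE)
  } else {
    NULL
  }
  truth <- data.frame(
    orthogroup = orthogroup,
    branch = config$wgd_branch,
    age = if (config$wgd_branch == "none") NA_real_ else config$wgd_age,
    n_tips = length(gt$phy$tip.label),
    n_lost = sum(lost),
    stringsAsFactors = FALSE
  )
  list(tree = gt, pair = pair, truth = truth)
}

#' Simulate a cohort of orthogroups
#'
#' @param config \code{\link{synthetic_config}}; \code{config$seed} makes
#'   the cohort reproducible.
#' @param n_orthogroups number of independent orthogroups (>= 1).
#' @return list with \code{trees} (named list of \code{gene_tree}),
#'   \code{pairs} (data.frame), \code{truth} (data.frame).
#' @export
simulate_cohort <- function(config, n_orthogroups) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_orthogroups < 1) stop("n_orthogroups must be >= 1")
  set.seed(config$seed)
  ids <- sprintf("%04d", seq_len(n_orthogroups))
  sims <- lapply(ids, function(id) simulate_orthogroup(config, id))
  trees <- stats::setNames(lapply(sims, `[[`, "tree"), ids)
  pairs <- do.call(rbind, Filter(Negate(is.null), lapply(sims, `[[`, "pair")))
  if (is.null(pairs))
    pairs <- data.frame(orthogroup = character(), gene_a = character(),
                        gene_b = character(), source = character(),
                        stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  rownames(pairs) <- rownames(truth) <- NULL
  list(trees = trees, pairs = pairs, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes one newick file per orthogroup plus \code{pairs.tsv} and
#' \code{truth.tsv}.
#'
#' @param cohort output of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$trees))
    writeLines(write_gene_tree(cohort$trees[[id]]),
               file.path(dir, paste0("OG", id, ".nwk")))
  utils::write.table(cohort$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
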