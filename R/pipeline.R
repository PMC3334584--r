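# Orchestration: classify -> date -> mixture (ages) and ks -> mixture (Ks),
# with per-record logging and tab-separated reports.

#' Load a directory of gene trees
#'
#' Reads every \code{.nwk}/\code{.newick}/\code{.tre} file; the orthogroup
#' id is the file name without extension (a leading \code{OG} is stripped
#' for matching pair lists).
#'
#' @param dir directory of newick files.
#' @param delim leaf-label delimiter.
#' @return named list of \code{gene_tree}.
#' @export
load_gene_trees <- function(dir, delim = "|") {
  files <- list.files(dir, pattern = "\\.(nwk|newick|tre)$",
                      full.names = TRUE)
  trees <- list()
  for (f in files) {
    id <- sub("^OG", "", sub("\\.[^.]+$", "", basename(f)))
    trees[[id]] <- read_gene_tree(paste(readLines(f, warn = FALSE),
                                        collapse = ""), delim = delim)
  }
  trees
}

.tree_for <- function(trees, orthogroup) {
  if (!is.null(trees[[orthogroup]])) return(trees[[orthogroup]])
  alt <- sub("^OG", "", orthogroup)
  if (!is.null(trees[[alt]])) return(trees[[alt]])
  NULL
}

#' Classify every paralog pair of a cohort
#'
#' Roots each tree on its deepest outgroup lineage, classifies each pair at
#' both support tiers, and summarizes per branch. Per-tree failures are
#' logged, not fatal; every input pair appears exactly once across the
#' classified and failed records.
#'
#' @param trees named list of \code{gene_tree} (keys are orthogroup ids).
#' @param pairs data.frame from \code{\link{read_pairs}} (or
#'   \code{\link{simulate_cohort}}).
#' @param panel \code{lineage_panel}.
#' @param thresholds ascending support tiers, default \code{c(50, 80)}.
#' @param use_grasses include grass monocots as evidence.
#' @param out_dir optional directory for \code{calls.tsv},
#'   \code{summary.tsv}, \code{log.tsv}.
#' @return list: \code{calls} (list of \code{duplication_call}),
#'   \code{calls_df}, \code{summary} (\code{\link{summarize_calls}}),
#'   \code{headline} (pre-rosid/asterid share per tier), \code{rooted_trees}
#'   (for downstream dating), \code{log} (status per pair).
#' @export
run_placement_pipeline <- function(trees, pairs, panel,
                                   thresholds = c(50, 80),
                                   use_grasses = TRUE, out_dir = NULL) {
  calls <- list()
  rooted <- list()
  log <- list()
  note <- function(og, pair, status, reason = "") {
    log[[length(log) + 1]] <<- data.frame(
      orthogroup = og, pair = pair, status = status, reason = reason,
      stringsAsFactors = FALSE)
  }
  if (!nrow(pairs)) {
    warning("empty pair list: nothing to classify")
  }
  for (i in seq_len(nrow(pairs))) {
    og <- pairs$orthogroup[i]
    pid <- paste(pairs$gene_a[i], pairs$gene_b[i], sep = "~")
    gt <- .tree_for(trees, og)
    if (is.null(gt)) {
      note(og, pid, "skipped", "no tree for orthogroup")
      next
    }
    key <- sub("^OG", "", og)
    if (is.null(rooted[[key]])) {
      rt <- tryCatch(root_by_deepest_outgroup(gt, panel),
                     error = function(e) conditionMessage(e))
      if (is.character(rt)) {
        note(og, pid, "failed", paste("rooting:", rt))
        next
      }
      rooted[[key]] <- rt
    }
    cl <- tryCatch(
      classify_pair(rooted[[key]], og, pairs$gene_a[i], pairs$gene_b[i],
                    panel, thresholds = thresholds,
                    use_grasses = use_grasses),
      error = function(e) conditionMessage(e))
    if (is.character(cl)) {
      note(og, pid, "failed", paste("classification:", cl))
      next
    }
    calls[[length(calls) + 1]] <- cl
    note(og, pid, "classified")
  }
  summary <- summarize_calls(calls)
  headline <- c(ge50 = headline_share(summary, "ge50"),
                ge80 = headline_share(summary, "ge80"))
  logdf <- if (length(log)) do.call(rbind, log) else
    data.frame(orthogroup = character(), pair = character(),
               status = character(), reason = character(),
               stringsAsFactors = FALSE)
  out <- list(calls = calls, calls_df = calls_to_df(calls),
              summary = summary, headline = headline,
              rooted_trees = rooted, log = logdf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out$calls_df, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sm <- out$summary
    utils::write.table(sm, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(logdf, file.path(out_dir, "log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# stratum membership: placement and minimum tier
.strata_def <- list(
  BR3_ge50 = list(br = "BR3", tiers = c("ge50", "ge80")),
  BR2_ge50 = list(br = "BR2", tiers = c("ge50", "ge80")),
  combined_ge50 = list(br = c("BR2", "BR3"), tiers = c("ge50", "ge80")),
  BR3_ge80 = list(br = "BR3", tiers = "ge80"),
  BR2_ge80 = list(br = "BR2", tiers = "ge80"),
  combined_ge80 = list(br = c("BR2", "BR3"), tiers = "ge80")
)

# mixture reports per stratum over a named numeric vector of values
.stratum_mixtures <- function(values_df, value_col, k_range, seed,
                              n_random_starts, n_kmeans_starts,
                              min_stratum) {
  mixtures <- list()
  reports <- list()
  for (sname in names(.strata_def)) {
    sd <- .strata_def[[sname]]
    sel <- values_df$placement %in% sd$br & values_df$tier %in% sd$tiers
    vals <- values_df[[value_col]][sel]
    vals <- vals[is.finite(vals)]
    if (length(vals) < min_stratum) {
      if (length(vals) > 0)
        warning("stratum ", sname, ": only ", length(vals),
                " values, mixture skipped")
      next
    }
    fit <- tryCatch(
      select_by_bic(vals, k_range = k_range, seed = seed,
                    n_random_starts = n_random_starts,
                    n_kmeans_starts = n_kmeans_starts),
      error = function(e) NULL)
    if (is.null(fit)) next
    mixtures[[sname]] <- fit
    reports[[sname]] <- data.frame(
      stratum = sname, n = length(vals), k = fit$k,
      components = paste(format_components(fit), collapse = "; "),
      ci95 = paste(apply(round(fit$mean_ci95, 2), 1, paste,
                         collapse = "-"), collapse = "; "),
      stringsAsFactors = FALSE)
  }
  list(mixtures = mixtures,
       reports = if (length(reports)) do.call(rbind, reports) else
         data.frame(stratum = character(), n = integer(), k = integer(),
                    components = character(), ci95 = character(),
                    stringsAsFactors = FALSE))
}

#' Date classified duplications and fit age mixtures
#'
#' Dates each resolved call's tree by penalized-likelihood rate smoothing
#' (smoothing chosen by cross-validation when \code{lambda_grid} has more
#' than one value), extracts the duplication-node ages, and fits
#' BIC-selected normal mixtures per placement stratum (BR3-only, BR2-only,
#' combined, each at the two tiers). Trees failing cross-validation or
#' optimization are excluded with reasons.
#'
#' @param placement result of \code{\link{run_placement_pipeline}}.
#' @param panel \code{lineage_panel} (for calibration transfer).
#' @param lambda_grid ascending smoothing grid (length 1 skips
#'   cross-validation).
#' @param cv_pilot \code{NULL} for per-tree cross-validation; an integer m
#'   cross-validates the first m resolvable trees only and dates the whole
#'   cohort at the modal winning lambda (ties to the smaller value) --
#'   appropriate when the cohort's trees are exchangeable draws from one
#'   process and per-tree selection would dominate the runtime.
#' @param nsites alignment length behind the branch lengths.
#' @param nstart optimizer restarts per dating fit.
#' @param k_range,n_random_starts,n_kmeans_starts mixture settings.
#' @param min_stratum minimum ages per stratum for a mixture (default 5).
#' @param seed seed for dating restarts and mixture starts.
#' @param out_dir optional output directory (\code{ages.tsv},
#'   \code{mixtures.tsv}, \code{dating_log.tsv}).
#' @return list: \code{ages} (data.frame), \code{mixtures},
#'   \code{reports}, \code{log}.
#' @export
run_dating_pipeline <- function(placement, panel,
                                lambda_grid = c(0.1, 1, 10, 100, 1000),
                                cv_pilot = NULL,
                                nsites = 1000, nstart = 3,
                                k_range = 1:4, n_random_starts = 100,
                                n_kmeans_starts = 10, min_stratum = 5,
                                seed = 1, out_dir = NULL) {
  calls <- placement$calls
  rooted <- placement$rooted_trees
  rows <- list()
  log <- list()
  note <- function(og, pair, status, reason = "") {
    log[[length(log) + 1]] <<- data.frame(
      orthogroup = og, pair = pair, status = status, reason = reason,
      stringsAsFactors = FALSE)
  }
  calib_fun <- function(gt) transfer_calibrations(gt, panel)
  resolved <- Filter(function(cl) cl$placement != "unresolved", calls)
  pilot_lambda <- NULL
  if (!is.null(cv_pilot) && length(lambda_grid) > 1 && length(resolved)) {
    picks <- numeric(0)
    for (cl in resolved[seq_len(min(cv_pilot, length(resolved)))]) {
      gt <- rooted[[sub("^OG", "", cl$orthogroup)]]
      cv <- tryCatch(
        cross_validate_smoothing(gt, calib_fun, lambda_grid,
                                 nsites = nsites, seed = seed),
        error = function(e) NULL)
      if (!is.null(cv)) picks <- c(picks, cv$lambda)
    }
    if (!length(picks))
      stop("every pilot tree failed cross-validation")
    tab <- table(picks)
    winners <- as.numeric(names(tab)[tab == max(tab)])
    pilot_lambda <- min(winners)
  }
  for (cl in calls) {
    pid <- paste(cl$gene_a, cl$gene_b, sep = "~")
    if (cl$placement == "unresolved") {
      note(cl$orthogroup, pid, "excluded", "unresolved placement")
      next
    }
    gt <- rooted[[sub("^OG", "", cl$orthogroup)]]
    res <- tryCatch({
      lam <- if (!is.null(pilot_lambda)) {
        pilot_lambda
      } else {
        cross_validate_smoothing(gt, calib_fun, lambda_grid,
                                 nsites = nsites, seed = seed)$lambda
      }
      fit <- penalized_likelihood_date(gt, calib_fun(gt),
                                       lambda = lam, nsites = nsites,
                                       nstart = nstart, seed = seed)
      list(lambda = lam, age = duplication_age(fit, cl))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      note(cl$orthogroup, pid, "excluded", res)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      orthogroup = cl$orthogroup, pair = pid, placement = cl$placement,
      tier = cl$tier, lambda = res$lambda, age = res$age,
      stringsAsFactors = FALSE)
    note(cl$orthogroup, pid, "dated")
  }
  ages <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup = character(), pair = character(),
               placement = character(), tier = character(),
               lambda = numeric(), age = numeric(), stringsAsFactors = FALSE)
  mix <- .stratum_mixtures(ages, "age", k_range, seed,
                           n_random_starts, n_kmeans_starts, min_stratum)
  logdf <- if (length(log)) do.call(rbind, log) else
    data.frame(orthogroup = character(), pair = character(),
               status = character(), reason = character(),
               stringsAsFactors = FALSE)
  out <- list(ages = ages, mixtures = mix$mixtures, reports = mix$reports,
              log = logdf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ages, file.path(out_dir, "ages.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(mix$reports, file.path(out_dir, "mixtures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(logdf, file.path(out_dir, "dating_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Estimate Ks per pair and fit Ks mixtures per stratum
#'
#' @param alignments named list of codon alignments (names are
#'   \code{"gene_a~gene_b"} pair ids matching the placement calls).
#' @param placement result of \code{\link{run_placement_pipeline}}; may be
#'   \code{NULL}, in which case a single all-pairs stratum is analyzed.
#' @param method \code{"gy94"} or \code{"ng86"}.
#' @param k_range,n_random_starts,n_kmeans_starts,min_stratum,seed mixture
#'   settings as in \code{\link{run_dating_pipeline}}.
#' @param out_dir optional output directory (\code{ks.tsv},
#'   \code{ks_mixtures.tsv}).
#' @return list: \code{ks} (data.frame), \code{mixtures}, \code{reports}.
#' @export
run_ks_pipeline <- function(alignments, placement = NULL, method = "gy94",
                            k_range = 1:4, n_random_starts = 100,
                            n_kmeans_starts = 10, min_stratum = 5, seed = 1,
                            out_dir = NULL) {
  ksdf <- ks_cohort(alignments, method = method)
  if (!is.null(placement) && nrow(ksdf)) {
    cdf <- placement$calls_df
    cdf$pairid <- paste(cdf$gene_a, cdf$gene_b, sep = "~")
    m <- match(ksdf$pair, cdf$pairid)
    ksdf$placement <- ifelse(is.na(m), "unresolved", cdf$placement[m])
    ksdf$tier <- ifelse(is.na(m), "none", cdf$tier[m])
  } else if (nrow(ksdf)) {
    ksdf$placement <- "BR3"
    ksdf$tier <- "ge50"
  } else {
    ksdf$placement <- character(0)
    ksdf$tier <- character(0)
  }
  mix <- .stratum_mixtures(ksdf, "ks", k_range, seed,
                           n_random_starts, n_kmeans_starts, min_stratum)
  out <- list(ks = ksdf, mixtures = mix$mixtures, reports = mix$reports)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(ksdf, file.path(out_dir, "ks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(mix$reports, file.path(out_dir, "ks_mixtures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form \code{key = value}; comma-separated values become
#' vectors; numeric strings become numbers; \code{#} starts a comment.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!any(is.na(num))) num else parts
  }
  cfg
}
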