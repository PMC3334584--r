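# Penalized-likelihood divergence-time estimation (semi-parametric rate
# smoothing). Branch substitution counts x_k = branch length * nsites are
# modelled as Poisson with mean r_k * t_k; the penalized log-likelihood
#
#   sum_k [ x_k log(r_k t_k) - r_k t_k ]
#     - lambda * [ sum_{k non-root} (r_k - r_parent(k))^2 + Var(root-child rates) ]
#
# is maximized over node ages (respecting ordering and calibrations) and
# per-branch rates. Ages are parameterized as bounded fractions of the
# parent age so ordering, fixed calibrations, and min/max constraints hold
# by construction.

#' Build a calibration set
#'
#' @param node internal node ids (ape numbering).
#' @param min,max minimum / maximum ages in mya (\code{NA} = unconstrained).
#'   A fixed calibration has \code{min == max}.
#' @return data.frame of class \code{calibration_set}.
#' @export
calibration_set <- function(node, min = NA_real_, max = NA_real_) {
  df <- data.frame(node = as.integer(node), min = as.numeric(min),
                   max = as.numeric(max))
  ok <- is.na(df$min) | is.na(df$max) | df$min <= df$max
  if (!all(ok)) stop("calibration min > max for node ",
                     paste(df$node[!ok], collapse = ", "))
  if (any(!is.na(df$min) & df$min <= 0) || any(!is.na(df$max) & df$max <= 0))
    stop("calibration ages must be positive")
  if (anyDuplicated(df$node)) stop("duplicate calibration node")
  class(df) <- c("calibration_set", "data.frame")
  df
}

#' Transfer scaffold calibrations onto a gene tree
#'
#' Applies the fossil calibrations used for dating: the root (crown of the
#' sampled angiosperms) receives a minimum of 131 and a maximum of 309 mya,
#' and every node representing a copy of the eudicot crown -- a minimal node
#' whose subtree contains only eudicot leaves, among them at least one basal
#' eudicot and one core eudicot -- is fixed at 125 mya. In a duplicated gene
#' tree each surviving copy of the crown speciation is calibrated.
#'
#' @param gt rooted \code{gene_tree}.
#' @param panel \code{lineage_panel}.
#' @param angiosperm_min,angiosperm_max root age bounds (mya).
#' @param eudicot_fixed fixed eudicot crown age (mya).
#' @return \code{calibration_set}.
#' @export
transfer_calibrations <- function(gt, panel, angiosperm_min = 131,
                                  angiosperm_max = 309,
                                  eudicot_fixed = 125) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  lin <- tip_lineages(gt, panel)
  sets <- .descendant_tip_sets(phy)
  eud <- c("basal_eudicot", "caryophyllid", "asterid", "rosid")
  core <- c("caryophyllid", "asterid", "rosid")
  internals <- (ntip + 1L):(ntip + phy$Nnode)
  qualifies <- vapply(internals, function(v) {
    lv <- lin[sets[[v]]]
    all(lv %in% eud) && any(lv == "basal_eudicot") && any(lv %in% core)
  }, logical(1))
  qn <- internals[qualifies]
  minimal <- qn[vapply(qn, function(v) {
    others <- setdiff(qn, v)
    !any(vapply(others, function(w)
      all(sets[[w]] %in% sets[[v]]) && length(sets[[w]]) < length(sets[[v]]),
      logical(1)))
  }, logical(1))]
  nodes <- integer(0); mins <- numeric(0); maxs <- numeric(0)
  if (root %in% minimal) {
    # degenerate all-eudicot tree: the fixed crown identifies the scale
    nodes <- root; mins <- eudicot_fixed; maxs <- eudicot_fixed
    minimal <- setdiff(minimal, root)
  } else {
    nodes <- root; mins <- angiosperm_min; maxs <- angiosperm_max
  }
  for (v in minimal) {
    nodes <- c(nodes, v); mins <- c(mins, eudicot_fixed)
    maxs <- c(maxs, eudicot_fixed)
  }
  calibration_set(nodes, mins, maxs)
}

# model skeleton shared by the fitter, its gradient, and cross-validation
.pl_model <- function(gt, calibrations, nsites) {
  phy <- ape::reorder.phylo(gt$phy, "cladewise")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  root <- ntip + 1L
  E <- nrow(phy$edge)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  x <- phy$edge.length * nsites
  nodes <- ntip + seq_len(nnode)
  fixed <- rep(NA_real_, ntip + nnode)
  cmin <- rep(NA_real_, ntip + nnode)
  cmax <- rep(NA_real_, ntip + nnode)
  for (i in seq_len(nrow(calibrations))) {
    n <- calibrations$node[i]
    if (n <= ntip || n > ntip + nnode) stop("calibration node out of range")
    if (!is.na(calibrations$min[i]) && !is.na(calibrations$max[i]) &&
        calibrations$min[i] == calibrations$max[i]) {
      fixed[n] <- calibrations$min[i]
    } else {
      cmin[n] <- calibrations$min[i]
      cmax[n] <- calibrations$max[i]
    }
  }
  has_scale <- any(!is.na(fixed)) ||
    any(!is.na(cmin) & !is.na(cmax))
  if (!has_scale)
    stop("unidentifiable time scale: need a fixed calibration or a node ",
         "with both min and max")
  # postorder floors
  floor_age <- rep(0, ntip + nnode)
  po <- ape::postorder(phy)
  for (e in po) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    f <- floor_age[ch]
    if (!is.na(fixed[ch])) f <- max(f, fixed[ch])
    if (!is.na(cmin[ch])) f <- max(f, cmin[ch])
    floor_age[p] <- max(floor_age[p], f)
  }
  for (n in nodes) {
    lo <- max(floor_age[n],
              if (!is.na(cmin[n])) cmin[n] else 0)
    if (!is.na(fixed[n]) && fixed[n] < floor_age[n] - 1e-12)
      stop("fixed calibration at node ", n,
           " below the floor implied by its descendants")
    floor_age[n] <- lo
  }
  # preorder node visit order (parents before children)
  pre_nodes <- root
  for (e in seq_len(E)) {
    ch <- phy$edge[e, 2]
    if (ch > ntip) pre_nodes <- c(pre_nodes, ch)
  }
  free <- pre_nodes[is.na(fixed[pre_nodes])]
  # parent edge index for each edge; root-child edges flagged
  edge_of_child <- integer(ntip + nnode)
  edge_of_child[phy$edge[, 2]] <- seq_len(E)
  parent_edge <- ifelse(phy$edge[, 1] == root, NA_integer_,
                        edge_of_child[phy$edge[, 1]])
  root_edges <- which(phy$edge[, 1] == root)
  list(phy = phy, ntip = ntip, nnode = nnode, root = root, E = E, x = x,
       fixed = fixed, cmin = cmin, cmax = cmax, floor_age = floor_age,
       pre_nodes = pre_nodes, free = free, parent_edge = parent_edge,
       root_edges = root_edges, nsites = nsites,
       parent = phy$edge[, 1], child = phy$edge[, 2])
}

# map theta (free-node parameters) to ages and the Jacobian d age / d theta
.pl_ages <- function(m, theta, jacobian = FALSE) {
  eps <- 1e-4
  nn <- m$ntip + m$nnode
  ages <- numeric(nn)
  nfree <- length(m$free)
  idx <- stats::setNames(seq_len(nfree), m$free)
  J <- if (jacobian) matrix(0, nn, nfree) else NULL
  pa_of <- integer(nn)
  pa_of[m$child] <- m$parent
  for (n in m$pre_nodes) {
    if (!is.na(m$fixed[n])) {
      ages[n] <- m$fixed[n]
      next
    }
    pa_age <- if (n == m$root) Inf else ages[pa_of[n]]
    hi <- min(pa_age, if (!is.na(m$cmax[n])) m$cmax[n] else Inf)
    lo <- m$floor_age[n]
    th <- theta[idx[[as.character(n)]]]
    if (!is.finite(hi)) {
      ages[n] <- lo + exp(min(th, 25))
      if (jacobian) J[n, idx[[as.character(n)]]] <- exp(min(th, 25))
    } else {
      s <- eps + (1 - 2 * eps) * stats::plogis(th)
      ages[n] <- lo + (hi - lo) * s
      if (jacobian) {
        ds <- (1 - 2 * eps) * stats::dlogis(th)
        J[n, idx[[as.character(n)]]] <- (hi - lo) * ds
        if (n != m$root && hi == pa_age && pa_of[n] != 0)
          J[n, ] <- J[n, ] + s * J[pa_of[n], ]
      }
    }
  }
  list(ages = ages, J = J)
}

# penalized negative log-likelihood and gradient; par = c(theta, log rates)
.pl_objective <- function(par, m, lambda, gradient = FALSE) {
  nfree <- length(m$free)
  theta <- par[seq_len(nfree)]
  logr <- par[nfree + seq_len(m$E)]
  r <- exp(pmin(logr, 50))
  am <- .pl_ages(m, theta, jacobian = gradient)
  ages <- am$ages
  t <- ages[m$parent] - ages[m$child]
  t <- pmax(t, 1e-6)
  lt <- log(r * t)
  L <- sum(ifelse(m$x > 0, m$x * lt, 0) - r * t)
  nr <- which(!is.na(m$parent_edge))
  dr <- r[nr] - r[m$parent_edge[nr]]
  pen <- sum(dr^2) + stats::var(r[m$root_edges])
  f <- -(L - lambda * pen)
  if (!gradient) return(f)
  dL_dt <- ifelse(m$x > 0, m$x / t, 0) - r
  dL_dlogr <- m$x - r * t
  dpen_dr <- numeric(m$E)
  dpen_dr[nr] <- dpen_dr[nr] + 2 * dr
  for (i in seq_along(nr))
    dpen_dr[m$parent_edge[nr[i]]] <- dpen_dr[m$parent_edge[nr[i]]] - 2 * dr[i]
  mrt <- mean(r[m$root_edges])
  mroot <- length(m$root_edges)
  dpen_dr[m$root_edges] <- dpen_dr[m$root_edges] +
    2 * (r[m$root_edges] - mrt) / (mroot - 1)
  g_logr <- -(dL_dlogr - lambda * dpen_dr * r)
  g_theta <- -(colSums(dL_dt * (am$J[m$parent, , drop = FALSE] -
                                  am$J[m$child, , drop = FALSE])))
  c(g_theta, g_logr)
}

# clock-rooted initialization: ages proportional to mean subtending depth,
# scaled to hit the fixed calibrations
.pl_init <- function(m) {
  nn <- m$ntip + m$nnode
  depth <- numeric(nn)
  for (e in ape::postorder(m$phy)) {
    p <- m$parent[e]; ch <- m$child[e]
    d <- depth[ch] + m$phy$edge.length[e]
    depth[p] <- if (depth[p] == 0) d else (depth[p] + d) / 2
  }
  anchors <- which(!is.na(m$fixed) & depth > 1e-12)
  scale <- if (length(anchors)) {
    mean(m$fixed[anchors] / depth[anchors])
  } else {
    mid <- mean(c(m$cmin[m$root], m$cmax[m$root]), na.rm = TRUE)
    mid / max(depth[m$root], 1e-12)
  }
  ages0 <- pmax(depth * scale, 0)
  # invert the age map to theta, clipping into feasible windows
  eps <- 1e-4
  theta <- numeric(length(m$free))
  idx <- stats::setNames(seq_along(m$free), m$free)
  pa_of <- integer(nn)
  pa_of[m$child] <- m$parent
  ages <- numeric(nn)
  for (n in m$pre_nodes) {
    if (!is.na(m$fixed[n])) { ages[n] <- m$fixed[n]; next }
    pa_age <- if (n == m$root) Inf else ages[pa_of[n]]
    hi <- min(pa_age, if (!is.na(m$cmax[n])) m$cmax[n] else Inf)
    lo <- m$floor_age[n]
    target <- min(max(ages0[n], lo + 1e-6), if (is.finite(hi)) hi else Inf)
    if (!is.finite(hi)) {
      theta[idx[[as.character(n)]]] <- log(max(target - lo, 1e-3))
      ages[n] <- lo + max(target - lo, 1e-3)
    } else {
      s <- (target - lo) / (hi - lo)
      s <- min(max(s, 2 * eps), 1 - 2 * eps)
      th <- stats::qlogis((s - eps) / (1 - 2 * eps))
      th <- min(max(th, -8), 8)
      theta[idx[[as.character(n)]]] <- th
      ages[n] <- lo + (hi - lo) * (eps + (1 - 2 * eps) * stats::plogis(th))
    }
  }
  tdur <- pmax(ages[m$parent] - ages[m$child], 1e-6)
  r0 <- max(sum(m$x) / sum(tdur), 1e-8)
  list(theta = theta, logr = rep(log(r0), m$E))
}

#' Date a gene tree by penalized-likelihood rate smoothing
#'
#' @param gt rooted \code{gene_tree} with branch lengths in
#'   substitutions/site.
#' @param calibrations \code{\link{calibration_set}}; at least one fixed
#'   node, or one node with both min and max, is required to identify the
#'   time scale.
#' @param lambda non-negative smoothing parameter; larger values pull
#'   branch rates toward a single clock.
#' @param nsites alignment length used to convert branch lengths to
#'   expected substitution counts (default 1000).
#' @param nstart number of optimizer restarts from jittered clock
#'   initializations; the best penalized likelihood is kept.
#' @param seed seed for the restart jitter (restores the caller's RNG).
#' @param maxit BFGS iteration cap per start.
#' @return object of class \code{rate_smoothing}: \code{node_ages} (mya,
#'   indexed by ape node id; tips 0), \code{branch_rates}
#'   (substitutions/site/my per edge of the reordered tree), \code{lambda},
#'   \code{objective} (penalized log-likelihood), \code{converged},
#'   \code{phy} (the reordered tree).
#' @export
penalized_likelihood_date <- function(gt, calibrations, lambda = 1,
                                      nsites = 1000, nstart = 5, seed = 1,
                                      maxit = 500) {
  stopifnot(inherits(gt, "gene_tree"), lambda >= 0, nsites > 0)
  m <- .pl_model(gt, calibrations, nsites)
  init <- .pl_init(m)
  par0 <- c(init$theta, init$logr)
  fn <- function(p) .pl_objective(p, m, lambda, gradient = FALSE)
  gr <- function(p) .pl_objective(p, m, lambda, gradient = TRUE)
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(nstart)) {
      p0 <- if (s == 1) par0 else
        par0 + c(stats::rnorm(length(init$theta), 0, 0.5),
                 stats::rnorm(length(init$logr), 0, 0.3))
      fit <- tryCatch(
        stats::optim(p0, fn, gr, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best))
    stop("penalized-likelihood optimization failed on all ", nstart,
         " starts")
  nfree <- length(m$free)
  ages <- .pl_ages(m, best$par[seq_len(nfree)])$ages
  rates <- exp(best$par[nfree + seq_len(m$E)]) / nsites
  structure(list(node_ages = ages,
                 branch_rates = rates,
                 lambda = lambda,
                 objective = -best$value,
                 converged = best$convergence == 0,
                 nsites = nsites,
                 phy = m$phy,
                 model = m),
            class = "rate_smoothing")
}

#' @export
print.rate_smoothing <- function(x, ...) {
  cat(sprintf(
    "<rate_smoothing> root age %.2f mya, lambda %g, objective %.4f%s\n",
    x$node_ages[x$model$root], x$lambda, x$objective,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Choose the smoothing parameter by cross-validation
#'
#' For each candidate lambda, each terminal branch is pruned in turn, the
#' remaining tree refitted, and the pruned branch's substitution count
#' predicted as (fitted rate at its attachment point) x (age of the
#' attachment point); the chi-squared prediction error is accumulated. The
#' lambda with the smallest error wins; ties go to the smaller lambda.
#'
#' @param gt rooted \code{gene_tree}.
#' @param calib_fun function mapping a \code{gene_tree} to a
#'   \code{\link{calibration_set}} (re-evaluated on each pruned tree), e.g.
#'   \code{function(t) transfer_calibrations(t, panel)}.
#' @param lambda_grid non-empty ascending grid of smoothing values.
#' @param nsites alignment length.
#' @param nstart restarts per pruned fit (1 keeps cross-validation cheap).
#' @param seed restart jitter seed.
#' @return list with \code{lambda} (the winner), \code{cv}
#'   (data.frame lambda, score, n_pruned).
#' @export
cross_validate_smoothing <- function(gt, calib_fun, lambda_grid,
                                     nsites = 1000, nstart = 1, seed = 1) {
  stopifnot(length(lambda_grid) >= 1)
  if (is.unsorted(lambda_grid, strictly = TRUE))
    stop("lambda_grid must be ascending")
  if (length(lambda_grid) == 1) {
    return(list(lambda = lambda_grid[1],
                cv = data.frame(lambda = lambda_grid, score = NA_real_,
                                n_pruned = 0)))
  }
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  scores <- numeric(length(lambda_grid))
  npruned <- integer(length(lambda_grid))
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    tot <- 0; used <- 0L; failed <- FALSE
    for (i in seq_len(ntip)) {
      pr <- .cv_prune_predict(gt, i, calib_fun, lam, nsites, nstart, seed)
      if (is.null(pr)) next
      if (is.na(pr)) { failed <- TRUE; break }
      tot <- tot + pr
      used <- used + 1L
    }
    if (failed || used == 0L) {
      scores[li] <- Inf
    } else {
      scores[li] <- tot
      npruned[li] <- used
    }
  }
  if (all(!is.finite(scores)))
    stop("tree fails cross-validation at every lambda")
  list(lambda = lambda_grid[which.min(scores)],
       cv = data.frame(lambda = lambda_grid, score = scores,
                       n_pruned = npruned))
}

# chi-squared CV contribution of pruning tip i; NULL = tip not usable
# (attachment vanishes at the root), NA = fit failure
.cv_prune_predict <- function(gt, i, calib_fun, lambda, nsites, nstart,
                              seed) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  tipedge <- which(phy$edge[, 2] == i)
  x_obs <- phy$edge.length[tipedge] * nsites
  P <- phy$edge[tipedge, 1]
  if (P == ntip + 1L && sum(phy$edge[, 1] == P) <= 2) return(NULL)
  sibs <- setdiff(phy$edge[phy$edge[, 1] == P, 2], i)
  sets <- .descendant_tip_sets(phy)
  attach_tips <- sort(phy$tip.label[setdiff(unlist(sets[sibs]), i)])
  lu <- phy$edge.length[which(phy$edge[, 2] == P)]
  lw <- if (length(sibs) == 1) phy$edge.length[which(phy$edge[, 2] == sibs)]
        else NA_real_
  pphy <- ape::drop.tip(phy, i, collapse.singles = TRUE)
  pgt <- gene_tree_from_phylo(pphy, delim = gt$delim)
  cal <- tryCatch(calib_fun(pgt), error = function(e) NULL)
  if (is.null(cal)) return(NULL)
  fit <- tryCatch(
    penalized_likelihood_date(pgt, cal, lambda = lambda, nsites = nsites,
                              nstart = nstart, seed = seed),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  # node in the pruned tree subtending exactly the former sibling tips
  psets <- .descendant_tip_sets(fit$phy)
  v <- NULL
  for (n in seq_along(psets)) {
    if (identical(sort(fit$phy$tip.label[psets[[n]]]), attach_tips)) {
      v <- n; break
    }
  }
  if (is.null(v)) return(NULL)
  vedge <- which(fit$phy$edge[, 2] == v)
  if (!length(vedge)) return(NULL)  # v is the pruned root
  r_hat <- fit$branch_rates[vedge] * nsites
  a_child <- fit$node_ages[v]
  a_par <- fit$node_ages[fit$phy$edge[vedge, 1]]
  attach_age <- if (length(sibs) == 1 && is.finite(lu + lw) && lu + lw > 0) {
    a_child + (lw / (lu + lw)) * (a_par - a_child)
  } else {
    (a_child + a_par) / 2
  }
  pred <- max(r_hat * attach_age, 1e-8)
  (x_obs - pred)^2 / pred
}

#' Age of a classified duplication node
#'
#' @param result \code{rate_smoothing} fit of the same tree the call was
#'   made on.
#' @param call \code{duplication_call} (must be resolved), or an integer
#'   node id.
#' @return age in mya.
#' @export
duplication_age <- function(result, call) {
  stopifnot(inherits(result, "rate_smoothing"))
  node <- if (inherits(call, "duplication_call")) {
    if (call$placement == "unresolved")
      stop("cannot date an unresolved duplication call")
    call$node
  } else {
    as.integer(call)
  }
  if (is.na(node) || node < 1 || node > length(result$node_ages))
    stop("node missing from the dated tree: ", node)
  unname(result$node_ages[node])
}
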