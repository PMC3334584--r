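# Pairwise synonymous divergence (Ks) estimation: Nei-Gojobori (1986)
# counting with Jukes-Cantor correction as the fast oracle, and the
# Goldman-Yang (1994) codon model with F3x4 frequencies fitted by maximum
# likelihood as the primary method (codeml-style mutational-opportunity
# definition of synonymous sites).

# ---- standard genetic code over the 61 sense codons ------------------------

.codon_env <- local({
  bases <- c("T", "C", "A", "G")
  aa64 <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  # first base slowest, third fastest (matches the amino-acid string above)
  codons64 <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons64[k] <- paste0(b1, b2, b3)
  }
  sense <- aa64 != "*"
  codons <- codons64[sense]
  aa <- aa64[sense]
  nt <- t(vapply(strsplit(codons, ""), function(x)
    match(x, bases), integer(3)))
  n <- length(codons)  # 61
  # single-nucleotide neighbor structure
  pairs <- which(
    outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      i != j && sum(nt[i, ] != nt[j, ]) == 1)),
    arr.ind = TRUE)
  is_ti <- function(a, b) {
    # bases coded 1=T 2=C 3=A 4=G; transitions: T<->C, A<->G
    (a <= 2 && b <= 2) || (a >= 3 && b >= 3)
  }
  ti <- logical(nrow(pairs))
  syn <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pos <- which(nt[i, ] != nt[j, ])
    ti[r] <- is_ti(nt[i, pos], nt[j, pos])
    syn[r] <- aa[i] == aa[j]
  }
  stop_codons <- codons64[!sense]
  list(bases = bases, codons = codons, aa = aa, nt = nt, n = n,
       pairs = pairs, ti = ti, syn = syn, stop_codons = stop_codons,
       aa64 = aa64, codons64 = codons64)
})

#' Build a pairwise codon alignment
#'
#' Validates two in-frame nucleotide sequences of equal length divisible by
#' three; codons containing gaps or ambiguity characters in either sequence
#' are masked pairwise; in-frame stop codons are an error.
#'
#' @param seq_a,seq_b nucleotide strings (case-insensitive; U accepted).
#' @return object of class \code{codon_alignment}: integer codon index
#'   vectors \code{a}, \code{b} (1..61), \code{n_codons} (unmasked),
#'   \code{n_masked}.
#' @export
codon_alignment <- function(seq_a, seq_b) {
  clean <- function(s) {
    s <- toupper(gsub("[[:space:]]", "", s))
    gsub("U", "T", s)
  }
  sa <- clean(seq_a); sb <- clean(seq_b)
  if (nchar(sa) != nchar(sb))
    stop("sequences differ in length (", nchar(sa), " vs ", nchar(sb), ")")
  if (nchar(sa) %% 3 != 0)
    stop("alignment length ", nchar(sa), " is not divisible by 3")
  nc <- nchar(sa) / 3
  split3 <- function(s) substring(s, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  ca <- split3(sa); cb <- split3(sb)
  valid <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  if (any(ca[valid] %in% .codon_env$stop_codons) ||
      any(cb[valid] %in% .codon_env$stop_codons))
    stop("in-frame stop codon in alignment")
  ia <- match(ca[valid], .codon_env$codons)
  ib <- match(cb[valid], .codon_env$codons)
  structure(list(a = ia, b = ib, n_codons = sum(valid),
                 n_masked = nc - sum(valid)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", x$n_codons, "codons (", x$n_masked, "masked )\n")
  invisible(x)
}

.new_ks_estimate <- function(ks, ka, t, kappa, omega_hat, method,
                             flags = character()) {
  structure(list(ks = ks, ka = ka,
                 omega = if (!is.null(omega_hat)) omega_hat else
                   if (ks > 0) ka / ks else NA_real_,
                 t = t, kappa = kappa, method = method, flags = flags),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("<ks_estimate %s> ks=%.4f ka=%.4f omega=%.4f t=%.4f kappa=%.3f%s\n",
              x$method, x$ks, x$ka, x$omega, x$t, x$kappa,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

# ---- NG86 ------------------------------------------------------------------

# synonymous site fraction of each sense codon (stops excluded from the
# alternatives at each position; every codon carries exactly 3 sites)
.ng86_syn_sites <- local({
  ce <- .codon_env
  s <- numeric(ce$n)
  for (i in seq_len(ce$n)) {
    tot <- 0
    for (pos in 1:3) {
      alts <- setdiff(1:4, ce$nt[i, pos])
      ns <- 0; nn <- 0
      for (a in alts) {
        ntj <- ce$nt[i, ]
        ntj[pos] <- a
        cdn <- paste0(ce$bases[ntj], collapse = "")
        j <- match(cdn, ce$codons)
        if (is.na(j)) next  # stop codon: excluded
        if (ce$aa[j] == ce$aa[i]) ns <- ns + 1 else nn <- nn + 1
      }
      tot <- tot + if (ns + nn > 0) ns / (ns + nn) else 0
    }
    s[i] <- tot
  }
  s
})

# average syn/nonsyn differences between two codons over all shortest
# substitution paths that avoid stop codons (uniform path weights)
.ng86_diffs <- function(i, j) {
  ce <- .codon_env
  pos <- which(ce$nt[i, ] != ce$nt[j, ])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  paths <- .permutations(pos)
  tot_s <- 0; tot_n <- 0; nvalid <- 0
  for (p in paths) {
    cur <- ce$nt[i, ]
    s <- 0; n <- 0; ok <- TRUE
    for (step in p) {
      nxt <- cur
      nxt[step] <- ce$nt[j, step]
      from <- match(paste0(ce$bases[cur], collapse = ""), ce$codons)
      to <- match(paste0(ce$bases[nxt], collapse = ""), ce$codons)
      if (is.na(to)) { ok <- FALSE; break }  # path through a stop codon
      if (ce$aa[from] == ce$aa[to]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) {
      tot_s <- tot_s + s; tot_n <- tot_n + n; nvalid <- nvalid + 1
    }
  }
  if (nvalid == 0) {
    # all paths blocked by stops: count every step as nonsynonymous
    return(c(syn = 0, nonsyn = length(pos)))
  }
  c(syn = tot_s / nvalid, nonsyn = tot_n / nvalid)
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

#' Nei-Gojobori (1986) Ks/Ka estimate
#'
#' Counts synonymous and nonsynonymous sites by codon-position degeneracy
#' (averaged over the two sequences, stop-codon changes excluded from the
#' per-position alternatives), counts differences averaging over all
#' shortest substitution paths avoiding stop codons, and applies the
#' Jukes-Cantor correction d = -3/4 log(1 - 4p/3).
#'
#' @param aln \code{\link{codon_alignment}}.
#' @return \code{ks_estimate} with \code{method = "NG86"}; additionally
#'   carries \code{sites} (S, N) and \code{diffs} (Sd, Nd) in attributes.
#' @export
ng86_ks <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$n_codons == 0) stop("empty alignment after masking")
  S <- (sum(.ng86_syn_sites[aln$a]) + sum(.ng86_syn_sites[aln$b])) / 2
  N <- 3 * aln$n_codons - S
  Sd <- 0; Nd <- 0
  diff <- which(aln$a != aln$b)
  for (idx in diff) {
    d <- .ng86_diffs(aln$a[idx], aln$b[idx])
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
  }
  jc <- function(p, what) {
    if (p >= 3 / 4)
      stop("saturation: proportion of ", what, " differences ",
           signif(p, 4), " >= 3/4, Jukes-Cantor correction undefined")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- if (S > 0) jc(Sd / S, "synonymous") else NA_real_
  ka <- if (N > 0) jc(Nd / N, "nonsynonymous") else NA_real_
  out <- .new_ks_estimate(ks, ka, t = NA_real_, kappa = NA_real_,
                          omega_hat = NULL, method = "NG86")
  attr(out, "sites") <- c(S = S, N = N)
  attr(out, "diffs") <- c(Sd = Sd, Nd = Nd)
  out
}

# ---- GY94 / F3x4 -----------------------------------------------------------

#' F3x4 codon frequencies
#'
#' Empirical nucleotide frequencies at each codon position, pooled over both
#' sequences; codon frequencies are the per-position products over sense
#' codons, renormalized. Positions with a zero nucleotide frequency receive
#' a pseudo-frequency of 1e-6 before renormalization.
#'
#' @param aln \code{\link{codon_alignment}}.
#' @return numeric vector of 61 codon frequencies (sums to 1), with the
#'   3x4 position frequencies in attribute \code{pos_freqs}.
#' @export
f3x4_frequencies <- function(aln) {
  ce <- .codon_env
  counts <- matrix(0, 3, 4)
  for (v in list(aln$a, aln$b))
    for (pos in 1:3)
      counts[pos, ] <- counts[pos, ] +
        tabulate(ce$nt[v, pos], nbins = 4)
  f <- counts / rowSums(counts)
  f[f <= 0] <- 1e-6
  f <- f / rowSums(f)
  .codon_freqs_from_positions(f)
}

# codon frequencies from a 3x4 matrix of position-specific base frequencies
.codon_freqs_from_positions <- function(f) {
  ce <- .codon_env
  pi <- f[1, ce$nt[, 1]] * f[2, ce$nt[, 2]] * f[3, ce$nt[, 3]]
  pi <- pi / sum(pi)
  attr(pi, "pos_freqs") <- f
  pi
}

# GY94 rate matrix scaled to one expected nucleotide substitution per codon
# per unit t; returns Q plus the synonymous flux proportion
.gy94_q <- function(kappa, omega, pi) {
  ce <- .codon_env
  Q <- matrix(0, ce$n, ce$n)
  rate <- pi[ce$pairs[, 2]] *
    ifelse(.codon_env$ti, kappa, 1) *
    ifelse(.codon_env$syn, 1, omega)
  Q[ce$pairs] <- rate
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  flux <- pi[ce$pairs[, 1]] * Q[ce$pairs]
  rho_syn <- sum(flux[ce$syn]) / sum(flux)
  list(Q = Q, rho_syn = rho_syn)
}

# eigen-decomposition of the reversible Q for cheap P(t) at many t
.gy94_decompose <- function(Q, pi) {
  sp <- sqrt(pi)
  M <- diag(sp) %*% Q %*% diag(1 / sp)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  list(U = e$vectors, d = e$values, sp = sp)
}

# P(t) = D^{-1/2} U exp(d t) U' D^{1/2}, D = diag(pi)
.gy94_pt <- function(dec, t) {
  M0 <- dec$U %*% (exp(dec$d * t) * t(dec$U))
  P <- M0 * outer(1 / dec$sp, dec$sp)
  pmax(P, 1e-300)
}

# pairwise log-likelihood profile over t for fixed (kappa, omega)
.gy94_proflik <- function(counts, pi, kappa, omega) {
  qd <- .gy94_q(kappa, omega, pi)
  dec <- .gy94_decompose(qd$Q, pi)
  nz <- which(counts > 0, arr.ind = TRUE)
  cts <- counts[nz]
  lpi <- log(pi[nz[, 1]])
  loglik_at <- function(t) {
    P <- .gy94_pt(dec, t)
    sum(cts * (lpi + log(P[nz])))
  }
  opt <- stats::optimize(loglik_at, interval = c(1e-6, 50), maximum = TRUE,
                         tol = 1e-7)
  list(t = opt$maximum, loglik = opt$objective, rho_syn = qd$rho_syn)
}

#' Goldman-Yang (1994) maximum-likelihood Ks estimate
#'
#' Fits the 61-state GY94 codon model with F3x4 frequencies to a sequence
#' pair by maximizing the pairwise likelihood over branch length t
#' (substitutions/codon), transition/transversion ratio kappa, and dN/dS
#' ratio omega. Expected substitutions are decomposed into synonymous and
#' nonsynonymous flux and divided by the model-defined site proportions
#' computed at omega = 1 (mutational-opportunity definition, as in codeml):
#' ks = t rhoS / (3 rhoS1), ka = t (1 - rhoS) / (3 (1 - rhoS1)).
#'
#' @param aln \code{\link{codon_alignment}} with at least \code{min_codons}
#'   unmasked codons.
#' @param min_codons minimum unmasked codons (default 50).
#' @return \code{ks_estimate} with \code{method = "GY94_F3x4"}; boundary
#'   hits on t or omega are reported in \code{flags}.
#' @export
gy94_ml_ks <- function(aln, min_codons = 50) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$n_codons < min_codons)
    stop("need >= ", min_codons, " unmasked codons, have ", aln$n_codons)
  if (all(aln$a == aln$b))
    return(.new_ks_estimate(0, 0, t = 0, kappa = NA_real_, omega_hat = NA,
                            method = "GY94_F3x4"))
  pi <- f3x4_frequencies(aln)
  ce <- .codon_env
  counts <- matrix(0, ce$n, ce$n)
  for (idx in seq_along(aln$a))
    counts[aln$a[idx], aln$b[idx]] <- counts[aln$a[idx], aln$b[idx]] + 1
  lb <- log(c(kappa = 0.1, omega = 1e-4))
  ub <- log(c(kappa = 20, omega = 10))
  obj <- function(par) {
    -.gy94_proflik(counts, pi, exp(par[1]), exp(par[2]))$loglik
  }
  starts <- list(log(c(2, 0.3)), log(c(1, 1)), log(c(5, 0.1)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("GY94 optimization failed to converge")
  kappa <- exp(best$par[1]); omega <- exp(best$par[2])
  prof <- .gy94_proflik(counts, pi, kappa, omega)
  t <- prof$t
  rho_s <- prof$rho_syn
  rho_s1 <- .gy94_q(kappa, 1, pi)$rho_syn
  ks <- t * rho_s / (3 * rho_s1)
  ka <- t * (1 - rho_s) / (3 * (1 - rho_s1))
  flags <- character()
  if (t >= 50 * 0.999 || t <= 2e-6) flags <- c(flags, "t_boundary")
  if (omega >= 10 * 0.999 || omega <= 1.1e-4)
    flags <- c(flags, "omega_boundary")
  out <- .new_ks_estimate(ks, ka, t = t, kappa = kappa, omega_hat = omega,
                          method = "GY94_F3x4")
  out$flags <- flags
  attr(out, "loglik") <- prof$loglik
  out
}

#' Estimate Ks for a cohort of paralog pairs
#'
#' @param alignments named list of \code{\link{codon_alignment}} (or
#'   2-element character vectors), named by pair id.
#' @param method \code{"gy94"} or \code{"ng86"}.
#' @param min_codons passed to \code{\link{gy94_ml_ks}}.
#' @return data.frame (pair, ks, ka, omega, t, kappa, method); per-pair
#'   failures are logged as warnings and skipped, recorded in attribute
#'   \code{skipped}.
#' @export
ks_cohort <- function(alignments, method = c("gy94", "ng86"),
                      min_codons = 50) {
  method <- match.arg(method)
  rows <- list()
  skipped <- character()
  for (id in names(alignments)) {
    al <- alignments[[id]]
    est <- tryCatch({
      if (!inherits(al, "codon_alignment"))
        al <- codon_alignment(al[[1]], al[[2]])
      if (method == "gy94") gy94_ml_ks(al, min_codons = min_codons)
      else ng86_ks(al)
    }, error = function(e) {
      warning("pair ", id, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(est)) {
      skipped <- c(skipped, id)
      next
    }
    rows[[id]] <- data.frame(pair = id, ks = est$ks, ka = est$ka,
                             omega = est$omega, t = est$t,
                             kappa = est$kappa, method = est$method,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair = character(), ks = numeric(), ka = numeric(),
               omega = numeric(), t = numeric(), kappa = numeric(),
               method = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Simulate a codon-sequence pair with a known synonymous divergence
#'
#' Evolves codons under the GY94/F3x4 model along a two-tip tree whose
#' length is chosen so that the model-defined synonymous divergence equals
#' \code{true_ks}: ancestral codons are drawn from the stationary
#' distribution and the second sequence from the transition probabilities at
#' t = 3 rhoS1 true_ks / rhoS.
#'
#' @param true_ks target synonymous substitutions per synonymous site.
#' @param kappa transition/transversion rate ratio.
#' @param omega dN/dS ratio (0 allowed: no nonsynonymous change).
#' @param n_codons number of codons.
#' @param seed integer seed (caller's RNG restored).
#' @param pos_freqs optional 3x4 matrix of position-specific base
#'   frequencies (rows: codon positions; columns: T, C, A, G); default
#'   uniform.
#' @return \code{\link{codon_alignment}}; the simulated strings are in
#'   attributes \code{seq_a}, \code{seq_b} and the branch length in
#'   attribute \code{t}.
#' @export
simulate_codon_pair <- function(true_ks, kappa = 2, omega = 0.2,
                                n_codons = 500, seed = 1,
                                pos_freqs = NULL) {
  stopifnot(true_ks >= 0, kappa > 0, omega >= 0, n_codons >= 1)
  ce <- .codon_env
  f <- if (is.null(pos_freqs)) matrix(0.25, 3, 4) else pos_freqs
  stopifnot(all(dim(f) == c(3, 4)))
  pi <- .codon_freqs_from_positions(f)
  with_seed(seed, {
    anc <- sample.int(ce$n, n_codons, replace = TRUE, prob = pi)
    if (true_ks == 0) {
      der <- anc
      t <- 0
    } else {
      qd <- .gy94_q(kappa, omega, pi)
      rho_s1 <- .gy94_q(kappa, 1, pi)$rho_syn
      t <- 3 * rho_s1 * true_ks / qd$rho_syn
      P <- .gy94_pt(.gy94_decompose(qd$Q, pi), t)
      der <- vapply(anc, function(a)
        sample.int(ce$n, 1, prob = P[a, ]), integer(1))
    }
    sa <- paste(ce$codons[anc], collapse = "")
    sb <- paste(ce$codons[der], collapse = "")
    out <- codon_alignment(sa, sb)
    attr(out, "seq_a") <- sa
    attr(out, "seq_b") <- sb
    attr(out, "t") <- t
    out
  })
}
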