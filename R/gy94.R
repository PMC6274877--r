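# Goldman-Yang codon-model likelihoods and the one-ratio / two-ratio
# branch-model likelihood-ratio test.

.patternize <- function(idx) {
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  list(states = idx[, u, drop = FALSE],
       weights = as.numeric(table(key)[key[u]]))
}

.treeParts <- function(tree, idx) {
  miss <- setdiff(tree$tip.label, rownames(idx))
  if (length(miss)) stop("no sequence for tip '", miss[1], "'")
  po <- ape::reorder.phylo(tree, "postorder")
  pat <- .patternize(idx[tree$tip.label, , drop = FALSE])
  list(edge = po$edge, ntip = ape::Ntip(tree),
       nnode = ape::Ntip(tree) + tree$Nnode,
       states = pat$states, weights = pat$weights)
}

.loglikParts <- function(parts, edgeLen, edgeClass, kappa, omegas, pi) {
  st <- .codonStep()
  codon_loglik_cpp(parts$edge, edgeLen, as.integer(edgeClass), kappa,
                   omegas, pi, parts$states, parts$weights,
                   st$TS, st$TV, st$SYN, parts$nnode, parts$ntip)
}

#' Codon-alignment log-likelihood on a tree (Felsenstein pruning)
#'
#' Sums per-site log-likelihoods over the 61 sense-codon states under the
#' Goldman-Yang model, with per-branch omega classes. Underflow is
#' guarded by per-node rescaling. The result is invariant to leaf input
#' order and, for a reversible model, to root placement.
#'
#' @param aln gapped CDS rows (DNAStringSet/character) or a codon-index
#'   matrix from [codonIndexMatrix()]; row names must match tip labels.
#' @param tree `phylo` with non-negative branch lengths (expected
#'   substitutions per codon).
#' @param kappa transition/transversion ratio.
#' @param omega numeric vector of omega values, one per branch class.
#' @param pi codon frequencies (default: F3x4 from the data).
#' @param edgeClass integer vector (postorder edge order) assigning each
#'   edge to an element of `omega`; default all 1.
#' @return total log-likelihood (numeric scalar).
#' @export
codonLogLik <- function(aln, tree, kappa, omega, pi = NULL,
                        edgeClass = NULL) {
  idx <- if (is.matrix(aln)) aln else codonIndexMatrix(aln)
  if (is.null(pi)) pi <- codonFreqsF3x4(idx)
  parts <- .treeParts(tree, idx)
  len <- tree$edge.length[match(paste(parts$edge[, 1], parts$edge[, 2]),
                                paste(tree$edge[, 1], tree$edge[, 2]))]
  if (is.null(len) || anyNA(len)) stop("tree must have branch lengths")
  if (any(len < 0)) stop("negative branch length")
  if (is.null(edgeClass)) edgeClass <- rep(1L, nrow(parts$edge))
  .loglikParts(parts, len, edgeClass, kappa, omega, pi)
}

# L-BFGS-B over log-parameters: theta = (log kappa, log omegas, log lens)
.fitCodonModel <- function(parts, pi, nclass, edgeClass, lenInit,
                           kappaInit = 2, omegaStarts = c(0.1, 0.5, 1.5),
                           tol = 1e-6) {
  E <- length(lenInit)
  lower <- c(log(0.1), rep(log(1e-4), nclass), rep(log(1e-6), E))
  upper <- c(log(20), rep(log(20), nclass), rep(log(20), E))
  obj <- function(theta) {
    -.loglikParts(parts, exp(theta[(nclass + 2):(nclass + 1 + E)]),
                  edgeClass, exp(theta[1]),
                  exp(theta[2:(nclass + 1)]), pi)
  }
  runFrom <- function(start, factr) {
    stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(factr = factr, maxit = 500))
  }
  best <- NULL
  for (w in omegaStarts) {
    start <- c(log(kappaInit), rep(log(w), nclass),
               log(pmin(pmax(lenInit, 1e-4), 19)))
    fit <- runFrom(start, 1e12)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  fit <- runFrom(best$par, tol / .Machine$double.eps / 10)
  if (fit$value > best$value) fit <- best
  theta <- fit$par
  list(lnL = -fit$value, kappa = exp(theta[1]),
       omega = exp(theta[2:(nclass + 1)]),
       lens = exp(theta[(nclass + 2):(nclass + 1 + E)]),
       convergence = fit$convergence)
}

#' Map a foreground specification to postorder edge indices
#'
#' @param tree `phylo`.
#' @param foreground either integer edge indices (postorder order),
#'   a character vector of tip labels (their pendant branches plus the
#'   internal branches of the subtree spanning them when `stem = TRUE`),
#'   or node ids.
#' @param stem include the internal edges of the spanned subtree.
#' @return integer vector of postorder edge indices.
#' @export
foregroundEdges <- function(tree, foreground, stem = TRUE) {
  po <- ape::reorder.phylo(tree, "postorder")$edge
  if (is.numeric(foreground) && all(foreground <= nrow(po)))
    return(as.integer(foreground))
  tips <- match(as.character(foreground), tree$tip.label)
  if (anyNA(tips)) stop("unknown foreground label")
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  nodes <- tips
  if (stem && length(tips) > 1) {
    # all nodes inside the spanning subtree of the tips
    n <- ape::Ntip(tree)
    anc <- .ancestorSets(tree)
    common <- Reduce(intersect, anc[tips])
    mrca <- common[which.max(.nodeDepths(tree)[common])]
    below <- function(v) {
      if (v <= n) return(v)
      c(v, unlist(lapply(kids[[as.character(v)]], below)))
    }
    sub <- below(mrca)
    nodes <- setdiff(sub, mrca)
    nodes <- nodes[vapply(nodes, function(v)
      all(.tipsUnder(tree, v, kids) %in% tips) ||
        v %in% tips, TRUE)]
  }
  which(po[, 2] %in% nodes)
}

#' One-ratio vs two-ratio branch-model likelihood-ratio test
#'
#' Fits the one-ratio model (a single omega shared by every branch) and
#' the two-ratio model (background omega1, foreground omega2) by
#' maximizing the codon likelihood over kappa, omega(s) and all branch
#' lengths (bounded quasi-Newton, multi-start over omega in {0.1, 0.5,
#' 1.5}), and compares them with 2*(lnL1 - lnL0) against chi-square
#' (df = 1).
#'
#' @param aln codon alignment (see [codonLogLik()]).
#' @param tree `phylo` topology; branch lengths, when present, seed the
#'   optimizer.
#' @param foreground foreground branch specification
#'   (see [foregroundEdges()]); must be a non-empty proper subset.
#' @param pi codon frequencies (default F3x4 from data).
#' @return a [BranchModelFit-class].
#' @export
branchModelLrt <- function(aln, tree, foreground, pi = NULL) {
  idx <- if (is.matrix(aln)) aln else codonIndexMatrix(aln)
  if (is.null(pi)) pi <- codonFreqsF3x4(idx)
  parts <- .treeParts(tree, idx)
  E <- nrow(parts$edge)
  fg <- foregroundEdges(tree, foreground)
  if (!length(fg) || length(fg) >= E)
    stop("foreground must be a non-empty proper subset of branches")
  lenInit <- tree$edge.length[match(paste(parts$edge[, 1], parts$edge[, 2]),
                                    paste(tree$edge[, 1], tree$edge[, 2]))]
  if (is.null(lenInit) || anyNA(lenInit)) lenInit <- rep(0.1, E)
  cls0 <- rep(1L, E)
  cls1 <- cls0; cls1[fg] <- 2L
  fit0 <- .fitCodonModel(parts, pi, 1, cls0, lenInit)
  fit1 <- .fitCodonModel(parts, pi, 2, cls1, fit0$lens,
                         kappaInit = fit0$kappa,
                         omegaStarts = unique(c(fit0$omega, 0.1, 0.5, 1.5)))
  if (fit1$lnL < fit0$lnL - 1e-4) {
    fit1b <- .fitCodonModel(parts, pi, 2, cls1, lenInit,
                            omegaStarts = c(0.05, 0.2, 0.8, 2, 5))
    if (fit1b$lnL > fit1$lnL) fit1 <- fit1b
    if (fit1$lnL < fit0$lnL - 1e-4)
      stop("two-ratio fit below one-ratio fit; optimizer failed")
  }
  stat <- max(0, 2 * (fit1$lnL - fit0$lnL))
  new("BranchModelFit", lnL0 = fit0$lnL, lnL1 = fit1$lnL,
      omega = fit0$omega[1], omega1 = fit1$omega[1], omega2 = fit1$omega[2],
      kappa0 = fit0$kappa, kappa1 = fit1$kappa,
      statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      foreground = as.character(foreground),
      branchLengths0 = fit0$lens, branchLengths1 = fit1$lens)
}

#' Pairwise Ka/Ks by maximum likelihood (GY94)
#'
#' Maximizes the two-sequence likelihood over divergence t, kappa and
#' omega with F3x4 codon frequencies estimated from the data, then
#' derives Ka and Ks from the fitted rate matrix: the synonymous and
#' nonsynonymous substitution flows are divided by the corresponding site
#' fractions evaluated at omega = 1.
#'
#' @param cds1,cds2 equal-length in-frame CDS rows.
#' @param pi codon frequencies (default F3x4 from data).
#' @return a [KaKsResult-class] with `method = "ML"`; identical sequences
#'   give Ka = Ks = 0 with `omega` missing.
#' @export
mlPairwiseOmega <- function(cds1, cds2, pi = NULL) {
  idx <- codonIndexMatrix(c(as.character(cds1), as.character(cds2)))
  L <- ncol(idx)
  if (L == 0) stop("no comparable codon columns")
  if (all(idx[1, ] == idx[2, ]))
    return(new("KaKsResult", ka = 0, ks = 0, omega = NA_real_,
               S = NA_real_, N = NA_real_, method = "ML", nCodons = L,
               kappa = NA_real_, t = 0))
  if (is.null(pi)) pi <- codonFreqsF3x4(idx)
  pat <- .patternize(idx)
  w <- pat$weights
  c1 <- pat$states[1, ]; c2 <- pat$states[2, ]
  obj <- function(theta) {
    Q <- codonRateMatrix(exp(theta[2]), exp(theta[3]), pi)
    P <- codonPMatrix(Q, pi, exp(theta[1]))
    p <- pi[c1] * P[cbind(c1, c2)]
    if (any(p <= 0)) return(1e12)
    -sum(w * log(p))
  }
  lower <- log(c(1e-6, 0.1, 1e-4)); upper <- log(c(20, 20, 20))
  best <- NULL
  for (ws in c(0.1, 0.5, 1.5)) {
    fit <- stats::optim(log(c(0.3, 2, ws)), obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e12, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  fit <- stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(factr = 1e9, maxit = 500))
  if (fit$value > best$value) fit <- best
  if (fit$convergence != 0)
    stop("ML pairwise optimizer failed to converge: ", fit$message)
  t <- exp(fit$par[1]); kap <- exp(fit$par[2]); om <- exp(fit$par[3])
  flows <- .rateFlows(kap, om, pi)
  flows1 <- .rateFlows(kap, 1, pi)
  S <- 3 * L * flows1$syn; N <- 3 * L * flows1$nonsyn
  ks <- t * flows$syn / (3 * flows1$syn)
  ka <- t * flows$nonsyn / (3 * flows1$nonsyn)
  new("KaKsResult", ka = ka, ks = ks,
      omega = if (ks == 0) NA_real_ else om,
      S = S, N = N, method = "ML", nCodons = L, kappa = kap, t = t)
}

# proportions of equilibrium substitution flow through synonymous and
# nonsynonymous one-step changes, for a scaled GY94 matrix
.rateFlows <- function(kappa, omega, pi) {
  st <- .codonStep()
  Q <- codonRateMatrix(kappa, omega, pi)
  flow <- pi * Q  # row-scaled
  syn <- sum(flow[st$SYN == 1])
  nonsyn <- sum(flow[(st$TS + st$TV) == 1 & st$SYN == 0])
  tot <- syn + nonsyn
  list(syn = syn / tot, nonsyn = nonsyn / tot)
}

#' Compare pairwise omega distributions between clades
#'
#' Collects the within-clade pairwise omega samples, ranks clade means,
#' and runs Welch two-sample t-tests between clades. Missing omega values
#' are excluded; clades left without values are dropped with a warning.
#'
#' @param omegaByClade named list of numeric vectors (one per clade) or a
#'   data.frame with columns `clade`, `omega`.
#' @return list with `ranking` (clade names, decreasing mean), `means`,
#'   and `tests` (data.frame cladeA, cladeB, t, p).
#' @export
cladeOmegaCompare <- function(omegaByClade) {
  if (is.data.frame(omegaByClade))
    omegaByClade <- split(omegaByClade$omega, omegaByClade$clade)
  omegaByClade <- lapply(omegaByClade, function(x) x[!is.na(x)])
  empty <- lengths(omegaByClade) == 0
  if (any(empty)) {
    warning("clade(s) with no omega values excluded: ",
            paste(names(omegaByClade)[empty], collapse = ", "))
    omegaByClade <- omegaByClade[!empty]
  }
  if (length(omegaByClade) < 2) stop("need at least two clades")
  means <- vapply(omegaByClade, mean, 0)
  ranking <- names(sort(means, decreasing = TRUE))
  pairs <- utils::combn(names(omegaByClade), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- omegaByClade[[pairs[1, k]]]; b <- omegaByClade[[pairs[2, k]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- if (mean(a) == mean(b)) list(statistic = 0, p.value = 1)
            else list(statistic = Inf, p.value = .Machine$double.xmin)
    } else {
      tt <- stats::t.test(a, b)
    }
    data.frame(cladeA = pairs[1, k], cladeB = pairs[2, k],
               t = unname(tt$statistic), p = unname(tt$p.value),
               stringsAsFactors = FALSE)
  }))
  list(ranking = ranking, means = means, tests = tests)
}
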