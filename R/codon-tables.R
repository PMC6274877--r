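# Codon state space: the 61 sense codons of the standard genetic code, in
# alphabetical order. All codon-model code indexes codons by position in
# .codons().

.codonEnv <- new.env(parent = emptyenv())

.codons <- function() {
  if (is.null(.codonEnv$codons)) {
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    .codonEnv$codons <- sense
    .codonEnv$aa <- unname(gc[sense])
  }
  .codonEnv$codons
}

.codonAA <- function() { .codons(); .codonEnv$aa }

# Pairwise single-nucleotide-change structure over the 61 sense codons:
# 61x61 0/1 matrices marking transitions (TS), transversions (TV) and, for
# one-step pairs, synonymy (SYN). Multi-step pairs are 0 everywhere.
.codonStep <- function() {
  if (is.null(.codonEnv$TS)) {
    cod <- .codons(); aa <- .codonAA(); n <- length(cod)
    sp <- do.call(rbind, strsplit(cod, ""))
    TS <- TV <- SYN <- matrix(0, n, n, dimnames = list(cod, cod))
    isTs <- function(x, y) paste0(x, y) %in% c("AG", "GA", "CT", "TC")
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      diff <- which(sp[i, ] != sp[j, ])
      if (length(diff) != 1) next
      if (isTs(sp[i, diff], sp[j, diff])) TS[i, j] <- TS[j, i] <- 1
      else TV[i, j] <- TV[j, i] <- 1
      if (aa[i] == aa[j]) SYN[i, j] <- SYN[j, i] <- 1
    }
    .codonEnv$TS <- TS; .codonEnv$TV <- TV; .codonEnv$SYN <- SYN
  }
  list(TS = .codonEnv$TS, TV = .codonEnv$TV, SYN = .codonEnv$SYN)
}

#' Goldman-Yang (GY94) codon rate matrix
#'
#' Instantaneous rates over the 61 sense codons: 0 for multi-nucleotide
#' changes; otherwise proportional to the target codon frequency, times
#' kappa for transitions, times omega for nonsynonymous changes. The
#' matrix is scaled so the mean substitution rate at equilibrium is 1
#' (branch lengths are then expected substitutions per codon).
#'
#' @param kappa transition/transversion rate ratio.
#' @param omega nonsynonymous/synonymous rate ratio.
#' @param pi codon frequencies (length 61, sums to 1).
#' @param scale rescale to mean rate 1 (default TRUE).
#' @return 61 x 61 rate matrix with rows summing to zero.
#' @export
codonRateMatrix <- function(kappa, omega, pi, scale = TRUE) {
  st <- .codonStep()
  S <- (kappa * st$TS + st$TV) * (st$SYN + omega * (1 - st$SYN) *
                                    (st$TS + st$TV))
  Q <- S * rep(pi, each = length(pi))  # Q_ij ~ pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

#' Codon transition-probability matrix
#'
#' exp(Q t) computed by symmetric eigendecomposition (the GY94 matrix is
#' time-reversible with respect to `pi`).
#'
#' @param Q rate matrix from [codonRateMatrix()].
#' @param pi the equilibrium frequencies used to build `Q`.
#' @param t branch length.
#' @return 61 x 61 stochastic matrix.
#' @export
codonPMatrix <- function(Q, pi, t) {
  d <- sqrt(pi)
  A <- Q * (d %o% (1 / d))  # diag(d) Q diag(1/d), symmetric
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  P <- ((1 / d) * e$vectors) %*% (exp(e$values * t) * t(e$vectors * d))
  P[P < 0] <- 0
  P
}

#' F3x4 codon frequencies from sequences
#'
#' Empirical nucleotide frequencies at each codon position, multiplied and
#' renormalized over the 61 sense codons (the common codeml default).
#'
#' @param cds character vector / DNAStringSet of in-frame coding
#'   sequences, or a codon-index matrix from [codonIndexMatrix()].
#' @return numeric vector of 61 codon frequencies summing to 1.
#' @export
codonFreqsF3x4 <- function(cds) {
  if (!is.matrix(cds)) cds <- codonIndexMatrix(cds)
  cod <- .codons()[as.vector(cds)]
  nt <- unlist(strsplit(cod, ""))
  posIdx <- rep_len(1:3, length(nt))
  f <- vapply(1:3, function(p)
    table(factor(nt[posIdx == p], levels = c("A", "C", "G", "T"))) /
      sum(posIdx == p), numeric(4))
  sp <- do.call(rbind, strsplit(.codons(), ""))
  pi <- f[, 1][sp[, 1]] * f[, 2][sp[, 2]] * f[, 3][sp[, 3]]
  pi <- as.numeric(pi)
  if (any(pi == 0)) pi <- pi + 1e-8  # guard absent states
  pi / sum(pi)
}

#' Codon index matrix from a (gapped) CDS alignment
#'
#' Splits equal-length, in-frame coding sequences into codon columns,
#' removes every codon column containing a gap or ambiguous base in any
#' row (complete deletion, PAL2NAL-style), errors on in-frame stop
#' codons, and returns 1-based indices into the 61 sense codons.
#'
#' @param cds DNAStringSet or character vector of aligned CDS rows.
#' @return integer matrix, rows = sequences, columns = retained codon
#'   sites; attribute `removed` = number of deleted codon columns.
#' @export
codonIndexMatrix <- function(cds) {
  s <- toupper(as.character(cds))
  if (length(unique(nchar(s))) != 1) stop("CDS rows must have equal length")
  if (nchar(s[1]) %% 3 != 0) stop("alignment length must be divisible by 3")
  ncod <- nchar(s[1]) %/% 3
  starts <- seq(1, by = 3, length.out = ncod)
  codRows <- lapply(s, function(x) substring(x, starts, starts + 2))
  codMat <- do.call(rbind, codRows)
  clean <- grepl("^[ACGT]{3}$", codMat)
  dim(clean) <- dim(codMat)
  keep <- colSums(clean) == nrow(codMat)
  codMat <- codMat[, keep, drop = FALSE]
  idx <- match(codMat, .codons())
  dim(idx) <- dim(codMat)
  if (any(is.na(idx))) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1, ]
    stop(sprintf("in-frame stop codon '%s' in row %d",
                 codMat[bad[1], bad[2]], bad[1]))
  }
  rownames(idx) <- if (!is.null(names(cds))) names(cds)
                   else paste0("seq", seq_along(s))
  attr(idx, "removed") <- ncod - sum(keep)
  idx
}
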