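# Nei-Gojobori (1986) counting with Jukes-Cantor correction.
#
# Site counting: each codon position contributes 1 site split between
# synonymous and nonsynonymous in proportion to the fraction of the three
# possible nucleotide changes that are synonymous; changes producing stop
# codons count as nonsynonymous, so every sense codon carries s + n = 3
# sites. Differences: codons differing at k positions are decomposed over
# all k! minimal mutational paths; paths passing through stop codons are
# excluded and the remaining paths weighted equally (if every path is
# blocked, all paths are used).

.ng86SiteCounts <- function() {
  if (!is.null(.codonEnv$ngS)) return(.codonEnv$ngS)
  gc <- Biostrings::GENETIC_CODE
  cod <- .codons()
  s <- vapply(cod, function(c) {
    sp <- strsplit(c, "")[[1]]
    syn <- 0
    for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), sp[p])) {
      alt <- sp; alt[p] <- nt
      altc <- paste(alt, collapse = "")
      if (gc[[altc]] != "*" && gc[[altc]] == gc[[c]]) syn <- syn + 1 / 3
    }
    syn
  }, 0)
  .codonEnv$ngS <- s
  s
}

# per-pair (syn, nonsyn) difference counts averaged over minimal paths
.ng86DiffCounts <- function() {
  if (!is.null(.codonEnv$ngSd)) return(list(Sd = .codonEnv$ngSd,
                                            Nd = .codonEnv$ngNd))
  gc <- Biostrings::GENETIC_CODE
  cod <- .codons(); n <- length(cod)
  sp <- do.call(rbind, strsplit(cod, ""))
  Sd <- Nd <- matrix(0, n, n, dimnames = list(cod, cod))
  stepCount <- function(from, to) {
    # one-nt step between sense codons: c(syn, nonsyn)
    if (gc[[from]] == gc[[to]]) c(1, 0) else c(0, 1)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diff <- which(sp[i, ] != sp[j, ])
    k <- length(diff)
    if (k == 0) next
    perms <- if (k == 1) list(diff) else
      lapply(asplit(.permutations(k), 1), function(o) diff[o])
    paths <- lapply(perms, function(ord) {
      cur <- sp[i, ]
      steps <- matrix(0, 0, 2)
      for (p in ord) {
        nxt <- cur; nxt[p] <- sp[j, p]
        nxtc <- paste(nxt, collapse = "")
        if (gc[[nxtc]] == "*") return(NULL)  # path through a stop
        steps <- rbind(steps, stepCount(paste(cur, collapse = ""), nxtc))
        cur <- nxt
      }
      colSums(steps)
    })
    ok <- !vapply(paths, is.null, TRUE)
    if (!any(ok)) {  # all paths blocked: fall back to all paths incl. stops
      paths <- lapply(perms, function(ord) {
        cur <- sp[i, ]; tot <- c(0, 0)
        for (p in ord) {
          nxt <- cur; nxt[p] <- sp[j, p]
          nxtc <- paste(nxt, collapse = "")
          curc <- paste(cur, collapse = "")
          aaFrom <- gc[[curc]]; aaTo <- gc[[nxtc]]
          tot <- tot + if (aaFrom == aaTo && aaTo != "*") c(1, 0) else c(0, 1)
          cur <- nxt
        }
        tot
      })
      ok <- rep(TRUE, length(paths))
    }
    avg <- colMeans(do.call(rbind, paths[ok]))
    Sd[i, j] <- Sd[j, i] <- avg[1]
    Nd[i, j] <- Nd[j, i] <- avg[2]
  }
  .codonEnv$ngSd <- Sd; .codonEnv$ngNd <- Nd
  list(Sd = Sd, Nd = Nd)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Pairwise Ka/Ks by Nei-Gojobori (NG86) counting
#'
#' Synonymous/nonsynonymous site fractions per codon are averaged over
#' the two sequences; observed differences are decomposed over all
#' minimal mutational paths (equal weights, stop-codon paths excluded);
#' the proportions are corrected for multiple hits by the Jukes-Cantor
#' formula d = -3/4 log(1 - 4p/3).
#'
#' @param cds1,cds2 equal-length in-frame CDS (character or DNAString);
#'   codon columns containing gaps or ambiguous bases are deleted.
#' @return a [KaKsResult-class]; `omega` is NA when Ks = 0.
#' @export
ng86KaKs <- function(cds1, cds2) {
  idx <- codonIndexMatrix(c(as.character(cds1), as.character(cds2)))
  L <- ncol(idx)
  if (L == 0) stop("no comparable codon columns")
  sSites <- .ng86SiteCounts()
  S <- (sum(sSites[idx[1, ]]) + sum(sSites[idx[2, ]])) / 2
  N <- 3 * L - S
  dc <- .ng86DiffCounts()
  ii <- cbind(idx[1, ], idx[2, ])
  Sd <- sum(dc$Sd[ii]); Nd <- sum(dc$Nd[ii])
  # a sequence of e.g. only ATG/TGG codons has S = 0 (and then Sd = 0)
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p, what) {
    if (p >= 3 / 4) stop("saturated: ", what,
                         " proportion exceeds the Jukes-Cantor limit")
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- jc(pS, "synonymous")
  ka <- jc(pN, "nonsynonymous")
  new("KaKsResult", ka = ka, ks = ks,
      omega = if (ks == 0) NA_real_ else ka / ks,
      S = S, N = N, method = "NG86", nCodons = L)
}
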