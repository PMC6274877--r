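# Independent oracles: straight-line implementations of the published
# formulas, kept deliberately separate from the package code paths they
# check (shared published constant tables are data, not code).

# --- protein properties ----------------------------------------------------

.orMass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.orKD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
           E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
           M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V = 4.2)

oracleCharge <- function(aa, pH) {
  pkN <- switch(aa[1], A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, 7.50)
  pos <- 1 / (1 + 10^(pH - pkN))
  for (r in aa) {
    if (r == "K") pos <- pos + 1 / (1 + 10^(pH - 10.0))
    if (r == "R") pos <- pos + 1 / (1 + 10^(pH - 12.0))
    if (r == "H") pos <- pos + 1 / (1 + 10^(pH - 5.98))
  }
  neg <- 1 / (1 + 10^(3.55 - pH))
  for (r in aa) {
    if (r == "D") neg <- neg + 1 / (1 + 10^(4.05 - pH))
    if (r == "E") neg <- neg + 1 / (1 + 10^(4.45 - pH))
    if (r == "C") neg <- neg + 1 / (1 + 10^(9.00 - pH))
    if (r == "Y") neg <- neg + 1 / (1 + 10^(10.00 - pH))
  }
  pos - neg
}

oracleProps <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  mw <- (sum(vapply(aa, function(r) .orMass[[r]], 0)) + 18.01524) / 1000
  gravy <- sum(vapply(aa, function(r) .orKD[[r]], 0)) / n
  molpct <- function(r) 100 * sum(aa == r) / n
  aliph <- molpct("A") + 2.9 * molpct("V") +
    3.9 * (molpct("I") + molpct("L"))
  inst <- if (n < 2) NA_real_ else {
    tot <- 0
    for (k in seq_len(n - 1)) tot <- tot + famevol:::.DIWV[aa[k], aa[k + 1]]
    10 * tot / n
  }
  pI <- stats::uniroot(function(p) oracleCharge(aa, p), c(0, 14),
                       tol = 1e-9)$root
  c(MW = mw, pI = pI, GRAVY = gravy, instability = inst, aliphatic = aliph)
}

randomPeptide <- function(len) {
  paste(sample(names(.orMass), len, replace = TRUE), collapse = "")
}

# --- NG86 site counting ----------------------------------------------------

# brute-force neighbor enumeration: synonymous site count of one codon
oracleNgSites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  sp <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (nt in nts) {
    if (nt == sp[pos]) next
    alt <- sp; alt[pos] <- nt
    altc <- paste(alt, collapse = "")
    if (gc[[altc]] != "*" && gc[[altc]] == gc[[codon]]) syn <- syn + 1
  }
  c(S = syn / 3, N = 3 - syn / 3)
}

senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# --- codon likelihood by exhaustive summation ------------------------------

# rooted 3-leaf tree ((a:ta,b:tb)u:tu,c:tc)r; enumerate the 61^2 internal
# state assignments; transition matrices from Matrix::expm (independent
# of the package's eigendecomposition path)
bruteLoglik3 <- function(states, ta, tb, tu, tc, kappa, omega, pi) {
  Q <- famevol::codonRateMatrix(kappa, omega, pi)
  Pa <- as.matrix(Matrix::expm(Q * ta)); Pb <- as.matrix(Matrix::expm(Q * tb))
  Pu <- as.matrix(Matrix::expm(Q * tu)); Pc <- as.matrix(Matrix::expm(Q * tc))
  tot <- 0
  for (s in seq_len(ncol(states))) {
    a <- states["a", s]; b <- states["b", s]; cc <- states["c", s]
    lik <- 0
    for (r in 1:61) {
      inner <- sum(Pu[r, ] * Pa[, a] * Pb[, b])
      lik <- lik + pi[r] * Pc[r, cc] * inner
    }
    tot <- tot + log(lik)
  }
  tot
}

# --- misc ------------------------------------------------------------------

iupacSets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

speciesSeqSet <- function(seqs, species) {
  xs <- Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(xs) <- S4Vectors::DataFrame(species = species)
  xs
}
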