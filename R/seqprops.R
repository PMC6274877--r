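# Physicochemical constants. Average (not monoisotopic) residue masses in
# daltons; Kyte-Doolittle hydropathy; Bjellqvist pK set as used by the
# common web calculators (N-terminal pK depends on the first residue).
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

.KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.PK_SIDE_POS <- c(K = 10.00, R = 12.00, H = 5.98)
.PK_SIDE_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
.PK_CTERM <- 3.55
.PK_NTERM_DEFAULT <- 7.50
.PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70)

#' Protein physicochemical properties
#'
#' Computes, for one amino-acid sequence, the summary properties commonly
#' reported for plant gene families: length, molecular weight (sum of
#' average residue masses plus one water, in kDa), theoretical isoelectric
#' point (unique root of the net-charge function under the Bjellqvist pK
#' set, found by bisection on \[0, 14\] to 1e-4), GRAVY (mean
#' Kyte-Doolittle hydropathy), instability index (Guruprasad dipeptide
#' weights, 10/L times the sum over the L-1 dipeptides; undefined for
#' length-1 sequences) and aliphatic index
#' (X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu), X in mole percent).
#'
#' @param seq a single protein sequence (character or AAString) using the
#'   20 standard residues; 'X' is not allowed (MW and pI are undefined).
#' @return a one-row data.frame with columns `length`, `MW` (kDa), `pI`,
#'   `GRAVY`, `instability`, `aliphatic`. `instability` is NA for
#'   length-1 sequences.
#' @examples
#' computeProperties("MDEAGKLIV")
#' @export
computeProperties <- function(seq) {
  aa <- strsplit(toupper(as.character(seq)), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- which(!aa %in% .AA_LETTERS)
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  n <- length(aa)
  mw <- (sum(.AA_MASS[aa]) + .WATER_MASS) / 1000
  gravy <- mean(.KYTE_DOOLITTLE[aa])
  comp <- table(factor(aa, levels = .AA_LETTERS)) / n * 100
  aliph <- comp[["A"]] + 2.9 * comp[["V"]] + 3.9 * (comp[["I"]] + comp[["L"]])
  inst <- if (n < 2) NA_real_ else
    10 / n * sum(.DIWV[cbind(aa[-n], aa[-1])])
  data.frame(length = n, MW = mw, pI = isoelectricPoint(aa),
             GRAVY = gravy, instability = inst, aliphatic = aliph)
}

#' Net charge of a protein at a given pH
#'
#' Positive groups (N-terminus, K, R, H) contribute
#' 1/(1 + 10^(pH - pK)); negative groups (C-terminus, D, E, C, Y)
#' contribute -1/(1 + 10^(pK - pH)). Strictly decreasing in pH.
#'
#' @param aa character vector of residues (one per element).
#' @param pH pH value(s).
#' @return net charge (vectorized over `pH`).
#' @export
netCharge <- function(aa, pH) {
  counts <- table(factor(aa, levels = .AA_LETTERS))
  nterm <- aa[1]
  pkN <- if (nterm %in% names(.PK_NTERM)) .PK_NTERM[[nterm]]
         else .PK_NTERM_DEFAULT
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pkN)) +
      sum(counts[names(.PK_SIDE_POS)] / (1 + 10^(p - .PK_SIDE_POS)))
    neg <- 1 / (1 + 10^(.PK_CTERM - p)) +
      sum(counts[names(.PK_SIDE_NEG)] / (1 + 10^(.PK_SIDE_NEG - p)))
    pos - neg
  }, 0)
}

#' Theoretical isoelectric point by bisection
#'
#' @param aa character vector of residues.
#' @param tol bisection tolerance in pH units.
#' @return the pH at which [netCharge()] crosses zero.
#' @export
isoelectricPoint <- function(aa, tol = 1e-4) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (netCharge(aa, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Property table for a protein sequence set
#'
#' Applies [computeProperties()] to every record, yielding a summary table
#' (values reported at full precision; round to 2 decimals for display).
#'
#' @param xs an AAStringSet from [readFastaSet()].
#' @return data.frame with one row per record, rownames = record ids.
#' @export
propertyTable <- function(xs) {
  out <- do.call(rbind, lapply(seq_along(xs),
                               function(i) computeProperties(xs[[i]])))
  rownames(out) <- names(xs)
  cbind(gene_id = names(xs), out)
}
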