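#' Pairwise Ka/Ks estimate
#'
#' Holds a pairwise estimate of the nonsynonymous (Ka) and synonymous (Ks)
#' substitution rates per site, their ratio omega = Ka/Ks, and the
#' synonymous/nonsynonymous site counts, from either Nei-Gojobori (NG86)
#' counting or maximum likelihood under the Goldman-Yang codon model.
#' `omega` is `NA` when Ks = 0 (ratio undefined).
#'
#' @slot ka numeric, nonsynonymous substitutions per nonsynonymous site.
#' @slot ks numeric, synonymous substitutions per synonymous site.
#' @slot omega numeric, Ka/Ks (NA when Ks = 0).
#' @slot S numeric, synonymous site count.
#' @slot N numeric, nonsynonymous site count.
#' @slot method character, "NG86" or "ML".
#' @slot nCodons integer, codon columns used after gap-column deletion.
#' @slot kappa numeric, ML transition/transversion ratio (NA for NG86).
#' @slot t numeric, ML divergence in substitutions per codon (NA for NG86).
#' @export
setClass("KaKsResult",
  representation(ka = "numeric", ks = "numeric", omega = "numeric",
                 S = "numeric", N = "numeric", method = "character",
                 nCodons = "integer", kappa = "numeric", t = "numeric"),
  prototype(kappa = NA_real_, t = NA_real_))

setValidity("KaKsResult", function(object) {
  msg <- character()
  if (length(object@ka) != 1 || (!is.na(object@ka) && object@ka < 0))
    msg <- c(msg, "ka must be a single value >= 0")
  if (length(object@ks) != 1 || (!is.na(object@ks) && object@ks < 0))
    msg <- c(msg, "ks must be a single value >= 0")
  if (!object@method %in% c("NG86", "ML"))
    msg <- c(msg, "method must be 'NG86' or 'ML'")
  if (length(msg)) msg else TRUE
})

#' Branch-model likelihood-ratio test fit
#'
#' Result of fitting the one-ratio (single omega shared by all branches)
#' and two-ratio (background omega1, foreground omega2) Goldman-Yang
#' branch models to a codon alignment on a fixed tree topology, and
#' comparing them by 2*(lnL1 - lnL0) against a chi-square distribution
#' with one degree of freedom.
#'
#' @slot lnL0,lnL1 numeric, log-likelihoods of the one- and two-ratio fits.
#' @slot omega numeric, one-ratio omega estimate.
#' @slot omega1,omega2 numeric, background and foreground omega estimates.
#' @slot kappa0,kappa1 numeric, transition/transversion ratio estimates.
#' @slot statistic numeric, 2*(lnL1 - lnL0).
#' @slot p numeric, chi-square (df = 1) tail probability.
#' @slot foreground character, labels of the foreground branches.
#' @slot branchLengths0,branchLengths1 numeric, fitted branch lengths
#'   (substitutions per codon) in tree edge order.
#' @export
setClass("BranchModelFit",
  representation(lnL0 = "numeric", lnL1 = "numeric", omega = "numeric",
                 omega1 = "numeric", omega2 = "numeric",
                 kappa0 = "numeric", kappa1 = "numeric",
                 statistic = "numeric", p = "numeric",
                 foreground = "character",
                 branchLengths0 = "numeric", branchLengths1 = "numeric"))

setValidity("BranchModelFit", function(object) {
  msg <- character()
  if (object@statistic < -1e-4) msg <- c(msg, "statistic must be >= 0")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Gene-tree / species-tree reconciliation result
#'
#' Duplication events (with their mapped species-tree node and an
#' old/recent age class), per-clade gene losses, and same-species sister
#' pairs inferred by LCA-mapping a rooted gene tree into a rooted species
#' tree. A duplication is "recent" when it maps to a terminal species
#' branch (all descendant genes come from one species) and "old" when it
#' maps to an ancestral (internal) species-tree node, i.e. predates the
#' corresponding radiation.
#'
#' @slot duplications data.frame with columns `node` (gene-tree node id),
#'   `mapped` (species-tree node label), `age` ("old"/"recent").
#' @slot speciations integer, number of internal nodes classed speciation.
#' @slot losses data.frame with columns `clade`, `species`.
#' @slot sisterPairs data.frame with columns `leaf1`, `leaf2`, `species`.
#' @export
setClass("ReconciliationResult",
  representation(duplications = "data.frame", speciations = "integer",
                 losses = "data.frame", sisterPairs = "data.frame"))

setValidity("ReconciliationResult", function(object) {
  msg <- character()
  need <- c("node", "mapped", "age")
  if (!all(need %in% names(object@duplications)))
    msg <- c(msg, "duplications needs columns node, mapped, age")
  else if (nrow(object@duplications) &&
           !all(object@duplications$age %in% c("old", "recent")))
    msg <- c(msg, "age must be 'old' or 'recent'")
  if (length(msg)) msg else TRUE
})

#' Expression matrix with clustering order
#'
#' A genes x conditions matrix of expression values (RPKM or relative
#' expression), the transform applied before clustering, and the row and
#' column orderings from average-linkage hierarchical clustering.
#'
#' @slot values numeric matrix, genes x conditions.
#' @slot transform character, e.g. "log2(x+1)" or "identity".
#' @slot rowOrder,colOrder integer permutations of rows/columns.
#' @slot sd numeric matrix of propagated per-cell standard deviations
#'   (0 x 0 when not applicable).
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", transform = "character",
                 rowOrder = "integer", colOrder = "integer", sd = "matrix"),
  prototype(transform = "identity", sd = matrix(numeric(), 0, 0)))

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@rowOrder) &&
      !identical(sort(object@rowOrder), seq_len(nrow(object@values))))
    msg <- c(msg, "rowOrder must be a permutation of row indices")
  if (length(object@colOrder) &&
      !identical(sort(object@colOrder), seq_len(ncol(object@values))))
    msg <- c(msg, "colOrder must be a permutation of column indices")
  if (length(msg)) msg else TRUE
})
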