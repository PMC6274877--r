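#' RPKM normalization of a read-count matrix
#'
#' RPKM(g, s) = counts(g, s) * 1e9 / (length(g) * libSize(s)) — reads per
#' kilobase of transcript per million mapped reads.
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @param geneLengths numeric vector of transcript lengths in bp (one per
#'   gene).
#' @param libSizes numeric vector of total mapped reads per sample; by
#'   default the column sums.
#' @return an [ExpressionMatrix-class] (no clustering order; see
#'   [clusterOrder()]).
#' @export
rpkm <- function(counts, geneLengths, libSizes = colSums(counts)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(geneLengths <= 0)) stop("gene lengths must be positive")
  if (any(libSizes <= 0)) stop("zero library size")
  v <- counts * 1e9 / outer(geneLengths, libSizes)
  dimnames(v) <- dimnames(counts)
  new("ExpressionMatrix", values = v, transform = "identity",
      rowOrder = integer(), colOrder = integer())
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per gene x sample cell; dCt =
#' Ct_target - Ct_reference (same sample); ddCt = dCt_sample -
#' dCt_calibrator; relative expression = 2^-ddCt. The replicate standard
#' deviation of dCt is propagated and reported per cell.
#'
#' @param ct data.frame with columns `gene`, `sample`, `replicate`, `ct`
#'   (threshold cycles, > 0).
#' @param reference reference (housekeeping) gene id, present in every
#'   sample.
#' @param calibrator calibrator sample id (default: first sample in the
#'   table). Every gene of the calibrator sample has value exactly 1.
#' @return an [ExpressionMatrix-class]; `@sd` holds the per-cell dCt SD.
#' @export
ddct <- function(ct, reference, calibrator = NULL) {
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  samples <- unique(ct$sample)
  genes <- setdiff(unique(ct$gene), reference)
  if (is.null(calibrator)) calibrator <- samples[1]
  miss <- samples[!vapply(samples, function(s)
    reference %in% ct$gene[ct$sample == s], TRUE)]
  if (length(miss))
    stop("reference gene missing in sample: ", miss[1])
  meanCt <- function(g, s) mean(ct$ct[ct$gene == g & ct$sample == s])
  v <- sdm <- matrix(NA_real_, length(genes), length(samples),
                     dimnames = list(genes, samples))
  for (g in genes) {
    dctCal <- meanCt(g, calibrator) - meanCt(reference, calibrator)
    for (s in samples) {
      dct <- meanCt(g, s) - meanCt(reference, s)
      v[g, s] <- 2^-(dct - dctCal)
      reps <- ct$ct[ct$gene == g & ct$sample == s] -
        mean(ct$ct[ct$gene == reference & ct$sample == s])
      sdm[g, s] <- stats::sd(reps)
    }
  }
  new("ExpressionMatrix", values = v, transform = "identity",
      rowOrder = integer(), colOrder = integer(), sd = sdm)
}

#' Hierarchical-clustering order for an expression matrix
#'
#' Transforms the values (default log2(x + 1)), then orders rows (and
#' optionally columns) by agglomerative clustering with the requested
#' linkage and metric. Leaf order is deterministic: ties are resolved by
#' input index, as in [stats::hclust()].
#'
#' @param x an [ExpressionMatrix-class] or numeric matrix.
#' @param transform "log2" (log2(x+1)) or "identity".
#' @param linkage linkage method for [stats::hclust()] (default
#'   "average").
#' @param metric distance metric for [stats::dist()] (default
#'   "euclidean").
#' @param clusterColumns also order columns (default FALSE).
#' @return an [ExpressionMatrix-class] carrying the transformed values
#'   and row/column orders; `attr(, "merges")` on the result's
#'   `rowOrder` holds the merge heights.
#' @export
clusterOrder <- function(x, transform = c("log2", "identity"),
                         linkage = "average", metric = "euclidean",
                         clusterColumns = FALSE) {
  transform <- match.arg(transform)
  m <- if (is(x, "ExpressionMatrix")) x@values else x
  tm <- if (transform == "log2") log2(m + 1) else m
  if (anyNA(tm)) stop("missing values after transform")
  ordOf <- function(mm) {
    if (nrow(mm) < 2) return(list(order = seq_len(nrow(mm)), height = numeric()))
    hc <- stats::hclust(stats::dist(mm, method = metric), method = linkage)
    list(order = hc$order, height = hc$height)
  }
  ro <- ordOf(tm)
  co <- if (clusterColumns) ordOf(t(tm)) else
    list(order = seq_len(ncol(tm)), height = numeric())
  out <- new("ExpressionMatrix", values = tm,
             transform = if (transform == "log2") "log2(x+1)" else "identity",
             rowOrder = as.integer(ro$order), colOrder = as.integer(co$order))
  attr(out@rowOrder, "merges") <- ro$height
  out
}

#' Side-by-side expression and metabolite series with correlation
#'
#' Emits, per gene, its expression series next to a metabolite series
#' (e.g. malic acid content over the same stages) and the Pearson
#' correlation between the two.
#'
#' @param expr an [ExpressionMatrix-class] (genes x stages).
#' @param series numeric vector, one value per stage.
#' @return data.frame with one row per gene: the expression values, the
#'   series values and `pearson`.
#' @export
expressionVsSeries <- function(expr, series) {
  v <- exprValues(expr)
  if (length(series) != ncol(v))
    stop("series length must match the number of stages")
  r <- apply(v, 1, function(row)
    if (stats::sd(row) == 0 || stats::sd(series) == 0) NA_real_
    else stats::cor(row, series))
  data.frame(gene = rownames(v), v,
             t(replicate(nrow(v), series)), pearson = r,
             row.names = NULL, check.names = FALSE)
}
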