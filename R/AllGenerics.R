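#' @title Accessors for famevol result objects
#' @name accessors
#' @param object a famevol result object.
NULL

#' @rdname accessors
#' @export
setGeneric("ka", function(object) standardGeneric("ka"))
#' @rdname accessors
#' @export
setGeneric("ks", function(object) standardGeneric("ks"))
#' @rdname accessors
#' @export
setGeneric("omega", function(object) standardGeneric("omega"))
#' @rdname accessors
#' @export
setGeneric("lrtStatistic", function(object) standardGeneric("lrtStatistic"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("duplications", function(object) standardGeneric("duplications"))
#' @rdname accessors
#' @export
setGeneric("losses", function(object) standardGeneric("losses"))
#' @rdname accessors
#' @export
setGeneric("sisterPairs", function(object) standardGeneric("sisterPairs"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("rowOrder", function(object) standardGeneric("rowOrder"))
#' @rdname accessors
#' @export
setGeneric("colOrder", function(object) standardGeneric("colOrder"))

#' @rdname accessors
#' @export
setMethod("ka", "KaKsResult", function(object) object@ka)
#' @rdname accessors
#' @export
setMethod("ks", "KaKsResult", function(object) object@ks)
#' @rdname accessors
#' @export
setMethod("omega", "KaKsResult", function(object) object@omega)
#' @rdname accessors
#' @export
setMethod("omega", "BranchModelFit",
          function(object) c(omega = object@omega, omega1 = object@omega1,
                             omega2 = object@omega2))
#' @rdname accessors
#' @export
setMethod("lrtStatistic", "BranchModelFit", function(object) object@statistic)
#' @rdname accessors
#' @export
setMethod("pValue", "BranchModelFit", function(object) object@p)
#' @rdname accessors
#' @export
setMethod("duplications", "ReconciliationResult",
          function(object) object@duplications)
#' @rdname accessors
#' @export
setMethod("losses", "ReconciliationResult", function(object) object@losses)
#' @rdname accessors
#' @export
setMethod("sisterPairs", "ReconciliationResult",
          function(object) object@sisterPairs)
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("rowOrder", "ExpressionMatrix", function(object) object@rowOrder)
#' @rdname accessors
#' @export
setMethod("colOrder", "ExpressionMatrix", function(object) object@colOrder)

setMethod("show", "KaKsResult", function(object) {
  cat(sprintf("KaKsResult (%s, %d codons)\n", object@method, object@nCodons))
  cat(sprintf("  Ka = %.4f  Ks = %.4f  omega = %s\n", object@ka, object@ks,
              if (is.na(object@omega)) "NA (Ks = 0)"
              else sprintf("%.2f", object@omega)))
  cat(sprintf("  S = %.2f  N = %.2f\n", object@S, object@N))
  if (!is.na(object@kappa))
    cat(sprintf("  kappa = %.3f  t = %.4f subs/codon\n",
                object@kappa, object@t))
})

setMethod("show", "BranchModelFit", function(object) {
  cat("Branch-model LRT (one-ratio vs two-ratio)\n")
  cat(sprintf("  lnL0 = %.2f (omega = %.2f)\n", object@lnL0, object@omega))
  cat(sprintf("  lnL1 = %.2f (omega1 = %.2f, omega2 = %.2f)\n",
              object@lnL1, object@omega1, object@omega2))
  cat(sprintf("  2*dlnL = %.2f, p = %.3g (chi-square, df = 1)\n",
              object@statistic, object@p))
  cat("  foreground:", paste(object@foreground, collapse = ", "), "\n")
})

setMethod("show", "ReconciliationResult", function(object) {
  d <- object@duplications
  cat(sprintf("ReconciliationResult: %d duplications (%d old, %d recent), %d speciations\n",
              nrow(d), sum(d$age == "old"), sum(d$age == "recent"),
              object@speciations))
  cat(sprintf("  %d losses, %d same-species sister pairs\n",
              nrow(object@losses), nrow(object@sisterPairs)))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d conditions (%s)\n",
              nrow(object@values), ncol(object@values), object@transform))
  if (length(object@rowOrder))
    cat("  row order:", paste(head(rownames(object@values)[object@rowOrder], 6),
                              collapse = ", "),
        if (nrow(object@values) > 6) "..." else "", "\n")
})
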