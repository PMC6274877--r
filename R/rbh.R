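#' Exact local alignment score between two proteins
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap costs
#' (open 11, extend 1), the classic protein-search scoring scheme.
#' Deterministic, no heuristics.
#'
#' @param a,b protein sequences (character or AAString).
#' @return list with `score` (raw alignment score) and `pident` (percent
#'   identity over aligned columns, gap columns excluded).
#' @examples
#' alignScore("AAAA", "AAAA")  # 4 x BLOSUM62(A,A) = 16
#' @export
alignScore <- function(a, b) {
  pa <- pairwiseAlignment(AAString(as.character(a)), AAString(as.character(b)),
                          type = "local", substitutionMatrix = "BLOSUM62",
                          gapOpening = 11, gapExtension = 1)
  nm <- nmatch(pa); nmm <- nmismatch(pa)
  list(score = score(pa),
       pident = if (nm + nmm > 0) 100 * nm / (nm + nmm) else 0)
}

#' All-against-all alignment hit table
#'
#' @param setA,setB species-labeled AAStringSets ([readFastaSet()]).
#' @return data.frame with columns `query`, `subject`, `score`, `pident`.
#' @export
hitTable <- function(setA, setB) {
  out <- expand.grid(query = names(setA), subject = names(setB),
                     stringsAsFactors = FALSE)
  sc <- mapply(function(q, s) {
    r <- alignScore(setA[[q]], setB[[s]])
    c(r$score, r$pident)
  }, out$query, out$subject)
  out$score <- sc[1, ]
  out$pident <- sc[2, ]
  out
}

#' Reciprocal best hits between two proteomes
#'
#' (a, b) is reported iff b is a's unique best scorer in setB and a is
#' b's unique best scorer in setA. Score ties are broken lexicographically
#' by id with a warning. The result is invariant to input record order.
#'
#' @param setA,setB non-empty species-labeled AAStringSets with distinct
#'   species labels.
#' @return data.frame with columns `idA`, `idB`, `speciesA`, `speciesB`,
#'   `score`.
#' @export
reciprocalBestHits <- function(setA, setB) {
  if (!length(setA) || !length(setB)) stop("empty sequence set")
  ht <- hitTable(setA, setB)
  bestIn <- function(tab, by, of) {
    res <- character(0)
    for (q in unique(tab[[by]])) {
      sub <- tab[tab[[by]] == q, ]
      top <- sub[sub$score == max(sub$score), of]
      if (length(top) > 1) {
        warning("score tie for '", q, "'; broken lexicographically")
        top <- sort(top)[1]
      }
      res[q] <- top
    }
    res
  }
  bestAB <- bestIn(ht, "query", "subject")
  bestBA <- bestIn(ht, "subject", "query")
  ids <- sort(names(bestAB))
  keep <- ids[bestBA[bestAB[ids]] == ids]
  spA <- setNames(mcols(setA)$species, names(setA))
  spB <- setNames(mcols(setB)$species, names(setB))
  data.frame(idA = keep, idB = unname(bestAB[keep]),
             speciesA = unname(spA[keep]),
             speciesB = unname(spB[bestAB[keep]]),
             score = ht$score[match(paste(keep, bestAB[keep]),
                                    paste(ht$query, ht$subject))],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expand RBH seed pairs into a gene family
#'
#' Takes the transitive closure of reciprocal-best-hit links and adds
#' within-species hits whose alignment score reaches `scoreFloor`.
#' Deterministic; members are returned sorted.
#'
#' @param seeds data.frame of RBH pairs ([reciprocalBestHits()], columns
#'   `idA`, `idB`), possibly concatenated over several species pairs.
#' @param hits data.frame of within-species (or any extra) hits with
#'   columns `query`, `subject`, `score`; may be NULL.
#' @param scoreFloor minimum raw score for a within-species hit to join
#'   the family (default 50).
#' @return character vector of family member ids.
#' @export
familyExpand <- function(seeds, hits = NULL, scoreFloor = 50) {
  if (is.null(seeds) || !nrow(seeds)) stop("empty seed set")
  edges <- cbind(seeds$idA, seeds$idB)
  if (!is.null(hits) && nrow(hits)) {
    keep <- hits$score >= scoreFloor & hits$query != hits$subject
    if (any(keep)) edges <- rbind(edges, cbind(hits$query[keep],
                                               hits$subject[keep]))
  }
  members <- unique(c(seeds$idA, seeds$idB))
  repeat {
    grow <- unique(c(edges[edges[, 1] %in% members, 2],
                     edges[edges[, 2] %in% members, 1]))
    new <- setdiff(grow, members)
    if (!length(new)) break
    members <- c(members, new)
  }
  sort(members)
}
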