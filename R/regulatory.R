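#' Exon-intron structure of a gene
#'
#' Returns exon intervals in transcription order (reverse of genomic
#' order on the minus strand) and the implied introns between consecutive
#' exons. All coordinates are 1-based inclusive.
#'
#' @param annotations an `AnnotationSet` from [readGff3()].
#' @param geneId gene identifier.
#' @return list with `gene_id`, `strand`, `exons` and `introns`
#'   (2-column start/end matrices, transcription order), `exon_count`.
#' @export
geneStructure <- function(annotations, geneId) {
  if (!geneId %in% names(annotations)) stop("unknown gene: ", geneId)
  g <- annotations[[geneId]]
  ex <- g$exons
  if (!nrow(ex)) stop("gene ", geneId, " has no exon records")
  introns <- matrix(numeric(), 0, 2,
                    dimnames = list(NULL, c("start", "end")))
  if (nrow(ex) > 1) {
    genomic <- ex[order(ex[, 1]), , drop = FALSE]
    introns <- cbind(start = genomic[-nrow(genomic), 2] + 1,
                     end = genomic[-1, 1] - 1)
    if (g$strand == "-")
      introns <- introns[rev(seq_len(nrow(introns))), , drop = FALSE]
  }
  list(gene_id = geneId, strand = g$strand, exons = ex, introns = introns,
       exon_count = nrow(ex))
}

#' Structure table for every gene in an annotation set
#'
#' @param annotations an `AnnotationSet`.
#' @return data.frame with columns `gene_id`, `chromosome`, `strand`,
#'   `exon_count`, `intron_count`.
#' @export
structureTable <- function(annotations) {
  do.call(rbind, lapply(names(annotations), function(g) {
    st <- geneStructure(annotations, g)
    data.frame(gene_id = g, chromosome = annotations[[g]]$chromosome,
               strand = st$strand, exon_count = st$exon_count,
               intron_count = nrow(st$introns), stringsAsFactors = FALSE)
  }))
}

#' Extract a promoter sequence
#'
#' The `length` bases immediately upstream of the translation start on
#' the coding strand (the 5' end of the CDS when CDS records exist,
#' otherwise the 5' end of the gene). On the minus strand this is the
#' reverse complement of the genomic window immediately downstream of the
#' gene end. Truncated at the contig edge with a warning.
#'
#' @param annotations an `AnnotationSet`.
#' @param genome named DNAStringSet of contig sequences.
#' @param geneId gene identifier.
#' @param length promoter length in bp (default 1800, i.e. 1.8 kb).
#' @return a DNAString; attribute `window` holds the genomic coordinates
#'   used (start, end).
#' @export
extractPromoter <- function(annotations, genome, geneId, length = 1800) {
  if (!geneId %in% names(annotations)) stop("unknown gene: ", geneId)
  g <- annotations[[geneId]]
  contig <- genome[[g$chromosome]]
  if (is.null(contig)) stop("contig not in genome: ", g$chromosome)
  anchor <- if (nrow(g$cds)) g$cds else g$exons
  if (g$strand == "+") {
    tss <- min(anchor[, 1])
    from <- tss - length
    if (from < 1) {
      if (tss == 1) stop("gene at contig start: no upstream sequence")
      warning("promoter truncated at contig start (",
              tss - 1, " bp available)")
      from <- 1
    }
    out <- subseq(contig, from, tss - 1)
    win <- c(from, tss - 1)
  } else {
    tss <- max(anchor[, 2])
    to <- tss + length
    if (to > length(contig)) {
      if (tss == length(contig))
        stop("gene at contig end: no upstream sequence")
      warning("promoter truncated at contig end (",
              length(contig) - tss, " bp available)")
      to <- length(contig)
    }
    out <- reverseComplement(subseq(contig, tss + 1, to))
    win <- c(tss + 1, to)
  }
  attr(out, "window") <- win
  out
}

.IUPAC <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

#' Scan a sequence for IUPAC-degenerate motifs
#'
#' Reports every position and strand where a motif pattern matches under
#' IUPAC expansion. Overlapping hits are all reported. Minus-strand hits
#' carry the plus-strand coordinate of the match start and the matched
#' substring as read on the minus strand.
#'
#' @param seq DNA sequence (character or DNAString).
#' @param motifs data.frame with columns `name`, `pattern`
#'   ([readMotifTable()]).
#' @param strands strands to scan, subset of c("+", "-").
#' @return data.frame with columns `motif`, `pattern`, `start`, `strand`,
#'   `match`.
#' @export
scanMotifs <- function(seq, motifs, strands = c("+", "-")) {
  s <- DNAString(as.character(seq))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", motifs$pattern)
  if (any(bad))
    stop("illegal IUPAC code in motif '", motifs$name[bad][1], "'")
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[i]
    if ("+" %in% strands) {
      m <- matchPattern(pat, s, fixed = FALSE)
      if (length(m))
        out[[length(out) + 1]] <- data.frame(
          motif = motifs$name[i], pattern = pat, start = start(m),
          strand = "+", match = as.character(m), stringsAsFactors = FALSE)
    }
    if ("-" %in% strands) {
      m <- matchPattern(reverseComplement(DNAString(pat)), s, fixed = FALSE)
      if (length(m))
        out[[length(out) + 1]] <- data.frame(
          motif = motifs$name[i], pattern = pat, start = start(m),
          strand = "-",
          match = as.character(reverseComplement(DNAStringSet(m))),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), pattern = character(),
                      start = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$motif, res$strand), , drop = FALSE]
}

.iupacMatches <- function(code, base) base %in% .IUPAC[[code]]

#' Classify SNP positions into promoter / exon / intron and test motif
#' disruption
#'
#' Region assignment is purely positional: the promoter window, then the
#' gene's exon intervals, then the introns between them. A motif hit is
#' "altered" by a SNP when the SNP falls inside the hit span and the
#' alternate allele violates the IUPAC code at that motif position
#' (positions whose code admits both alleles are not altered).
#'
#' @param snps data.frame with columns `position` (1-based genomic),
#'   `ref`, `alt` (single bases).
#' @param structure a gene structure from [geneStructure()] (genomic
#'   coordinates).
#' @param promoterWindow numeric length-2 vector (start, end) of the
#'   promoter on the genome.
#' @param motifHits optional data.frame from [scanMotifs()] run on the
#'   promoter, with `promoterStrand` giving how promoter position 1 maps
#'   to the genome: a list with `start` (genomic coordinate of promoter
#'   base 1) and `strand`.
#' @param promoterMap list(start =, strand =) mapping promoter-local
#'   coordinates to the genome; defaults to plus strand starting at
#'   `promoterWindow[1]`.
#' @return data.frame with columns `position`, `region`, `altered_motifs`
#'   (comma-separated, possibly "").
#' @export
classifySnps <- function(snps, structure, promoterWindow,
                         motifHits = NULL, promoterMap = NULL) {
  if (is.null(promoterMap))
    promoterMap <- list(start = promoterWindow[1], strand = "+")
  inIv <- function(p, iv) any(nrow(iv) > 0 & p >= iv[, 1] & p <= iv[, 2])
  out <- lapply(seq_len(nrow(snps)), function(k) {
    p <- snps$position[k]
    region <- if (p >= promoterWindow[1] && p <= promoterWindow[2]) "promoter"
      else if (inIv(p, structure$exons)) "exon"
      else if (inIv(p, structure$introns)) "intron"
      else { warning("SNP at ", p, " outside promoter+gene span"); "other" }
    altered <- character()
    if (region == "promoter" && !is.null(motifHits) && nrow(motifHits)) {
      local <- if (promoterMap$strand == "+") p - promoterMap$start + 1
               else promoterMap$start - p + 1
      alt <- toupper(snps$alt[k])
      if (promoterMap$strand == "-") alt <- chartr("ACGT", "TGCA", alt)
      for (h in seq_len(nrow(motifHits))) {
        w <- nchar(motifHits$pattern[h])
        if (local < motifHits$start[h] || local > motifHits$start[h] + w - 1)
          next
        off <- local - motifHits$start[h] + 1
        code <- if (motifHits$strand[h] == "+")
          substr(motifHits$pattern[h], off, off)
        else substr(motifHits$pattern[h], w - off + 1, w - off + 1)
        allele <- if (motifHits$strand[h] == "+") alt
                  else chartr("ACGT", "TGCA", alt)
        if (!.iupacMatches(code, allele))
          altered <- c(altered, motifHits$motif[h])
      }
    }
    data.frame(position = p, region = region,
               altered_motifs = paste(unique(altered), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
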