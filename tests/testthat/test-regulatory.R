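mkAnn <- function(...) {
  genes <- list(...)
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  class(genes) <- "AnnotationSet"
  genes
}

plusGene <- list(gene_id = "gP", chromosome = "c1", strand = "+",
                 exons = rbind(c(start = 2001, end = 2100),
                               c(start = 2201, end = 2300)),
                 cds = matrix(numeric(), 0, 2,
                              dimnames = list(NULL, c("start", "end"))))
minusGene <- list(gene_id = "gM", chromosome = "c1", strand = "-",
                  exons = rbind(c(start = 1200, end = 1300),
                                c(start = 1000, end = 1100)),
                  cds = matrix(numeric(), 0, 2,
                               dimnames = list(NULL, c("start", "end"))))

test_that("gene structures imply introns in transcription order", {
  ann <- mkAnn(plusGene, minusGene)
  st <- geneStructure(ann, "gP")
  expect_equal(st$exon_count, 2)
  expect_equal(unname(st$introns[1, ]), c(2101, 2200))
  stm <- geneStructure(ann, "gM")
  # minus strand: first exon has the larger genomic coordinate
  expect_equal(unname(stm$exons[1, ]), c(1200, 1300))
  expect_equal(unname(stm$introns[1, ]), c(1101, 1199))
  expect_error(geneStructure(ann, "nope"), "unknown gene")
})

test_that("promoters are taken upstream on the coding strand", {
  set.seed(61)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  ann <- mkAnn(plusGene, minusGene)
  p <- extractPromoter(ann, genome, "gP", length = 1800)
  expect_equal(length(p), 1800)
  expect_equal(as.character(p), substr(contig, 201, 2000))
  # minus strand: reverse complement of the window downstream in genome
  pm <- extractPromoter(ann, genome, "gM", length = 500)
  expect_equal(as.character(pm),
               revcomp(substr(contig, 1301, 1800)))
  # truncation at the contig edge
  shortGene <- plusGene; shortGene$gene_id <- "gS"
  shortGene$exons <- rbind(c(start = 1000, end = 1100))
  ann2 <- mkAnn(shortGene)
  expect_warning(ps <- extractPromoter(ann2, genome, "gS", length = 1800),
                 "truncated")
  expect_equal(length(ps), 999)
  edgeGene <- plusGene; edgeGene$gene_id <- "gE"
  edgeGene$exons <- rbind(c(start = 1, end = 100))
  expect_error(extractPromoter(mkAnn(edgeGene), genome, "gE"),
               "no upstream")
})

test_that("IUPAC motif scanning matches on both strands", {
  mot <- data.frame(name = c("TATA-box", "As"),
                    pattern = c("TATWWAAW", "TGACG"))
  hits <- scanMotifs("TATTAAAA", mot)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1)
  expect_equal(hits$strand, "+")
  # TGACG matches CGTCA on the minus strand
  h2 <- scanMotifs("CGTCA", mot)
  expect_equal(h2$motif, "As")
  expect_equal(h2$strand, "-")
  expect_equal(h2$match, "TGACG")
  expect_error(scanMotifs("ACGT", data.frame(name = "x", pattern = "AC?T")),
               "IUPAC")
})

test_that("scanning a sequence and its reverse complement mirrors hits", {
  set.seed(62)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  mot <- data.frame(name = c("m1", "m2"), pattern = c("TATWWAAW", "RRYGACG"))
  h <- scanMotifs(seq, mot)
  hr <- scanMotifs(revcomp(seq), mot)
  expect_equal(nrow(h), nrow(hr))
  if (nrow(h)) {
    w <- nchar(mot$pattern[match(h$motif, mot$name)])
    mirrored <- sort(nchar(seq) - (h$start + w - 1) + 1)
    expect_equal(sort(hr$start), mirrored)
  }
})

test_that("every reported hit re-validates against its pattern", {
  set.seed(63)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
  mot <- data.frame(name = c("a", "b", "c"),
                    pattern = c("WWAA", "CCNNGG", "TRYAT"))
  h <- scanMotifs(seq, mot)
  for (k in seq_len(nrow(h))) {
    pat <- strsplit(h$pattern[k], "")[[1]]
    obs <- strsplit(h$match[k], "")[[1]]
    expect_true(all(mapply(function(code, base)
      base %in% iupacSets[[code]], pat, obs)))
  }
})

test_that("SNPs are classified by region and motif disruption re-checked", {
  structure <- list(gene_id = "g", strand = "+",
                    exons = rbind(c(start = 1801, end = 2000),
                                  c(start = 2101, end = 2300)),
                    introns = rbind(c(start = 2001, end = 2100)),
                    exon_count = 2)
  promoterWindow <- c(1, 1800)
  hits <- data.frame(motif = "TATA-box", pattern = "TATWWAAW",
                     start = 100, strand = "+", match = "TATTAAAA")
  snps <- data.frame(position = c(1900, 2050, 103, 100, 2500),
                     ref = c("A", "A", "T", "T", "A"),
                     alt = c("G", "G", "T", "G", "C"))
  expect_warning(ann <- classifySnps(snps, structure, promoterWindow, hits),
                 "outside")
  expect_equal(ann$region, c("exon", "intron", "promoter", "promoter",
                             "other"))
  # position 103 is a W slot (A/T allowed): alt T does not break the motif
  expect_equal(ann$altered_motifs[3], "")
  # position 100 is the fixed leading T: alt G breaks it
  expect_equal(ann$altered_motifs[4], "TATA-box")
})

test_that("minus-strand motif hits are re-checked on the right base", {
  # As element TGACG planted on the minus strand: promoter shows CGTCA
  hits <- data.frame(motif = "As", pattern = "TGACG",
                     start = 11, strand = "-", match = "TGACG")
  structure <- list(gene_id = "g", strand = "+",
                    exons = rbind(c(start = 101, end = 200)),
                    introns = matrix(numeric(), 0, 2),
                    exon_count = 1)
  snps <- data.frame(position = c(11), ref = "C", alt = "A")
  ann <- classifySnps(snps, structure, c(1, 100), hits)
  expect_equal(ann$region, "promoter")
  expect_equal(ann$altered_motifs, "As")
})
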