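#' Read a FASTA file into a species-labeled sequence set
#'
#' Reads protein or DNA FASTA and attaches a species label to each record.
#' The species is taken from a configurable '|'-separated header field
#' (default: second field), and a species map (see [readSpeciesMap()])
#' overrides header parsing when supplied.
#'
#' @param path FASTA file path.
#' @param alphabet "protein" or "dna".
#' @param speciesMap optional named character vector (names = record ids)
#'   mapping ids to species; overrides header-derived species.
#' @param speciesField 1-based index of the '|'-separated header field
#'   holding the species (the first field is the record id).
#' @param gapped allow the gap character '-' (for pre-aligned FASTA).
#' @return An [Biostrings::AAStringSet] or [Biostrings::DNAStringSet] with
#'   record ids as names and a `species` column in `mcols()`.
#' @export
readFastaSet <- function(path, alphabet = c("protein", "dna"),
                         speciesMap = NULL, speciesField = 2L,
                         gapped = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  xs <- if (alphabet == "protein") readAAStringSet(path)
        else readDNAStringSet(path)
  headers <- names(xs)
  fields <- strsplit(headers, "|", fixed = TRUE)
  ids <- vapply(fields, function(f) sub("\\s.*$", "", f[[1]]), "")
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1])
  species <- vapply(fields, function(f)
    if (length(f) >= speciesField) f[[speciesField]] else NA_character_, "")
  if (!is.null(speciesMap)) {
    hit <- ids %in% names(speciesMap)
    species[hit] <- unname(speciesMap[ids[hit]])
  }
  names(xs) <- ids
  .checkAlphabet(xs, ids, alphabet, gapped)
  mcols(xs) <- DataFrame(species = species)
  xs
}

.checkAlphabet <- function(xs, ids, alphabet, gapped = FALSE) {
  ok <- if (alphabet == "protein") .AA_LETTERS_X else c("A", "C", "G", "T", "N", "-")
  if (gapped) ok <- unique(c(ok, "-"))
  for (i in seq_along(xs)) {
    ch <- strsplit(as.character(xs[[i]]), "")[[1]]
    bad <- which(!ch %in% ok)
    if (length(bad))
      stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                   alphabet, ch[bad[1]], ids[i], bad[1]))
  }
  invisible(TRUE)
}

#' Write a species-labeled sequence set as FASTA
#'
#' Headers are written as `id|species` (plain `id` when the species is NA)
#' so that [readFastaSet()] round-trips records exactly.
#'
#' @param xs an XStringSet as returned by [readFastaSet()].
#' @param path output file path.
#' @export
writeFastaSet <- function(xs, path) {
  sp <- mcols(xs)$species
  out <- xs
  names(out) <- ifelse(is.na(sp) | is.null(sp), names(xs),
                       paste(names(xs), sp, sep = "|"))
  writeXStringSet(out, path)
  invisible(path)
}

#' Read a species map TSV (gene_id <TAB> species)
#'
#' @param path two-column TSV without header.
#' @return named character vector, names = gene ids.
#' @export
readSpeciesMap <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("species map needs two columns: gene_id, species")
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read gene annotations from GFF3
#'
#' Parses gene/mRNA/exon (and CDS) features and groups exon intervals per
#' gene. Coordinates follow the public data model: 1-based, inclusive.
#' Minus-strand exon lists are stored in transcription order (descending
#' genomic coordinate). Exons whose Parent chain does not resolve to a
#' gene are skipped with a warning; malformed lines raise an error naming
#' the line number.
#'
#' @param path GFF3 file path.
#' @return a list of class `AnnotationSet`: one element per gene, each a
#'   list with `gene_id`, `chromosome`, `strand`, `exons` (2-column matrix
#'   start/end in transcription order) and `cds` (same shape, possibly
#'   0-row).
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9))
    stop("malformed GFF3 line ", body[which(nf != 9)[1]],
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  md$type <- as.character(md$type)
  getAttr <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v[[1]]) else NA_character_, "")
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA, nrow(md))
  parent <- if ("Parent" %in% names(md)) getAttr(md$Parent)
            else rep(NA_character_, nrow(md))
  geneRows <- which(md$type == "gene")
  geneIds <- id[geneRows]
  mrna2gene <- setNames(parent[md$type == "mRNA"], id[md$type == "mRNA"])
  resolveGene <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% geneIds) return(p)
    if (p %in% names(mrna2gene)) return(mrna2gene[[p]])
    NA_character_
  }
  ann <- lapply(seq_along(geneRows), function(k) {
    g <- geneRows[k]
    list(gene_id = geneIds[k], chromosome = as.character(md$seqnames[g]),
         strand = as.character(md$strand[g]),
         exons = matrix(numeric(), 0, 2,
                        dimnames = list(NULL, c("start", "end"))),
         cds = matrix(numeric(), 0, 2,
                      dimnames = list(NULL, c("start", "end"))))
  })
  names(ann) <- geneIds
  for (ft in c("exon", "CDS")) {
    rows <- which(md$type == ft)
    for (r in rows) {
      gene <- resolveGene(parent[r])
      if (is.na(gene) || !gene %in% names(ann)) {
        warning(sprintf("%s at %s:%d-%d has no parent gene; skipped",
                        ft, md$seqnames[r], md$start[r], md$end[r]))
        next
      }
      slot <- if (ft == "exon") "exons" else "cds"
      ann[[gene]][[slot]] <- rbind(ann[[gene]][[slot]],
                                   c(start = md$start[r], end = md$end[r]))
    }
  }
  for (g in names(ann)) {
    for (slot in c("exons", "cds")) {
      iv <- ann[[g]][[slot]]
      if (nrow(iv)) {
        if (any(iv[, 1] > iv[, 2])) stop("interval start > end in gene ", g)
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
          stop("overlapping ", slot, " in gene ", g)
        if (ann[[g]]$strand == "-")
          iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
        ann[[g]][[slot]] <- iv
      }
    }
  }
  class(ann) <- "AnnotationSet"
  ann
}

#' Read a Newick tree
#'
#' Branch lengths and internal-node support labels are preserved; an
#' unrooted tree is represented with a trifurcating root, as in
#' [ape::read.tree()].
#'
#' @param path Newick file path.
#' @return an [ape] `phylo` object.
#' @export
readNewick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  if (.parenBalance(txt) != 0L)
    stop("unbalanced parentheses in Newick file: ", path)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}

.parenBalance <- function(txt) {
  ch <- strsplit(txt, "")[[1]]
  sum(ch == "(") - sum(ch == ")")
}

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output file path.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a cis-element motif table (TSV: name, pattern, annotation)
#'
#' Patterns use IUPAC one-letter nucleotide codes. An entry whose pattern
#' contains '/' lists alternative patterns sharing one name; it is split
#' into one row per alternative.
#'
#' @param path TSV path with a header row.
#' @return data.frame with columns `name`, `pattern`, `annotation`.
#' @export
readMotifTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("name", "pattern")
  if (ncol(df) < 3) df$annotation <- "" else names(df)[3] <- "annotation"
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    pats <- strsplit(df$pattern[i], "/", fixed = TRUE)[[1]]
    data.frame(name = df$name[i], pattern = toupper(pats),
               annotation = df$annotation[i], stringsAsFactors = FALSE)
  }))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", out$pattern)
  if (any(bad))
    stop("illegal IUPAC code in motif '", out$name[bad][1], "': ",
         out$pattern[bad][1])
  out
}

#' Read a run configuration (YAML)
#'
#' A single YAML document with per-stage sections. Every stochastic stage
#' (bootstrap, simulate) must carry an explicit integer `seed`.
#'
#' @param path YAML file path.
#' @return named list of stage parameter lists.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read run configurations")
  cfg <- yaml::read_yaml(path)
  stochastic <- intersect(names(cfg), c("bootstrap", "simulate"))
  for (s in stochastic)
    if (is.null(cfg[[s]]$seed) || cfg[[s]]$seed != as.integer(cfg[[s]]$seed))
      stop("stage '", s, "' needs an explicit integer seed")
  cfg
}

.AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_LETTERS_X <- c(.AA_LETTERS, "X")
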