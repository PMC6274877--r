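# Synthetic-data generators. Every generator takes an explicit integer
# seed and returns, beside the data, a ground-truth log that downstream
# stages are tested against. Truth-log quantities are computed with
# simulator-local bookkeeping (species sets, ancestor chains), not with
# the inference code they are used to check.

#' Simulate a gene family by birth-death along a species tree
#'
#' One gene lineage enters the species-tree root edge. Along every
#' species branch each lineage duplicates at rate `lambda` and is lost at
#' rate `mu` (independent Poisson processes); at a species-tree node each
#' surviving lineage splits into the descendant branches; lineages
#' surviving to the species tips become genes (named
#' `<species>_g<k>`). Extinct inner branches are pruned, so the returned
#' gene tree is the observable one. Internal nodes are labeled `d<k>`
#' (duplication) or `s<k>` (speciation).
#'
#' The truth log classifies every surviving duplication as it would
#' appear to a topology-based observer: `age` is "recent" when the
#' surviving descendant genes come from a single species and "old"
#' otherwise, and `detectable` is TRUE when the species mappings of its
#' two surviving child lineages are nested in the species tree (a
#' duplication both of whose sides survive only in disjoint,
#' non-comparable parts of the species tree leaves no topological
#' signature and cannot be recovered by any reconciliation).
#'
#' @param speciesTree rooted `phylo` with branch lengths in time units.
#' @param lambda duplication rate per gene per time unit.
#' @param mu loss rate per gene per time unit.
#' @param seed integer seed (mandatory).
#' @param rootEdge length of the stem edge above the species-tree root.
#' @param maxRetry resample attempts when fewer than two genes survive
#'   (an error is raised after `maxRetry` failures).
#' @param retryExtinct resample when fewer than two genes survive
#'   (default). With `FALSE` the outcome of the first draw is returned
#'   as-is (`geneTree = NULL`, `size` 0 or 1), which keeps family-size
#'   statistics unbiased.
#' @return list with `geneTree` (phylo, NULL when `size < 2`), `size`
#'   (surviving gene count), `truth` (list: `duplications` data.frame
#'   with columns node label/species branch/age/detectable,
#'   `nLossEvents`, `absentSpecies`, `speciesMap`).
#' @export
simulateGeneFamily <- function(speciesTree, lambda, mu, seed,
                               rootEdge = 0.1, maxRetry = 100,
                               retryExtinct = TRUE) {
  stopifnot(lambda >= 0, mu >= 0)
  set.seed(as.integer(seed))
  ns <- ape::Ntip(speciesTree)
  kids <- split(speciesTree$edge[, 2], speciesTree$edge[, 1])
  elen <- setNames(speciesTree$edge.length, speciesTree$edge[, 2])
  parent <- integer(ns + speciesTree$Nnode)
  parent[speciesTree$edge[, 2]] <- speciesTree$edge[, 1]
  ancChain <- function(v) { p <- v; while (parent[v] != 0) { v <- parent[v]; p <- c(p, v) }; p }
  spLabel <- function(v) if (v <= ns) speciesTree$tip.label[v] else paste0("n", v)

  for (attempt in seq_len(maxRetry)) {
    env <- new.env()
    env$leaf <- 0L; env$dup <- 0L; env$spec <- 0L; env$nloss <- 0L
    env$dups <- list()

    evolve <- function(spNode, tRemain) {
      # returns NULL (extinct) or list(nwk=, stem=, species=set); stem is
      # the time from this lineage's birth to the subtree's top node
      elapsed <- 0
      repeat {
        wait <- if (lambda + mu > 0) stats::rexp(1, lambda + mu) else Inf
        if (wait >= tRemain) break
        tRemain <- tRemain - wait
        elapsed <- elapsed + wait
        if (stats::runif(1) < mu / (lambda + mu)) {
          env$nloss <- env$nloss + 1L
          return(NULL)
        }
        left <- evolve(spNode, tRemain)
        right <- evolve(spNode, tRemain)
        if (is.null(left) && is.null(right)) return(NULL)
        if (is.null(left) || is.null(right)) {
          surv <- if (is.null(left)) right else left
          surv$stem <- surv$stem + elapsed
          return(surv)
        }
        env$dup <- env$dup + 1L
        lab <- paste0("d", env$dup)
        spp <- union(left$species, right$species)
        age <- if (length(spp) == 1) "recent" else "old"
        # nestedness of the two sides' species-tree mappings
        lcaOf <- function(spset) {
          nodes <- match(spset, speciesTree$tip.label)
          Reduce(function(a, b) {
            ca <- ancChain(a); cb <- ancChain(b)
            ca[ca %in% cb][1]
          }, nodes)
        }
        ml <- lcaOf(left$species); mr <- lcaOf(right$species)
        detectable <- ml %in% ancChain(mr) || mr %in% ancChain(ml)
        env$dups[[lab]] <- data.frame(
          node = lab, speciesBranch = spLabel(spNode), age = age,
          detectable = detectable, stringsAsFactors = FALSE)
        return(list(nwk = sprintf("(%s:%.8f,%s:%.8f)%s",
                                  left$nwk, left$stem, right$nwk, right$stem,
                                  lab),
                    stem = elapsed, species = spp))
      }
      # reached the end of this species branch
      if (spNode <= ns) {
        env$leaf <- env$leaf + 1L
        leaf <- paste0(speciesTree$tip.label[spNode], "_g", env$leaf)
        return(list(nwk = leaf, stem = elapsed + tRemain,
                    species = speciesTree$tip.label[spNode]))
      }
      ch <- kids[[as.character(spNode)]]
      sub <- lapply(ch, function(c) evolve(c, elen[[as.character(c)]]))
      sub <- sub[!vapply(sub, is.null, TRUE)]
      if (!length(sub)) return(NULL)
      if (length(sub) == 1) {
        s <- sub[[1]]
        s$stem <- s$stem + elapsed + tRemain
        return(s)
      }
      env$spec <- env$spec + 1L
      lab <- paste0("s", env$spec)
      nwk <- paste0("(", paste(vapply(sub, function(s)
        sprintf("%s:%.8f", s$nwk, s$stem), ""), collapse = ","), ")", lab)
      list(nwk = nwk, stem = elapsed + tRemain,
           species = Reduce(union, lapply(sub, `[[`, "species")))
    }

    res <- evolve(ns + 1L, rootEdge)
    dups <- if (length(env$dups)) do.call(rbind, env$dups) else
      data.frame(node = character(), speciesBranch = character(),
                 age = character(), detectable = logical(),
                 stringsAsFactors = FALSE)
    rownames(dups) <- NULL
    if (!is.null(res) && grepl(",", res$nwk)) {
      tree <- ape::read.tree(text = paste0(res$nwk, ";"))
      sp <- sub("_.*$", "", tree$tip.label)
      truth <- list(duplications = dups[order(dups$node), , drop = FALSE],
                    nLossEvents = env$nloss,
                    absentSpecies = setdiff(speciesTree$tip.label, sp),
                    speciesMap = setNames(sp, tree$tip.label))
      return(list(geneTree = tree, size = ape::Ntip(tree), truth = truth))
    }
    if (!retryExtinct) {
      size <- if (is.null(res)) 0L else 1L
      sp <- if (is.null(res)) character() else res$species
      return(list(geneTree = NULL, size = size,
                  truth = list(duplications = dups,
                               nLossEvents = env$nloss,
                               absentSpecies = setdiff(speciesTree$tip.label, sp),
                               speciesMap = setNames(sp, character(length(sp))))))
    }
  }
  stop("fewer than two genes survived in ", maxRetry, " attempts")
}

#' Evolve a codon alignment along a tree under the Goldman-Yang model
#'
#' The root sequence is drawn from `pi`; each branch applies the
#' transition matrix exp(Q t) of the scaled GY94 rate matrix with that
#' branch's omega class. No gaps are introduced.
#'
#' @param tree `phylo` with branch lengths (expected substitutions per
#'   codon).
#' @param nCodons alignment length in codons.
#' @param kappa transition/transversion ratio.
#' @param omega numeric vector, one omega per branch class.
#' @param pi codon frequencies (default uniform over the 61 sense
#'   codons).
#' @param edgeClass integer per-edge class (postorder order; default all
#'   1).
#' @param seed integer seed (mandatory).
#' @return DNAStringSet of ungapped CDS rows, one per tip; attribute
#'   `rootCodons` holds the root states (indices).
#' @export
evolveCodons <- function(tree, nCodons, kappa, omega, pi = NULL,
                         edgeClass = NULL, seed) {
  set.seed(as.integer(seed))
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- nrow(po$edge)
  if (is.null(edgeClass)) edgeClass <- rep(1L, E)
  n <- ape::Ntip(tree)
  nodes <- n + tree$Nnode
  states <- vector("list", nodes)
  root <- po$edge[E, 1]
  states[[root]] <- sample.int(61, nCodons, replace = TRUE, prob = pi)
  Qs <- lapply(seq_along(omega), function(c)
    codonRateMatrix(kappa, omega[c], pi))
  for (e in rev(seq_len(E))) {  # preorder: parents before children
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    P <- codonPMatrix(Qs[[edgeClass[e]]], pi, po$edge.length[e])
    from <- states[[par]]
    out <- integer(nCodons)
    for (s in unique(from)) {
      sel <- from == s
      out[sel] <- sample.int(61, sum(sel), replace = TRUE, prob = P[s, ])
    }
    states[[child]] <- out
  }
  cod <- .codons()
  seqs <- vapply(seq_len(n), function(i)
    paste(cod[states[[i]]], collapse = ""), "")
  out <- DNAStringSet(setNames(seqs, tree$tip.label))
  attr(out, "rootCodons") <- states[[root]]
  out
}

#' Generate a promoter + gene locus with planted motifs and SNPs
#'
#' Builds a plus-strand locus: a promoter of `promoterLength` bp followed
#' by a gene with the requested exon/intron sizes. Motif instances
#' (concrete sequences satisfying each IUPAC pattern) are planted at
#' non-overlapping logged positions on random strands within the
#' promoter; SNPs are placed in the promoter, exons and introns per the
#' requested counts, with logged alleles.
#'
#' @param motifs data.frame `name`, `pattern` ([readMotifTable()]); one
#'   instance of each is planted.
#' @param promoterLength promoter length in bp (default 1800).
#' @param exonLengths,intronLengths numeric vectors of exon and intron
#'   sizes (length of `intronLengths` must be one less).
#' @param snpCounts named numeric vector with elements `promoter`,
#'   `exon`, `intron`.
#' @param gc background GC content (default 0.5).
#' @param seed integer seed (mandatory).
#' @return list: `locus` (DNAString), `promoterWindow`, `structure` (as
#'   [geneStructure()]), `motifLog` (name, start, strand, instance;
#'   promoter-local 1-based start of the plus-strand match),
#'   `snpLog` (position, region, ref, alt).
#' @export
generatePromoter <- function(motifs, promoterLength = 1800,
                             exonLengths = c(300, 300, 300),
                             intronLengths = c(150, 150),
                             snpCounts = c(promoter = 5, exon = 2, intron = 2),
                             gc = 0.5, seed) {
  set.seed(as.integer(seed))
  stopifnot(length(intronLengths) == length(exonLengths) - 1)
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  geneLen <- sum(exonLengths) + sum(intronLengths)
  total <- promoterLength + geneLen
  locus <- sample(bases, total, replace = TRUE, prob = pb)
  # plant motifs, non-overlapping
  occupied <- logical(promoterLength)
  motifLog <- list()
  for (i in seq_len(nrow(motifs))) {
    w <- nchar(motifs$pattern[i])
    inst <- vapply(strsplit(motifs$pattern[i], "")[[1]],
                   function(code) sample(.IUPAC[[code]], 1), "")
    strand <- sample(c("+", "-"), 1)
    planted <- if (strand == "+") inst else
      rev(chartr("ACGT", "TGCA", inst))
    ok <- FALSE
    for (try in seq_len(200)) {
      pos <- sample.int(promoterLength - w + 1, 1)
      if (!any(occupied[pos:(pos + w - 1)])) { ok <- TRUE; break }
    }
    if (!ok) stop("requested motifs do not fit in the promoter")
    locus[pos:(pos + w - 1)] <- planted
    occupied[pos:(pos + w - 1)] <- TRUE
    motifLog[[i]] <- data.frame(name = motifs$name[i],
                                pattern = motifs$pattern[i], start = pos,
                                strand = strand,
                                instance = paste(inst, collapse = ""),
                                stringsAsFactors = FALSE)
  }
  # gene model (plus strand, exons/introns alternating)
  exStart <- promoterLength + 1
  exons <- matrix(0, length(exonLengths), 2,
                  dimnames = list(NULL, c("start", "end")))
  introns <- matrix(0, length(intronLengths), 2,
                    dimnames = list(NULL, c("start", "end")))
  p <- exStart
  for (k in seq_along(exonLengths)) {
    exons[k, ] <- c(p, p + exonLengths[k] - 1)
    p <- p + exonLengths[k]
    if (k <= length(intronLengths)) {
      introns[k, ] <- c(p, p + intronLengths[k] - 1)
      p <- p + intronLengths[k]
    }
  }
  structure <- list(gene_id = "simgene", strand = "+", exons = exons,
                    introns = introns, exon_count = nrow(exons))
  # SNPs
  pickIn <- function(iv, k) {
    pool <- unlist(lapply(seq_len(nrow(iv)), function(r) iv[r, 1]:iv[r, 2]))
    sample(pool, k)
  }
  snpPos <- c(if (snpCounts[["promoter"]] > 0)
                sample.int(promoterLength, snpCounts[["promoter"]]),
              if (snpCounts[["exon"]] > 0) pickIn(exons, snpCounts[["exon"]]),
              if (snpCounts[["intron"]] > 0)
                pickIn(introns, snpCounts[["intron"]]))
  region <- rep(c("promoter", "exon", "intron"),
                c(snpCounts[["promoter"]], snpCounts[["exon"]],
                  snpCounts[["intron"]]))
  snpLog <- data.frame(position = snpPos, region = region,
                       ref = locus[snpPos],
                       alt = vapply(locus[snpPos], function(b)
                         sample(setdiff(bases, b), 1), ""),
                       stringsAsFactors = FALSE)
  list(locus = DNAString(paste(locus, collapse = "")),
       promoterWindow = c(1, promoterLength), structure = structure,
       motifLog = do.call(rbind, motifLog), snpLog = snpLog)
}

#' Generate RNA-seq counts and qPCR Ct tables with known truth
#'
#' Counts are drawn negative-binomially around means implied by a true
#' expression profile (so that RPKM recovers the profile up to noise);
#' replicate Ct values are drawn normally around
#' `offset - log2(relative expression)` so that the 2^-ddCt method
#' recovers the configured fold changes.
#'
#' @param expr genes x samples matrix of true expression levels (RPKM
#'   scale); the first column doubles as the qPCR calibrator sample.
#' @param geneLengths transcript lengths in bp.
#' @param libSizes mapped reads per sample.
#' @param dispersion negative-binomial dispersion (0 = deterministic
#'   rounding of the means).
#' @param ctSd replicate standard deviation of the Ct values (cycles).
#' @param nReplicates biological replicates per cell (default 3).
#' @param reference name of the reference gene added to the Ct table.
#' @param seed integer seed (mandatory).
#' @return list: `counts` (matrix), `ct` (data.frame gene/sample/
#'   replicate/ct), `truth` (list with `expr`, `relExpr`).
#' @export
generateCountsAndCt <- function(expr, geneLengths,
                                libSizes = rep(2e7, ncol(expr)),
                                dispersion = 0.05, ctSd = 0.15,
                                nReplicates = 3, reference = "ref",
                                seed) {
  set.seed(as.integer(seed))
  mu <- expr * outer(geneLengths, libSizes) / 1e9
  counts <- if (dispersion == 0) round(mu) else
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow(mu), dimnames = dimnames(mu))
  rel <- expr / expr[, 1]  # relative to the calibrator sample
  genes <- rownames(expr)
  samples <- colnames(expr)
  grid <- expand.grid(replicate = seq_len(nReplicates), sample = samples,
                      gene = c(genes, reference),
                      stringsAsFactors = FALSE)[, 3:1]
  offset <- 25
  ctVal <- function(g, s) {
    if (g == reference) return(20)
    offset - log2(rel[g, s])
  }
  grid$ct <- mapply(function(g, s) ctVal(g, s), grid$gene, grid$sample) +
    stats::rnorm(nrow(grid), 0, ctSd)
  list(counts = counts, ct = grid,
       truth = list(expr = expr, relExpr = rel))
}
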