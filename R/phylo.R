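#' Pairwise p-distance matrix from a protein alignment
#'
#' p-distance = proportion of differing residues among compared columns.
#' Under pairwise deletion (the default), each pair is compared over the
#' columns where both rows are non-gap; under complete deletion, columns
#' containing any gap are removed first.
#'
#' @param aln an aligned AAStringSet/DNAStringSet or a character matrix
#'   (rows = sequences, one residue per cell), gap character '-'.
#' @param deletion "pairwise" or "complete".
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pDistance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- .alnMatrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences")
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop(sprintf("no shared non-gap columns between '%s' and '%s'",
                   rownames(m)[i], rownames(m)[j]))
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

.alnMatrix <- function(aln) {
  if (is.matrix(aln)) {
    if (is.null(rownames(aln)))
      rownames(aln) <- paste0("seq", seq_len(nrow(aln)))
    return(aln)
  }
  if (length(unique(width(aln))) != 1)
    stop("alignment rows must have equal length")
  m <- t(vapply(seq_along(aln),
                function(i) strsplit(as.character(aln[[i]]), "")[[1]],
                character(width(aln)[1])))
  rownames(m) <- names(aln)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively join the pair minimizing the
#' Q-criterion, with branch lengths from the standard NJ formulas.
#' Q-ties are broken by the lowest index pair (row-major), so the result
#' is deterministic. Negative branch-length estimates are clamped to 0
#' with a message. The returned tree is unrooted (trifurcating root).
#'
#' @param D symmetric distance matrix with taxa dimnames, n >= 3.
#' @return an [ape] `phylo` object.
#' @export
njTree <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  # each active element carries a growing newick substring
  nwk <- labs
  d <- D
  clamped <- FALSE
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(d) > 3) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    # lowest-index tie-break: scan column-major over upper triangle
    best <- c(NA, NA); bq <- Inf
    for (i in seq_len(r - 1)) for (j in (i + 1):r)
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0 || lj < 0) clamped <- TRUE
    li <- max(li, 0); lj <- max(lj, 0)
    newRow <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newRow[keep]),
               c(newRow[keep], 0))
    nwk <- c(nwk[keep], merged)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) clamped <- TRUE
  if (clamped) message("negative NJ branch length estimate(s) clamped to 0")
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(max(la, 0)),
                 nwk[2], fmt(max(lb, 0)), nwk[3], fmt(max(lc, 0)))
  ape::read.tree(text = txt)
}

# canonical bipartition keys of the internal edges of an unrooted tree;
# each key is the sorted tip set on the side not containing the reference
# tip, so keys are comparable across differently-rooted replicates
.bipartitionKeys <- function(tree, ref = NULL) {
  labs <- tree$tip.label
  if (is.null(ref)) ref <- sort(labs)[1]
  pp <- ape::prop.part(tree)
  ids <- attr(pp, "labels")
  n <- length(labs)
  keys <- vapply(seq_along(pp), function(k) {
    side <- ids[pp[[k]]]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1 || length(side) >= n - 1) return(NA_character_)
    paste(sort(side), collapse = "\r")
  }, "")
  names(keys) <- seq_along(pp) + n  # internal node numbers
  keys
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `replicates` times, rebuilds the NJ tree for
#' each replicate, and sets the support of each internal branch to the
#' percentage of replicates containing the same bipartition. A replicate
#' in which some pair shares no non-gap column is redrawn (at most 10
#' times, then an error is raised). Reproducible given `seed`.
#'
#' @param aln aligned sequences (see [pDistance()]).
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param deletion passed to [pDistance()].
#' @return a `phylo` tree whose `node.label` holds percent support
#'   (NA on the root).
#' @export
bootstrapSupport <- function(aln, replicates = 1000, seed, deletion = "pairwise") {
  m <- .alnMatrix(aln)
  tree <- njTree(pDistance(m, deletion))
  keys <- .bipartitionKeys(tree)
  hits <- setNames(numeric(length(keys)), names(keys))
  set.seed(as.integer(seed))
  for (b in seq_len(replicates)) {
    for (try in seq_len(10)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      db <- tryCatch(pDistance(m[, cols, drop = FALSE], deletion),
                     error = function(e) NULL)
      if (!is.null(db)) break
      message("bootstrap replicate ", b, " redrawn (incomparable pair)")
      db <- NULL
    }
    if (is.null(db)) stop("bootstrap replicate failed after 10 redraws")
    rkeys <- .bipartitionKeys(njTree(db))
    hits <- hits + (keys %in% rkeys)
  }
  supp <- round(100 * hits / replicates, 6)
  supp[is.na(keys)] <- NA  # root pseudo-bipartition
  tree$node.label <- as.character(supp)
  tree
}

#' Midpoint-root a tree
#'
#' @param tree unrooted `phylo` tree with branch lengths.
#' @return rooted `phylo` tree (support labels preserved by phangorn).
#' @export
midpointRoot <- function(tree) phangorn::midpoint(tree)

#' Assign clades from bootstrap support
#'
#' A clade is a maximal subtree whose subtending branch has support at
#' least `minSupport` percent. Clades are labeled with Roman numerals
#' I, II, ... in depth-first order from the root; leaves not inside any
#' supported subtree are unassigned (NA).
#'
#' @param tree rooted `phylo` tree with `node.label` percent supports.
#' @param minSupport minimum percent support (default 50).
#' @return data.frame with columns `leaf`, `clade`.
#' @export
assignClades <- function(tree, minSupport = 50) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted (root it first)")
  n <- ape::Ntip(tree)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  clade <- setNames(rep(NA_character_, n), tree$tip.label)
  counter <- 0L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tipsBelow <- function(v) {
    if (v <= n) return(v)
    unlist(lapply(kids[[as.character(v)]], tipsBelow))
  }
  root <- n + 1L
  visit <- function(v) {
    if (v <= n) return(invisible())
    s <- if (v == root) NA else supp[v - n]
    if (!is.na(s) && s >= minSupport) {
      counter <<- counter + 1L
      clade[tree$tip.label[tipsBelow(v)]] <<- as.character(utils::as.roman(counter))
    } else {
      for (ch in kids[[as.character(v)]]) visit(ch)
    }
  }
  visit(root)
  data.frame(leaf = tree$tip.label, clade = unname(clade[tree$tip.label]),
             stringsAsFactors = FALSE)
}
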