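#' LCA-mapping reconciliation of a gene tree into a species tree
#'
#' Maps every gene-tree node to the most recent common ancestor (in the
#' species tree) of the species of its descendant genes. An internal
#' gene-tree node is a duplication when it maps to the same species-tree
#' node as at least one of its children, otherwise a speciation. A
#' duplication is classed "recent" when its mapped node is a species-tree
#' leaf (a within-species duplication) and "old" when it maps to an
#' ancestral node, i.e. the event predates the corresponding species
#' radiation. At a multifurcation (soft polytomy, e.g. after collapsing
#' weakly supported branches) a duplication is only inferred when some
#' species occurs in more than one child subtree.
#'
#' @param geneTree rooted `phylo` gene tree.
#' @param speciesTree rooted `phylo` species tree whose tip labels cover
#'   every species in the gene set.
#' @param speciesMap named character vector mapping gene leaf labels to
#'   species; leaves named `species_gene` are parsed automatically when
#'   NULL.
#' @param collapseBelow optional support threshold; branches of
#'   `geneTree` with support below it are collapsed to polytomies before
#'   reconciliation (NULL = no collapsing).
#' @return a [ReconciliationResult-class] (losses empty; see
#'   [inferLosses()]).
#' @export
lcaReconcile <- function(geneTree, speciesTree, speciesMap = NULL,
                         collapseBelow = NULL) {
  if (!ape::is.rooted(geneTree)) stop("gene tree must be rooted")
  if (!ape::is.rooted(speciesTree)) stop("species tree must be rooted")
  if (!is.null(collapseBelow))
    geneTree <- collapseWeakBranches(geneTree, collapseBelow)
  sp <- .resolveSpecies(geneTree$tip.label, speciesMap)
  if (any(!sp %in% speciesTree$tip.label))
    stop("gene leaf '", geneTree$tip.label[!sp %in% speciesTree$tip.label][1],
         "' maps to species absent from the species tree")
  ns <- ape::Ntip(speciesTree)
  sAnc <- .ancestorSets(speciesTree)
  sDepth <- .nodeDepths(speciesTree)
  sLca <- function(nodes) {
    nodes <- unique(nodes)
    if (length(nodes) == 1) return(nodes)
    common <- Reduce(intersect, sAnc[nodes])
    common[which.max(sDepth[common])]
  }
  ng <- ape::Ntip(geneTree)
  kids <- split(geneTree$edge[, 2], geneTree$edge[, 1])
  M <- integer(ng + geneTree$Nnode)
  spNodeLabel <- function(v) {
    if (v <= ns) speciesTree$tip.label[v]
    else if (!is.null(speciesTree$node.label) &&
             nzchar(speciesTree$node.label[v - ns]))
      speciesTree$node.label[v - ns]
    else paste0("node", v)
  }
  dup <- data.frame(node = integer(), mapped = character(),
                    age = character(), stringsAsFactors = FALSE)
  nSpec <- 0L
  internalPO <- unique(ape::reorder.phylo(geneTree, "postorder")$edge[, 1])
  for (v in seq_len(ng))
    M[v] <- match(sp[geneTree$tip.label[v]], speciesTree$tip.label)
  for (v in internalPO) {  # children before parents
    ch <- kids[[as.character(v)]]
    M[v] <- sLca(M[ch])
    isDup <- if (length(ch) == 2) any(M[ch] == M[v]) else {
      chSpecies <- lapply(ch, function(c) unique(sp[geneTree$tip.label[.tipsUnder(geneTree, c, kids)]]))
      any(table(unlist(chSpecies)) > 1)
    }
    if (isDup) {
      age <- if (M[v] <= ns) "recent" else "old"
      dup <- rbind(dup, data.frame(node = v, mapped = spNodeLabel(M[v]),
                                   age = age, stringsAsFactors = FALSE))
    } else nSpec <- nSpec + 1L
  }
  new("ReconciliationResult", duplications = dup, speciations = nSpec,
      losses = data.frame(clade = character(), species = character(),
                          stringsAsFactors = FALSE),
      sisterPairs = findSisterPairs(geneTree, speciesMap = speciesMap))
}

.tipsUnder <- function(tree, v, kids = NULL) {
  n <- ape::Ntip(tree)
  if (is.null(kids)) kids <- split(tree$edge[, 2], tree$edge[, 1])
  if (v <= n) return(v)
  unlist(lapply(kids[[as.character(v)]], function(c) .tipsUnder(tree, c, kids)))
}

# ancestor sets (self included) and root-distance depths for LCA queries
.ancestorSets <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(n + tree$Nnode), function(v) {
    path <- v
    while (parent[v] != 0) { v <- parent[v]; path <- c(path, v) }
    path
  })
}

.nodeDepths <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_len(n + tree$Nnode), function(v) {
    d <- 0L
    while (parent[v] != 0) { v <- parent[v]; d <- d + 1L }
    d
  }, 0L)
}

.resolveSpecies <- function(leaves, speciesMap) {
  if (!is.null(speciesMap)) {
    miss <- setdiff(leaves, names(speciesMap))
    if (length(miss)) stop("no species mapping for gene leaf '", miss[1], "'")
    return(speciesMap[leaves])
  }
  setNames(sub("_.*$", "", leaves), leaves)
}

#' Collapse weakly supported branches to polytomies
#'
#' @param tree `phylo` with numeric `node.label` supports.
#' @param minSupport branches with support below this are collapsed.
#' @return `phylo`, possibly multifurcating.
#' @export
collapseWeakBranches <- function(tree, minSupport) {
  supp <- suppressWarnings(as.numeric(tree$node.label))
  if (is.null(tree$node.label)) return(tree)
  n <- ape::Ntip(tree)
  weak <- which(!is.na(supp) & supp < minSupport) + n
  root <- n + 1L
  weak <- setdiff(weak, root)
  if (!length(weak)) return(tree)
  # zero the subtending branch lengths and let ape collapse them
  tree$edge.length[tree$edge[, 2] %in% weak] <- 0
  ape::di2multi(tree, tol = 1e-12)
}

#' Per-clade gene-loss inference
#'
#' Following the clade-completeness assumption (each gene clade should
#' contain at least one member from every species), a loss is recorded
#' for every species absent from a clade.
#'
#' @param clades data.frame with columns `leaf`, `clade`
#'   ([assignClades()]), or a named character vector leaf -> clade.
#' @param speciesSet character vector of all species under study.
#' @param speciesMap named vector mapping leaves to species (NULL =
#'   parse `species_gene` leaf names).
#' @return data.frame with columns `clade`, `species` (one row per loss).
#' @export
inferLosses <- function(clades, speciesSet, speciesMap = NULL) {
  if (is.data.frame(clades))
    clades <- setNames(clades$clade, clades$leaf)
  sp <- .resolveSpecies(names(clades), speciesMap)
  out <- data.frame(clade = character(), species = character(),
                    stringsAsFactors = FALSE)
  for (cl in unique(stats::na.omit(clades))) {
    present <- unique(sp[names(clades)[clades == cl & !is.na(clades)]])
    missing <- setdiff(speciesSet, present)
    if (length(missing))
      out <- rbind(out, data.frame(clade = cl, species = sort(missing),
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Same-species sister pairs (cherries)
#'
#' Finds two-leaf subtrees whose leaves come from the same species -- the
#' signature of a recent (tandem) duplication.
#'
#' @param geneTree rooted `phylo`.
#' @param speciesMap named vector mapping leaves to species (NULL =
#'   parse `species_gene` leaf names).
#' @return data.frame with columns `leaf1`, `leaf2`, `species`.
#' @export
findSisterPairs <- function(geneTree, speciesMap = NULL) {
  sp <- .resolveSpecies(geneTree$tip.label, speciesMap)
  n <- ape::Ntip(geneTree)
  kids <- split(geneTree$edge[, 2], geneTree$edge[, 1])
  out <- data.frame(leaf1 = character(), leaf2 = character(),
                    species = character(), stringsAsFactors = FALSE)
  for (v in names(kids)) {
    ch <- kids[[v]]
    if (length(ch) == 2 && all(ch <= n)) {
      l1 <- geneTree$tip.label[ch[1]]; l2 <- geneTree$tip.label[ch[2]]
      if (sp[l1] == sp[l2]) {
        pair <- sort(c(l1, l2))
        out <- rbind(out, data.frame(leaf1 = pair[1], leaf2 = pair[2],
                                     species = unname(sp[l1]),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$leaf1), , drop = FALSE]
}
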