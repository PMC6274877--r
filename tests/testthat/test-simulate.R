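stree4 <- ape::read.tree(text = "(((A:0.3,B:0.3):0.2,C:0.5):0.2,D:0.7);")

test_that("zero rates give a species-congruent gene tree with no events", {
  sim <- simulateGeneFamily(stree4, 0, 0, seed = 1)
  expect_equal(sort(sub("_.*", "", sim$geneTree$tip.label)),
               sort(stree4$tip.label))
  expect_equal(nrow(sim$truth$duplications), 0)
  expect_equal(sim$truth$nLossEvents, 0)
  gt <- sim$geneTree
  gt$tip.label <- sub("_.*", "", gt$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(gt), ape::unroot(stree4)), 0,
               ignore_attr = TRUE)
})

test_that("family simulation is reproducible under a fixed seed", {
  s1 <- simulateGeneFamily(stree4, 0.3, 0.1, seed = 99)
  s2 <- simulateGeneFamily(stree4, 0.3, 0.1, seed = 99)
  expect_identical(ape::write.tree(s1$geneTree), ape::write.tree(s2$geneTree))
  expect_identical(s1$truth, s2$truth)
})

test_that("mean surviving family size tracks the birth-death expectation", {
  # species branch A of length 1; the zero-length Z branch always keeps
  # exactly one gene, so the A-gene count has E[N(1)] = exp(lambda - mu)
  st <- ape::read.tree(text = "(A:1.0,Z:0);")
  lambda <- 0.5; mu <- 0.2
  sizes <- vapply(1:600, function(i) {
    sim <- simulateGeneFamily(st, lambda, mu, seed = 20000 + i,
                              rootEdge = 0, retryExtinct = FALSE)
    if (is.null(sim$geneTree)) sim$size - 1 else
      sum(grepl("^A_", sim$geneTree$tip.label))
  }, 0)
  expected <- exp((lambda - mu) * 1.0)
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 4 * se + 0.02)
})

test_that("codon simulation is stationary and seed-reproducible", {
  tr <- ape::read.tree(text = "(a:0.01,b:3.0);")
  set.seed(81)
  pi <- as.numeric(rexp(61) + 0.2); pi <- pi / sum(pi)
  sim <- evolveCodons(tr, 20000, kappa = 2, omega = 0.5, pi = pi, seed = 7)
  idxB <- codonIndexMatrix(as.character(sim["b"]))
  emp <- tabulate(idxB, 61) / length(idxB)
  expect_lt(max(abs(emp - pi)), 0.01)  # long-branch leaf stays at pi
  sim2 <- evolveCodons(tr, 20000, kappa = 2, omega = 0.5, pi = pi, seed = 7)
  expect_identical(as.character(sim), as.character(sim2))
  # zero branch lengths: leaves equal the root sequence
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  sim0 <- evolveCodons(tr0, 50, kappa = 2, omega = 0.5, seed = 3)
  expect_equal(as.character(sim0)[["a"]], as.character(sim0)[["b"]])
})

test_that("the simulator's transition kernel matches a matrix exponential", {
  set.seed(82)
  pi <- rep(1 / 61, 61)
  Q <- codonRateMatrix(1.8, 0.35, pi)
  for (t in c(0.05, 0.4, 1.2)) {
    P1 <- codonPMatrix(Q, pi, t)
    P2 <- as.matrix(Matrix::expm(Q * t))
    expect_lt(max(abs(P1 - P2)), 1e-9)
    expect_equal(rowSums(P1), rep(1, 61), tolerance = 1e-9)
  }
})

test_that("likelihood at the true parameters beats perturbed parameters", {
  tr <- ape::unroot(ape::read.tree(
    text = "((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);"))
  wins <- 0
  for (k in 1:10) {
    sim <- evolveCodons(tr, 300, kappa = 2, omega = 0.3, seed = 8200 + k)
    idx <- codonIndexMatrix(as.character(sim))
    pi <- codonFreqsF3x4(idx)
    lTrue <- codonLogLik(idx, tr, 2, 0.3, pi)
    lPert <- codonLogLik(idx, tr, 2, 1.2, pi)
    wins <- wins + (lTrue > lPert)
  }
  expect_gte(wins, 8)
})

test_that("planted motifs and SNP regions are recovered from the log", {
  tab <- data.frame(name = c("TATA-box", "GT1", "As"),
                    pattern = c("TATWWAAW", "GGTTAA", "TGACG"))
  g <- generatePromoter(tab, promoterLength = 600,
                        snpCounts = c(promoter = 4, exon = 2, intron = 2),
                        seed = 9)
  prom <- Biostrings::subseq(g$locus, 1, 600)
  hits <- scanMotifs(prom, tab)
  for (k in seq_len(nrow(g$motifLog)))
    expect_true(any(hits$motif == g$motifLog$name[k] &
                    hits$start == g$motifLog$start[k] &
                    hits$strand == g$motifLog$strand[k]))
  ann <- classifySnps(g$snpLog, g$structure, g$promoterWindow, hits)
  expect_equal(ann$region, g$snpLog$region)
  # reproducible
  g2 <- generatePromoter(tab, promoterLength = 600,
                         snpCounts = c(promoter = 4, exon = 2, intron = 2),
                         seed = 9)
  expect_identical(as.character(g$locus), as.character(g2$locus))
  expect_error(generatePromoter(tab, promoterLength = 12, seed = 1,
                                snpCounts = c(promoter = 1, exon = 0,
                                              intron = 0)),
               "do not fit|invalid")
})

test_that("count and Ct generation recover the configured truth", {
  set.seed(84)
  expr <- matrix(c(10, 40, 5, 10, 80, 5), 3,
                 dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  len <- c(1000, 2000, 500)
  # zero-dispersion limit: counts equal their rounded means
  g0 <- generateCountsAndCt(expr, len, dispersion = 0, ctSd = 0, seed = 5)
  mu <- expr * outer(len, rep(2e7, 2)) / 1e9
  expect_equal(g0$counts, round(mu))
  e0 <- exprValues(rpkm(g0$counts, len, rep(2e7, 2)))
  expect_equal(e0, expr, tolerance = 0.02)
  r0 <- ddct(g0$ct, "ref", "s1")
  expect_equal(exprValues(r0)[rownames(expr), ], expr / expr[, 1],
               tolerance = 1e-9)
  # noisy case: recovery up to sampling error
  g1 <- generateCountsAndCt(expr, len, dispersion = 0.02, ctSd = 0.1,
                            seed = 6)
  e1 <- exprValues(rpkm(g1$counts, len, rep(2e7, 2)))
  expect_lt(max(abs(e1 - expr) / expr), 0.5)
  r1 <- ddct(g1$ct, "ref", "s1")
  expect_lt(max(abs(log2(exprValues(r1)[rownames(expr), ]) -
                    log2(expr / expr[, 1]))), 0.5)
})
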