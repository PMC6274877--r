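# a 50-codon frame used to dilute single-codon changes below saturation
frame50 <- paste(rep("GCTATTCGTGAAAAA", 10), collapse = "")

test_that("NG86 handles identical and single-change pairs", {
  r0 <- ng86KaKs(frame50, frame50)
  expect_equal(ka(r0), 0)
  expect_equal(ks(r0), 0)
  expect_true(is.na(omega(r0)))
  # one synonymous third-position change: Ka = 0, Ks > 0, omega = 0
  s2 <- paste0(substr(frame50, 1, nchar(frame50) - 3), "AAG")  # AAA -> AAG
  r1 <- ng86KaKs(frame50, s2)
  expect_equal(ka(r1), 0)
  expect_gt(ks(r1), 0)
  expect_equal(omega(r1), 0)
  # one nonsynonymous change: Ks = 0 so omega missing
  s3 <- sub("^GCT", "CCT", frame50)  # Ala -> Pro
  r2 <- ng86KaKs(frame50, s3)
  expect_gt(ka(r2), 0)
  expect_true(is.na(omega(r2)))
  # S + N = 3 x codons, always
  for (r in list(r0, r1, r2)) expect_equal(r@S + r@N, 3 * r@nCodons)
})

test_that("NG86 signals Jukes-Cantor saturation", {
  expect_error(ng86KaKs("TTTAAA", "TTCAAG"), "saturated")
})

test_that("gap and ambiguous codon columns are deleted before counting", {
  a <- paste0("ATG", "---", "AAA")
  b <- paste0("ATG", "CCC", "AAG")
  idx <- codonIndexMatrix(c(a, b))
  expect_equal(ncol(idx), 2)
  expect_equal(attr(idx, "removed"), 1)
  expect_error(codonIndexMatrix(c("ATGTAA", "ATGCCC")), "stop codon")
})

test_that("the GY94 rate matrix is a proper scaled generator", {
  set.seed(51)
  pi <- as.numeric(rexp(61) + 0.1)
  pi <- pi / sum(pi)
  Q <- codonRateMatrix(2, 0.5, pi)
  expect_lt(max(abs(rowSums(Q))), 1e-10)
  expect_lt(max(abs(pi %*% Q)), 1e-10)       # stationarity
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)  # mean rate 1
  # detailed balance (time reversibility)
  expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)
})

test_that("zero-length branches give site likelihood pi_c", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  pi <- rep(1 / 61, 61)
  idx <- rbind(a = 5L, b = 5L)
  expect_equal(codonLogLik(idx, tr, 2, 1, pi), log(pi[5]))
})

test_that("the total log-likelihood ignores leaf input order", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,c:0.15);")
  sim <- evolveCodons(tr, 40, kappa = 2, omega = 0.4, seed = 8)
  idx <- codonIndexMatrix(as.character(sim))
  pi <- codonFreqsF3x4(idx)
  l1 <- codonLogLik(idx, tr, 2, 0.4, pi)
  l2 <- codonLogLik(idx[c("c", "a", "b"), ], tr, 2, 0.4, pi)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("fitted branch lengths sit at a local maximum", {
  tr <- ape::unroot(ape::read.tree(
    text = "((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1);"))
  sim <- evolveCodons(tr, 200, kappa = 2, omega = 0.3, seed = 52)
  fit <- branchModelLrt(as.character(sim), tr, foreground = "A")
  idx <- codonIndexMatrix(as.character(sim))
  pi <- codonFreqsF3x4(idx)
  po <- ape::reorder.phylo(tr, "postorder")
  tr2 <- tr
  tr2$edge.length[match(paste(po$edge[, 1], po$edge[, 2]),
                        paste(tr$edge[, 1], tr$edge[, 2]))] <-
    fit@branchLengths0
  base <- codonLogLik(idx, tr2, fit@kappa0, fit@omega, pi)
  expect_equal(base, fit@lnL0, tolerance = 1e-6)
  for (e in c(1, 3)) {
    for (eps in c(-0.02, 0.02)) {
      pert <- tr2
      pert$edge.length[e] <- max(1e-6, pert$edge.length[e] + eps)
      expect_lte(codonLogLik(idx, pert, fit@kappa0, fit@omega, pi),
                 base + 1e-6)
    }
  }
})

test_that("identical sequences make the pairwise ML omega unidentifiable", {
  r <- mlPairwiseOmega(frame50, frame50)
  expect_true(is.na(omega(r)))
  expect_equal(r@t, 0)
})

test_that("pairwise ML recovers a moderate simulated omega", {
  tr <- ape::read.tree(text = "(x:0.25,y:0.25);")
  sim <- evolveCodons(tr, 500, kappa = 2, omega = 0.5, seed = 42)
  fit <- mlPairwiseOmega(as.character(sim)[1], as.character(sim)[2])
  expect_equal(fit@method, "ML")
  expect_gt(omega(fit), 0.3)
  expect_lt(omega(fit), 0.8)
  expect_equal(fit@S + fit@N, 3 * fit@nCodons, tolerance = 1e-6)
})

test_that("the branch-model LRT is a valid nested comparison", {
  tr <- ape::unroot(ape::read.tree(
    text = "((A:0.15,B:0.15):0.1,(C:0.15,D:0.15):0.1);"))
  sim <- evolveCodons(tr, 300, kappa = 2, omega = 0.2, seed = 101)
  fit <- branchModelLrt(as.character(sim), tr, foreground = "A")
  expect_gte(fit@lnL1, fit@lnL0 - 1e-4)
  expect_gte(lrtStatistic(fit), 0)
  expect_gt(pValue(fit), 0)
  expect_lte(pValue(fit), 1)
  expect_error(branchModelLrt(as.character(sim), tr,
                              foreground = c("A", "B", "C", "D")),
               "proper subset")
})

test_that("clade omega comparisons rank means and test differences", {
  same <- list(I = c(0.2, 0.2, 0.2), II = c(0.2, 0.2, 0.2))
  r <- cladeOmegaCompare(same)
  expect_equal(r$tests$t, 0)
  expect_equal(r$tests$p, 1)
  far <- list(lo = rep(0.1, 10) + rnorm(10, 0, 1e-3),
              hi = rep(0.9, 10) + rnorm(10, 0, 1e-3))
  r2 <- cladeOmegaCompare(far)
  expect_lt(r2$tests$p, 0.01)
  expect_equal(r2$ranking, c("hi", "lo"))
  expect_warning(cladeOmegaCompare(list(a = c(0.1, 0.2), b = c(0.3, 0.4),
                                        c = c(NA_real_, NA_real_))),
                 "excluded")
})
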