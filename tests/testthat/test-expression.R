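test_that("RPKM follows the definition and its identities", {
  cm <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  e <- rpkm(cm, geneLengths = c(1000, 500), libSizes = 1e6)
  expect_equal(exprValues(e)["g1", "s1"], 10)
  expect_equal(exprValues(e)["g2", "s1"], 0)
  expect_error(rpkm(cm, c(1000, 500), 0), "zero library size")

  # scale invariance and the column-sum identity on random matrices
  set.seed(71)
  for (k in 1:5) {
    ng <- sample(5:20, 1); ns <- sample(2:5, 1)
    cm <- matrix(rpois(ng * ns, 50), ng,
                 dimnames = list(paste0("g", 1:ng), paste0("s", 1:ns)))
    len <- sample(200:3000, ng)
    lib <- colSums(cm) + sample(1e5, ns)
    v1 <- exprValues(rpkm(cm, len, lib))
    v2 <- exprValues(rpkm(2 * cm, len, 2 * lib))
    expect_equal(v1, v2, tolerance = 1e-12)
    expect_equal(colSums(v1),
                 1e9 / lib * colSums(cm / len), tolerance = 1e-9)
  }
})

mkCt <- function(vals, reps = 1) {
  grid <- expand.grid(replicate = seq_len(reps),
                      sample = colnames(vals$target),
                      gene = c(rownames(vals$target), "ref"),
                      stringsAsFactors = FALSE)[, 3:1]
  grid$ct <- mapply(function(g, s)
    if (g == "ref") vals$ref[[s]] else vals$target[g, s],
    grid$gene, grid$sample)
  grid
}

test_that("ddct reproduces hand-computed relative expression", {
  vals <- list(target = matrix(c(25, 24), 1, 2,
                               dimnames = list("g", c("cal", "s2"))),
               ref = c(cal = 20, s2 = 20))
  e <- ddct(mkCt(vals), "ref", "cal")
  expect_equal(exprValues(e)["g", "cal"], 1)   # calibrator identity
  expect_equal(exprValues(e)["g", "s2"], 2)    # ddCt = -1 -> 2
  # identical target and reference Cts everywhere -> 1.0
  vals2 <- list(target = matrix(20, 1, 2,
                                dimnames = list("g", c("cal", "s2"))),
                ref = c(cal = 20, s2 = 20))
  expect_equal(unname(exprValues(ddct(mkCt(vals2), "ref", "cal"))["g", ]),
               c(1, 1))
  bad <- mkCt(vals); bad <- bad[!(bad$gene == "ref" & bad$sample == "s2"), ]
  expect_error(ddct(bad, "ref", "cal"), "reference gene missing")
})

test_that("replicate order does not change the ddct means", {
  set.seed(72)
  ct <- expand.grid(replicate = 1:3, sample = c("cal", "s2"),
                    gene = c("g1", "g2", "ref"),
                    stringsAsFactors = FALSE)[, 3:1]
  ct$ct <- runif(nrow(ct), 18, 30)
  e1 <- ddct(ct, "ref", "cal")
  e2 <- ddct(ct[sample(nrow(ct)), ], "ref", "cal")
  expect_equal(exprValues(e1),
               exprValues(e2)[rownames(exprValues(e1)),
                              colnames(exprValues(e1))])
})

test_that("clustering orders put similar rows together", {
  m <- rbind(a = c(1, 2, 3), b = c(50, 60, 70), c = c(1, 2, 3))
  e <- clusterOrder(m, transform = "identity")
  ord <- rownames(m)[rowOrder(e)]
  expect_equal(abs(which(ord == "a") - which(ord == "c")), 1)
  # two well-separated blocks stay contiguous
  set.seed(73)
  blocks <- rbind(matrix(rnorm(20, 0), 4), matrix(rnorm(20, 50), 4))
  rownames(blocks) <- paste0("r", 1:8)
  e2 <- clusterOrder(blocks, transform = "identity")
  pos <- match(paste0("r", 1:8), rownames(blocks)[rowOrder(e2)])
  expect_true(max(pos[1:4]) < min(pos[5:8]) ||
              max(pos[5:8]) < min(pos[1:4]))
  # single row: identity ordering
  expect_equal(rowOrder(clusterOrder(m[1, , drop = FALSE],
                                     transform = "identity")), 1L,
               ignore_attr = TRUE)
})

test_that("merge heights match a hand agglomeration on 3 rows", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 1))
  # pairwise euclidean: d(a,c) = 1, d(a,b) = 5, d(b,c) = sqrt(9+9)
  e <- clusterOrder(m, transform = "identity")
  h <- attr(rowOrder(e), "merges")
  expect_equal(h[1], 1)                       # join a,c at height 1
  expect_equal(h[2], mean(c(5, sqrt(18))))    # average linkage to b
})

test_that("expression series are compared by Pearson correlation", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1))
  e <- new("ExpressionMatrix", values = m, transform = "identity",
           rowOrder = integer(), colOrder = integer())
  out <- expressionVsSeries(e, c(10, 20, 30))
  expect_equal(out$pearson, c(1, -1))
  expect_error(expressionVsSeries(e, 1:4), "must match")
})
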