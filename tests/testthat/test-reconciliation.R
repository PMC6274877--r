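stree2 <- ape::read.tree(text = "(A:1,B:1);")
stree3 <- ape::read.tree(text = "((A:1,B:1)AB:1,C:2)r;")

test_that("LCA mapping classifies hand-worked duplication cases", {
  # root duplication mapped to the A-B ancestor: old
  gt <- ape::read.tree(text = "((A_g1:1,B_g1:1):1,(A_g2:1,B_g2:1):1);")
  r <- lcaReconcile(gt, stree2)
  d <- duplications(r)
  expect_equal(nrow(d), 1)
  expect_equal(d$age, "old")
  expect_equal(d$node, ape::Ntip(gt) + 1L)  # the root
  # within-species duplication mapped to leaf A: recent
  gt2 <- ape::read.tree(text = "((A_g1:1,A_g2:1):1,B_g1:2);")
  d2 <- duplications(lcaReconcile(gt2, stree2))
  expect_equal(d2$age, "recent")
  expect_equal(d2$mapped, "A")
  # species-congruent tree: no duplications
  gt3 <- ape::read.tree(text = "((A_g1:1,B_g1:1):1,C_g1:2);")
  r3 <- lcaReconcile(gt3, stree3)
  expect_equal(nrow(duplications(r3)), 0)
  expect_error(lcaReconcile(gt3, ape::read.tree(text = "(A:1,B:1);")),
               "absent from the species tree")
})

test_that("one-species trees make every duplication recent", {
  gt <- ape::read.tree(text = "((A_g1:1,A_g2:1):1,A_g3:2);")
  st <- ape::read.tree(text = "(A:1,dummy:1);")
  d <- duplications(lcaReconcile(gt, st))
  expect_equal(d$age, rep("recent", 2))
})

test_that("duplications plus speciations equal the internal node count", {
  set.seed(41)
  st <- ape::read.tree(text = "(((A:0.3,B:0.3):0.2,C:0.5):0.2,D:0.7);")
  for (k in 1:20) {
    sim <- simulateGeneFamily(st, 0.4, 0.15, seed = 4000 + k)
    r <- lcaReconcile(sim$geneTree, st, speciesMap = sim$truth$speciesMap)
    expect_equal(nrow(duplications(r)) + r@speciations,
                 sim$geneTree$Nnode)
  }
})

test_that("reconciliation is invariant to child-order rotations", {
  gt <- ape::read.tree(text = "((A_g1:1,A_g2:1):1,(B_g1:1,C_g1:1):1);")
  gtRot <- ape::read.tree(text = "(((C_g1:1,B_g1:1):1),(A_g2:1,A_g1:1):1);")
  gtRot <- ape::read.tree(text = "((B_g1:1,C_g1:1):1,(A_g2:1,A_g1:1):1);")
  r1 <- lcaReconcile(gt, stree3)
  r2 <- lcaReconcile(gtRot, stree3)
  expect_equal(duplications(r1)$age, duplications(r2)$age)
  expect_equal(duplications(r1)$mapped, duplications(r2)$mapped)
})

test_that("per-clade losses list exactly the absent species", {
  cl <- data.frame(leaf = c("A_g1", "B_g1"), clade = c("I", "I"))
  lo <- inferLosses(cl, c("A", "B", "C"))
  expect_equal(lo$clade, "I")
  expect_equal(lo$species, "C")
  cl2 <- data.frame(leaf = c("A_g1", "B_g1", "C_g1"), clade = "I")
  expect_equal(nrow(inferLosses(cl2, c("A", "B", "C"))), 0)
})

test_that("sister pairs are same-species cherries only", {
  gt <- ape::read.tree(text = "((A_g1:1,A_g2:1):1,B_g1:2);")
  sp <- sisterPairs(lcaReconcile(gt, stree2))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$species, "A")
  expect_setequal(c(sp$leaf1, sp$leaf2), c("A_g1", "A_g2"))
  gt2 <- ape::read.tree(text = "((A_g1:1,B_g1:1):1,C_g1:2);")
  expect_equal(nrow(sisterPairs(lcaReconcile(gt2, stree3))), 0)
})

test_that("soft polytomies suppress duplications unless a species repeats", {
  gt <- ape::read.tree(text = "((A_g1:1,B_g1:1)20:1,C_g1:2)90;")
  # collapsing the weak branch gives (A,B,C) polytomy: no duplication
  r <- lcaReconcile(gt, stree3, collapseBelow = 50)
  expect_equal(nrow(duplications(r)), 0)
  gt2 <- ape::read.tree(text = "((A_g1:1,A_g2:1)20:1,C_g1:2)90;")
  r2 <- lcaReconcile(gt2, stree3, collapseBelow = 50)
  expect_equal(nrow(duplications(r2)), 1)  # A repeats among the children
})

test_that("simulated families are reconciled back to the truth log", {
  st <- ape::read.tree(text = "(((A:0.3,B:0.3):0.2,C:0.5):0.2,D:0.7);")
  for (k in 1:25) {
    sim <- simulateGeneFamily(st, 0.3, 0.1, seed = 7000 + k)
    r <- lcaReconcile(sim$geneTree, st, speciesMap = sim$truth$speciesMap)
    d <- duplications(r)
    lab <- sim$geneTree$node.label[d$node - ape::Ntip(sim$geneTree)]
    truth <- sim$truth$duplications
    truthDet <- truth[truth$detectable, ]
    expect_setequal(lab, truthDet$node)
    got <- setNames(d$age, lab)
    expect_equal(unname(got[truthDet$node]), truthDet$age)
    # losses: the family as one clade must list exactly the absent species
    cl <- data.frame(leaf = sim$geneTree$tip.label, clade = "I")
    lo <- inferLosses(cl, st$tip.label, speciesMap = sim$truth$speciesMap)
    expect_setequal(lo$species, sim$truth$absentSpecies)
  }
})
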