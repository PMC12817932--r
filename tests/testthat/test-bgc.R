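test_that("regions split exactly at the gap and correlation boundaries", {
  ## gaps [100, 301, 100, 100], all adjacent r = 0.9, cores at genes 1 and 4
  fx <- regionFixture(gaps = c(100, 301, 100, 100), rhos = rep(0.9, 4),
                      cores = c(1, 4))
  sc <- refineRegion(fx$region, fx$expr)
  expect_identical(sc$suffix, c("a", "b"))
  expect_identical(sc$members[[1]], fx$region$gene_id[1:2])
  expect_identical(sc$members[[2]], fx$region$gene_id[3:5])
  expect_identical(sc$status, c("retained", "retained"))

  ## gap 300 instead of 301 merges: a single sub-cluster
  fx2 <- regionFixture(gaps = c(100, 300, 100, 100), rhos = rep(0.9, 4),
                       cores = c(1, 4))
  sc2 <- refineRegion(fx2$region, fx2$expr)
  expect_identical(sc2$suffix, "a")
  expect_length(sc2$members[[1]], 5)
  expect_true(sc2$whole_region)

  ## r = 0.4 between genes 2 and 3 breaks the chain; only "a" keeps a core
  fx3 <- regionFixture(gaps = rep(100, 4), rhos = c(0.9, 0.4, 0.9, 0.9),
                       cores = 1)
  sc3 <- refineRegion(fx3$region, fx3$expr)
  expect_identical(sc3$suffix, c("a", "b"))
  expect_identical(sc3$status, c("retained", "discarded"))
  expect_identical(sc3$reason[2], "no core gene")

  ## the correlation boundary: the rule is r > 0.5, so just below breaks
  ## and just above merges
  fx4 <- regionFixture(gaps = rep(100, 2), rhos = c(0.5 - 1e-6, 0.9),
                       cores = c(1, 2))
  expect_identical(refineRegion(fx4$region, fx4$expr)$suffix, c("a", "b"))
  fx5 <- regionFixture(gaps = rep(100, 2), rhos = c(0.5 + 1e-5, 0.9),
                       cores = c(1, 2))
  expect_identical(refineRegion(fx5$region, fx5$expr)$suffix, "a")
})

test_that("unexpressed genes break chains and are recorded unassigned", {
  fx <- regionFixture(gaps = rep(100, 3), rhos = rep(0.9, 3), cores = c(1, 4))
  expr <- fx$expr[-2, , drop = FALSE]   # gene 2 failed the filter
  sc <- refineRegion(fx$region, expr)
  expect_identical(attr(sc, "unassigned"), fx$region$gene_id[2])
  expect_identical(sc$members[[1]], fx$region$gene_id[1])
  expect_identical(sc$members[[2]], fx$region$gene_id[3:4])
  ## sub-clusters partition the expressed members
  expect_setequal(unlist(sc$members), rownames(expr))
})

test_that("refinement ignores input row order and coarsens monotonically", {
  fx <- regionFixture(gaps = c(100, 400, 100, 250), rhos = rep(0.9, 4),
                      cores = c(1, 3))
  shuffled <- fx$region[c(4, 1, 5, 3, 2), ]
  expect_identical(refineRegion(shuffled, fx$expr)$members,
                   refineRegion(fx$region, fx$expr)$members)
  expect_error(refineRegion(fx$region[0, ], fx$expr), "no member genes")

  withr::local_seed(7)
  for (i in 1:10) {
    gaps <- sample(c(50, 200, 350, 500), 5, replace = TRUE)
    rhos <- runif(5, 0, 1)
    fx <- regionFixture(gaps = gaps, rhos = rhos, cores = 1,
                        seed = i)
    n1 <- nrow(refineRegion(fx$region, fx$expr, maxGap = 300, rMin = 0.5))
    n2 <- nrow(refineRegion(fx$region, fx$expr, maxGap = 450, rMin = 0.5))
    n3 <- nrow(refineRegion(fx$region, fx$expr, maxGap = 300, rMin = 0.2))
    expect_lte(n2, n1)
    expect_lte(n3, n1)
  }
})

test_that("retention filters discard by the stated rules with an audit log", {
  ## 10-gene cluster, 8 genes below the filter (0.8 > 0.7) -> rule b
  tg <- simulateToyGenome(list(list(contig = "c", taxon = "t", nGenes = 10,
                                    gaps = rep(100, 9), cores = 1)))
  cl <- asSubCluster(tg$region)
  passed <- tg$region$gene_id[1:2]
  expr <- chainCor(20, 0.9, seed = 2)
  rownames(expr) <- passed
  out <- filterSubClusters(cl, passed, expr)
  expect_identical(nrow(out$retained), 0L)
  expect_identical(out$audit$rule, "b")

  ## single core whose best correlation is 0.45 -> rule c
  fx <- regionFixture(gaps = rep(100, 2), rhos = c(0.45, 0.45), cores = 1)
  cl2 <- asSubCluster(fx$region)
  out2 <- filterSubClusters(cl2, fx$region$gene_id, fx$expr)
  expect_identical(out2$audit$rule, "c")

  ## core with r = 0.9 to a neighbour and 30% failing genes -> retained
  tg3 <- simulateToyGenome(list(list(contig = "c", taxon = "t", nGenes = 10,
                                     gaps = rep(100, 9), cores = 1)))
  passed3 <- tg3$region$gene_id[1:7]
  expr3 <- chainCor(20, rep(0.9, 6), seed = 3)
  rownames(expr3) <- passed3
  out3 <- filterSubClusters(asSubCluster(tg3$region), passed3, expr3)
  expect_identical(nrow(out3$retained), 1L)

  ## no core passing the filter -> rule a
  out4 <- filterSubClusters(asSubCluster(tg3$region),
                            tg3$region$gene_id[2:7], expr3[2:6, ])
  expect_identical(out4$audit$rule, "a")

  ## singleton: discarded unless it is the whole region
  tg5 <- simulateToyGenome(list(list(contig = "c", taxon = "t", nGenes = 1,
                                     gaps = integer(0), cores = 1)))
  e5 <- matrix(rnorm(20), 1, dimnames = list(tg5$region$gene_id, NULL))
  whole <- filterSubClusters(asSubCluster(tg5$region), tg5$region$gene_id, e5)
  expect_identical(whole$retained$flag, "singleton whole region")
  part <- asSubCluster(tg5$region); part$whole_region <- FALSE
  out5 <- filterSubClusters(part, tg5$region$gene_id, e5)
  expect_identical(out5$audit$rule, "c")
})

test_that("eigengenes match an independent eigendecomposition oracle", {
  withr::local_seed(31)
  counts <- matrix(rnbinom(6 * 15, mu = 150, size = 4), 6, 15,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:15)))
  eg <- clusterEigengene(paste0("g", 1:6), counts)
  or <- eigengeneOracle(paste0("g", 1:6), counts)
  flip <- sign(sum(eg$eigengene * or$eigengene))
  expect_equal(unname(eg$eigengene), flip * or$eigengene, tolerance = 1e-8)
  expect_equal(eg$varianceExplained, or$varianceExplained, tolerance = 1e-8)
  ## sign convention: non-negative correlation with the mean profile
  xs <- t(scale(t(log2(counts + 1))))
  expect_gte(cor(eg$eigengene, colMeans(xs)), 0)

  ## two identical profiles: the eigengene carries each gene completely
  c2 <- rbind(g1 = counts[1, ], g2 = counts[1, ])
  eg2 <- clusterEigengene(c("g1", "g2"), c2)
  expect_equal(abs(cor(eg2$eigengene, log2(c2["g1", ] + 1))), 1,
               tolerance = 1e-9)
  expect_equal(eg2$varianceExplained, 1, tolerance = 1e-12)

  ## constant rows are dropped with a warning; all-constant is an error
  c3 <- counts; c3["g2", ] <- 7
  expect_warning(eg3 <- clusterEigengene(paste0("g", 1:6), c3), "constant")
  expect_identical(eg3$nGenesUsed, 5L)
  c4 <- matrix(5, 2, 10, dimnames = list(c("a", "b"), NULL))
  expect_error(suppressWarnings(clusterEigengene(c("a", "b"), c4)),
               "constant")
})
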