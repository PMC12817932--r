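test_that("correlations use only shared present samples", {
  ## taxon A present in samples 1-8, B in 5-12: 4 shared samples
  vals <- matrix(rnorm(24), 2, 12,
                 dimnames = list(c("a1", "b1"), paste0("s", 1:12)))
  pres <- rbind(A = 1:12 %in% 1:8, B = 1:12 %in% 5:12)
  colnames(pres) <- paste0("s", 1:12)
  e <- correlateFeatures(vals, c("A", "B"), presence = pres)
  expect_identical(e$n_shared, 4)
  expect_identical(e$removed_by, "min_samples")   # 4 < default floor of 5
  e2 <- correlateFeatures(vals, c("A", "B"), presence = pres, minShared = 3)
  expect_identical(e2$removed_by, "none")
  ## the value equals the correlation over exactly samples 5-8
  expect_equal(e$r, cor(vals[1, 5:8], vals[2, 5:8]), tolerance = 1e-12)
})

test_that("exact linear relations and the covariance-formula oracle agree", {
  withr::local_seed(13)
  x <- rnorm(30); y <- 2 * x + 1
  vals <- rbind(a1 = x, b1 = y)
  colnames(vals) <- paste0("s", 1:30)
  e <- correlateFeatures(vals, c("A", "B"))
  expect_equal(e$r, 1, tolerance = 1e-12)
  expect_equal(e$rho, 1, tolerance = 1e-12)

  for (i in 1:5) {
    v <- matrix(rnorm(60), 2, 30, dimnames = list(c("a1", "b1"), NULL))
    colnames(v) <- paste0("s", 1:30)
    e <- correlateFeatures(v, c("A", "B"))
    expect_equal(e$r, pearsonOracle(v[1, ], v[2, ]), tolerance = 1e-12)
  }

  ## zero-variance feature: recorded as undefined, never silently dropped
  v <- rbind(a1 = rep(3, 10), b1 = rnorm(10))
  colnames(v) <- paste0("s", 1:10)
  e <- suppressWarnings(correlateFeatures(v, c("A", "B")))
  expect_identical(e$removed_by, "undefined")
  expect_identical(nrow(e), 1L)
})

test_that("Pearson is affine-invariant; Spearman survives arcsinh", {
  withr::local_seed(4)
  v <- matrix(rexp(90), 3, 30,
              dimnames = list(c("a1", "a2", "b1"), paste0("s", 1:30)))
  taxa <- c("A", "A", "B")
  e1 <- correlateFeatures(v, taxa)
  v2 <- v; v2[1, ] <- 5 * v2[1, ] + 2
  e2 <- correlateFeatures(v2, taxa)
  expect_equal(e1$r, e2$r, tolerance = 1e-12)
  e3 <- correlateFeatures(asinh(v), taxa)
  expect_equal(e1$rho, e3$rho, tolerance = 1e-12)
  ## no self-edges, no duplicate unordered pairs
  key <- paste(pmin(e1$node_a, e1$node_b), pmax(e1$node_a, e1$node_b))
  expect_false(any(e1$node_a == e1$node_b))
  expect_false(anyDuplicated(key) > 0)
  expect_identical(nrow(e1), 3L)   # C(3,2) pairs
})

test_that("discrepancy filter removes |r - rho| strictly above the gap", {
  e <- data.frame(node_a = "x", node_b = "y", taxon_a = "A", taxon_b = "B",
                  kind_a = "module", kind_b = "module",
                  r = c(0.9, 0.9, 0.8), rho = c(0.5, 0.7, 0.5),
                  n_shared = 10, cross_species = TRUE, removed_by = "none")
  out <- discrepancyFilter(e)
  expect_identical(out$removed_by,
                   c("discrepancy",  # 0.4 > 0.3
                     "none",         # 0.2
                     "none"))        # exactly 0.3: kept (strict)
})

test_that("signed power scaling preserves sign, order and fixed points", {
  expect_identical(signedPower(c(-1, 0, 1)), c(-1, 0, 1))
  r <- seq(-1, 1, by = 0.05)
  w <- signedPower(r)
  expect_true(all(abs(w) <= abs(r)))
  expect_true(all(diff(signedPower(seq(0, 1, 0.01))) > 0))
  expect_identical(sign(w), sign(r))
  ## display cut-offs: weight 0.2 <-> r 0.76, 0.5 <-> 0.89 (two decimals)
  expect_equal(signedPower(0.2^(1 / 6)), 0.2, tolerance = 1e-12)
  expect_equal(round(0.2^(1 / 6), 2), 0.76)
  expect_equal(round(0.5^(1 / 6), 2), 0.89)
  expect_equal(signedPower(-0.5^(1 / 6)), -0.5, tolerance = 1e-12)
  expect_error(signedPower(1.2), "exceed")
  expect_error(signedPower(0.5, beta = 0.5), "beta")
})

test_that("soft-threshold selection scores hub-like topologies", {
  ## connectivity built from heavy-tailed node propensities follows an
  ## approximate power law; the signed fit index must recognise it
  withr::local_seed(99)
  n <- 60
  x <- (1 - runif(n))^(-1 / 2.5)          # Pareto tail
  x <- x / max(x)
  r <- outer(x, x, function(a, b) pmin((a * b)^(1 / 6), 1))
  diag(r) <- 1
  dimnames(r) <- list(paste0("n", 1:n), paste0("n", 1:n))
  ps <- pickSoftThreshold(r, betaGrid = 1:10, targetR2 = 0.8)
  fit6 <- ps$fitTable$fit[ps$fitTable$beta == 6]
  expect_gt(fit6, 0.8)
  expect_identical(nrow(ps$fitTable), 10L)
  expect_gte(ps$fitTable$fit[ps$fitTable$beta == ps$power], 0.8)

  ## degenerate inputs
  flat <- matrix(0.5, 25, 25); diag(flat) <- 1
  dimnames(flat) <- list(paste0("n", 1:25), paste0("n", 1:25))
  expect_error(pickSoftThreshold(flat), "degenerate")
  expect_error(pickSoftThreshold(r[1:10, 1:10]), "20 nodes")
})

test_that("Fisher-z averaging has its fixed point, oddness and closed form", {
  expect_equal(fisherAverage(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisherAverage(c(0.8, -0.8)), 0, tolerance = 1e-12)
  expect_equal(fisherAverage(c(0.5, 0.9)),
               tanh((atanh(0.5) + atanh(0.9)) / 2), tolerance = 1e-12)
  expect_equal(fisherAverage(c(0.5, 0.9)), 0.766, tolerance = 5e-4)
  ## permutation invariance and bounds
  withr::local_seed(8)
  rs <- runif(20, -1, 1)
  expect_equal(fisherAverage(rs), fisherAverage(sample(rs)))
  expect_true(abs(fisherAverage(c(1, 1, 1))) < 1)
})

test_that("cluster-cluster correlation averages inter-cluster gene pairs", {
  ## two single-gene clusters with exact correlations 0.8 and -0.8 to b
  n <- 30
  p1 <- exactCorPair(n, 0.8, seed = 1)
  b <- p1$x
  e <- rnorm(n); e <- e - mean(e)
  e <- e - sum(e * b) * b / sum(b^2); e <- e / sqrt(sum(e^2))
  a1 <- p1$y
  a2 <- -(0.8 * b + sqrt(1 - 0.64) * e)
  exprA <- rbind(a1 = a1, a2 = a2)
  exprB <- rbind(b = b)
  out <- clusterCorrelation(exprA, exprB)
  expect_identical(out$nPairs, 2L)
  expect_equal(out$r, 0, tolerance = 1e-9)
  ## equal pair correlations are a fixed point
  out2 <- clusterCorrelation(rbind(a1 = a1), exprB)
  expect_equal(out2$r, 0.8, tolerance = 1e-9)
  ## no valid pair
  bad <- clusterCorrelation(rbind(a1 = rep(1, n)), exprB)
  expect_true(is.na(bad$r))
  expect_identical(bad$reason, "no valid gene pair")
})

test_that("network assembly thresholds weights and annotates shared KOs", {
  f <- withr::local_tempfile()
  writeLines(c("M1\ta", "K1", "K2", "///", "M2\tb", "K2", "K3", "///"), f)
  db <- readGmmDatabase(f)
  e <- data.frame(
    node_a = c("A|M1", "A|M1", "B|M1"), node_b = c("A|M2", "B|M1", "B|M2"),
    taxon_a = c("A", "A", "B"), taxon_b = c("A", "B", "B"),
    kind_a = "module", kind_b = "module",
    r = c(0.9, 0.85, 0.5), rho = c(0.88, 0.8, 0.45), n_shared = 10,
    cross_species = c(FALSE, TRUE, FALSE), removed_by = "none",
    stringsAsFactors = FALSE)
  net <- buildNetwork(e, beta = 6, minWeight = 0.2, db = db)
  ke <- networkEdges(net)
  ## every retained edge satisfies |r| > 0.2^(1/6)
  expect_true(all(abs(ke$r) > 0.2^(1 / 6)))
  expect_identical(nrow(ke), 2L)
  ## within-species module edges carry the shared-KO fraction
  within <- ke[!ke$cross_species, ]
  expect_equal(within$shared_ko_fraction, 1 / 3)
  expect_true(all(is.na(ke$shared_ko_fraction[ke$cross_species])))
  ## min_weight = 1 empties the network
  empty <- buildNetwork(e, beta = 6, minWeight = 1)
  expect_identical(nrow(networkEdges(empty)), 0L)
  expect_identical(nrow(networkNodes(empty)), 0L)
  ## singletons kept on request
  full <- buildNetwork(e, beta = 6, minWeight = 1, dropSingletons = FALSE)
  expect_identical(nrow(networkNodes(full)), 4L)
})
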