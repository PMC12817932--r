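## Independent oracles, coded separately from the pipeline path.

## Robinson-Oshlack TMM, written directly from the published formulas:
## M = log2 ratio of library-scaled proportions vs the reference column,
## A = average log proportion, genes with a zero in either column excluded,
## double trim (30% on M, 5% on A), precision-weighted mean, factors
## rescaled to geometric mean 1. Reference column: upper quartile closest
## to the mean upper quartile.
tmmOracle <- function(mat, logratioTrim = 0.30, sumTrim = 0.05) {
  lib <- colSums(mat)
  mat <- mat[rowSums(mat > 0) > 0, , drop = FALSE]
  f75 <- apply(mat, 2, function(x) quantile(x, p = 0.75)) / lib
  ref <- if (median(f75) < 1e-20) which.max(colSums(sqrt(mat)))
         else which.min(abs(f75 - mean(f75)))
  oneTMM <- function(obs, refc, nO, nR) {
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1;     hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
            (rank(absE) >= loS & rank(absE) <= hiS)
    2^(sum(logR[keep] / v[keep], na.rm = TRUE) /
         sum(1 / v[keep], na.rm = TRUE))
  }
  f <- vapply(seq_len(ncol(mat)), function(j)
    oneTMM(mat[, j], mat[, ref], lib[j], lib[ref]), numeric(1))
  f / exp(mean(log(f)))
}

## Pearson correlation straight from the textbook covariance formula.
pearsonOracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

## Eigengene via eigen-decomposition of the sample-sample cross-product
## (no svd), same preprocessing contract as the pipeline.
eigengeneOracle <- function(members, counts) {
  x <- log2(counts[members, , drop = FALSE] + 1)
  xs <- t(scale(t(x)))
  ev <- eigen(crossprod(xs), symmetric = TRUE)
  list(eigengene = ev$vectors[, 1] / sqrt(sum(ev$vectors[, 1]^2)),
       varianceExplained = ev$values[1] / sum(ev$values))
}
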