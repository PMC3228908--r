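test_that("two-locus haplotype frequencies honor D' and the marginals", {
  expect_equal(haplotypeFreqs(0.5, 0.5, 1),
               c(AM = 0.5, Am = 0, aM = 0, am = 0.5))
  expect_equal(haplotypeFreqs(0.3, 0.6, 0),
               c(AM = 0.18, Am = 0.12, aM = 0.42, am = 0.28))
  # D = 0.6 * min(0.3*0.5, 0.7*0.5) = 0.6 * 0.15 = 0.09
  f <- haplotypeFreqs(0.3, 0.5, 0.6)
  expect_equal(unname(f["AM"] - 0.3 * 0.5), 0.09)
  expect_equal(sum(f), 1)
  expect_equal(unname(f["AM"] + f["Am"]), 0.3)
  expect_equal(unname(f["AM"] + f["aM"]), 0.5)

  # property: any (pA, pM, D') gives non-negative frequencies that
  # preserve the marginals
  set.seed(3)
  for (i in 1:50) {
    pA <- runif(1, 0.05, 0.95); pM <- runif(1, 0.05, 0.95)
    d <- runif(1, -1, 1)
    f <- haplotypeFreqs(pA, pM, d)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1)
    expect_equal(unname(f["AM"] + f["Am"]), pA)
    expect_equal(unname(f["AM"] + f["aM"]), pM)
  }
  expect_error(haplotypeFreqs(0, 0.5, 0.5), "strictly")
  expect_error(haplotypeFreqs(0.5, 0.5, 1.2), "\\[-1, 1\\]")
})

test_that("the joint haplotype distribution reproduces its constraints", {
  # k = 1 reduces exactly to the two-locus decomposition
  m1 <- regulatoryModel(0.4, variantTable("A", 0.3, 0.5, 0.6))
  j1 <- buildJoint(m1)
  f <- haplotypeFreqs(0.3, 0.4, 0.6)
  expect_equal(j1$freq[j1$A == 1 & j1$M == 1], unname(f["AM"]))
  expect_equal(j1$freq[j1$A == 1 & j1$M == 0], unname(f["Am"]))
  expect_equal(j1$freq[j1$A == 0 & j1$M == 1], unname(f["aM"]))

  # two unlinked variants: product of marginals
  m2 <- regulatoryModel(0.5, variantTable(c("A", "B"), c(0.3, 0.6),
                                          c(0.5, 0.4), c(0, 0)))
  j2 <- buildJoint(m2)
  expect_equal(j2$freq[j2$A == 1 & j2$B == 1 & j2$M == 1], 0.3 * 0.6 * 0.5)

  # mixed linkage: marginalizing the joint over the other variant
  # recovers each pairwise table
  m3 <- regulatoryModel(0.5, variantTable(c("A", "B"), c(0.5, 0.4),
                                          c(0.8, 0.3), c(1, 0)))
  j3 <- buildJoint(m3)
  fA <- haplotypeFreqs(0.5, 0.5, 1)
  fB <- haplotypeFreqs(0.4, 0.5, 0)
  expect_equal(sum(j3$freq[j3$A == 1 & j3$M == 1]), unname(fA["AM"]),
               tolerance = 1e-9)
  expect_equal(sum(j3$freq[j3$B == 1 & j3$M == 1]), unname(fB["AM"]),
               tolerance = 1e-9)
  expect_equal(sum(j3$freq[j3$B == 1]), 0.4, tolerance = 1e-9)

  # explicit pairwise D' between variants is matched by IPF
  pw <- matrix(NA_real_, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  pw["A", "B"] <- 0.5
  m4 <- regulatoryModel(0.5, variantTable(c("A", "B"), c(0.4, 0.4),
                                          c(0.5, 0.5), c(0.3, 0.3)),
                        pairwiseDprime = pw)
  j4 <- buildJoint(m4)
  fAB <- haplotypeFreqs(0.4, 0.4, 0.5)
  expect_equal(sum(j4$freq[j4$A == 1 & j4$B == 1]), unname(fAB["AM"]),
               tolerance = 1e-8)

  # infeasible constraint set: A and B fully coupled to M but
  # fully repulsed from each other
  pw2 <- pw; pw2["A", "B"] <- -1
  m5 <- regulatoryModel(0.5, variantTable(c("A", "B"), c(0.5, 0.5),
                                          c(0.5, 0.5), c(1, 1)),
                        pairwiseDprime = pw2)
  expect_error(buildJoint(m5), "infeasible")
})

test_that("diplotype enumeration conditions on marker heterozygosity", {
  # complete coupling with matched frequencies forces the phase
  j <- buildJoint(regulatoryModel(0.5, variantTable("A", 0.5, 0.8, 1)))
  cfg <- enumerateDiplotypes(j)
  expect_equal(nrow(cfg), 1L)
  expect_equal(cfg$s_A, 1)
  expect_equal(cfg$prob, 1)

  # unlinked variant at pA = 0.5: hand enumeration of the 4 x 4
  # haplotype pairs gives P(+1) = P(-1) = 1/4, P(0) = 1/2
  j0 <- buildJoint(regulatoryModel(0.3, variantTable("A", 0.5, 0.8, 0)))
  cfg0 <- enumerateDiplotypes(j0)
  expect_equal(cfg0$prob[cfg0$s_A == 1], 0.25)
  expect_equal(cfg0$prob[cfg0$s_A == -1], 0.25)
  expect_equal(cfg0$prob[cfg0$s_A == 0], 0.5)

  # oracle: brute-force over all ordered haplotype pairs
  bruteForce <- function(joint) {
    vn <- setdiff(names(joint), c("M", "freq"))
    tot <- 0; acc <- list()
    for (i in seq_len(nrow(joint))) for (k in seq_len(nrow(joint))) {
      if (joint$M[i] != 1 || joint$M[k] != 0) next
      p <- joint$freq[i] * joint$freq[k]
      tot <- tot + p
      key <- paste(unlist(joint[i, vn]) - unlist(joint[k, vn]),
                   collapse = ",")
      acc[[key]] <- (acc[[key]] %||% 0) + p
    }
    vapply(acc, function(p) p / tot, numeric(1))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  j2 <- buildJoint(regulatoryModel(0.4, variantTable(c("A", "B"),
                                                     c(0.3, 0.6),
                                                     c(0.5, -0.4),
                                                     c(0.7, 0.2))))
  cfg2 <- enumerateDiplotypes(j2)
  bf <- bruteForce(j2)
  key2 <- paste(cfg2$s_A, cfg2$s_B, sep = ",")
  expect_equal(cfg2$prob, unname(bf[key2]), tolerance = 1e-9)
  expect_equal(sum(cfg2$prob), 1)

  # probabilities sum to 1 for random models
  set.seed(13)
  for (i in 1:10) {
    m <- regulatoryModel(runif(1, 0.1, 0.9),
                         variantTable(c("A", "B"), runif(2, 0.1, 0.9),
                                      rnorm(2, 0, 0.5), runif(2, -1, 1)))
    expect_equal(sum(enumerateDiplotypes(buildJoint(m))$prob), 1)
  }
})

test_that("expected log2 AEI is additive over phased variants", {
  cfg <- data.frame(s_A = c(0, 1, 1), s_B = c(0, 0, -1), prob = 1 / 3)
  expect_equal(expectedLog2AEI(cfg, c(0.9, 0.4)), c(0, 0.9, 0.5))
  expect_equal(expectedLog2AEI(data.frame(s_A = 1, prob = 1), 0.8), 0.8)
  expect_error(expectedLog2AEI(cfg, 0.9), "match")
})

test_that("mixtures are sign-equivariant and match Monte-Carlo sampling", {
  m <- regulatoryModel(0.5, variantTable(c("A", "B"), c(0.4, 0.6),
                                         c(0.7, -0.3), c(0.6, 0.1)),
                       noiseSd = 0.1)
  mneg <- regulatoryModel(0.5, variantTable(c("A", "B"), c(0.4, 0.6),
                                            c(-0.7, 0.3), c(0.6, 0.1)),
                          noiseSd = 0.1)
  mx <- predictMixture(m)
  mxn <- predictMixture(mneg)
  expect_equal(sort(mxn$support), sort(-mx$support))
  expect_equal(mxn$weights[order(mxn$support)],
               rev(mx$weights[order(mx$support)]))

  # exact mean/variance vs sampling at n = 1e5 within 3 standard errors
  mu <- sum(mx$support * mx$weights)
  v <- sum((mx$support - mu)^2 * mx$weights) + mx$noise_sd^2
  draws <- predictDistribution(m, 1e5, seed = 4)
  expect_equal(mean(draws), mu, tolerance = 3 * sqrt(v / 1e5) / max(abs(mu), 1e-3))
  expect_lt(abs(var(draws) - v), 3 * v * sqrt(2 / 1e5))

  # CDF/quantile round trip
  p <- c(0.05, 0.25, 0.5, 0.9)
  q <- mixtureQuantile(mx, p)
  expect_equal(mixtureCDF(mx, q), p, tolerance = 1e-3)
})

test_that("archetypal regulatory architectures yield the canonical shapes", {
  gab2 <- regulatoryModel(0.5, variantTable("A", 0.5, 0.8, 1),
                          noiseSd = 0.1)
  d <- predictDistribution(gab2, 30, seed = 5)
  expect_false(is.unsorted(d))
  expect_true(all(d > 0.29))          # 100% positive calls, uniphasic
  expect_equal(classifyShape(d), "uniphasic")

  # multiple variants unlinked to the marker: balanced biphasic
  disc1 <- regulatoryModel(0.4, variantTable(c("A", "B"), c(0.5, 0.5),
                                             c(0.5, 0.4), c(0, 0)),
                           noiseSd = 0.1)
  mx <- predictMixture(disc1)
  expect_equal(sum(mx$support * mx$weights), 0, tolerance = 1e-9)
  d2 <- predictDistribution(disc1, 10000, seed = 6)
  fpos <- mean(d2 > 0.29); fneg <- mean(d2 < -0.29)
  expect_equal(fpos, fneg, tolerance = 3 * sqrt(0.25 / 10000) / fpos)
  expect_equal(classifyShape(d2), "biphasic")

  # one partially linked plus one unlinked variant: skewed
  gnb1l <- regulatoryModel(0.5, variantTable(c("A", "B"), c(0.5, 0.3),
                                             c(0.8, 0.4), c(0.6, 0)),
                           noiseSd = 0.1)
  d3 <- predictDistribution(gnb1l, 52, seed = 7)
  expect_equal(classifyShape(d3), "skewed")
  expect_gt(mean(d3 > 0.29), 0.5)
  expect_gt(mean(d3 < -0.29), 0)
})

test_that("shape classification follows the significant-sign rule", {
  expect_equal(classifyShape(c(-0.1, 0, 0.05, 0.2, -0.25)), "null")
  expect_equal(classifyShape(c(0.3, 0.4, 0.5, 0.6, 0.1)), "uniphasic")
  expect_equal(classifyShape(c(-0.5, 0.4, 0.5, 0.6, 0.1)), "biphasic")
  expect_equal(classifyShape(c(-0.5, rep(0.5, 7))), "skewed")
  expect_error(classifyShape(c(0.1, 0.2)), "at least 5")
})

test_that("model fitting recovers planted parameters and prefers parsimony", {
  truem <- regulatoryModel(0.5, variantTable("A", 0.5, 0.8, 1),
                           noiseSd = 0.1)
  obs <- predictDistribution(truem, 30, seed = 11)
  fit <- fitModel(obs, markerFreq = 0.5, k = 1, noiseSd = 0.1)
  v <- modelVariants(fit$model)
  expect_lte(abs(v$effect - 0.8), 0.1)
  expect_lte(abs(v$dprime_marker - 1), 0.1)
  expect_equal(length(fit$fitted), 30L)

  # null data: the best fit carries (essentially) no effect
  nullobs <- predictDistribution(
    regulatoryModel(0.5, variantTable(), noiseSd = 0.1), 30, seed = 12)
  nullfit <- fitModel(nullobs, 0.5, 1, 0.1,
                      grid = list(P = c(0.3, 0.5, 0.7),
                                  effect = seq(0, 1.2, 0.1),
                                  dprime = seq(0, 1, 0.25)))
  expect_lte(abs(modelVariants(nullfit$model)$effect), 0.1)

  # k = 2 fit on single-variant data: parsimony picks a k=1-equivalent
  # solution (second variant collapses to zero effect)
  smallgrid <- list(P = 0.5, effect = c(0, 0.4, 0.8), dprime = c(0, 1))
  fit2 <- fitModel(obs, 0.5, k = 2, noiseSd = 0.1, grid = smallgrid)
  v2 <- modelVariants(fit2$model)
  expect_equal(sort(abs(v2$effect)), c(0, 0.8))
  fit1 <- fitModel(obs, 0.5, k = 1, noiseSd = 0.1, grid = smallgrid)
  expect_lte(fit2$objective, fit1$objective + 1e-8)

  expect_warning(fitModel(rep(0.4, 8), 0.5, 1, 0.1,
                          grid = list(P = 0.5, effect = c(0, 0.4),
                                      dprime = c(0, 1))), "identical")
  expect_error(fitModel(c(0.1, 0.2), 0.5), "at least 5")
})
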