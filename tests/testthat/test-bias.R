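test_that("hexamer registration centers the window on the cut position", {
  g <- Biostrings::DNAString("ACGTACGTACGT")
  # window [i-3, i+2]: the cut sits on the 4th base of its hexamer
  expect_equal(hexamerAt(g, 4), "ACGTAC")
  expect_equal(hexamerAt(g, 5), "CGTACG")
  expect_equal(hexamerAt(g, c(3, 11)), c(NA_character_, NA_character_))
})

test_that("uniform cuts over a toy genome give unit bias everywhere", {
  g <- generateGenome(4000, 0.5, seed = 31)
  L <- length(g)
  # one cut at every position carrying a full hexamer window: cut-bearing
  # positions 4..L-2 match the genomic windows 1..L-5 one to one
  y <- rep(0, L)
  y[4:(L - 2)] <- 1
  bt <- estimateBias(CutProfile(y), g)
  b <- biasValues(bt)
  expect_true(all(abs(b[!is.na(b)] - 1) < 1e-12))
  # hexamers absent from the genome are flagged, not fabricated
  expect_true(all(is.na(b[bt@metadata$missing])))
  expect_error(estimateBias(CutProfile(rep(0, L)), g), "zero total")
})

test_that("a hexamer with twice its genomic share of cuts gets bias 2", {
  # 10 A's give 5 poly-A hexamer windows; 15 trailing distinct bases give
  # 15 more windows, so AAAAAA occupies 25% of positions; tripling its cuts
  # gives it 50% of cuts and a bias of exactly 2
  g <- Biostrings::DNAString(paste0(strrep("A", 10), "CGTCGGTACTGCACT"))
  L <- length(g)
  expect_equal(unname(Biostrings::oligonucleotideFrequency(g, 6)["AAAAAA"]),
               5L)
  y <- rep(0, L)
  y[4:(L - 2)] <- 1
  y[4:8] <- 3                     # the five poly-A cut positions
  bt <- estimateBias(CutProfile(y), g)
  expect_equal(unname(biasValues(bt, "AAAAAA")), 2.0)
  # direct ratio oracle on every observed hexamer of a random profile
  set.seed(5)
  g2 <- generateGenome(3000, 0.4, seed = 32)
  y2 <- rep(0, 3000)
  y2[4:(3000 - 2)] <- rpois(3000 - 5, 2)
  bt2 <- estimateBias(CutProfile(y2), g2)
  hx <- hexamerAt(g2, 4:(3000 - 2))
  pcOracle <- tapply(y2[4:(3000 - 2)], hx, sum) / sum(y2)
  pOracle <- table(hx) / (3000 - 5)
  for (w in names(pcOracle)[pcOracle > 0]) {
    expect_equal(unname(biasValues(bt2, w)),
                 unname(pcOracle[w] / as.numeric(pOracle[w])))
  }
})

test_that("a planted single-hexamer preference is recovered from simulation", {
  target <- "ACGTCA"
  pref <- c(2); names(pref) <- target
  model <- BiasTable(pref)
  g <- generateGenome(50000, 0.5, seed = 33)
  n <- 2e5L
  fs <- simulateFragments(g, NULL, model, nEvents = n, seed = 34)
  prof <- countCuts(fs, start = 1L, end = length(g))
  bt <- estimateBias(prof, g)
  bhat <- unname(biasValues(bt, target))
  # binomial standard error on the cut share (events are the independent
  # draws; both mates share a position)
  pc <- bt@freqCuts[[target]]
  p <- bt@freqGenome[[target]]
  se <- sqrt(pc * (1 - pc) / n) / p
  expect_lt(abs(bhat - 2), 3 * se)
})

test_that("HINT correction matches the printed formula and its artifact", {
  g <- generateGenome(1000, 0.5, seed = 35)
  bt <- BiasTable()
  # zero profile maps to all ones: the add-one artifact
  z <- CutProfile(rep(0, 1000), librarySize = 1000)
  expect_equal(cutCounts(correctHint(z, bt, g)), rep(1, 1000))
  # uniform y = 1 with uniform bias: interior x = 2 / (1/50 + 1) = 100/51
  u <- CutProfile(rep(1, 1000), librarySize = 1000)
  xu <- cutCounts(correctHint(u, bt, g))
  expect_equal(xu[100:900], rep(100 / 51, 801))
  # random profile and non-uniform bias: brute-force oracle equivalence
  set.seed(6)
  y <- rpois(1000, 3)
  prof <- CutProfile(y, librarySize = sum(y))
  set.seed(7)
  bvals <- exp(rnorm(4096, 0, 0.3))
  names(bvals) <- allHexamers()
  bt2 <- BiasTable(bvals)
  b <- positionBiasVec(prof, bt2, g)
  expect_equal(cutCounts(correctHint(prof, bt2, g)), oracleHint(y, b))
})

test_that("direct bias division is exact and flattens naked-DNA profiles", {
  g <- generateGenome(1000, 0.5, seed = 36)
  set.seed(8)
  y <- rpois(1000, 5)
  prof <- CutProfile(y, librarySize = sum(y))
  expect_equal(cutCounts(correctBagfoot(prof, BiasTable(), g)), y)
  bvals <- exp(rnorm(4096, 0, 0.4)); names(bvals) <- allHexamers()
  bt <- BiasTable(bvals)
  b <- positionBiasVec(prof, bt, g)
  expect_equal(cutCounts(correctBagfoot(prof, bt, g)), y / b)
  expect_equal(cutCounts(correctBagfoot(CutProfile(10, librarySize = 10),
                                        BiasTable(c(GGGGGG = 2)),
                                        Biostrings::DNAString("AAAGGGGGGAAA"))),
               10)  # position 1 has no hexamer window; left uncorrected

  # flattening: self-estimated bias correction lowers the coefficient of
  # variation of a biased naked-DNA profile
  target <- "TGACGT"; pref <- c(4); names(pref) <- target
  gg <- generateGenome(30000, 0.5, seed = 37)
  fs <- simulateFragments(gg, NULL, BiasTable(pref), nEvents = 2e5, seed = 38)
  naked <- countCuts(fs, start = 1L, end = length(gg))
  est <- estimateBias(naked, gg)
  corr <- correctBagfoot(naked, est, gg)
  cv <- function(v) sd(v) / mean(v)
  usable <- 5:(length(gg) - 4)
  expect_lt(cv(cutCounts(corr)[usable]), cv(cutCounts(naked)[usable]))
})

test_that("the Poisson gate threshold follows the log-gamma mass oracle", {
  expect_equal(gateThreshold(0.1, 2.73e9, 0.01), 8L)
  # direct scan oracle at another parameter point
  lam <- 0.01; G <- 1e6; alpha <- 0.01
  ystar <- 0L
  while (oracleLogPmf(ystar, lam) >= log(alpha / G)) ystar <- ystar + 1L
  expect_equal(gateThreshold(lam, G, alpha), ystar)
  # enormous alpha: everything is corrected
  expect_equal(gateThreshold(0.5, 10, alpha = 1e12), 0L)
  expect_error(gateThreshold(1.5, 1e6), "lambda < 1")
  expect_error(gateThreshold(0, 1e6), "positive")
})

test_that("Poisson-gated correction rescales only above-background positions", {
  # lambda = 0.1, G = 2.73e9: the implied threshold is 8 cuts
  g <- generateGenome(200, 0.5, seed = 39)
  bvals <- c(2); names(bvals) <- hexamerAt(g, 50)
  bt <- BiasTable(bvals)
  y <- rep(0, 200); y[50] <- 8; y[51] <- 3
  prof <- CutProfile(y, librarySize = 100)
  out <- cutCounts(correctPoissonGated(prof, bt, g, genomeSize = 2.73e9,
                                       alpha = 0.01, lambda = 0.1))
  expect_equal(out[50], 4)        # 8 cuts on a bias-2 hexamer
  expect_equal(out[51], 3)        # below the gate: untouched
  expect_equal(out[-c(50, 51)], rep(0, 198))  # zeros never corrected

  # zero profile maps to itself for any realistic lambda
  z <- CutProfile(rep(0, 200), librarySize = 100)
  expect_equal(cutCounts(correctPoissonGated(z, bt, g, genomeSize = 2.73e9,
                                             lambda = 0.1)),
               rep(0, 200))
  expect_error(correctPoissonGated(z, bt, g, genomeSize = 1e6, lambda = 0),
               "lambda")
})

test_that("gated correction is piecewise equal to direct division", {
  g <- generateGenome(2000, 0.5, seed = 40)
  set.seed(9)
  y <- rpois(2000, 1)
  y[sample(2000, 30)] <- rpois(30, 25)   # accessible islands
  prof <- CutProfile(y, librarySize = sum(y))
  bvals <- exp(rnorm(4096, 0, 0.3)); names(bvals) <- allHexamers()
  bt <- BiasTable(bvals)
  G <- 1e7
  lam <- librarySize(prof) / G
  ystar <- gateThreshold(lam, G)
  gated <- cutCounts(correctPoissonGated(prof, bt, g, genomeSize = G))
  direct <- cutCounts(correctBagfoot(prof, bt, g))
  expect_identical(gated[y < ystar], cutCounts(prof)[y < ystar])
  expect_identical(gated[y >= ystar], direct[y >= ystar])
})

test_that("bias tables round-trip through TSV", {
  g <- generateGenome(3000, 0.5, seed = 41)
  y <- rep(0, 3000); y[4:(3000 - 2)] <- rpois(3000 - 5, 2)
  bt <- estimateBias(CutProfile(y), g)
  tsv <- tempfile(fileext = ".tsv")
  writeBiasTable(bt, tsv)
  bt2 <- readBiasTable(tsv)
  expect_equal(bt2@bias, bt@bias)
  expect_equal(bt2@freqGenome, bt@freqGenome)
})
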