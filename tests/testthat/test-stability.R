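test_that("noiseless chemical unfolding curves are recovered exactly", {
  truth <- list(dG0 = 4.0, m = 1.5, aN = 1.0, bN = -0.02,
                aU = 0.25, bU = 0.01)
  sim <- simulateUnfolding("chemical", params = truth, nPoints = 30,
                           noiseSd = 0, seed = 1)
  fit <- fitChemicalUnfolding(sim$curve$x, sim$curve$y)
  for (p in names(truth))
    expect_equal(fit@coefficients[[p]], truth[[p]], tolerance = 1e-6)
  expect_equal(fit@Cm, truth$dG0 / truth$m, tolerance = 1e-6)
})

test_that("the unfolded fraction is exactly one half at the midpoint", {
  # pure two-state populations: native baseline 0, unfolded baseline 1
  f <- chemicalUnfoldingSignal(4.3 / 1.55, dG0 = 4.3, m = 1.55,
                               aN = 0, bN = 0, aU = 1, bU = 0)
  expect_identical(f, 0.5)
  # and it increases monotonically with denaturant
  cs <- seq(0, 8, by = 0.1)
  fu <- chemicalUnfoldingSignal(cs, 4.3, 1.55, 0, 0, 1, 0)
  expect_true(all(diff(fu) > 0))
})

test_that("noisy replicate fits are unbiased at the study preset", {
  ests <- t(vapply(1:60, function(s) {
    sim <- simulateUnfolding("chemical", params = list(dG0 = 4.3, m = 1.55),
                             nPoints = 37, noiseSd = 0.02, seed = 1000 + s)
    fit <- fitChemicalUnfolding(sim$curve$x, sim$curve$y)
    c(dG0 = fit@coefficients[["dG0"]], m = fit@coefficients[["m"]],
      seDG = fit@se[["dG0"]])
  }, numeric(3)))
  expect_lt(abs(mean(ests[, "dG0"]) - 4.3),
            2 * sd(ests[, "dG0"]) / sqrt(nrow(ests)) + 0.02)
  expect_lt(abs(mean(ests[, "m"]) - 1.55), 0.02)
})

test_that("chemical fit rejects curves without a transition", {
  x <- seq(0, 7, length.out = 20)
  expect_error(fitChemicalUnfolding(x, 1 - 0.01 * x), "no unfolding")
  expect_error(fitChemicalUnfolding(x[1:5], rnorm(5)), "at least 8")
  expect_error(fitChemicalUnfolding(rev(x), rnorm(20)), "increasing")
})

test_that("noiseless thermal unfolding curves are recovered exactly", {
  truth <- list(Tm = 330, dHm = 60, dCp = 1.6)
  sim <- simulateUnfolding("thermal", params = truth, nPoints = 40,
                           noiseSd = 0, seed = 1)
  fit <- fitThermalUnfolding(sim$curve$x, sim$curve$y, dCp = 1.6)
  expect_equal(fit@coefficients[["Tm"]], 330, tolerance = 1e-6)
  expect_equal(fit@coefficients[["dHm"]], 60, tolerance = 1e-6)
  expect_error(fitThermalUnfolding(sim$curve$x, sim$curve$y, dCp = -1),
               "positive")
})

test_that("the Gibbs-Helmholtz stability curve is internally consistent", {
  expect_equal(gibbsHelmholtz(330, Tm = 330, dHm = 60, dCp = 1.6), 0)
  # fraction unfolded at Tm is one half
  f <- thermalUnfoldingSignal(330, 330, 60, 1.6, aN = 0, bN = 0,
                              aU = 1, bU = 0)
  expect_equal(f, 0.5)
  # the reported dG(Tref) is recomputable from the fitted parameters
  sim <- simulateUnfolding("thermal", nPoints = 40, noiseSd = 0, seed = 2)
  fit <- fitThermalUnfolding(sim$curve$x, sim$curve$y, dCp = 1.6)
  expect_equal(fit@dGTref,
               gibbsHelmholtz(293.15, fit@coefficients[["Tm"]],
                              fit@coefficients[["dHm"]], 1.6))
})

test_that("Myers chain-length correlations reproduce their printed anchors", {
  p <- myersPredict(116)
  expect_equal(unname(p["deltaASA"]), 9881)
  expect_equal(signif(unname(p["m_urea"]), 3), 1.46)
  expect_equal(signif(unname(p["dCp"]), 2), 1.6)
  # affine in chain length
  n <- c(50, 100, 150)
  d <- vapply(n, function(k) myersPredict(k)[["deltaASA"]], numeric(1))
  expect_equal(diff(d, differences = 2), 0)
  expect_error(myersPredict(10), "at least 20")
})

test_that("ddG correlations hit the algebraic extremes and planted correlation", {
  base <- data.frame(position_a = 1:30, position_b = 1:30,
                     ddg_a = seq(-1, 4, length.out = 30),
                     class = rep(c("conserved", "non_conserved", "disease"),
                                 10))
  same <- transform(base, ddg_b = ddg_a)
  r <- ddgCorrelation(same)
  expect_equal(r$pearson_r, rep(1, 4))
  expect_equal(r$slope, rep(1, 4))
  anti <- transform(base, ddg_b = -ddg_a)
  expect_equal(ddgCorrelation(anti, "all")$pearson_r, -1)

  set.seed(5)
  n <- 500
  xa <- rnorm(n)
  xb <- 0.8 * xa + sqrt(1 - 0.64) * rnorm(n)
  tab <- data.frame(position_a = 1:n, position_b = 1:n, ddg_a = xa,
                    ddg_b = xb, class = "conserved")
  r2 <- ddgCorrelation(tab, "conserved")
  expect_gt(r2$pearson_r, 0.75)
  expect_lt(r2$pearson_r, 0.85)
})

test_that("ddG correlation is invariant under exchanging the homolog columns", {
  set.seed(6)
  tab <- data.frame(position_a = 1:40, position_b = 1:40,
                    ddg_a = rnorm(40), ddg_b = rnorm(40),
                    class = rep(c("conserved", "disease"), 20))
  sw <- data.frame(position_a = tab$position_b, position_b = tab$position_a,
                   ddg_a = tab$ddg_b, ddg_b = tab$ddg_a, class = tab$class)
  expect_equal(ddgCorrelation(tab, "disease")$pearson_r,
               ddgCorrelation(sw, "disease")$pearson_r)
  expect_error(ddgCorrelation(tab[1:2, ], "all"), "fewer than 3")
  degen <- transform(tab, ddg_a = 1)
  expect_true(is.na(suppressMessages(ddgCorrelation(degen, "all"))$pearson_r))
  bad <- transform(tab, class = "weird")
  expect_error(ddgCorrelation(bad), "unknown conservation class")
})

test_that("sequence-derived constants: masses, extinction and additivity", {
  gg <- sequenceProperties("GG")
  expect_equal(gg@averageMass, 2 * 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(round(gg@averageMass, 2), 132.12)

  arom <- sequenceProperties(strrep("WY", 3))
  expect_equal(arom@epsilon280, 3 * 5500 + 3 * 1490)
  expect_equal(arom@epsilon280, 20970)

  # additive over concatenation minus one water per extra peptide bond
  a <- "ACDEFGHIKLMNPQRSTVWY"
  b <- "WWYYCCKKDD"
  pa <- sequenceProperties(a); pb <- sequenceProperties(b)
  pab <- sequenceProperties(paste0(a, b))
  expect_equal(pab@averageMass,
               pa@averageMass + pb@averageMass - 18.01524,
               tolerance = 1e-9)
  expect_equal(pab@epsilon280, pa@epsilon280 + pb@epsilon280)
  expect_error(sequenceProperties("ACXD"), "X")
  expect_error(sequenceProperties("ACDE", nCystine = 3), "nCystine")
})

test_that("average masses agree with an independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(11)
  for (i in 1:5) {
    s <- random_aa(80)
    ours <- sequenceProperties(s)@averageMass
    theirs <- seqinr::pmw(strsplit(s, "")[[1]])
    expect_equal(ours, unname(theirs), tolerance = 1e-3)
  }
})

test_that("the isoelectric point tracks sequence charge", {
  acidic <- sequenceProperties(paste0(strrep("D", 10), strrep("G", 20)))
  basic <- sequenceProperties(paste0(strrep("K", 10), strrep("G", 20)))
  expect_lt(acidic@pI, 5)
  expect_gt(basic@pI, 9)
  # net charge at the reported pI is approximately zero
  comp <- acidic@composition
  expect_lt(abs(FeSConserv:::.net_charge(acidic@pI, as.list(comp), 0L)),
            0.05)
})

test_that("SEC calibration recovers planted lines and flags extrapolation", {
  # exact line: log10(mass) = 5 - 0.25 ve
  ve <- c(8, 10, 12, 14)
  std <- data.frame(mass_kDa = 10^(5 - 0.25 * ve), ve = ve)
  out <- secInferMass(std, unknownVe = 11)
  expect_equal(out$mass_kDa, 10^(5 - 0.25 * 11), tolerance = 1e-9)
  expect_equal(out$r_squared, 1)
  expect_false(out$extrapolated)
  # an unknown eluting exactly at a standard returns that standard's mass
  out2 <- secInferMass(std, unknownVe = 10)
  expect_equal(out2$mass_kDa, std$mass_kDa[2], tolerance = 1e-9)
  expect_warning(secInferMass(std, unknownVe = 20), "extrapolat")
  jumbled <- std; jumbled$mass_kDa <- rev(jumbled$mass_kDa)
  expect_warning(secInferMass(jumbled, 11), "monotone")
  expect_error(secInferMass(std[1:2, ], 11), "at least 3")
})
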