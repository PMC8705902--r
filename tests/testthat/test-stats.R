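test_that("spearman reproduces the rank closed form and printed p", {
  x <- 1:7
  y <- c(2, 3, 1, 4, 5, 6, 7) # one 3-cycle, sum(d^2) = 6
  s <- spearman(x, y)
  expect_equal(s$rho, 1 - 6 * 6 / (7 * 48), tolerance = 1e-15)
  expect_equal(signif(s$p, 2), 0.0068) # the n = 7 clinical-pair value
  expect_equal(spearman(x, x)$rho, 1)
  expect_equal(spearman(x, x)$p, 0)
  expect_true(spearman(x, x)$degenerate)
  expect_equal(spearman(x, rev(x))$rho, -1)
  expect_error(spearman(x, rep(1, 7)), "constant")
  expect_error(spearman(1:5, 1:6), "length mismatch")
  expect_error(spearman(1:3, 3:1), "at least 4")
})

test_that("spearman matches the closed form on random permutations", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    x <- sample(n); y <- sample(n)
    s <- spearman(x, y)
    expect_equal(s$rho, 1 - 6 * sum((x - y)^2) / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }
})

test_that("t-approximation agrees with cor.test", {
  set.seed(21)
  for (i in 1:25) {
    a <- rnorm(9); b <- rnorm(9)
    s <- spearman(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman",
                                     exact = FALSE))
    expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(s$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact permutation p agrees with cor.test's exact method", {
  set.seed(31)
  for (i in 1:10) {
    x <- sample(7); y <- sample(7)
    se <- spearman(x, y, method = "exact")
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(se$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(spearman(c(1, 1, 2, 3), 1:4, method = "exact"), "tie")
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.3), 0.3)
  expect_length(fdr_bh(numeric(0)), 0)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_bh(p), p.adjust(p, method = "BH"), tolerance = 1e-15)
  }
})

test_that("feature correlation keeps planted pairs and skips constants", {
  set.seed(51)
  n <- 7
  mt <- cbind(planted = 1:n, noise = sample(n), flat = rep(2, n))
  clinical <- data.frame(timepoint = paste0("t", 1:n),
                         BMI = (1:n) * 2 + 100) # rank-identical to planted
  expect_warning(ed <- correlate_features(mt, clinical), "constant")
  keep <- ed[ed$kept, ]
  expect_true(any(keep$metabolite == "planted" & keep$clinical == "BMI"))
  expect_false("flat" %in% ed$metabolite)
  expect_true(all(ed$p_fdr >= ed$p_raw - 1e-15))
  expect_error(correlate_features(mt[1:3, ], clinical[1:3, ]),
               "at least 4")
})

test_that("null features are retained at no more than the nominal rate", {
  set.seed(61)
  tested <- 0; kept <- 0
  for (seed in 1:50) {
    mt <- matrix(runif(7 * 5), 7, 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
    clinical <- data.frame(timepoint = paste0("t", 1:7),
                           BMI = runif(7), leptin = runif(7))
    ed <- correlate_features(mt, clinical)
    tested <- tested + nrow(ed)
    kept <- kept + sum(ed$kept)
  }
  rate <- kept / tested
  mc_slack <- 2 * sqrt(0.1 * 0.9 / tested)
  expect_lte(rate, 0.1 + mc_slack)
})

test_that("the adipokine ratio divides the printed day-0/day-105 values", {
  cl <- data.frame(timepoint = c("day0", "day105"),
                   leptin = c(63.8, 34.5), adiponectin = c(2.17, 5.39))
  out <- derived_ratio(cl)
  expect_equal(round(out$lep_adip_ratio, 2), c(29.40, 6.40))
  same <- derived_ratio(data.frame(timepoint = "a", leptin = 3,
                                   adiponectin = 3))
  expect_equal(same$lep_adip_ratio, 1)
  expect_error(derived_ratio(data.frame(timepoint = "a", leptin = 1,
                                        adiponectin = 0)),
               "zero at timepoint")
})

test_that("network assembly links clinical, metabolites and producers", {
  edges <- data.frame(metabolite = c("fol", "junk"),
                      clinical = c("BMI", "BMI"),
                      rho = c(-0.9, 0.2), p_raw = c(0.005, 0.7),
                      p_fdr = c(0.02, 0.9), sign = c("-", "+"),
                      kept = c(TRUE, FALSE))
  contr <- data.frame(metabolite = c("fol", "junk"),
                      strain = c("bifA", "strB"), share = c(1, 1))
  g <- build_network(edges, contr)
  expect_equal(igraph::vcount(g), 3) # BMI, fol, bifA
  expect_equal(igraph::ecount(g), 2)
  expect_false("junk" %in% igraph::V(g)$name) # fails thresholds
  expect_false("strB" %in% igraph::V(g)$name) # its producer link goes too
  # every production edge's metabolite also carries a correlation edge
  et <- igraph::E(g)$etype
  ends <- igraph::ends(g, igraph::E(g))
  vtype <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  for (e in which(et == "production")) {
    met <- ends[e, ][vtype[ends[e, ]] == "metabolite"]
    corr_ends <- ends[et == "correlation", , drop = FALSE]
    expect_true(met %in% corr_ends)
  }
  # duplicate contribution records merge with a warning
  dup <- rbind(contr, contr[1, ])
  expect_warning(g2 <- build_network(edges, dup), "merged")
  sh <- igraph::E(g2)$share
  expect_equal(sh[!is.na(sh)], 2)
  # empty input -> empty graph
  expect_equal(igraph::vcount(build_network(edges[edges$kept == FALSE, ],
                                            contr)), 0)
})
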