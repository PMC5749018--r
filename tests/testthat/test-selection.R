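test_that("aucSingle counts case-control pairs with ties at one half", {
    expect_equal(aucSingle(c(3, 4, 1, 2),
                           c("case", "case", "control", "control")), 1)
    expect_equal(aucSingle(rep(5, 6),
                           rep(c("case", "control"), 3)), 0.5)
    expect_equal(aucSingle(c(5, 3, 1, 2, 4),
                           c("case", "case", "control", "control",
                             "control")), 5 / 6)
    expect_error(aucSingle(1:3, rep("case", 3)), "controls")
    ## invariance under strictly monotone transforms
    set.seed(41)
    v <- rnorm(30); lab <- sample(c("case", "control"), 30, TRUE,
                                  prob = c(.5, .5))
    expect_equal(aucSingle(v, lab), aucSingle(exp(2 * v), lab))
    expect_equal(aucSingle(v, lab), aucSingle(rank(v), lab))
})

test_that("dfi is the Euclidean distance from the ideal ROC corner", {
    expect_equal(dfi(1, 1), 0)
    expect_equal(dfi(0, 0), sqrt(2))
    expect_equal(dfi(0.73, 0.70), sqrt(0.27^2 + 0.30^2))
    expect_error(dfi(1.2, 0.5), "sensitivity")
    set.seed(42)
    s <- runif(50); p <- runif(50)
    expect_equal(dfi(s, p), dfi(p, s))
    expect_true(all(dfi(s, p) >= 0 & dfi(s, p) <= sqrt(2)))
})

test_that("panelCall is any-positive with an inclusive cut-off", {
    cut <- c("MYC Gain" = 4, "PTEN Homozygous" = 10)
    expect_identical(panelCall(c("MYC Gain" = 5, "PTEN Homozygous" = 0),
                               cut), "positive")
    expect_identical(panelCall(c("MYC Gain" = 4, "PTEN Homozygous" = 0),
                               cut), "positive")  # boundary: >= is positive
    expect_identical(panelCall(c("MYC Gain" = 3, "PTEN Homozygous" = 9),
                               cut), "negative")
    m <- matrix(c(NA, 2), nrow = 1,
                dimnames = list("S9", names(cut)))
    expect_error(panelCall(m, cut), "S9.*MYC Gain")
    expect_error(panelCall(c("MYC Gain" = 3), cut), "PTEN Homozygous")
})

test_that("cutoffGrid maps parameter classes to the printed ranges", {
    g <- cutoffGrid(c("MYC Gain", "PTEN Homozygous", "PTEN Loss",
                      "ETV1 Split", "ERG 2Edel"))
    expect_equal(g[["MYC Gain"]], seq(2, 15))
    expect_equal(g[["PTEN Homozygous"]], seq(10, 20))
    expect_equal(g[["PTEN Loss"]], seq(10, 20))
    expect_equal(g[["ETV1 Split"]], seq(4, 10))
    expect_equal(g[["ERG 2Edel"]], seq(4, 10))
    expect_equal(cutoffGrid("MYC Gain", step = 5)[[1]], c(2, 7, 12))
    expect_error(cutoffGrid("PTEN Ratio"), "no cut-off class")
})

test_that("perfect separation selects the largest tied cut-off", {
    m <- matrix(c(rep(20, 4), rep(0, 4)), ncol = 1,
                dimnames = list(sprintf("S%d", 1:8), "MYC Gain"))
    lab <- rep(c("case", "control"), each = 4)
    res <- optimizeCutoffs("MYC Gain", m, lab)
    expect_equal(unname(res$cutoffs), 15)
    expect_equal(res$sensitivity, 1)
    expect_equal(res$specificity, 1)
    expect_equal(res$dfi, 0)
    expect_identical(unname(res$calls),
                     rep(c("positive", "negative"), each = 4))
})

test_that("singleton grids reduce to direct evaluation", {
    set.seed(43)
    ds <- randomDataset(5, 5, c("A Gain", "B Gain"))
    grid <- list("A Gain" = 7, "B Gain" = 3)
    res <- optimizeCutoffs(c("A Gain", "B Gain"), ds$values, ds$labels,
                           grid = grid)
    direct <- sensSpecAt(ds$values, ds$labels,
                         c("A Gain" = 7, "B Gain" = 3))
    expect_equal(res$sensitivity, direct$sens)
    expect_equal(res$specificity, direct$spec)
    expect_equal(res$dfi, dfi(direct$sens, direct$spec))
})

test_that("the dominance-count search equals naive enumeration on a
           3-parameter toy instance", {
    set.seed(44)
    pars <- c("A Gain", "B Gain", "C Gain")
    ds <- randomDataset(6, 6, pars, maxVal = 12)
    grid <- list("A Gain" = c(2, 6, 10), "B Gain" = c(3, 5, 9),
                 "C Gain" = c(1, 4, 12))
    res <- optimizeCutoffs(pars, ds$values, ds$labels, grid = grid)
    ref <- naiveOptimize(pars, ds$values, ds$labels, grid)
    expect_equal(res$dfi, ref$d)
    expect_equal(res$cutoffs, ref$cut)
    expect_equal(res$sensitivity, ref$sens)
    expect_equal(res$specificity, ref$spec)
})

test_that("combinationAuc reduces to aucSingle for one parameter and
           ignores duplicated parameters", {
    set.seed(45)
    n <- 40
    v <- c(rnorm(20, 8, 3), rnorm(20, 4, 3))
    m <- cbind("MYC Gain" = v, "NMYC Gain" = rnorm(n, 5, 2))
    rownames(m) <- sprintf("S%02d", 1:n)
    lab <- rep(c("case", "control"), each = 20)
    a1 <- combinationAuc("MYC Gain", m, lab)
    expect_equal(as.numeric(a1), aucSingle(m[, "MYC Gain"], lab),
                 tolerance = 1e-12)
    a2 <- combinationAuc(c("MYC Gain", "MYC Gain", "NMYC Gain"), m, lab)
    a3 <- combinationAuc(c("MYC Gain", "NMYC Gain"), m, lab)
    expect_equal(as.numeric(a2), as.numeric(a3), tolerance = 1e-12)
})

test_that("logistic combination scores agree with a glm oracle and
           pair counting", {
    set.seed(46)
    pars <- c("MYC Gain", "FGFR1 Gain")
    m <- cbind(c(rnorm(15, 6, 3), rnorm(15, 4, 3)),
               c(rnorm(15, 5, 2), rnorm(15, 5, 2)))
    colnames(m) <- pars
    rownames(m) <- sprintf("S%02d", 1:30)
    lab <- rep(c("case", "control"), each = 15)
    got <- combinationAuc(pars, m, lab)
    g <- glm(I(lab == "case") ~ m[, 1] + m[, 2], family = binomial)
    expect_equal(as.numeric(got), bruteAuc(fitted(g), lab),
                 tolerance = 1e-9)
})

test_that("enumerateAndRank covers all subsets and orders by AUC then
           DFI", {
    set.seed(47)
    pars <- c("MYC Gain", "FGFR1 Gain", "NMYC Gain", "ETV1 Split")
    ds <- randomDataset(8, 8, pars, maxVal = 20)
    rk <- enumerateAndRank(ds$values, candidates = pars,
                           labels = ds$labels, kMin = 3, kMax = 4)
    expect_equal(nrow(rk$table), choose(4, 3) + 1)
    expect_true(all(diff(rk$table$auc) <= 1e-12))
    ties <- diff(rk$table$auc) == 0
    expect_true(all(diff(rk$table$dfi)[ties] >= -1e-12))
    ## per-size leaders are the best row of each size
    for (k in 3:4) {
        sub <- rk$table[rk$table$n_parameters == k, ]
        expect_identical(rk$leaders$combination_id[
            rk$leaders$n_parameters == k], sub$combination_id[1])
    }
    expect_identical(
        nrow(enumerateAndRank(ds$values, candidates = pars[1:3],
                              labels = ds$labels, kMin = 3,
                              kMax = 3)$table), 1L)
    expect_error(enumerateAndRank(ds$values, candidates = pars[1:2],
                                  labels = ds$labels), "kMin")
})
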