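test_that("fitLogistic matches the 2x2 closed form and a glm oracle", {
    ## saturated 2x2: OR is the cross-product ratio, SE the root of the
    ## summed reciprocal cells
    fit <- fitLogistic(matrix(c(1, 0), ncol = 1,
                              dimnames = list(NULL, "marker")),
                       y = c(19 / 25, 10 / 29), weights = c(25, 29))
    expect_true(fit$converged)
    tr <- fit$terms[fit$terms$term == "marker", ]
    expect_equal(tr$odds_ratio, crossProductOr(19, 10, 6, 19),
                 tolerance = 1e-8)
    expect_equal(tr$standard_error, waldSe2x2(19, 10, 6, 19),
                 tolerance = 1e-8)
    expect_equal(tr$ci_low, exp(tr$coefficient -
                                    qnorm(0.975) * tr$standard_error))

    set.seed(51)
    n <- 120
    x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-0.4 + 0.9 * x1 - 0.5 * x2))
    fit <- fitLogistic(cbind(x1 = x1, x2 = x2), y)
    g <- glm(y ~ x1 + x2, family = binomial)
    expect_equal(fit$terms$coefficient, unname(coef(g)),
                 tolerance = 1e-7)
    expect_equal(fit$terms$standard_error,
                 unname(summary(g)$coefficients[, 2]), tolerance = 1e-6)
    expect_equal(fit$log_likelihood, as.numeric(logLik(g)),
                 tolerance = 1e-8)
})

test_that("the IRLS log-likelihood never decreases", {
    set.seed(52)
    for (i in 1:20) {
        n <- sample(20:60, 1)
        x <- matrix(rnorm(2 * n), ncol = 2,
                    dimnames = list(NULL, c("a", "b")))
        y <- rbinom(n, 1, plogis(x %*% c(1.5, -1)))
        if (length(unique(y)) < 2) next
        fit <- fitLogistic(x, y)
        expect_true(all(diff(fit$log_lik_trace) >= -1e-8))
    }
})

test_that("degenerate designs raise named errors; separation is
           diagnosed, not fatal", {
    x <- matrix(1, nrow = 10, ncol = 1, dimnames = list(NULL, "flat"))
    y <- rep(c(0, 1), 5)
    expect_error(fitLogistic(x, y), "collinear.*flat")
    set.seed(53)
    xs <- matrix(c(rnorm(10, 5), rnorm(10, -5)), ncol = 1,
                 dimnames = list(NULL, "x"))
    ys <- rep(c(1, 0), each = 10)
    fit <- fitLogistic(xs, ys)
    expect_false(fit$converged)
    expect_match(fit$message, "separation")
})

test_that("fits are invariant to row order and flip sign under label
           swap", {
    set.seed(54)
    n <- 60
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
    y <- rbinom(n, 1, plogis(0.8 * x))
    f1 <- fitLogistic(x, y)
    perm <- sample(n)
    f2 <- fitLogistic(x[perm, , drop = FALSE], y[perm])
    expect_equal(f1$terms$coefficient, f2$terms$coefficient,
                 tolerance = 1e-9)
    f3 <- fitLogistic(x, 1 - y)
    expect_equal(f3$terms$coefficient[2], -f1$terms$coefficient[2],
                 tolerance = 1e-7)
})

test_that("fishOnlyModel reports the FISH odds ratio and handles empty
           cells", {
    calls <- rep(c("positive", "negative", "positive", "negative"),
                 c(19, 10, 6, 19))
    outcome <- rep(c("case", "control"), c(29, 25))
    fit <- fishOnlyModel(calls, outcome)
    expect_equal(fit$terms$odds_ratio[2], 6.0167, tolerance = 1e-4)
    expect_null(fit$haldane)
    expect_error(fishOnlyModel(rep("positive", 10),
                               rep(c("case", "control"), 5)),
                 "collinear")
    ## an empty 2x2 cell: divergence flagged, Haldane auxiliary reported
    calls0 <- rep(c("positive", "negative"), c(10, 10))
    out0 <- rep(c("case", "control"), each = 10)
    fit0 <- fishOnlyModel(calls0, out0)
    expect_false(fit0$converged)
    expect_equal(fit0$haldane$odds_ratio,
                 (10.5 * 10.5) / (0.5 * 0.5))
})

test_that("fishClinicalModel adjusts for NCCN risk and degrades
           gracefully", {
    set.seed(55)
    n <- 80
    risk <- sample(c("Low", "Intermediate", "High"), n, TRUE)
    fish <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(-1 + 1.2 * fish + 0.5 * nccnOrdinal(risk)))
    calls <- ifelse(fish == 1, "positive", "negative")
    outcome <- ifelse(y == 1, "case", "control")
    fit <- fishClinicalModel(calls, risk, outcome)
    expect_setequal(fit$terms$term, c("(Intercept)", "FISH", "NCCN"))
    ref <- glm(y ~ fish + nccnOrdinal(risk), family = binomial)
    expect_equal(fit$terms$coefficient, unname(coef(ref)),
                 tolerance = 1e-7)
    ## dummy coding fits one term per non-reference risk group
    fitD <- fishClinicalModel(calls, risk, outcome, riskCoding = "dummy")
    expect_true(all(c("NCCNIntermediate", "NCCNHigh") %in%
                        fitD$terms$term))
    ## constant risk group reduces to the FISH-only model
    fitC <- fishClinicalModel(calls, rep("Low", n), outcome)
    f0 <- fishOnlyModel(calls, outcome)
    expect_equal(fitC$terms[fitC$terms$term == "FISH", -1],
                 f0$terms[f0$terms$term == "FISH", -1])
    expect_match(fitC$message, "constant")
})

test_that("adjustment moves the FISH OR only under confounding", {
    set.seed(56)
    n <- 400
    risk <- sample(c("Low", "Intermediate", "High"), n, TRUE)
    ## confounded: positivity increases with risk, outcome driven by risk
    pFish <- plogis(-2 + nccnOrdinal(risk))
    fish <- rbinom(n, 1, pFish)
    y <- rbinom(n, 1, plogis(-2.5 + 0.9 * nccnOrdinal(risk)))
    calls <- ifelse(fish == 1, "positive", "negative")
    outcome <- ifelse(y == 1, "case", "control")
    un <- fishOnlyModel(calls, outcome)
    ad <- fishClinicalModel(calls, risk, outcome)
    orUn <- un$terms$odds_ratio[un$terms$term == "FISH"]
    orAd <- ad$terms$odds_ratio[ad$terms$term == "FISH"]
    ## positive confounding inflates the crude OR; adjustment shrinks it
    expect_lt(orAd, orUn)

    ## orthogonal: calls independent of risk leave the OR essentially
    ## unchanged (averaged over replicates)
    diffs <- vapply(1:10, function(i) {
        fish <- rbinom(n, 1, 0.4)
        y <- rbinom(n, 1, plogis(-1 + 1.1 * fish))
        calls <- ifelse(fish == 1, "positive", "negative")
        outcome <- ifelse(y == 1, "case", "control")
        a <- fishOnlyModel(calls, outcome)
        b <- fishClinicalModel(calls, risk, outcome)
        log(b$terms$odds_ratio[b$terms$term == "FISH"]) -
            log(a$terms$odds_ratio[a$terms$term == "FISH"])
    }, numeric(1))
    expect_lt(abs(mean(diffs)), 0.1)
})

test_that("clinicalOnlyModel recovers a planted risk effect and a null
           age effect", {
    set.seed(57)
    n <- 300
    risk <- sample(c("VeryLow", "Low", "Intermediate", "High"), n, TRUE)
    age <- sample(50:80, n, TRUE)
    y <- rbinom(n, 1, plogis(-2 + 0.8 * nccnOrdinal(risk)))
    fit <- clinicalOnlyModel(risk, age,
                             ifelse(y == 1, "case", "control"))
    trN <- fit$terms[fit$terms$term == "NCCN", ]
    trA <- fit$terms[fit$terms$term == "Age", ]
    expect_gt(trN$odds_ratio, 1)
    expect_lt(trN$p_value, 0.05)
    ## age was generated independent of outcome: CI covers the null
    expect_true(trA$ci_low < 1 && trA$ci_high > 1)
})

test_that("stratifiedAnalysis partitions correctly and skips degenerate
           strata", {
    set.seed(58)
    n <- 90
    risk <- sample(c("VeryLow", "Low", "Intermediate", "High"), n, TRUE)
    clin <- makeClinical(sprintf("S%02d", 1:n),
                         sample(c("case", "control"), n, TRUE),
                         risk = risk)
    calls <- sample(c("positive", "negative"), n, TRUE)
    st <- stratifiedAnalysis(calls, clin)
    expect_identical(st$stratum, c("Lower", "Intermediate", "Higher"))
    ## merging VeryLow+Low matches a direct filtering oracle
    lower <- clin$risk_group %in% c("VeryLow", "Low")
    ref <- fishOnlyModel(calls[lower], clin$outcome[lower])
    expect_equal(st$odds_ratio[1],
                 ref$terms$odds_ratio[ref$terms$term == "FISH"],
                 tolerance = 1e-9)
    expect_identical(st$n_cases[1], sum(clin$outcome[lower] == "case"))

    ## a stratum with one outcome class is skipped with a note
    clin2 <- clin
    clin2$outcome[clin2$risk_group == "High"] <- "case"
    st2 <- stratifiedAnalysis(calls, clin2)
    expect_match(st2$note[st2$stratum == "Higher"], "single outcome")
    expect_true(is.na(st2$odds_ratio[st2$stratum == "Higher"]))
})

test_that("haldaneOddsRatio applies the +0.5 correction", {
    h <- haldaneOddsRatio(5, 0, 2, 7)
    expect_equal(h$odds_ratio, (5.5 * 7.5) / (0.5 * 2.5))
    expect_equal(h$standard_error,
                 sqrt(1 / 5.5 + 1 / 0.5 + 1 / 2.5 + 1 / 7.5))
})

test_that("the fish-only OR recovers a planted positivity-outcome
           association across seeds", {
    set.seed(59)
    ## generating model: P(case | pos)/P(case | neg) odds multiplier 5
    ors <- vapply(1:50, function(i) {
        n <- 120
        fish <- rbinom(n, 1, 0.45)
        y <- rbinom(n, 1, plogis(-0.9 + log(5) * fish))
        tab <- table(factor(fish, 0:1), factor(y, 0:1))
        if (any(tab == 0)) return(NA_real_)
        fit <- fishOnlyModel(ifelse(fish == 1, "positive", "negative"),
                             ifelse(y == 1, "case", "control"))
        fit$terms$odds_ratio[fit$terms$term == "FISH"]
    }, numeric(1))
    ors <- ors[!is.na(ors)]
    mlog <- mean(log(ors))
    se <- sd(log(ors)) / sqrt(length(ors))
    expect_lt(abs(mlog - log(5)), 3 * se + 0.05)
})
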