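.fastDF <- function(lst, n) {
    structure(lst, class = "data.frame", row.names = seq_len(n))
}

## solve(A, b) / diag(solve(A)) with a closed form for the ubiquitous
## 2x2 case (intercept + one predictor), avoiding LAPACK dispatch cost
.solveSym <- function(A, b) {
    if (nrow(A) == 2L) {
        d <- A[1L] * A[4L] - A[2L] * A[3L]
        if (!is.finite(d) || d == 0) stop("singular information matrix")
        c(A[4L] * b[1L] - A[3L] * b[2L],
          A[1L] * b[2L] - A[2L] * b[1L]) / d
    } else as.vector(solve(A, b))
}

.invDiagSym <- function(A) {
    if (nrow(A) == 2L) {
        d <- A[1L] * A[4L] - A[2L] * A[3L]
        if (!is.finite(d) || d == 0) stop("singular information matrix")
        c(A[4L], A[1L]) / d
    } else as.vector(diag(solve(A)))
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits an unpenalised logistic regression by iteratively reweighted
#' least squares with step-halving (so the log-likelihood is
#' non-decreasing across iterations), convergence tolerance `1e-8` on
#' the maximum coefficient change and at most 50 iterations. Wald
#' standard errors come from the inverse observed information; odds
#' ratios, 95% Wald confidence limits and Wald chi-square p-values are
#' reported per term. A rank-deficient design is an error naming the
#' collinear terms; (quasi-)complete separation yields
#' `converged = FALSE` with a diagnostic message rather than an error.
#'
#' @param x Numeric design matrix of predictors (no intercept column;
#'   one is added unless `intercept = FALSE`).
#' @param y Outcome: 0/1 (or proportions in `[0, 1]` with case
#'   `weights`), or a `"case"`/`"control"` vector.
#' @param weights Optional non-negative case/frequency weights
#'   (binomial denominators when `y` is a proportion).
#' @param intercept Add an intercept column (default `TRUE`).
#' @param tol,maxIter IRLS convergence tolerance and iteration cap.
#' @return A list of class `"LogisticFit"`: `terms` (a `data.frame`
#'   with `term`, `coefficient`, `standard_error`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`), `converged`, `message`,
#'   `n_cases`, `n_controls`, `log_likelihood`, `log_lik_trace`,
#'   `iterations`, `fitted`.
#' @examples
#' ## 2x2 table a=19 (case, marker+), b=10, c=6, d=19: OR = 19*19/(10*6)
#' fit <- fitLogistic(matrix(c(1, 0), ncol = 1,
#'                           dimnames = list(NULL, "marker")),
#'                    y = c(19 / 25, 10 / 29), weights = c(25, 29))
#' fit$terms
#' @export
fitLogistic <- function(x, y, weights = NULL, intercept = TRUE,
                        tol = 1e-8, maxIter = 50L) {
    if (!is.matrix(x)) x <- as.matrix(x)
    if (is.character(y) || is.factor(y)) {
        y <- as.character(y)
        if (!all(y %in% c("case", "control")))
            stop("character outcome must be 'case'/'control'")
        y <- as.numeric(y == "case")
    }
    if (any(y < 0 | y > 1)) stop("y must lie in [0, 1]")
    n <- length(y)
    if (nrow(x) != n) stop("design and outcome sizes differ")
    if (is.null(weights)) weights <- rep(1, n)
    if (any(weights < 0)) stop("weights must be non-negative")
    if (intercept) x <- cbind(`(Intercept)` = 1, x)
    p <- ncol(x)
    if (is.null(colnames(x)))
        colnames(x) <- paste0("x", seq_len(p))
    nCase <- sum(weights * y); nCtl <- sum(weights * (1 - y))
    if (nCase <= 0 || nCtl <= 0)
        stop("both cases and controls are required")
    xe <- if (any(weights == 0)) x * sqrt(weights) else x
    G <- crossprod(xe)
    fullRank <- if (p <= 2L) {
        det2 <- if (p == 1L) G[1L] else G[1L] * G[4L] - G[2L] * G[3L]
        det2 > max(1e-10 * prod(diag(G)), 0)
    } else FALSE
    if (!fullRank) {  # confirm and name the collinear terms
        qx <- qr(xe)
        if (qx$rank < p) {
            dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):p]]
            stop("rank-deficient design: collinear term(s) ",
                 paste(dropped, collapse = ", "))
        }
    }

    logLik <- function(mu)
        sum(weights * (y * log(mu) + (1 - y) * log(1 - mu)))
    clamp <- function(mu) {  # cheaper than pmin/pmax on short vectors
        mu[mu < 1e-12] <- 1e-12
        mu[mu > 1 - 1e-12] <- 1 - 1e-12
        mu
    }
    beta <- numeric(p)
    eta <- drop(x %*% beta)
    mu <- clamp(plogis(eta))
    ll <- logLik(mu)
    llTrace <- ll
    converged <- FALSE
    msg <- ""
    iter <- 0L
    tryCatch(while (iter < maxIter) {
        iter <- iter + 1L
        v <- mu * (1 - mu)
        v[v < 1e-12] <- 1e-12
        xw <- x * (weights * v)
        betaNew <- .solveSym(crossprod(x, xw),
                             crossprod(xw, eta + (y - mu) / v))
        ## step-halve if the full Newton step decreases the likelihood
        step <- betaNew - beta
        h <- 1
        repeat {
            cand <- beta + h * step
            etaC <- as.vector(x %*% cand)
            muC <- clamp(plogis(etaC))
            llC <- logLik(muC)
            if (llC >= ll - 1e-12 || h < 1e-4) break
            h <- h / 2
        }
        delta <- max(abs(cand - beta))
        beta <- cand; eta <- etaC; mu <- muC; ll <- llC
        llTrace <- c(llTrace, ll)
        if (delta < tol) { converged <- TRUE; break }
    }, error = function(e)
        msg <<- "information matrix is numerically singular")
    if (!converged && msg == "") {
        msg <- if (max(abs(beta)) > 10)
            paste0("did not converge in ", maxIter, " iterations; ",
                   "coefficients diverging (possible quasi-complete ",
                   "separation)")
        else
            paste0("did not converge in ", maxIter, " iterations")
    }
    v <- mu * (1 - mu)
    info <- crossprod(x, x * (weights * v))
    se <- tryCatch(sqrt(.invDiagSym(info)),
                   error = function(e) rep(NA_real_, p))
    zq <- qnorm(0.975)
    wald <- (beta / se)^2
    terms <- .fastDF(list(
        term = colnames(x),
        coefficient = beta,
        standard_error = se,
        odds_ratio = exp(beta),
        ci_low = exp(beta - zq * se),
        ci_high = exp(beta + zq * se),
        p_value = pchisq(wald, df = 1, lower.tail = FALSE)), p)
    out <- list(terms = terms, converged = converged, message = msg,
                n_cases = nCase, n_controls = nCtl,
                log_likelihood = ll, log_lik_trace = llTrace,
                iterations = iter, fitted = unname(mu))
    class(out) <- "LogisticFit"
    out
}

#' @export
print.LogisticFit <- function(x, ...) {
    cat("LogisticFit:", x$n_cases, "cases /", x$n_controls, "controls;",
        if (x$converged) "converged" else paste0("NOT converged (",
                                                 x$message, ")"),
        "in", x$iterations, "iterations\n")
    print(x$terms, row.names = FALSE, digits = 4)
    invisible(x)
}

#' Haldane-Anscombe corrected odds ratio of a 2x2 table
#'
#' Adds 0.5 to every cell before forming the cross-product ratio and
#' its Wald interval; the standard auxiliary estimate reported when a
#' table cell is empty and the logistic MLE diverges. Never silently
#' substituted for the MLE.
#'
#' @param a,b,c,d Cell counts: case/positive, case/negative,
#'   control/positive, control/negative.
#' @return List with `odds_ratio`, `standard_error` (log scale),
#'   `ci_low`, `ci_high`.
#' @export
haldaneOddsRatio <- function(a, b, c, d) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c + 0.5) +
                   1 / (d + 0.5))
    zq <- qnorm(0.975)
    list(odds_ratio = or, standard_error = se,
         ci_low = exp(log(or) - zq * se), ci_high = exp(log(or) + zq * se))
}

.fish01 <- function(calls) {
    calls <- as.character(calls)
    if (!all(calls %in% c("positive", "negative")))
        stop("calls must be 'positive'/'negative'")
    as.numeric(calls == "positive")
}

.outcome01 <- function(outcome) {
    outcome <- as.character(outcome)
    if (!all(outcome %in% c("case", "control")))
        stop("outcome must be 'case'/'control'")
    as.numeric(outcome == "case")
}

.crossTable <- function(fish, y) {
    c(a = sum(y == 1 & fish == 1), b = sum(y == 1 & fish == 0),
      c = sum(y == 0 & fish == 1), d = sum(y == 0 & fish == 0))
}

#' FISH-only logistic model
#'
#' `outcome ~ intercept + FISH positivity`. When a cell of the implied
#' 2x2 table is empty the MLE diverges: the fit is flagged
#' non-converged and a Haldane-Anscombe corrected odds ratio is
#' attached as the auxiliary `haldane` element.
#'
#' @param calls `"positive"`/`"negative"` panel call per specimen.
#' @param outcome `"case"`/`"control"` per specimen.
#' @return A `"LogisticFit"` (see [fitLogistic()]) with an extra
#'   `haldane` element when any 2x2 cell is empty.
#' @export
fishOnlyModel <- function(calls, outcome) {
    fish <- .fish01(calls)
    y <- .outcome01(outcome)
    fit <- fitLogistic(matrix(fish, ncol = 1,
                              dimnames = list(NULL, "FISH")), y)
    tab <- .crossTable(fish, y)
    if (any(tab == 0))
        fit$haldane <- haldaneOddsRatio(tab[["a"]], tab[["b"]],
                                        tab[["c"]], tab[["d"]])
    fit
}

#' FISH plus NCCN risk-group logistic model
#'
#' `outcome ~ intercept + FISH + NCCN risk`, with NCCN risk entered as
#' a single ordinal score (Very Low = 1 .. High = 4) by default, or
#' dummy-coded with `riskCoding = "dummy"`. When the risk group is
#' constant the NCCN term is dropped (with a note in `message`) and
#' the fit reduces to the FISH-only model.
#'
#' @param calls,outcome As in [fishOnlyModel()].
#' @param riskGroup NCCN risk-group label per specimen.
#' @param riskCoding `"ordinal"` or `"dummy"`.
#' @return A `"LogisticFit"`.
#' @export
fishClinicalModel <- function(calls, riskGroup, outcome,
                              riskCoding = c("ordinal", "dummy")) {
    riskCoding <- match.arg(riskCoding)
    fish <- .fish01(calls)
    y <- .outcome01(outcome)
    if (length(unique(riskGroup)) < 2) {
        fit <- fishOnlyModel(calls, outcome)
        fit$message <- paste0("risk group is constant; NCCN term dropped",
                              if (nzchar(fit$message))
                                  paste0(" / ", fit$message))
        return(fit)
    }
    X <- if (riskCoding == "ordinal") {
        cbind(FISH = fish, NCCN = nccnOrdinal(riskGroup))
    } else {
        lev <- intersect(.riskGroups, unique(riskGroup))
        dummies <- vapply(lev[-1], function(g) as.numeric(riskGroup == g),
                          numeric(length(fish)))
        colnames(dummies) <- paste0("NCCN", lev[-1])
        cbind(FISH = fish, dummies)
    }
    fitLogistic(X, y)
}

#' Clinical-only logistic model
#'
#' `outcome ~ intercept + NCCN ordinal score + age (years)`.
#'
#' @param riskGroup NCCN risk-group label per specimen.
#' @param age Age in years per specimen.
#' @param outcome `"case"`/`"control"` per specimen.
#' @return A `"LogisticFit"`.
#' @export
clinicalOnlyModel <- function(riskGroup, age, outcome) {
    y <- .outcome01(outcome)
    X <- cbind(NCCN = nccnOrdinal(riskGroup), Age = as.numeric(age))
    fitLogistic(X, y)
}

#' Risk-stratified FISH-only analysis
#'
#' Collapses NCCN risk groups into three strata (Lower = Very Low +
#' Low, Intermediate, Higher = High) and fits the FISH-only model
#' within each. Strata with a single outcome class or constant calls
#' are skipped with a diagnostic note rather than failing; empty-cell
#' strata additionally report the Haldane-Anscombe corrected odds
#' ratio.
#'
#' @param calls `"positive"`/`"negative"` panel call per specimen.
#' @param clinical Clinical records with `risk_group` (and `outcome`
#'   unless given separately).
#' @param outcome Optional `"case"`/`"control"` vector overriding
#'   `clinical$outcome`.
#' @return A `data.frame` with one row per stratum: `stratum`,
#'   `n_cases`, `n_controls`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `converged`, `odds_ratio_haldane`, `note`. Fit objects
#'   are attached as attribute `"fits"`.
#' @export
stratifiedAnalysis <- function(calls, clinical, outcome = NULL) {
    if (is.null(outcome)) outcome <- clinical$outcome
    strata <- riskStratum(clinical$risk_group)
    rows <- list(); fits <- list()
    for (s in levels(strata)) {
        idx <- strata == s
        y <- .outcome01(outcome[idx])
        nCase <- as.integer(sum(y == 1)); nCtl <- as.integer(sum(y == 0))
        row <- data.frame(stratum = s, n_cases = nCase, n_controls = nCtl,
                          odds_ratio = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = NA_real_,
                          converged = FALSE,
                          odds_ratio_haldane = NA_real_, note = "",
                          stringsAsFactors = FALSE)
        if (nCase == 0 || nCtl == 0) {
            row$note <- "skipped: single outcome class"
        } else if (length(unique(calls[idx])) < 2) {
            row$note <- "skipped: constant FISH call"
        } else {
            fit <- fishOnlyModel(calls[idx], outcome[idx])
            fits[[s]] <- fit
            tr <- fit$terms[fit$terms$term == "FISH", ]
            row$converged <- fit$converged
            if (fit$converged) {
                row$odds_ratio <- tr$odds_ratio
                row$ci_low <- tr$ci_low
                row$ci_high <- tr$ci_high
            } else {
                row$note <- fit$message
            }
            row$p_value <- tr$p_value
            if (!is.null(fit$haldane))
                row$odds_ratio_haldane <- fit$haldane$odds_ratio
        }
        rows[[s]] <- row
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "fits") <- fits
    out
}

.term <- function(fit, name) fit$terms[fit$terms$term == name, ]

#' Association-model summary tables for selected combinations
#'
#' For each selected combination, fits the FISH-only and FISH +
#' NCCN risk-group models and assembles one row per combination
#' (combination, n cases/controls, FISH-only OR/CI/p, adjusted FISH
#' OR/CI/p, NCCN OR/CI/p); `stratifiedModelTable()` does the same for
#' the three-stratum risk-stratified analysis.
#'
#' @param ranking A `"CombinationRanking"` from [enumerateAndRank()].
#' @param cohort The [`FishCohort`] the ranking was computed on.
#' @param combinationIds Combinations to model (default: the per-size
#'   leaders).
#' @return A `data.frame`, one row per combination (for
#'   `stratifiedModelTable()`, one row per combination and stratum).
#' @export
modelTable <- function(ranking, cohort,
                       combinationIds = ranking$leaders$combination_id) {
    clin <- clinicalData(cohort)
    rows <- lapply(combinationIds, function(id) {
        res <- ranking$results[[id]]
        calls <- res$calls[clin$specimen_id]
        f0 <- fishOnlyModel(calls, clin$outcome)
        f1 <- fishClinicalModel(calls, clin$risk_group, clin$outcome)
        t0 <- .term(f0, "FISH"); t1 <- .term(f1, "FISH")
        tn <- .term(f1, "NCCN")
        data.frame(
            combination_id = id,
            parameters = paste(res$parameters, collapse = " & "),
            n_cases = res$n_cases, n_controls = res$n_controls,
            fish_or = t0$odds_ratio, fish_ci_low = t0$ci_low,
            fish_ci_high = t0$ci_high, fish_p = t0$p_value,
            fish_converged = f0$converged,
            adj_fish_or = t1$odds_ratio, adj_fish_ci_low = t1$ci_low,
            adj_fish_ci_high = t1$ci_high, adj_fish_p = t1$p_value,
            nccn_or = if (nrow(tn)) tn$odds_ratio else NA_real_,
            nccn_ci_low = if (nrow(tn)) tn$ci_low else NA_real_,
            nccn_ci_high = if (nrow(tn)) tn$ci_high else NA_real_,
            nccn_p = if (nrow(tn)) tn$p_value else NA_real_,
            adj_converged = f1$converged,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' @rdname modelTable
#' @export
stratifiedModelTable <- function(ranking, cohort,
                                 combinationIds =
                                     ranking$leaders$combination_id) {
    clin <- clinicalData(cohort)
    rows <- lapply(combinationIds, function(id) {
        res <- ranking$results[[id]]
        calls <- res$calls[clin$specimen_id]
        st <- stratifiedAnalysis(calls, clin)
        cbind(combination_id = id,
              parameters = paste(res$parameters, collapse = " & "),
              st, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
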