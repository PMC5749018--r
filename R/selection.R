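## Coerce (x, labels) into a specimens-by-parameters value matrix plus a
## control/case factor. x may be a FishCohort or a numeric matrix.
.valuesAndLabels <- function(x, labels = NULL) {
    if (methods::is(x, "FishCohort")) {
        values <- t(parameterMatrix(x))
        labels <- outcomeLabels(x)
    } else {
        values <- as.matrix(x)
        if (is.null(labels))
            stop("labels are required when x is a matrix")
    }
    labels <- as.character(labels)
    if (!all(labels %in% c("case", "control")))
        stop("labels must be 'case' or 'control'")
    if (length(labels) != nrow(values))
        stop("labels length must match the number of specimens")
    list(values = values, labels = labels)
}

#' Mann-Whitney AUC of a single marker
#'
#' Area under the empirical ROC curve for one continuous marker:
#' the probability that a random case outscores a random control, ties
#' counted one half. Equals the trapezoidal area under the empirical
#' ROC curve and is invariant under strictly monotone transforms.
#'
#' @param values Numeric marker values, one per specimen.
#' @param labels `"case"` / `"control"` per specimen (character or
#'   factor).
#' @return AUC in `[0, 1]`.
#' @examples
#' aucSingle(c(5, 3, 1, 2, 4), c("case", "case", "control", "control",
#'                               "control"))  # 5/6
#' @export
aucSingle <- function(values, labels) {
    labels <- as.character(labels)
    if (length(values) != length(labels))
        stop("values and labels must have equal length")
    isCase <- labels == "case"
    nCase <- sum(isCase); nCtl <- sum(labels == "control")
    if (nCase == 0 || nCtl == 0)
        stop("both cases and controls are required")
    r <- rank(values, ties.method = "average")
    (sum(r[isCase]) - nCase * (nCase + 1) / 2) / (nCase * nCtl)
}

#' Distance from ideal (DFI)
#'
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)`: the Euclidean
#' distance of an operating point from the perfect-classifier corner of
#' ROC space. 0 is ideal; the worst corner (0, 0) gives `sqrt(2)`.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]` (vectorised).
#' @return DFI in `[0, sqrt(2)]`.
#' @examples
#' dfi(1, 1)          # 0
#' dfi(0.73, 0.70)    # 0.40361...
#' @export
dfi <- function(sensitivity, specificity) {
    if (any(!is.finite(sensitivity)) || any(sensitivity < 0) ||
        any(sensitivity > 1))
        stop("sensitivity must lie in [0, 1]")
    if (any(!is.finite(specificity)) || any(specificity < 0) ||
        any(specificity > 1))
        stop("specificity must lie in [0, 1]")
    sqrt((1 - sensitivity)^2 + (1 - specificity)^2)
}

#' Any-positive panel call
#'
#' A specimen is panel-positive if any FISH parameter in the
#' combination is greater than or equal to its cut-off, and negative
#' only if all parameters fall below their cut-offs.
#'
#' @param values A specimens-by-parameters numeric matrix (or a single
#'   named row vector).
#' @param cutoffs Named numeric cut-offs; every name must be a column
#'   of `values`, with no missing values.
#' @return Character vector `"positive"` / `"negative"` per specimen.
#' @examples
#' panelCall(c("MYC Gain" = 5, "PTEN Homozygous" = 0),
#'           c("MYC Gain" = 4, "PTEN Homozygous" = 10))  # "positive"
#' @export
panelCall <- function(values, cutoffs) {
    wasVector <- is.null(dim(values))
    if (wasVector)
        values <- matrix(values, nrow = 1,
                         dimnames = list("specimen", names(values)))
    missing <- setdiff(names(cutoffs), colnames(values))
    if (length(missing))
        stop("missing parameter value(s): ",
             paste(missing, collapse = ", "))
    v <- values[, names(cutoffs), drop = FALSE]
    if (anyNA(v)) {
        bad <- which(is.na(v), arr.ind = TRUE)
        stop("missing parameter value for specimen '",
             rownames(v)[bad[1, 1]], "', parameter '",
             colnames(v)[bad[1, 2]], "'")
    }
    pos <- rowSums(v >= rep(cutoffs, each = nrow(v))) > 0
    out <- ifelse(pos, "positive", "negative")
    if (wasVector) unname(out) else out
}

#' Candidate cut-off grids per parameter
#'
#' Cut-off search ranges in percent-of-cells units by parameter class:
#' amplification (`Gain`) 2-15, deletion (`Loss`, `Homozygous`) 10-20,
#' break-apart (`Split`, `2Edel`) 4-10; integer step by default (with
#' 100 enumerated cells per specimen percent values are integers, so a
#' step of 1 is exhaustive).
#'
#' @param parameters Character vector of parameter names.
#' @param step Grid step in percentage points.
#' @return Named list of strictly increasing candidate cut-off vectors.
#' @examples
#' cutoffGrid(c("MYC Gain", "PTEN Homozygous", "ETV1 Split"))
#' @export
cutoffGrid <- function(parameters, step = 1) {
    if (!is.finite(step) || step <= 0) stop("step must be positive")
    stat <- splitParameterName(parameters)$statistic
    ranges <- list(Gain = c(2, 15), Loss = c(10, 20),
                   Homozygous = c(10, 20), Split = c(4, 10),
                   `2Edel` = c(4, 10))
    out <- lapply(seq_along(parameters), function(i) {
        rg <- ranges[[stat[i]]]
        if (is.null(rg))
            stop("no cut-off class for parameter '", parameters[i], "'")
        seq(rg[1], rg[2], by = step)
    })
    names(out) <- parameters
    out
}

## In-place cumulative sum of a k-dimensional array along every
## dimension, turning a histogram into a dominance-count table.
.cumsumAllDims <- function(arr, dims) {
    k <- length(dims)
    for (d in seq_len(k)) {
        pre <- prod(dims[seq_len(d - 1L)])
        post <- prod(dims[-seq_len(d)])
        dim(arr) <- c(pre, dims[d], post)
        for (i in seq(2L, length.out = dims[d] - 1L))
            arr[, i, ] <- arr[, i, ] + arr[, i - 1L, ]
    }
    dim(arr) <- dims
    arr
}

#' Exhaustive cut-off optimisation for a parameter combination
#'
#' Evaluates the full Cartesian product of candidate cut-offs for every
#' parameter in the combination under the any-positive panel rule, and
#' returns the cut-off vector minimising the DFI. Internally the search
#' counts panel-negative specimens with a k-dimensional histogram and
#' cumulative-sum dominance table, which is exact and equivalent to
#' naive enumeration. Ties on DFI are broken deterministically and
#' conservatively: highest specificity first, then element-wise larger
#' cut-offs in parameter order (fewest positive calls).
#'
#' @param parameters Parameter names forming the combination.
#' @param x A [`FishCohort`] or a specimens-by-parameters matrix.
#' @param labels `"case"`/`"control"` labels (ignored for a
#'   `FishCohort`).
#' @param grid Named list of candidate cut-offs (default
#'   [cutoffGrid()]).
#' @return A list of class `"CombinationResult"`: `parameters`,
#'   `cutoffs` (named), `sensitivity`, `specificity`, `dfi`, `calls`
#'   (named character vector of panel calls), `n_cases`, `n_controls`.
#' @examples
#' m <- cbind("MYC Gain" = c(12, 9, 1, 2), "PTEN Homozygous" = c(0, 14, 0, 11))
#' rownames(m) <- paste0("S", 1:4)
#' optimizeCutoffs(colnames(m), m, c("case", "case", "control", "control"))
#' @export
optimizeCutoffs <- function(parameters, x, labels = NULL, grid = NULL) {
    vl <- .valuesAndLabels(x, labels)
    values <- vl$values; labels <- vl$labels
    if (is.null(grid)) grid <- cutoffGrid(parameters)
    missing <- setdiff(parameters, names(grid))
    if (length(missing))
        stop("no cut-off grid for parameter(s): ",
             paste(missing, collapse = ", "))
    grid <- grid[parameters]
    if (any(vapply(grid, length, integer(1)) == 0L))
        stop("empty cut-off grid")
    if (any(vapply(grid, function(g) is.unsorted(g, strictly = TRUE),
                   logical(1))))
        stop("cut-off grids must be strictly increasing")
    missingPar <- setdiff(parameters, colnames(values))
    if (length(missingPar))
        stop("parameter(s) absent from the value matrix: ",
             paste(missingPar, collapse = ", "))
    isCase <- labels == "case"
    nCase <- sum(isCase); nCtl <- sum(!isCase)
    if (nCase == 0 || nCtl == 0)
        stop("both cases and controls are required")

    k <- length(parameters)
    g <- vapply(grid, length, integer(1))
    dims <- g + 1L
    ## r_j = number of candidate cut-offs <= value: the specimen is
    ## panel-negative at cut-off indices t_j > r_j for every j
    r <- vapply(seq_len(k), function(j)
        findInterval(values[, parameters[j]], grid[[j]]),
        numeric(nrow(values)))
    if (nrow(values) == 1L) r <- matrix(r, nrow = 1L)
    stride <- cumprod(c(1L, dims[-k]))
    lin <- as.vector(1 + r %*% stride)
    nBins <- prod(dims)
    negCase <- .cumsumAllDims(tabulate(lin[isCase], nBins) + 0, dims)
    negCtl <- .cumsumAllDims(tabulate(lin[!isCase], nBins) + 0, dims)
    region <- lapply(g, seq_len)
    negCase <- do.call(`[`, c(list(negCase), region, list(drop = FALSE)))
    negCtl <- do.call(`[`, c(list(negCtl), region, list(drop = FALSE)))

    sens <- (nCase - negCase) / nCase
    spec <- negCtl / nCtl
    d2 <- (1 - sens)^2 + (1 - spec)^2
    eps <- 1e-12
    cand <- which(d2 <= min(d2) + eps)
    bestSpec <- max(spec[cand])
    cand <- cand[spec[cand] >= bestSpec - eps]
    idx <- arrayInd(cand, .dim = g)
    for (j in seq_len(k)) {   # prefer larger cut-offs, parameter order
        best <- max(idx[, j])
        keep <- idx[, j] == best
        idx <- idx[keep, , drop = FALSE]
        cand <- cand[keep]
    }
    t <- idx[1, ]
    cutoffs <- setNames(vapply(seq_len(k),
                               function(j) grid[[j]][t[j]], numeric(1)),
                        parameters)
    calls <- panelCall(values, cutoffs)
    names(calls) <- rownames(values)
    res <- list(parameters = parameters, cutoffs = cutoffs,
                sensitivity = sens[matrix(t, 1)],
                specificity = spec[matrix(t, 1)],
                dfi = sqrt(d2[matrix(t, 1)]),
                calls = calls, n_cases = nCase, n_controls = nCtl)
    class(res) <- "CombinationResult"
    res
}

#' @export
print.CombinationResult <- function(x, ...) {
    cat("CombinationResult:", paste(x$parameters, collapse = " & "), "\n")
    cat("  cutoffs:", paste0(names(x$cutoffs), " >= ", x$cutoffs,
                             collapse = "; "), "\n")
    cat(sprintf("  sensitivity %.3f, specificity %.3f, DFI %.4f\n",
                x$sensitivity, x$specificity, x$dfi))
    invisible(x)
}

#' AUC of a parameter combination
#'
#' Scores the combination's ability to separate cases from controls on
#' a continuous scale. The default `"logistic"` method fits an
#' unpenalised logistic model on the combination's continuous parameter
#' values (exactly duplicated columns are collapsed first) and computes
#' the Mann-Whitney AUC of the fitted probabilities; if the fit does
#' not converge the score falls back to the per-specimen maximum of
#' rank-standardised parameter values, and the result is flagged. The
#' `"single-point"` method is the trapezoidal area of the
#' one-point ROC polygon of the optimised dichotomised panel call,
#' `(sensitivity + specificity) / 2`.
#'
#' @param parameters Parameter names forming the combination.
#' @param x A [`FishCohort`] or a specimens-by-parameters matrix.
#' @param labels `"case"`/`"control"` labels (ignored for a
#'   `FishCohort`).
#' @param method `"logistic"` or `"single-point"`.
#' @param result A `"CombinationResult"` (required for
#'   `"single-point"`).
#' @return AUC in `[0, 1]`, with attribute `"fallback"` (logical) for
#'   the logistic method.
#' @export
combinationAuc <- function(parameters, x, labels = NULL,
                           method = c("logistic", "single-point"),
                           result = NULL) {
    method <- match.arg(method)
    if (method == "single-point") {
        if (is.null(result))
            result <- optimizeCutoffs(parameters, x, labels)
        return((result$sensitivity + result$specificity) / 2)
    }
    vl <- .valuesAndLabels(x, labels)
    X <- vl$values[, parameters, drop = FALSE]
    X <- X[, !duplicated(t(X)), drop = FALSE]
    y <- as.numeric(vl$labels == "case")
    fit <- tryCatch(fitLogistic(X, y), error = function(e) NULL)
    fallback <- is.null(fit) || !fit$converged
    score <- if (fallback) {
        rk <- apply(X, 2, function(v) rank(v) / length(v))
        if (is.null(dim(rk))) rk <- matrix(rk, nrow = nrow(X))
        apply(rk, 1, max)
    } else {
        fit$fitted
    }
    auc <- aucSingle(score, vl$labels)
    attr(auc, "fallback") <- fallback
    auc
}

#' Enumerate and rank all parameter combinations
#'
#' Evaluates every subset of the candidate parameters of size `kMin`
#' to `kMax`: exhaustive cut-off optimisation ([optimizeCutoffs()])
#' plus combination AUC ([combinationAuc()]). Combinations are ranked
#' by AUC descending, DFI ascending, then lexicographically by
#' parameter names; the per-size leaders are reported alongside the
#' full table.
#'
#' @param x A [`FishCohort`] or a specimens-by-parameters matrix.
#' @param candidates Candidate parameter names (default
#'   [candidateParameters()]).
#' @param labels `"case"`/`"control"` labels (ignored for a
#'   `FishCohort`).
#' @param kMin,kMax Combination sizes (defaults 3 and 6).
#' @param gridStep Cut-off grid step in percentage points.
#' @param aucMethod `"logistic"` or `"single-point"`.
#' @return A list of class `"CombinationRanking"`:
#'   \describe{
#'     \item{table}{one row per combination (ranked): `combination_id`,
#'       `n_parameters`, `parameters`, `cutoffs`, `sensitivity`,
#'       `specificity`, `dfi`, `auc`, `auc_fallback`;}
#'     \item{leaders}{the best row per combination size;}
#'     \item{results}{named list of `"CombinationResult"` objects
#'       (panel calls included).}
#'   }
#' @examples
#' sim <- simulateCohort(simulationConfig(nCases = 15, nControls = 15,
#'                                        cellsPerSpecimen = 50, seed = 4))
#' cohort <- buildParameterMatrix(sim$cells, sim$clinical, sim$panel)
#' rk <- enumerateAndRank(cohort, kMin = 3, kMax = 3)
#' head(rk$table)
#' @export
enumerateAndRank <- function(x, candidates = candidateParameters(),
                             labels = NULL, kMin = 3, kMax = 6,
                             gridStep = 1,
                             aucMethod = c("logistic", "single-point")) {
    aucMethod <- match.arg(aucMethod)
    vl <- .valuesAndLabels(x, labels)
    if (length(candidates) < kMin)
        stop("need at least kMin (", kMin, ") candidate parameters, got ",
             length(candidates))
    kMax <- min(kMax, length(candidates))
    grid <- cutoffGrid(candidates, step = gridStep)
    sets <- list()
    for (k in seq(kMin, kMax))
        sets <- c(sets, utils::combn(candidates, k, simplify = FALSE))
    results <- vector("list", length(sets))
    rows <- vector("list", length(sets))
    for (i in seq_along(sets)) {
        pars <- sets[[i]]
        res <- optimizeCutoffs(pars, vl$values, vl$labels, grid = grid)
        auc <- if (aucMethod == "logistic")
            combinationAuc(pars, vl$values, vl$labels, method = "logistic")
        else
            combinationAuc(pars, vl$values, vl$labels,
                           method = "single-point", result = res)
        results[[i]] <- res
        rows[[i]] <- data.frame(
            n_parameters = length(pars),
            parameters = paste(pars, collapse = " & "),
            cutoffs = paste0(names(res$cutoffs), ">=", res$cutoffs,
                             collapse = "; "),
            sensitivity = res$sensitivity,
            specificity = res$specificity,
            dfi = res$dfi,
            auc = as.numeric(auc),
            auc_fallback = isTRUE(attr(auc, "fallback")),
            stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    ord <- order(-tab$auc, tab$dfi, tab$parameters)
    tab <- tab[ord, , drop = FALSE]
    results <- results[ord]
    tab <- cbind(combination_id = sprintf("C%03d", seq_len(nrow(tab))),
                 tab, stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    names(results) <- tab$combination_id
    leaders <- do.call(rbind, lapply(split(tab, tab$n_parameters),
                                     function(d) d[1, , drop = FALSE]))
    rownames(leaders) <- NULL
    out <- list(table = tab, leaders = leaders, results = results,
                auc_method = aucMethod)
    class(out) <- "CombinationRanking"
    out
}

#' @export
print.CombinationRanking <- function(x, ...) {
    cat("CombinationRanking:", nrow(x$table), "combinations (AUC method:",
        x$auc_method, ")\nPer-size leaders:\n")
    print(x$leaders[, c("n_parameters", "parameters", "auc", "dfi")],
          row.names = FALSE)
    invisible(x)
}

#' Write combination ranking tables
#'
#' `combinations.tsv`: one row per combination with cut-offs,
#' sensitivity, specificity, DFI and AUC. `calls.tsv`: the panel call
#' of every specimen under every combination.
#'
#' @param ranking A `"CombinationRanking"`.
#' @param dir Output directory.
#' @return File paths, invisibly.
#' @export
writeCombinationTables <- function(ranking, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, c("combinations.tsv", "calls.tsv"))
    write.table(ranking$table, paths[1], sep = "\t", quote = FALSE,
                na = "", row.names = FALSE)
    calls <- do.call(rbind, lapply(names(ranking$results), function(id) {
        r <- ranking$results[[id]]
        data.frame(specimen_id = names(r$calls), combination_id = id,
                   call = unname(r$calls), stringsAsFactors = FALSE)
    }))
    write.table(calls, paths[2], sep = "\t", quote = FALSE, na = "",
                row.names = FALSE)
    invisible(paths)
}
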