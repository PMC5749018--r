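#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation between two numeric vectors with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom
#' (delegates to [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with
#'   non-zero variance.
#' @return A list with elements `r` and `p`.
#' @examples
#' pearson(c(1, 2, 3), c(3, 2, 1))  # r = -1
#' @export
pearson <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    ok <- complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3)
        stop("need at least 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: zero variance")
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value)
}

.stageOrdinal <- function(stage) {
    score <- match(stage, c("T1c", "T2a", "T2b", "T2c"))
    if (anyNA(score))
        stop("unknown tumour stage: ",
             paste(unique(stage[is.na(score)]), collapse = ", "))
    score
}

#' Screen FISH parameters against clinical covariates
#'
#' Pearson-correlates every FISH parameter with age, Gleason score, PSA
#' and tumour stage (coded ordinally T1c=1 .. T2c=4). A probe is
#' excluded when any of its parameters correlates with any clinical
#' variable at `p < alpha`; the exclusion then applies to all
#' parameters of that probe (the rule under which NKX3.1 is removed
#' when its Loss parameter tracks Gleason score). Parameters with zero
#' variance are reported as not evaluable rather than excluded. No
#' multiple-testing correction is applied.
#'
#' @param cohort A [`FishCohort`].
#' @param alpha Significance threshold (default 0.05).
#' @return A `data.frame` with one row per (parameter, clinical
#'   variable) pair: `parameter`, `probe_id`, `clinical_variable`, `r`,
#'   `p_value`, `evaluable`, `excluded` (probe-level flag, repeated on
#'   every row of the probe). Attribute `"excludedProbes"` lists the
#'   excluded probe ids; [excludedProbes()] retrieves it.
#' @examples
#' sim <- simulateCohort(simulationConfig(nCases = 10, nControls = 10,
#'                                        cellsPerSpecimen = 30, seed = 3))
#' cohort <- buildParameterMatrix(sim$cells, sim$clinical, sim$panel)
#' screen <- screenParameters(cohort)
#' excludedProbes(screen)
#' @export
screenParameters <- function(cohort, alpha = 0.05) {
    m <- parameterMatrix(cohort)
    clin <- clinicalData(cohort)
    if (ncol(m) < 3)
        stop("need at least 3 specimens to screen")
    vars <- list(age = clin$age, gleason = clin$gleason, psa = clin$psa,
                 stage = .stageOrdinal(clin$stage))
    rd <- as.data.frame(rowData(cohort))
    rows <- list()
    for (i in seq_len(nrow(m))) {
        for (v in names(vars)) {
            res <- tryCatch(pearson(m[i, ], vars[[v]]),
                            error = function(e) NULL)
            rows[[length(rows) + 1L]] <- data.frame(
                parameter = rownames(m)[i],
                probe_id = rd$probe_id[i],
                clinical_variable = v,
                r = if (is.null(res)) NA_real_ else res$r,
                p_value = if (is.null(res)) NA_real_ else res$p,
                evaluable = !is.null(res),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    sig <- out$evaluable & out$p_value < alpha
    excluded <- sort(unique(out$probe_id[sig]))
    out$excluded <- out$probe_id %in% excluded
    attr(out, "excludedProbes") <- excluded
    attr(out, "alpha") <- alpha
    out
}

#' @rdname screenParameters
#' @param screen The result of `screenParameters()`.
#' @export
excludedProbes <- function(screen) attr(screen, "excludedProbes")

#' Write the screening report
#'
#' @param screen Result of [screenParameters()].
#' @param path File path for the tab-separated report.
#' @return `path`, invisibly.
#' @export
writeScreenTable <- function(screen, path) {
    write.table(screen, path, sep = "\t", quote = FALSE, na = "",
                row.names = FALSE)
    invisible(path)
}
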