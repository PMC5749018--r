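#' Assign an NCCN clinical risk group
#'
#' Deterministic rule over tumour stage, diagnostic PSA and biopsy
#' Gleason score for clinically localised disease (T1c-T2c):
#' \itemize{
#'   \item High if Gleason >= 8 or PSA > 20 ng/mL;
#'   \item else Intermediate if Gleason = 7, 10 <= PSA <= 20, or stage
#'     T2b/T2c;
#'   \item else Very Low if stage T1c, Gleason <= 6, PSA < 10 and the
#'     caller sets `veryLow` (a stand-in for the core-count and
#'     percent-involvement criteria, which are not modelled here);
#'   \item else Low.
#' }
#'
#' @param stage Tumour stage, one of `"T1c"`, `"T2a"`, `"T2b"`, `"T2c"`.
#' @param psa Diagnostic PSA in ng/mL (> 0).
#' @param gleason Biopsy Gleason score, integer 2-10.
#' @param veryLow Logical flag enabling the Very Low classification.
#' @return One of `"VeryLow"`, `"Low"`, `"Intermediate"`, `"High"`
#'   (vectorised over the inputs).
#' @examples
#' assignNccnRisk("T1c", 5, 6)           # "Low"
#' assignNccnRisk("T2a", 8, 7)           # "Intermediate"
#' assignNccnRisk("T2a", 25, 6)          # "High"
#' assignNccnRisk("T1c", 5, 6, veryLow = TRUE)
#' @export
assignNccnRisk <- function(stage, psa, gleason, veryLow = FALSE) {
    n <- max(length(stage), length(psa), length(gleason), length(veryLow))
    stage <- rep_len(as.character(stage), n)
    psa <- rep_len(psa, n)
    gleason <- rep_len(gleason, n)
    veryLow <- rep_len(veryLow, n)
    if (!all(stage %in% c("T1c", "T2a", "T2b", "T2c")))
        stop("stage must be one of T1c, T2a, T2b, T2c")
    if (any(!is.finite(psa)) || any(psa <= 0))
        stop("psa must be positive")
    if (any(!is.finite(gleason)) || any(gleason < 2) || any(gleason > 10) ||
        any(gleason != round(gleason)))
        stop("gleason must be an integer in 2..10")
    out <- rep("Low", n)
    out[stage == "T1c" & gleason <= 6 & psa < 10 & veryLow] <- "VeryLow"
    out[gleason == 7 | (psa >= 10 & psa <= 20) |
            stage %in% c("T2b", "T2c")] <- "Intermediate"
    out[gleason >= 8 | psa > 20] <- "High"
    out
}

#' Ordinal coding of NCCN risk groups
#'
#' Very Low = 1, Low = 2, Intermediate = 3, High = 4.
#'
#' @param riskGroup Character vector of risk-group labels.
#' @return Integer scores.
#' @export
nccnOrdinal <- function(riskGroup) {
    score <- match(riskGroup, .riskGroups)
    if (anyNA(score))
        stop("unknown risk group: ",
             paste(unique(riskGroup[is.na(score)]), collapse = ", "))
    score
}

#' Collapse NCCN risk groups into analysis strata
#'
#' Lower = Very Low + Low, Intermediate, Higher = High, matching the
#' three-category risk-stratified analysis.
#'
#' @param riskGroup Character vector of risk-group labels.
#' @return Factor with levels `Lower`, `Intermediate`, `Higher`.
#' @export
riskStratum <- function(riskGroup) {
    nccnOrdinal(riskGroup)  # validates labels
    out <- ifelse(riskGroup %in% c("VeryLow", "Low"), "Lower",
                  ifelse(riskGroup == "Intermediate", "Intermediate",
                         "Higher"))
    factor(out, levels = c("Lower", "Intermediate", "Higher"))
}
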