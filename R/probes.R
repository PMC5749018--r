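#' Default FISH probe panel
#'
#' The ten-probe developmental panel assembled in three four-colour
#' hybridisation mixes: mix 1 = PTEN (10q23), CEP10 and the ERG
#' break-apart pair; mix 2 = NKX3.1 (8p21), CEP8, FGFR1 (8p12) and
#' MYC (8q24); mix 3 = CDKN1B (9p21), NMYC (2p24) and the ETV1
#' break-apart pair. Break-apart probe pairs are represented as a single
#' logical probe (`ERG_BA`, `ETV1_BA`) whose enumeration records fused
#' and isolated red/green signal counts.
#'
#' @return A `data.frame` with one row per probe and columns
#'   `probe_id`, `probe_class` (`locus`, `centromere_control` or
#'   `break_apart`), `mix_id` (1-3), `control_probe_id` (same-chromosome
#'   centromeric control, or `NA`) and `cutoff_class` (`amplification`,
#'   `deletion`, `break_apart` or `none`).
#' @examples
#' defaultProbePanel()
#' @export
defaultProbePanel <- function() {
    panel <- data.frame(
        probe_id = c("PTEN", "CEP10", "ERG_BA",
                     "NKX3.1", "CEP8", "FGFR1", "MYC",
                     "CDKN1B", "NMYC", "ETV1_BA"),
        probe_class = c("locus", "centromere_control", "break_apart",
                        "locus", "centromere_control", "locus", "locus",
                        "locus", "locus", "break_apart"),
        mix_id = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L),
        control_probe_id = c("CEP10", NA, NA,
                             "CEP8", NA, "CEP8", "CEP8",
                             NA, NA, NA),
        cutoff_class = c("deletion", "none", "break_apart",
                         "deletion", "none", "amplification",
                         "amplification",
                         "deletion", "amplification", "break_apart"),
        stringsAsFactors = FALSE
    )
    validateProbePanel(panel)
    panel
}

#' Validate a probe panel table
#'
#' Checks the structural invariants of a probe definition table:
#' required columns, known probe classes and cut-off classes, control
#' probes referencing a centromeric probe in the same mix, and
#' `cutoff_class = "none"` reserved for centromere controls.
#'
#' @param panel A probe panel `data.frame` as returned by
#'   [defaultProbePanel()].
#' @return The validated panel, invisibly.
#' @export
validateProbePanel <- function(panel) {
    required <- c("probe_id", "probe_class", "mix_id", "control_probe_id",
                  "cutoff_class")
    missing <- setdiff(required, names(panel))
    if (length(missing))
        stop("probe panel is missing columns: ",
             paste(missing, collapse = ", "))
    if (anyDuplicated(panel$probe_id))
        stop("duplicated probe_id in probe panel")
    if (!all(panel$probe_class %in%
             c("locus", "centromere_control", "break_apart")))
        stop("unknown probe_class in probe panel")
    if (!all(panel$cutoff_class %in%
             c("amplification", "deletion", "break_apart", "none")))
        stop("unknown cutoff_class in probe panel")
    bad_none <- panel$cutoff_class == "none" &
        panel$probe_class != "centromere_control"
    if (any(bad_none))
        stop("cutoff_class 'none' is only valid for centromere_control ",
             "probes: ", paste(panel$probe_id[bad_none], collapse = ", "))
    has_ctrl <- !is.na(panel$control_probe_id)
    for (i in which(has_ctrl)) {
        j <- match(panel$control_probe_id[i], panel$probe_id)
        if (is.na(j))
            stop("control_probe_id '", panel$control_probe_id[i],
                 "' of probe '", panel$probe_id[i],
                 "' not found in panel")
        if (panel$probe_class[j] != "centromere_control")
            stop("control probe '", panel$probe_id[j],
                 "' is not a centromere_control probe")
        if (panel$mix_id[j] != panel$mix_id[i])
            stop("control probe '", panel$probe_id[j],
                 "' is not in the same mix as '", panel$probe_id[i], "'")
    }
    invisible(panel)
}

## Display label used in parameter names: break-apart probes drop the
## "_BA" suffix so parameters read "ERG Split", "ETV1 Split" etc.
probeLabel <- function(probe_id) sub("_BA$", "", probe_id)

#' FISH parameters applicable to each probe
#'
#' Locus and centromeric probes yield percent `Gain`, `Loss` and
#' `Homozygous` parameters plus a `Ratio` parameter when a
#' same-chromosome centromeric control is defined; break-apart probes
#' yield percent `Split`, and `2Edel` for the ERG break-apart probe.
#'
#' @param panel A probe panel `data.frame`.
#' @return A `data.frame` with columns `parameter`, `probe_id` and
#'   `statistic` in a deterministic (panel, statistic) order.
#' @export
panelParameters <- function(panel = defaultProbePanel()) {
    validateProbePanel(panel)
    rows <- lapply(seq_len(nrow(panel)), function(i) {
        p <- panel[i, ]
        lbl <- probeLabel(p$probe_id)
        if (p$probe_class == "break_apart") {
            stat <- "Split"
            if (grepl("^ERG", p$probe_id)) stat <- c(stat, "2Edel")
        } else {
            stat <- c("Gain", "Loss", "Homozygous")
            if (!is.na(p$control_probe_id)) stat <- c(stat, "Ratio")
        }
        data.frame(parameter = paste(lbl, stat), probe_id = p$probe_id,
                   statistic = stat, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' The seven candidate FISH parameters
#'
#' The candidate parameter list carried into combination selection after
#' feasibility screening: PTEN Homozygous, MYC Gain, FGFR1 Gain,
#' NMYC Gain, ETV1 Split, PTEN Loss and ERG 2Edel.
#'
#' @return Character vector of parameter names.
#' @export
candidateParameters <- function() {
    c("PTEN Homozygous", "MYC Gain", "FGFR1 Gain", "NMYC Gain",
      "ETV1 Split", "PTEN Loss", "ERG 2Edel")
}

#' Read / write a probe panel table
#'
#' Tab-separated with header; columns as in [defaultProbePanel()].
#'
#' @param path File path.
#' @param panel Probe panel `data.frame`.
#' @return `readProbeTable()` returns the validated panel;
#'   `writeProbeTable()` returns `path` invisibly.
#' @export
readProbeTable <- function(path) {
    panel <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
    panel$mix_id <- as.integer(panel$mix_id)
    validateProbePanel(panel)
    panel
}

#' @rdname readProbeTable
#' @export
writeProbeTable <- function(panel, path) {
    validateProbePanel(panel)
    write.table(panel, path, sep = "\t", quote = FALSE, na = "",
                row.names = FALSE)
    invisible(path)
}
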