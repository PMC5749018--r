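## Independent oracles and small fixture builders shared across tests.

## Brute-force Mann-Whitney AUC by explicit case-control pair counting,
## ties counted one half.
bruteAuc <- function(values, labels) {
    cs <- values[labels == "case"]
    ct <- values[labels == "control"]
    tot <- 0
    for (a in cs) for (b in ct)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(cs) * length(ct))
}

## Naive exhaustive cut-off search by explicit Cartesian enumeration,
## honouring the documented tie-break: lowest DFI, then highest
## specificity, then element-wise larger cut-offs in parameter order.
naiveOptimize <- function(parameters, values, labels, grid) {
    grid <- grid[parameters]
    combos <- as.matrix(expand.grid(grid, KEEP.OUT.ATTRS = FALSE))
    isCase <- labels == "case"
    nCase <- sum(isCase); nCtl <- sum(!isCase)
    v <- values[, parameters, drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(combos))) {
        cut <- combos[i, ]
        pos <- rowSums(v >= rep(cut, each = nrow(v))) > 0
        sens <- sum(pos & isCase) / nCase
        spec <- sum(!pos & !isCase) / nCtl
        d <- sqrt((1 - sens)^2 + (1 - spec)^2)
        better <- FALSE
        if (is.null(best) || d < best$d) {
            better <- TRUE
        } else if (d == best$d) {
            if (spec > best$spec) {
                better <- TRUE
            } else if (spec == best$spec) {
                for (j in seq_along(cut)) {
                    if (cut[j] != best$cut[j]) {
                        better <- cut[j] > best$cut[j]
                        break
                    }
                }
            }
        }
        if (better)
            best <- list(cut = cut, d = d, sens = sens, spec = spec)
    }
    names(best$cut) <- parameters
    best
}

## Closed-form saturated-model quantities for a 2x2 table
## (a = case/positive, b = case/negative, c = control/positive,
##  d = control/negative).
crossProductOr <- function(a, b, c, d) (a * d) / (b * c)
waldSe2x2 <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

## Textbook product-moment correlation and its t-based p-value.
textbookPearson <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

## All-normal enumeration records for every probe of a panel: diploid
## locus/CEP cells (2 signals), intact break-apart cells (2 fused).
makeNormalCells <- function(panel, specimens, nCells = 20) {
    blocks <- lapply(seq_len(nrow(panel)), function(i) {
        pr <- panel[i, ]
        ba <- pr$probe_class == "break_apart"
        data.frame(
            specimen_id = rep(specimens, each = nCells),
            mix_id = pr$mix_id,
            cell_index = rep(seq_len(nCells), length(specimens)),
            probe_id = pr$probe_id,
            n_signals = if (ba) NA_integer_ else 2L,
            n_fusion = if (ba) 2L else NA_integer_,
            n_single_red = if (ba) 0L else NA_integer_,
            n_single_green = if (ba) 0L else NA_integer_,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
}

## Minimal clinical table for hand-built fixtures.
makeClinical <- function(specimens, outcome,
                         risk = "Low", gleason = 6L, psa = 5,
                         stage = "T1c", age = 65L) {
    data.frame(specimen_id = specimens, outcome = outcome,
               age = rep_len(age, length(specimens)),
               psa = rep_len(psa, length(specimens)),
               gleason = rep_len(gleason, length(specimens)),
               stage = rep_len(stage, length(specimens)),
               risk_group = rep_len(risk, length(specimens)),
               stringsAsFactors = FALSE)
}

## Random value matrix + labels for property sweeps (integer percents).
randomDataset <- function(nCase, nCtl, parameters, maxVal = 25) {
    n <- nCase + nCtl
    m <- matrix(sample(0:maxVal, n * length(parameters), replace = TRUE),
                nrow = n, dimnames = list(sprintf("S%02d", seq_len(n)),
                                          parameters))
    list(values = m,
         labels = c(rep("case", nCase), rep("control", nCtl)))
}

## Panel sensitivity/specificity at a fixed cut-off vector.
sensSpecAt <- function(values, labels, cutoffs) {
    calls <- panelCall(values, cutoffs)
    isCase <- labels == "case"
    list(sens = mean(calls[isCase] == "positive"),
         spec = mean(calls[!isCase] == "negative"))
}
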