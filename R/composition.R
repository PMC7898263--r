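#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test with the probability-mass two-sided
#' rule: p is the sum over tables (margins fixed) whose point probability
#' does not exceed the observed table's. The odds ratio is the sample
#' `ad/bc`: 0 or Inf when exactly one cross product is zero, NaN when both
#' are. A zero margin makes the table degenerate: p = 1, OR NaN.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out as
#'   `rbind(c(a, b), c(c, d))`.
#' @return list: `odds_ratio`, `p`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
            a == round(a), b == round(b), c == round(c), d == round(d))
  or <- if (a * d == 0 && b * c == 0) NaN
        else if (b * c == 0) Inf else (a * d) / (b * c)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(odds_ratio = NaN, p = 1))
  m <- a + c; nn <- b + d; kk <- a + b
  lo <- max(0, kk - nn); hi <- min(kk, m)
  dens <- stats::dhyper(lo:hi, m, nn, kk)
  dobs <- dens[a - lo + 1]
  p <- min(1, sum(dens[dens <= dobs * (1 + 1e-7)]))
  list(odds_ratio = or, p = p)
}

#' Pearson chi-square test for a 2x2 table
#'
#' One degree of freedom; no continuity correction by default. A zero
#' expected count gives NaN with a warning.
#'
#' @param a,b,c,d non-negative counts as in [fisher_2x2()].
#' @param correct apply Yates continuity correction.
#' @return list: `stat`, `p`.
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  tab <- rbind(c(a, b), c(c, d))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    warning("chisq_2x2: zero expected count")
    return(list(stat = NaN, p = NaN))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(stat = unname(ct$statistic), p = unname(ct$p.value))
}

#' Cell-type composition by age group, with per-type tests
#'
#' Counts and within-compartment proportions per age group (cells pooled
#' across samples within an age group), plus, per type, the 2x2 test of
#' (this type vs all other compartment types) x (young vs aged): sample
#' odds ratio, Fisher exact p, chi-square p, and the proportion fold
#' change reported in the direction of change.
#'
#' @param labels named character vector barcode -> type.
#' @param samples named character vector barcode -> sample id.
#' @param meta a [sample_meta()].
#' @param compartment optional character vector of types defining the
#'   compartment (default: all observed types).
#' @return data.frame with class `CompositionTable`.
#' @export
composition_table <- function(labels, samples, meta, compartment = NULL) {
  stopifnot(inherits(meta, "SampleMeta"))
  common <- intersect(names(labels), names(samples))
  labels <- labels[common]
  age_of_sample <- stats::setNames(meta$age_group, meta$sample_id)
  age <- age_of_sample[samples[common]]
  if (is.null(compartment)) compartment <- sort(unique(labels))
  keep <- labels %in% compartment
  if (!any(keep)) stop("composition_table: no cells in compartment")
  labels <- factor(labels[keep], levels = compartment)
  age <- factor(age[keep], levels = c("young", "aged"))
  counts <- table(labels, age)
  tot <- colSums(counts)
  out <- data.frame(cell_type = rownames(counts),
                    n_young = as.integer(counts[, "young"]),
                    n_aged = as.integer(counts[, "aged"]),
                    prop_young = as.numeric(counts[, "young"] / tot["young"]),
                    prop_aged = as.numeric(counts[, "aged"] / tot["aged"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  tests <- lapply(seq_len(nrow(out)), function(i) {
    a <- out$n_young[i]; b <- out$n_aged[i]
    cc <- tot["young"] - a; dd <- tot["aged"] - b
    f <- fisher_2x2(a, b, cc, dd)
    x2 <- chisq_2x2(a, b, cc, dd)
    c(odds_ratio = f$odds_ratio, fisher_p = f$p, chisq_p = x2$p)
  })
  tests <- do.call(rbind, tests)
  out <- cbind(out, as.data.frame(tests, row.names = NULL))
  ratio <- out$prop_aged / out$prop_young
  out$prop_fold <- ifelse(is.nan(ratio), NaN,
                          ifelse(ratio >= 1, ratio, 1 / ratio))
  out$prop_direction <- ifelse(is.nan(ratio) | ratio == 1, "unchanged",
                               ifelse(ratio > 1, "increase", "decrease"))
  class(out) <- c("CompositionTable", "data.frame")
  out
}

#' Proportion fold change for one type
#'
#' Ratio of within-compartment proportions between age groups, reported in
#' the direction of change. A zero in the shrinking side yields `Inf` with
#' the direction tag.
#'
#' @param ct a `CompositionTable`.
#' @param type cell-type name.
#' @return list: `fold`, `direction` (`"increase"`/`"decrease"`/
#'   `"unchanged"`).
#' @export
proportion_fold <- function(ct, type) {
  i <- match(type, ct$cell_type)
  if (is.na(i)) stop("proportion_fold: type '", type, "' absent")
  list(fold = ct$prop_fold[i], direction = ct$prop_direction[i])
}
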