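#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks handle ties. For combined sample sizes up to 12 the null
#' distribution is enumerated exhaustively over all group assignments of
#' the observed values (so ties are exact too); above that a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. When the pooled values are all identical the test is vacuous and
#' p = 1.
#'
#' @param xA,xB numeric vectors (both non-empty).
#' @param exact_max largest combined n for exhaustive enumeration.
#' @return list: `statistic` (U for group A), `p` (two-sided).
#' @export
wilcoxon_test <- function(xA, xB, exact_max = 12) {
  stopifnot(length(xA) >= 1, length(xB) >= 1)
  nA <- length(xA); nB <- length(xB); n <- nA + nB
  x <- c(xA, xB)
  r <- rank(x)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  if (length(unique(x)) == 1L) return(list(statistic = U, p = 1))
  if (n <= exact_max) {
    combos <- utils::combn(n, nA)
    Uperm <- colSums(matrix(r[combos], nrow = nA)) - nA * (nA + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    return(list(statistic = U, p = p))
  }
  ties <- rle(sort(x))$lengths
  sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = U, p = 1))
  z <- U - mu
  z <- sign(z) * max(abs(z) - 0.5, 0)  # continuity correction
  list(statistic = U, p = min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2))))
}

# Vectorized normal-approximation Wilcoxon over the rows of a genes x cells
# matrix; used by the DE and signature machinery where n is large.
wilcoxon_rows <- function(mat, idxA, idxB) {
  nA <- length(idxA); nB <- length(idxB); n <- nA + nB
  sub <- as.matrix(mat[, c(idxA, idxB), drop = FALSE])
  mu <- nA * nB / 2
  apply(sub, 1, function(x) {
    if (all(x == x[1])) return(1)
    r <- rank(x)
    U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    ties <- rle(sort(x))$lengths
    sigma2 <- nA * nB / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- U - mu
    z <- sign(z) * max(abs(z) - 0.5, 0)
    min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1.
#' NA/NaN inputs propagate and are excluded from the family size.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

# Shared EM core for the (possibly degenerate) ZINB fit. With pi0 = 0 the
# weights stay pinned at 1 and this is the plain NB moment/likelihood fit.
zinb_em <- function(Y, S, groups, gidx, zero, pi0, max_iter = 100,
                    tol = 1e-6) {
  G <- nrow(Y); n <- ncol(Y)
  W <- matrix(1, G, n)
  if (pi0 > 0) W[zero] <- 0.5
  pi <- rep(pi0, G)
  beta <- vapply(gidx, function(ix)
    rowSums(W[, ix, drop = FALSE] * Y[, ix, drop = FALSE]) /
      rowSums(W[, ix, drop = FALSE] * S[, ix, drop = FALSE]),
    numeric(G))
  beta <- pmax(beta, 1e-10)
  mu <- beta[, as.integer(groups)] * S
  phi <- pmax(rowSums(W * ((Y - mu)^2 - mu)) / rowSums(W * mu^2), 1e-8)
  for (it in seq_len(max_iter)) {
    p0 <- exp(-log1p(mu * phi) / phi)  # NB P(0)
    denom <- pi + (1 - pi) * p0
    Wz <- (1 - pi) * p0 / pmax(denom, 1e-300)
    W <- matrix(1, G, n); W[zero] <- Wz[zero]
    pi_new <- rowSums(1 - W) / n
    beta_new <- vapply(gidx, function(ix)
      rowSums(W[, ix, drop = FALSE] * Y[, ix, drop = FALSE]) /
        pmax(rowSums(W[, ix, drop = FALSE] * S[, ix, drop = FALSE]), 1e-300),
      numeric(G))
    beta_new <- pmax(beta_new, 1e-10)
    mu <- beta_new[, as.integer(groups)] * S
    phi_new <- pmax(rowSums(W * ((Y - mu)^2 - mu)) / rowSums(W * mu^2), 1e-8)
    delta <- max(abs(pi_new - pi), abs(beta_new - beta), abs(phi_new - phi))
    pi <- pi_new; beta <- beta_new; phi <- phi_new
    if (delta < tol) break
  }
  list(pi = pi, beta = beta, phi = phi, W = W, mu = mu)
}

nb_loglik <- function(Y, mu, phi) {
  # phi: per-gene vector recycled down columns; elementwise NB log-density
  size <- 1 / phi
  lgamma(Y + size) - lgamma(size) - lgamma(Y + 1) +
    Y * log(mu * phi / (1 + mu * phi)) - size * log1p(mu * phi)
}

#' Zero-inflated negative binomial EM weights
#'
#' Per gene, fits the mixture `pi * delta_0 + (1 - pi) * NB(mu, phi)` with
#' `mu_gc = s_c * beta_{group(c)}` (s_c the relative library size), by EM:
#' the E-step computes posterior weights `w = P(count drawn from the NB)`
#' (1 wherever the count is positive), the M-step updates `pi` as the mean
#' posterior structural-zero mass, the group means by weighted totals, and
#' `phi` by weighted method of moments floored at 1e-8. Convergence when
#' the largest parameter change drops below `tol` or after `max_iter`
#' iterations. After EM, each gene's observed-data log-likelihood is
#' compared with the plain NB fit (pi = 0) through a boundary
#' likelihood-ratio screen for zero inflation, Bonferroni-controlled at
#' `boundary_alpha` across the genes; genes without evidence of structural
#' zeros collapse to `pi_hat = 0` and unit weights exactly.
#'
#' @param counts genes x cells matrix of raw counts (no all-zero rows).
#' @param libsize per-cell total UMIs.
#' @param groups factor/character of length cells with 2 levels.
#' @param max_iter,tol EM controls.
#' @param boundary_alpha familywise level of the zero-inflation boundary
#'   screen (default 0.01).
#' @return list with class `ZinbFit`: `pi_hat`, `mu_hat` (gene x group
#'   betas), `phi_hat`, `weights` (genes x cells), `groups`, `s` (relative
#'   library sizes), `genes`.
#' @export
fit_zinb_weights <- function(counts, libsize, groups, max_iter = 100,
                             tol = 1e-6, boundary_alpha = 0.01) {
  Y <- as.matrix(counts)
  G <- nrow(Y); n <- ncol(Y)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, length(groups) == n, length(libsize) == n)
  if (any(Matrix::rowSums(Y) == 0))
    stop("fit_zinb_weights: all-zero gene present; apply the detection filter first")
  s <- libsize / mean(libsize)
  S <- matrix(s, G, n, byrow = TRUE)
  gidx <- split(seq_len(n), groups)
  zero <- Y == 0

  em_run <- function(pi0) zinb_em(Y, S, groups, gidx, zero, pi0,
                                  max_iter, tol)
  fit <- em_run(0.1)
  nbfit <- em_run(0)  # weights pinned at 1: plain NB fit

  obs_ll <- function(f) {
    mu <- f$beta[, as.integer(groups), drop = FALSE] * S
    ll <- nb_loglik(Y, mu, f$phi)
    p0 <- exp(-log1p(mu * f$phi) / f$phi)
    mix <- log(pmax(f$pi + (1 - f$pi) * p0, 1e-300))
    ll[zero] <- mix[zero]
    nz_adj <- log1p(-pmin(f$pi, 1 - 1e-12))
    rowSums(ll) + nz_adj * rowSums(!zero)
  }
  # Boundary model choice: pi sits on the edge of its parameter space, so
  # under pure-NB truth the fitted pi is spuriously positive for about half
  # of all genes. Keep the mixture only when the boundary LRT for zero
  # inflation (null: half chi2_0 + half chi2_1) is significant at
  # `boundary_alpha` familywise (Bonferroni over genes); otherwise collapse
  # to pi = 0 with unit weights, where the engine reduces exactly to the
  # plain NB test.
  thresh <- stats::qchisq(1 - pmin(1, 2 * boundary_alpha / G), df = 1)
  keep_mix <- 2 * (obs_ll(fit) - obs_ll(nbfit)) > thresh
  pi_hat <- ifelse(keep_mix, fit$pi, 0)
  W <- nbfit$W; W[keep_mix, ] <- fit$W[keep_mix, ]
  beta <- nbfit$beta; beta[keep_mix, ] <- fit$beta[keep_mix, ]
  phi <- ifelse(keep_mix, fit$phi, nbfit$phi)
  structure(list(pi_hat = pi_hat, mu_hat = beta, phi_hat = phi,
                 weights = W, groups = groups, s = s,
                 genes = rownames(Y)),
            class = "ZinbFit")
}

#' Weighted negative binomial likelihood-ratio test
#'
#' Per gene: twice the difference between the weight-discounted NB
#' log-likelihood of the two-group-mean model and of the common-mean
#' model, dispersion shared between the two (profiled under the
#' alternative), referred to chi-square with 1 df. The posterior weights
#' from [fit_zinb_weights()] already discount ambiguous zeros, so the
#' statistic's effective sample size is the weight total; no further
#' scaling is applied. Equal weighted group means give statistic 0, p = 1.
#'
#' @param fit a `ZinbFit`.
#' @param counts the same genes x cells count matrix the fit was made on.
#' @param max_iter IRLS iteration cap; non-converged genes get p = NaN.
#' @return list: `stat`, `p` (named by gene when names are available).
#' @export
zinb_nb_lrt <- function(fit, counts, max_iter = 50) {
  Y <- as.matrix(counts)
  groups <- fit$groups
  G <- nrow(Y); n <- ncol(Y)
  S <- matrix(fit$s, G, n, byrow = TRUE)
  W <- fit$weights
  phi <- fit$phi_hat

  # Weighted NB ML fit of a per-gene log-mean over a column subset, phi
  # fixed: scalar Newton on b with score Sum w (y - mu)/(1 + phi mu) and
  # Fisher information Sum w mu/(1 + phi mu).
  irls_fit <- function(cols) {
    y <- Y[, cols, drop = FALSE]; w <- W[, cols, drop = FALSE]
    s <- S[, cols, drop = FALSE]
    b <- log(pmax(rowSums(w * y) / pmax(rowSums(w * s), 1e-300), 1e-10))
    conv <- rep(FALSE, G)
    for (it in seq_len(max_iter)) {
      mu <- exp(b) * s
      denom <- 1 + mu * phi
      score <- rowSums(w * (y - mu) / denom)
      info <- pmax(rowSums(w * mu / denom), 1e-300)
      step <- pmin(pmax(score / info, -5), 5)
      b <- b + step
      conv <- conv | abs(step) < 1e-10
      if (all(abs(step) < 1e-10)) break
    }
    ll <- rowSums(w * nb_loglik(y, exp(b) * s, phi))
    list(ll = ll, conv = conv)
  }

  gidx <- split(seq_len(n), groups)
  alt <- lapply(gidx, irls_fit)
  null <- irls_fit(seq_len(n))
  ll_alt <- Reduce(`+`, lapply(alt, `[[`, "ll"))
  conv <- null$conv & Reduce(`&`, lapply(alt, `[[`, "conv"))
  stat <- pmax(2 * (ll_alt - null$ll), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (any(!conv)) {
    warning("zinb_nb_lrt: ", sum(!conv), " gene(s) failed to converge; p = NaN")
    p[!conv] <- NaN; stat[!conv] <- NaN
  }
  list(stat = stats::setNames(stat, fit$genes),
       p = stats::setNames(p, fit$genes))
}

#' Plain negative binomial likelihood-ratio test
#'
#' The degenerate limit of the ZINB engine with all weights fixed at 1;
#' used as the reference in the pi = 0 limit check.
#'
#' @inheritParams fit_zinb_weights
#' @return list: `stat`, `p`.
#' @export
nb_lrt <- function(counts, libsize, groups, max_iter = 100, tol = 1e-6) {
  Y <- as.matrix(counts)
  groups <- as.factor(groups)
  n <- ncol(Y); G <- nrow(Y)
  s <- libsize / mean(libsize)
  S <- matrix(s, G, n, byrow = TRUE)
  gidx <- split(seq_len(n), groups)
  f <- zinb_em(Y, S, groups, gidx, Y == 0, 0, max_iter, tol)
  fit <- structure(list(pi_hat = rep(0, G), mu_hat = f$beta,
                        phi_hat = f$phi, weights = f$W, groups = groups,
                        s = s, genes = rownames(Y)), class = "ZinbFit")
  zinb_nb_lrt(fit, Y)
}

#' Grouped criterion (i)
#'
#' Pass iff the grouped fold change is at least `fc_grouped_min` in either
#' direction (inclusive, "at least") and the adjusted p-value is strictly
#' below `alpha_adj`.
#'
#' @param fold grouped fold change (aged/young).
#' @param padj adjusted p-value.
#' @param cfg a [de_config()].
#' @return logical (vectorized).
#' @export
grouped_criterion <- function(fold, padj, cfg = de_config()) {
  (fold >= cfg$fc_grouped_min | fold <= 1 / cfg$fc_grouped_min) &
    !is.na(padj) & padj < cfg$alpha_adj
}

#' Per-sample criterion (ii)
#'
#' Pass iff every young x aged per-sample fold is at least
#' `fc_persample_min` in the same direction (all up or all down); a missing
#' entry (sample with too few cells) fails.
#'
#' @param folds numeric matrix (young samples x aged samples) of per-sample
#'   fold changes (aged/young).
#' @param cfg a [de_config()].
#' @return list: `pass` (logical), `direction` (`"up_in_aged"`,
#'   `"down_in_aged"` or NA).
#' @export
per_sample_criterion <- function(folds, cfg = de_config()) {
  f <- as.numeric(folds)
  if (anyNA(f)) return(list(pass = FALSE, direction = NA_character_))
  if (all(f >= cfg$fc_persample_min))
    return(list(pass = TRUE, direction = "up_in_aged"))
  if (all(f <= 1 / cfg$fc_persample_min))
    return(list(pass = TRUE, direction = "down_in_aged"))
  list(pass = FALSE, direction = NA_character_)
}

#' Three-criteria consensus differential expression, young vs aged
#'
#' For one cell type: applies the detection filter (genes present in at
#' least `detect_frac_min` of cells in either age group), computes the
#' shared grouped fold change (de-logged normalized means, aged/young,
#' with pseudocount), runs the Wilcoxon and ZINB engines with one BH
#' family per engine, tabulates every young x aged per-sample fold, and
#' calls consensus for genes passing the grouped criterion under both
#' engines plus the per-sample criterion with a consistent direction.
#'
#' @param m a `CountMatrix` (all genes; library sizes are totals over all
#'   genes).
#' @param labels named character vector barcode -> cell type.
#' @param meta a [sample_meta()].
#' @param cell_type the type to test.
#' @param cfg a [de_config()].
#' @return data.frame (one row per tested gene): fold and per-engine p /
#'   padj columns, one `fold_<young>_vs_<aged>` column per sample pair,
#'   criterion flags, `consensus` and `direction`.
#' @export
consensus_de <- function(m, labels, meta, cell_type, cfg = de_config()) {
  stopifnot(inherits(m, "CountMatrix"), inherits(meta, "SampleMeta"))
  cells <- names(labels)[labels == cell_type]
  cells <- intersect(cells, m$barcodes)
  if (!length(cells)) stop("consensus_de: no cells of type '", cell_type, "'")
  age_of_sample <- stats::setNames(meta$age_group, meta$sample_id)
  age <- age_of_sample[m$sample_of_cell[cells]]
  young <- cells[age == "young"]; aged <- cells[age == "aged"]
  if (!length(young)) stop("consensus_de: '", cell_type,
                           "' absent in group young")
  if (!length(aged)) stop("consensus_de: '", cell_type,
                          "' absent in group aged")

  keep_genes <- filter_detected_genes(m, young, aged, cfg$detect_frac_min)
  if (!length(keep_genes))
    return(empty_de_result())
  gidx <- match(keep_genes, m$gene_ids)
  libsize <- library_sizes(m)
  norm <- m$counts[gidx, c(young, aged), drop = FALSE] %*%
    Matrix::Diagonal(x = cfg$scale_factor /
                       pmax(libsize[c(young, aged)], 1))
  norm <- as.matrix(norm)
  colnames(norm) <- c(young, aged)
  iy <- seq_along(young); ia <- length(young) + seq_along(aged)

  mean_y <- rowMeans(norm[, iy, drop = FALSE])
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  fold_grouped <- fold_change(mean_a, mean_y, cfg$fc_pseudocount)

  p_wil <- wilcoxon_rows(norm, ia, iy)
  padj_wil <- bh_adjust(p_wil)

  zfit <- fit_zinb_weights(m$counts[gidx, c(young, aged), drop = FALSE],
                           libsize[c(young, aged)],
                           factor(rep(c("young", "aged"),
                                      c(length(young), length(aged))),
                                  levels = c("young", "aged")))
  p_zinb <- zinb_nb_lrt(zfit, m$counts[gidx, c(young, aged), drop = FALSE])$p
  padj_zinb <- bh_adjust(p_zinb)

  ys <- meta$sample_id[meta$age_group == "young"]
  as_ <- meta$sample_id[meta$age_group == "aged"]
  sample_means <- sapply(c(ys, as_), function(sid) {
    sc <- cells[m$sample_of_cell[cells] == sid]
    if (length(sc) < cfg$min_cells_per_sample) {
      warning("consensus_de: sample ", sid, " has ", length(sc),
              " cells of type '", cell_type,
              "' (< ", cfg$min_cells_per_sample, "); per-sample folds NA")
      return(rep(NA_real_, length(keep_genes)))
    }
    rowMeans(norm[, match(sc, colnames(norm)), drop = FALSE])
  })
  fold_cols <- list()
  for (y in ys) for (a in as_) {
    fold_cols[[paste0("fold_", y, "_vs_", a)]] <-
      fold_change(sample_means[, a], sample_means[, y], cfg$fc_pseudocount)
  }
  fold_tab <- do.call(cbind, fold_cols)

  pass_gw <- grouped_criterion(fold_grouped, padj_wil, cfg)
  pass_gz <- grouped_criterion(fold_grouped, padj_zinb, cfg)
  ps <- apply(fold_tab, 1, function(f)
    per_sample_criterion(matrix(f, nrow = length(ys)), cfg),
    simplify = FALSE)
  pass_ps <- vapply(ps, `[[`, TRUE, "pass")
  dir_ps <- vapply(ps, `[[`, "", "direction")
  dir_grouped <- ifelse(fold_grouped > 1, "up_in_aged",
                        ifelse(fold_grouped < 1, "down_in_aged", NA))
  consensus <- pass_gw & pass_gz & pass_ps &
    !is.na(dir_ps) & !is.na(dir_grouped) & dir_ps == dir_grouped

  out <- data.frame(gene = keep_genes, fold_grouped = fold_grouped,
                    mean_young = mean_y, mean_aged = mean_a,
                    p_wilcoxon = p_wil, padj_wilcoxon = padj_wil,
                    p_zinb = as.numeric(p_zinb),
                    padj_zinb = as.numeric(padj_zinb),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, as.data.frame(fold_tab, row.names = NULL))
  out$pass_grouped_wilcoxon <- pass_gw
  out$pass_grouped_zinb <- pass_gz
  out$pass_per_sample <- pass_ps
  out$consensus <- consensus
  out$direction <- ifelse(consensus, dir_grouped, NA_character_)
  out
}

empty_de_result <- function() {
  data.frame(gene = character(0), fold_grouped = numeric(0),
             mean_young = numeric(0), mean_aged = numeric(0),
             p_wilcoxon = numeric(0), padj_wilcoxon = numeric(0),
             p_zinb = numeric(0), padj_zinb = numeric(0),
             pass_grouped_wilcoxon = logical(0),
             pass_grouped_zinb = logical(0), pass_per_sample = logical(0),
             consensus = logical(0), direction = character(0))
}
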