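#' Median-of-ratios size factors
#'
#' Sample `j`'s factor is the median across features of
#' `count[p,j] / geometric-mean_p`, computed over features with nonzero
#' counts in every sample; factors are rescaled to geometric mean 1. If no
#' feature is nonzero in all samples, library-size ratios are used with a
#' warning.
#'
#' @param counts features x samples matrix.
#' @return numeric vector of per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with nonzero counts in all samples; ",
            "falling back to library-size ratios")
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  lc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- exp(apply(lc - loggeo, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Match footprint samples to their input samples
#'
#' Input sample pairing is by (condition, batch, replicate index), where
#' the replicate index is the order of appearance within each
#' condition/batch group.
#'
#' @param samples the `samples` data.frame of a [count_table()] holding
#'   both assays, or of two tables (pass `rbind` of both).
#' @return named character vector: footprint sample name -> input sample
#'   name.
#' @export
match_input_samples <- function(samples) {
  key <- paste(samples$condition, samples$batch, sep = "\r")
  rep_idx <- stats::ave(seq_len(nrow(samples)),
                        paste(key, samples$assay), FUN = seq_along)
  ep <- samples$assay == "eprint"
  inp <- samples$assay == "input"
  m <- match(paste(key, rep_idx)[ep], paste(key, rep_idx)[inp])
  if (anyNA(m)) {
    stop("no matching input sample for: ",
         paste(samples$name[ep][is.na(m)], collapse = ", "))
  }
  stats::setNames(samples$name[inp][m], samples$name[ep])
}

#' Per-peak host-expression offsets
#'
#' Builds the log-scale offset matrix through which host-gene expression
#' measured in the input libraries enters the count model:
#' `offset[p, j] = log(sf_j) + log(max(normalised input expression of
#' host(p) in the input sample matched to j, pseudocount))`. A peak whose
#' counts simply track its host gene's expression then fits with a
#' condition coefficient of ~0, so differential binding means a change in
#' peak amplitude beyond the change in host-gene expression.
#'
#' @param size_factors footprint-sample size factors (named).
#' @param gene_expr gene-level `count_table` of input samples.
#' @param hosts named character vector, peak id -> host gene id.
#' @param sample_match named vector from [match_input_samples()].
#' @param pseudocount floor applied to normalised expression (default 0.5).
#' @return matrix peaks x footprint samples of log offsets.
#' @export
build_offsets <- function(size_factors, gene_expr, hosts, sample_match,
                          pseudocount = 0.5) {
  missing <- setdiff(unique(hosts), rownames(gene_expr$counts))
  if (length(missing)) {
    stop("host gene(s) absent from expression table for peaks: ",
         paste(names(hosts)[hosts %in% missing][1:min(5, sum(hosts %in% missing))],
               collapse = ", "),
         if (sum(hosts %in% missing) > 5) " ..." else "")
  }
  in_sf <- estimate_size_factors(gene_expr$counts)
  norm <- sweep(gene_expr$counts, 2, in_sf, "/")
  ep_names <- names(size_factors)
  in_names <- unname(sample_match[ep_names])
  expr <- norm[match(hosts, rownames(norm)), in_names, drop = FALSE]
  off <- log(pmax(expr, pseudocount))
  off <- sweep(off, 2, log(size_factors), "+")
  dimnames(off) <- list(names(hosts), ep_names)
  if (any(!is.finite(off))) stop("non-finite offsets")
  off
}

#' Offsets carrying size factors only
#' @param size_factors named per-sample factors.
#' @param feature_ids row names for the offset matrix.
#' @return matrix features x samples.
#' @export
size_factor_offsets <- function(size_factors, feature_ids) {
  matrix(log(size_factors), nrow = length(feature_ids),
         ncol = length(size_factors), byrow = TRUE,
         dimnames = list(feature_ids, names(size_factors)))
}

#' Per-feature NB dispersion (moments + trend shrinkage)
#'
#' Method-of-moments dispersion on offset-normalised counts, shrunk
#' toward a fitted mean-dispersion trend `a0 + a1/mu` and clamped to
#' `[1e-8, 10]`. The per-feature moment estimate receives weight
#' `df / (df + 4)` with `df = n - #groups` — an equal 50/50 blend at
#' df = 4, and progressively more weight on the trend as the residual
#' degrees of freedom shrink (at the common 2+2 design, df = 2, the
#' moment estimate is too noisy to carry half the weight: letting it do
#' so makes the downstream Wald tests anticonservative). This is a
#' deliberately simple stabiliser, not an empirical-Bayes treatment.
#' Rows with all-zero counts get the clamped trend value and are flagged.
#'
#' @param counts features x samples matrix.
#' @param offsets log-offset matrix of the same shape.
#' @param groups factor of biological groups (conditions) used for the
#'   within-group moment estimate; needs >= 2 samples per group.
#' @return list with `alpha` (shrunk, clamped), `alpha_mom` (raw moments),
#'   `trend` (trend values), `all_zero` (logical).
#' @export
estimate_dispersion <- function(counts, offsets, groups) {
  counts <- as.matrix(counts)
  groups <- droplevels(as.factor(groups))
  if (any(table(groups) < 2)) {
    stop("need >= 2 samples per group for moment estimation")
  }
  f <- exp(offsets - rowMeans(offsets))   # geometric mean 1 per row
  q <- counts / f
  mu <- rowMeans(q)
  G <- nlevels(groups)
  n <- ncol(counts)
  gmeans <- vapply(levels(groups), function(g) {
    rowMeans(q[, groups == g, drop = FALSE])
  }, numeric(nrow(q)))
  if (is.null(dim(gmeans))) gmeans <- matrix(gmeans, nrow = 1)
  resid <- q - gmeans[, as.integer(groups), drop = FALSE]
  varhat <- rowSums(resid^2) / (n - G)
  # Var(q_j) ~ mu/f_j + alpha mu^2, so subtract the Poisson part scaled by
  # the mean inverse normalisation factor
  alpha_mom <- (varhat - mu * rowMeans(1 / f)) / mu^2
  all_zero <- mu == 0
  alpha_mom[all_zero] <- NA_real_

  ok <- !all_zero & is.finite(alpha_mom) & alpha_mom > 0 & mu > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm(alpha_mom[ok] ~ I(1 / mu[ok]))
    a0 <- max(unname(coef(fit)[1]), 1e-8)
    a1 <- max(unname(coef(fit)[2]), 0)
  } else {
    a0 <- max(mean(alpha_mom[ok], na.rm = TRUE), 1e-8)
    if (!is.finite(a0)) a0 <- 0.1
    a1 <- 0
  }
  mu_t <- mu
  mu_t[all_zero] <- min(mu[!all_zero], na.rm = TRUE)
  trend <- pmin(pmax(a0 + a1 / mu_t, 1e-8), 10)
  w <- (n - G) / (n - G + 4)
  alpha <- w * pmax(alpha_mom, 0) + (1 - w) * trend
  alpha[all_zero | !is.finite(alpha)] <- trend[all_zero | !is.finite(alpha)]
  alpha <- pmin(pmax(alpha, 1e-8), 10)
  list(alpha = alpha, alpha_mom = alpha_mom, trend = trend,
       all_zero = all_zero)
}

#' Fit one negative-binomial log-link GLM with fixed dispersion
#'
#' Iteratively reweighted least squares for `y ~ NB(mu, alpha)` with
#' `log(mu) = X beta + offset` and fixed `alpha`. Convergence when the
#' largest coefficient change is below `1e-8`, at most 100 iterations.
#' The returned covariance is the inverse Fisher information at the final
#' coefficients.
#'
#' @param y counts (one feature).
#' @param X design matrix (must be full rank).
#' @param offset log offsets per sample.
#' @param alpha NB dispersion (`alpha -> 0` is the Poisson limit).
#' @return list `beta`, `cov`, `converged`, `iter`.
#' @export
fit_nb_glm <- function(y, X, offset, alpha) {
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  beta <- tryCatch(
    qr.solve(X, log(pmax(y, 0.5)) - offset),
    error = function(e) rep(0, ncol(X)))
  converged <- FALSE
  iter <- 0L
  A <- NULL
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X
    bnew <- tryCatch(drop(solve(A, XtW %*% z)), error = function(e) NULL)
    if (is.null(bnew) || any(!is.finite(bnew))) {
      return(list(beta = rep(NA_real_, ncol(X)), cov = NULL,
                  converged = FALSE, iter = iter))
    }
    delta <- max(abs(bnew - beta))
    beta <- bnew
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  cov <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(cov)) converged <- FALSE
  list(beta = beta, cov = cov, converged = converged, iter = iter)
}

#' Wald tests with BH adjustment
#'
#' Two-sided normal Wald p-values on the condition coefficient and
#' Benjamini-Hochberg adjustment across all tested features. The ranking
#' statistic for downstream set enrichment is the signed Wald statistic.
#'
#' @param fits data.frame with columns `feature_id`, `beta` (natural log),
#'   `se` (natural log), `base_mean`, `converged`.
#' @return `data.frame` of class `differential_result` with columns
#'   `peak_id`, `base_mean`, `log2fc`, `se`, `wald`, `p`, `padj`,
#'   `converged`.
#' @export
wald_and_adjust <- function(fits) {
  log2fc <- fits$beta / log(2)
  se2 <- fits$se / log(2)
  wald <- fits$beta / fits$se
  p <- 2 * stats::pnorm(-abs(wald))
  p[!fits$converged] <- NA_real_
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(peak_id = fits$feature_id, base_mean = fits$base_mean,
                    log2fc = log2fc, se = se2, wald = wald, p = p,
                    padj = padj, converged = fits$converged,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Significance presets for differential peaks
#'
#' `"fus"`: adjusted p < 0.05 and |log2 fold change| > 1 (knockdown
#' screen); `"mn"`: adjusted p < 0.01 and fold change > 2 (cell-state
#' comparison).
#'
#' @param preset `"fus"` or `"mn"`.
#' @return list with `padj` and `lfc` thresholds.
#' @export
significance_preset <- function(preset = c("fus", "mn")) {
  preset <- match.arg(preset)
  switch(preset,
         fus = list(padj = 0.05, lfc = 1),
         mn = list(padj = 0.01, lfc = 1))
}

#' Differentially bound peaks under a preset
#' @param res `differential_result`.
#' @param preset see [significance_preset()].
#' @return `res` with a `direction` column, subset to significant peaks.
#' @export
significant_peaks <- function(res, preset = "fus") {
  th <- significance_preset(preset)
  keep <- !is.na(res$padj) & res$padj < th$padj & abs(res$log2fc) > th$lfc
  out <- res[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "enhanced", "reduced")
  out
}

nb_fit_table <- function(counts, X, offsets, alpha, coef_name) {
  ci <- match(coef_name, colnames(X))
  if (is.na(ci)) stop("coefficient not found in design: ", coef_name)
  n <- nrow(counts)
  beta <- se <- rep(NA_real_, n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    fit <- fit_nb_glm(counts[i, ], X, offsets[i, ], alpha[i])
    if (!is.null(fit$cov) && all(is.finite(fit$beta))) {
      beta[i] <- fit$beta[ci]
      se[i] <- sqrt(fit$cov[ci, ci])
      conv[i] <- fit$converged && is.finite(se[i]) && se[i] > 0
    }
  }
  data.frame(feature_id = rownames(counts), beta = beta, se = se,
             base_mean = rowMeans(counts / exp(offsets - rowMeans(offsets))),
             converged = conv, stringsAsFactors = FALSE)
}

# groups for moment dispersion estimation: condition x batch cells when
# enough residual df remain, otherwise condition alone
dispersion_groups <- function(samples) {
  cond <- as.factor(samples$condition)
  if (!all(is.na(samples$batch))) {
    g <- droplevels(interaction(cond, as.factor(samples$batch)))
    if (nrow(samples) - nlevels(g) >= 2 && all(table(g) >= 2)) return(g)
  }
  cond
}

build_design <- function(samples, reference = NULL) {
  cond <- as.factor(samples$condition)
  if (nlevels(cond) != 2) {
    stop("differential testing needs exactly 2 condition levels, got ",
         nlevels(cond))
  }
  if (is.null(reference)) reference <- sort(levels(cond))[1]
  cond <- stats::relevel(cond, ref = reference)
  batch <- samples$batch
  use_batch <- !all(is.na(batch)) && length(unique(batch[!is.na(batch)])) > 1
  df <- data.frame(condition = cond)
  if (use_batch) {
    df$batch <- as.factor(batch)
    X <- stats::model.matrix(~ condition + batch, df)
  } else {
    X <- stats::model.matrix(~ condition, df)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is not full rank (batch confounded with condition?)")
  }
  list(X = X, coef = paste0("condition", levels(cond)[2]),
       condition = cond, reference = reference)
}

#' Differential RBP binding with host-gene expression offsets
#'
#' Fits, for every peak, a negative-binomial GLM of the footprint counts
#' on condition (and batch when present) in which host-gene expression
#' measured in the matched input samples enters as a per-peak, per-sample
#' offset (see [build_offsets()]). The condition coefficient therefore
#' estimates the change in peak amplitude beyond the change in host-gene
#' expression. Wald tests, BH adjustment.
#'
#' @param ct footprint `count_table` (only `eprint` samples are used); row
#'   names are peak ids.
#' @param gene_expr gene-level `count_table` of input samples.
#' @param hosts named vector peak id -> host gene (required when
#'   `use_offsets`).
#' @param reference reference condition level (default lexicographically
#'   first).
#' @param use_offsets include host-expression offsets (`FALSE` reduces the
#'   model to plain size-factor normalisation, which confounds binding
#'   with host-gene expression changes; exposed for diagnostic contrast).
#' @param pseudocount expression floor for the offsets.
#' @return `differential_result` data.frame (one row per peak).
#' @export
differential_binding <- function(ct, gene_expr, hosts = NULL,
                                 reference = NULL, use_offsets = TRUE,
                                 pseudocount = 0.5) {
  ep <- subset_count_table(ct, assay = "eprint")
  des <- build_design(ep$samples, reference)
  sf <- estimate_size_factors(ep$counts)
  ids <- rownames(ep$counts)
  if (use_offsets) {
    if (is.null(hosts)) stop("hosts required when use_offsets = TRUE")
    hosts <- hosts[ids]
    if (anyNA(hosts)) {
      stop("missing host gene for peaks: ",
           paste(utils::head(ids[is.na(hosts)], 5), collapse = ", "))
    }
    smatch <- match_input_samples(rbind(ep$samples, gene_expr$samples))
    offsets <- build_offsets(sf, gene_expr, hosts, smatch, pseudocount)
  } else {
    offsets <- size_factor_offsets(sf, ids)
  }
  disp <- estimate_dispersion(ep$counts, offsets, dispersion_groups(ep$samples))
  fits <- nb_fit_table(ep$counts, des$X, offsets, disp$alpha, des$coef)
  res <- wald_and_adjust(fits)
  attr(res, "dispersion") <- disp
  attr(res, "reference") <- des$reference
  res
}

#' Conventional differential expression on the input libraries
#'
#' Gene-level NB differential expression of the input (un-enriched)
#' samples with size-factor offsets only. Genes with zero counts in all
#' samples are excluded and reported via the `"excluded"` attribute.
#'
#' @param gene_expr gene-level `count_table` (only `input` samples used).
#' @param reference reference condition level.
#' @return `differential_result` (rows are genes).
#' @export
deg_on_input <- function(gene_expr, reference = NULL) {
  inp <- subset_count_table(gene_expr, assay = "input")
  zero <- rowSums(inp$counts) == 0
  excluded <- rownames(inp$counts)[zero]
  inp <- subset_count_table(inp, features = rownames(inp$counts)[!zero])
  des <- build_design(inp$samples, reference)
  sf <- estimate_size_factors(inp$counts)
  offsets <- size_factor_offsets(sf, rownames(inp$counts))
  disp <- estimate_dispersion(inp$counts, offsets,
                              dispersion_groups(inp$samples))
  fits <- nb_fit_table(inp$counts, des$X, offsets, disp$alpha, des$coef)
  res <- wald_and_adjust(fits)
  attr(res, "dispersion") <- disp
  attr(res, "excluded") <- excluded
  attr(res, "reference") <- des$reference
  res
}

#' Ranked peak list (most enhanced first)
#'
#' Orders tested features by signed Wald statistic, most enhanced first,
#' with deterministic tie-break by id; features without a p-value are
#' dropped.
#'
#' @param res `differential_result`.
#' @return data.frame `peak_id`, `stat`, sorted.
#' @export
ranked_peaks <- function(res) {
  ok <- is.finite(res$wald)
  df <- data.frame(peak_id = res$peak_id[ok], stat = res$wald[ok],
                   stringsAsFactors = FALSE)
  df[order(-df$stat, df$peak_id), , drop = FALSE]
}
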