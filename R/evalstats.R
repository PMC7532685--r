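# Evaluation and agreement statistics ----------------------------------------

#' Percentage enumeration error
#'
#' Per-unit percentage error `100 * |y - x| / x` against reference counts
#' `x`, with the pooled mean and SD. Units with zero reference count are
#' excluded (with a message).
#'
#' @param x reference (ground-truth) counts.
#' @param y comparison counts.
#' @return list with `errors` (per included unit), `mean`, `sd`,
#'   `n_excluded`.
#' @export
percentage_error <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  zero <- x == 0
  if (any(zero)) {
    message(sum(zero), " unit(s) with zero reference count excluded")
  }
  e <- 100 * abs(y[!zero] - x[!zero]) / x[!zero]
  list(errors = e, mean = mean(e), sd = if (length(e) > 1) sd(e) else 0,
       n_excluded = sum(zero))
}

# greedy centroid matching: pairs within the per-truth-cell radius, closest
# first; returns indices of matched prediction/truth rows
match_cells <- function(px, py, tx, ty, tr) {
  if (length(px) == 0 || length(tx) == 0) {
    return(list(pred = integer(0), truth = integer(0)))
  }
  d <- outer(px, tx, function(a, b) (a - b)^2) +
    outer(py, ty, function(a, b) (a - b)^2)
  d <- sqrt(d)
  ok <- sweep(d, 2, tr, "<=")
  pares <- which(ok, arr.ind = TRUE)
  if (nrow(pares) == 0) return(list(pred = integer(0), truth = integer(0)))
  pares <- pares[order(d[pares]), , drop = FALSE]
  up <- logical(length(px)); ut <- logical(length(tx))
  mp <- integer(0); mt <- integer(0)
  for (j in seq_len(nrow(pares))) {
    i <- pares[j, 1]; t <- pares[j, 2]
    if (up[i] || ut[t]) next
    up[i] <- TRUE; ut[t] <- TRUE
    mp <- c(mp, i); mt <- c(mt, t)
  }
  list(pred = mp, truth = mt)
}

#' Cell-level detection metrics
#'
#' Matches predicted to true cells greedily by centroid distance (a
#' prediction matches a truth cell of the same phenotype when their
#' centroids are within the truth cell's nucleus radius) and pools
#' sensitivity and specificity across FOVs and phenotypes. True negatives
#' for a target phenotype are the truth cells of other phenotypes that were
#' not claimed by a prediction of the target phenotype.
#'
#' @param pred data frame of predictions: `fov`, `x`, `y`, `phenotype`.
#' @param truth data frame of truth cells: `fov`, `x`, `y`, `radius`,
#'   `phenotype`.
#' @param boot number of percentile-bootstrap replicates over FOVs for the
#'   CIs (0 disables).
#' @param seed bootstrap seed.
#' @return list with pooled `sensitivity`, `specificity`, the raw
#'   `tp`/`fn`/`fp`/`tn` tallies and optional CI fields.
#' @export
detection_metrics <- function(pred, truth, boot = 0, seed = 1) {
  fovs <- unique(c(pred$fov, truth$fov))
  tally <- function(sel_fovs) {
    tp <- fn <- fp <- tn <- 0
    for (f in sel_fovs) {
      p <- pred[pred$fov == f, , drop = FALSE]
      t <- truth[truth$fov == f, , drop = FALSE]
      for (ph in unique(c(p$phenotype, t$phenotype))) {
        pp <- p[p$phenotype == ph, , drop = FALSE]
        tt <- t[t$phenotype == ph, , drop = FALSE]
        m <- match_cells(pp$x, pp$y, tt$x, tt$y, tt$radius)
        tp <- tp + length(m$pred)
        fn <- fn + nrow(tt) - length(m$truth)
        nfp <- nrow(pp) - length(m$pred)
        fp <- fp + nfp
        other <- t[t$phenotype != ph, , drop = FALSE]
        # other-phenotype truth cells claimed by leftover target predictions
        lp <- setdiff(seq_len(nrow(pp)), m$pred)
        mo <- match_cells(pp$x[lp], pp$y[lp], other$x, other$y,
                          other$radius)
        tn <- tn + nrow(other) - length(mo$truth)
      }
    }
    c(tp = tp, fn = fn, fp = fp, tn = tn)
  }
  tl <- tally(fovs)
  res <- list(sensitivity = unname(tl["tp"] / (tl["tp"] + tl["fn"])),
              specificity = unname(tl["tn"] / (tl["tn"] + tl["fp"])),
              tp = unname(tl["tp"]), fn = unname(tl["fn"]),
              fp = unname(tl["fp"]), tn = unname(tl["tn"]))
  if (boot > 0) {
    set.seed(seed)
    bs <- replicate(boot, {
      t2 <- tally(sample(fovs, length(fovs), replace = TRUE))
      c(t2["tp"] / (t2["tp"] + t2["fn"]), t2["tn"] / (t2["tn"] + t2["fp"]))
    })
    res$sensitivity_ci <- unname(quantile(bs[1, ], c(0.025, 0.975),
                                          na.rm = TRUE))
    res$specificity_ci <- unname(quantile(bs[2, ], c(0.025, 0.975),
                                          na.rm = TRUE))
  }
  res
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric line fit from the shifted median of all pairwise slopes
#' (slopes of exactly -1 excluded, the shift K counting slopes below -1),
#' with rank-based confidence intervals, Kendall's tau correlation pre-test
#' and the cusum linearity test.
#'
#' @param x reference method values.
#' @param y comparison method values.
#' @param conf confidence level.
#' @return object of class `pb_fit` with `slope`, `slope_ci`, `intercept`,
#'   `intercept_ci`, `kendall_tau`, `kendall_p`, `cusum_stat`,
#'   `linearity_pass`, `n`.
#' @export
passing_bablok <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 10) stop("Passing-Bablok requires n >= 10")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  S <- ifelse(dx == 0 & dy == 0, NA_real_,
              ifelse(dx == 0, sign(dy) * Inf, dy / dx))
  S <- S[!is.na(S) & S != -1]
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  med_at <- function(pos) {
    pos <- clamp(pos, 1, N)
    if (N %% 2 == 1) S[pos] else (S[pos] + S[pos + 1]) / 2
  }
  b <- if (N %% 2 == 1) S[(N + 1) / 2 + K] else
    0.5 * (S[N / 2 + K] + S[min(N / 2 + 1 + K, N)])
  z <- qnorm(1 - (1 - conf) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  b_lo <- S[clamp(M1 + K, 1, N)]
  b_hi <- S[clamp(M2 + K, 1, N)]
  a <- median(y - b * x)
  a_lo <- median(y - b_hi * x)
  a_hi <- median(y - b_lo * x)
  kt <- suppressWarnings(cor.test(x, y, method = "kendall"))
  # cusum linearity test: signs of residuals, ordered along the fitted line
  r <- sign(y - a - b * x)
  ord <- order(b * x + y)
  rs <- r[ord]
  rs <- rs[rs != 0]
  L <- length(rs)
  cus <- if (L > 0) max(abs(cumsum(rs))) / sqrt(L + 1) else 0
  structure(list(slope = b, slope_ci = c(b_lo, b_hi), intercept = a,
                 intercept_ci = sort(c(a_lo, a_hi)),
                 kendall_tau = unname(kt$estimate),
                 kendall_p = kt$p.value, cusum_stat = cus,
                 linearity_pass = cus < 1.36, n = n,
                 x = x, y = y, conf = conf), class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf(
    "Passing-Bablok (n = %d): slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f]\n  Kendall tau %.3f (p = %.3g); cusum %.3f -> linearity %s\n",
    x$n, x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
    x$intercept_ci[1], x$intercept_ci[2], x$kendall_tau, x$kendall_p,
    x$cusum_stat, if (x$linearity_pass) "ok" else "violated"))
  invisible(x)
}

#' @export
plot.pb_fit <- function(x, ...) {
  plot(x$x, x$y, xlab = "reference count", ylab = "comparison count", ...)
  abline(0, 1, lty = 2)
  abline(x$intercept, x$slope, col = "red")
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' @param x,y paired measurements.
#' @return object of class `ba_result` with `bias`, `bias_ci`, `loa`
#'   (95% limits of agreement) and `loa_ci` (matrix, one row per limit).
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("Bland-Altman requires n >= 3")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  tq <- qt(0.975, n - 1)
  structure(list(bias = bias, sd = s,
                 bias_ci = bias + c(-1, 1) * tq * se_bias,
                 loa = loa,
                 loa_ci = rbind(lower = loa[1] + c(-1, 1) * tq * se_loa,
                                upper = loa[2] + c(-1, 1) * tq * se_loa),
                 n = n, x = x, y = y), class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.3f [%.3f, %.3f]; LoA [%.3f, %.3f]\n",
    x$n, x$bias, x$bias_ci[1], x$bias_ci[2], x$loa[1], x$loa[2]))
  invisible(x)
}

#' @export
plot.ba_result <- function(x, ...) {
  m <- (x$x + x$y) / 2
  d <- x$y - x$x
  plot(m, d, xlab = "mean of counts", ylab = "difference", ...)
  abline(h = x$bias, col = "orange", lty = 2)
  abline(h = x$loa, col = "purple")
  invisible(x)
}

#' Gwet's AC1 chance-corrected agreement
#'
#' AC1 = (pa - pe) / (1 - pe) with Gwet's chance agreement
#' pe = sum_q pi_q (1 - pi_q) / (Q - 1), pi_q the mean marginal proportion
#' of category q. The variance and CI follow Gwet's linearization; the
#' Landis-Koch benchmark band of the point estimate is reported.
#'
#' @param rater_a,rater_b categorical ratings of the same units.
#' @param conf confidence level.
#' @return list with `ac1`, `se`, `ci`, `pa`, `pe`, `benchmark`, `n`.
#' @export
gwet_ac1 <- function(rater_a, rater_b, conf = 0.95) {
  stopifnot(length(rater_a) == length(rater_b))
  n <- length(rater_a)
  a <- as.character(rater_a); b <- as.character(rater_b)
  cats <- sort(unique(c(a, b)))
  Q <- length(cats)
  agree <- a == b
  pa <- mean(agree)
  riq <- (outer(a, cats, "==") + outer(b, cats, "==")) / 2  # n x Q
  piq <- colMeans(riq)
  if (Q == 1) {
    return(list(ac1 = 1, se = 0, ci = c(1, 1), pa = 1, pe = 0,
                benchmark = "almost perfect", n = n))
  }
  pe <- sum(piq * (1 - piq)) / (Q - 1)
  ac1 <- (pa - pe) / (1 - pe)
  pe_i <- as.vector(riq %*% (1 - piq)) / (Q - 1)
  ac1_star_i <- (agree - pe) / (1 - pe)
  ac1_i <- ac1_star_i - 2 * (1 - ac1) * (pe_i - pe) / (1 - pe)
  v <- sum((ac1_i - mean(ac1_i))^2) / (n * (n - 1))
  se <- sqrt(v)
  tq <- qt(1 - (1 - conf) / 2, n - 1)
  ci <- clamp(ac1 + c(-1, 1) * tq * se, -1, 1)
  bench <- cut(ac1, c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
               labels = c("poor", "slight", "fair", "moderate",
                          "substantial", "almost perfect"))
  list(ac1 = ac1, se = se, ci = ci, pa = pa, pe = pe,
       benchmark = as.character(bench), n = n)
}

# ---- count models ----------------------------------------------------------

zip_loglik <- function(par, y, g) {
  mu <- exp(par[1] + par[2] * g)
  pz <- stats::plogis(par[3] + par[4] * g)
  ll <- ifelse(y == 0,
               log(pz + (1 - pz) * exp(-mu)),
               log(1 - pz) + dpois(y, mu, log = TRUE))
  sum(ll)
}

zinb_loglik <- function(par, y, g) {
  mu <- exp(par[1] + par[2] * g)
  pz <- stats::plogis(par[3] + par[4] * g)
  th <- exp(par[5])
  ll <- ifelse(y == 0,
               log(pz + (1 - pz) * dnbinom(0, mu = mu, size = th)),
               log(1 - pz) + dnbinom(y, mu = mu, size = th, log = TRUE))
  sum(ll)
}

fit_zi <- function(y, g, family = c("zip", "zinb")) {
  family <- match.arg(family)
  pois <- glm(y ~ g, family = "poisson")
  b0 <- unname(coef(pois))
  zexc <- clamp(mean(y == 0) - mean(dpois(0, exp(b0[1] + b0[2] * g))),
                0.02, 0.9)
  starts <- list(c(b0, stats::qlogis(zexc), 0),
                 c(b0, -2, 0),
                 c(b0, -20, 0),     # the Poisson boundary (pi ~ 0): keeps
                                    # the fitted ZIP from undercutting Poisson
                 c(b0 + 0.3, 0, 0))
  if (family == "zinb") starts <- lapply(starts, c, 0.5)
  nll <- function(p) {
    v <- if (family == "zip") zip_loglik(p, y, g) else zinb_loglik(p, y, g)
    if (!is.finite(v)) 1e10 else -v
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(optim(s, nll, method = "BFGS", hessian = TRUE,
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) return(NULL)
  vc <- tryCatch(solve(best$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(best$par)) else
    sqrt(pmax(diag(vc), 0))
  list(par = best$par, se = se, loglik = -best$value,
       npar = length(best$par))
}

#' Fit and compare count-model families for two enumeration methods
#'
#' Fits Poisson, negative binomial, zero-inflated Poisson and
#' zero-inflated negative binomial models of the counts with the
#' enumeration method as a two-level factor (log link on the count mean;
#' logit link on the zero-inflation probability, also with the method
#' factor), and selects the family with the lowest AIC (ties broken toward
#' the simpler family).
#'
#' @param counts non-negative integer counts.
#' @param group two-level factor (reference level first; e.g. human vs
#'   software enumeration).
#' @return object of class `count_model_comparison`: per-family rows with
#'   `loglik`, `aic`, `irr` (+ CI) and, for zero-inflated families, the
#'   zero-part odds ratio (+ CI); `selected` names the winning family.
#' @export
fit_count_models <- function(counts, group) {
  y <- as.integer(counts)
  stopifnot(all(y >= 0))
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2) stop("group must have exactly two levels")
  z <- qnorm(0.975)
  rows <- list()
  addrow <- function(family, loglik, npar, b1, se1, g1 = NA, seg1 = NA) {
    rows[[family]] <<- data.frame(
      family = family, loglik = loglik, npar = npar,
      aic = 2 * npar - 2 * loglik,
      irr = exp(b1), irr_lo = exp(b1 - z * se1), irr_hi = exp(b1 + z * se1),
      zero_or = if (is.na(g1)) NA_real_ else exp(g1),
      zero_or_lo = if (is.na(g1)) NA_real_ else exp(g1 - z * seg1),
      zero_or_hi = if (is.na(g1)) NA_real_ else exp(g1 + z * seg1))
  }
  pois <- glm(y ~ g, family = "poisson")
  sp <- summary(pois)$coefficients
  addrow("P", as.numeric(logLik(pois)), 2, sp[2, 1], sp[2, 2])
  nb <- tryCatch(suppressWarnings(MASS::glm.nb(y ~ g)),
                 error = function(e) NULL)
  if (!is.null(nb) && nb$converged) {
    sn <- summary(nb)$coefficients
    addrow("NB", as.numeric(logLik(nb)), 3, sn[2, 1], sn[2, 2])
  } else {
    warning("negative binomial fit failed; excluded from selection")
  }
  zp <- fit_zi(y, g, "zip")
  if (!is.null(zp)) {
    addrow("ZIP", zp$loglik, 4, zp$par[2], zp$se[2], zp$par[4], zp$se[4])
  } else warning("ZIP fit failed; excluded from selection")
  znb <- fit_zi(y, g, "zinb")
  if (!is.null(znb)) {
    addrow("ZINB", znb$loglik, 5, znb$par[2], znb$se[2], znb$par[4],
           znb$se[4])
  } else warning("ZINB fit failed; excluded from selection")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(tab$aic, tab$npar)
  structure(list(table = tab, selected = tab$family[ord[1]]),
            class = "count_model_comparison")
}

#' @export
print.count_model_comparison <- function(x, ...) {
  cat("Count-model comparison (lowest AIC selected):\n")
  print(x$table[, c("family", "loglik", "aic", "irr", "irr_lo", "irr_hi")],
        row.names = FALSE, digits = 4)
  cat("Selected family:", x$selected, "\n")
  invisible(x)
}

# ---- diagnostics -----------------------------------------------------------

# Mann-Whitney AUC of scores for binary labels
auc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Optimism-adjusted AUC by bootstrap validation
#'
#' Apparent AUC (Mann-Whitney form) of a univariate logistic model, with
#' the bootstrap optimism correction: for each replicate a logistic model
#' is fitted to the bootstrap sample, its AUC on that sample and on the
#' original sample are compared, and the mean difference (optimism) is
#' subtracted from the apparent AUC.
#'
#' @param scores predictor values.
#' @param labels binary outcome (0/1 or logical).
#' @param B bootstrap iterations (default 10000; 0 returns the apparent
#'   AUC unadjusted).
#' @param seed bootstrap seed.
#' @return list with `apparent_auc`, `optimism`, `adjusted_auc`, `B`.
#' @export
roc_optimism_auc <- function(scores, labels, B = 10000, seed = 1) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("both classes must be present")
  apparent <- auc_mw(scores, y)
  if (B == 0) {
    return(list(apparent_auc = apparent, optimism = 0,
                adjusted_auc = apparent, B = 0))
  }
  set.seed(seed)
  n <- length(y)
  opt <- numeric(B)
  b <- 1
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2) next
    fit <- suppressWarnings(glm(y[idx] ~ scores[idx], family = binomial()))
    co <- coef(fit)
    pb <- co[1] + co[2] * scores[idx]
    po <- co[1] + co[2] * scores
    opt[b] <- auc_mw(pb, y[idx]) - auc_mw(po, y)
    b <- b + 1
  }
  list(apparent_auc = apparent, optimism = mean(opt),
       adjusted_auc = apparent - mean(opt), B = B)
}

#' Youden-optimal cutoff
#'
#' Scans the observed score values as candidate cutoffs (rule: score >=
#' cutoff is called positive) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1, ties broken toward the lowest
#' cutoff.
#'
#' @param scores predictor values.
#' @param labels binary outcome.
#' @return the selected cutoff.
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  cand <- sort(unique(scores))
  if (length(cand) == 1) {
    warning("single observed score value; returning it")
    return(cand)
  }
  J <- vapply(cand, function(ct) {
    pred <- as.integer(scores >= ct)
    sens <- sum(pred == 1 & y == 1) / sum(y == 1)
    spec <- sum(pred == 0 & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(J)]
}

metrics_from_counts <- function(tp, fp, tn, fn) {
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Diagnostic 2x2 analysis
#'
#' Computes sensitivity, specificity, PPV, NPV and accuracy either from a
#' 2x2 table (`tp`, `fp`, `tn`, `fn`) or from scores, labels and a cutoff
#' (score >= cutoff called positive). Percentile-bootstrap CIs over units
#' and an optional leave-one-out cross-validated variant (the Youden
#' cutoff is re-derived on every fold and the held-out unit scored with
#' it) are available for the score-based form.
#'
#' @param tp,fp,tn,fn 2x2 cell counts (table form).
#' @param scores,labels,cutoff score-based form; `cutoff = NULL` selects
#'   the Youden cutoff on the full sample.
#' @param B bootstrap iterations for the CIs (0 disables).
#' @param loocv also compute the LOOCV variant (score-based form only).
#' @param seed bootstrap seed.
#' @return object of class `diagnostic_result`: `counts`, `metrics`,
#'   optional `ci` (matrix), `cutoff`, optional `loocv` (counts +
#'   metrics).
#' @export
diagnostics_2x2 <- function(tp = NULL, fp = NULL, tn = NULL, fn = NULL,
                            scores = NULL, labels = NULL, cutoff = NULL,
                            B = 1000, loocv = FALSE, seed = 1) {
  from_scores <- !is.null(scores)
  if (from_scores) {
    y <- as.integer(as.logical(labels))
    if (is.null(cutoff)) cutoff <- youden_cutoff(scores, y)
    pred <- as.integer(scores >= cutoff)
    tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
    tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  } else {
    stopifnot(!is.null(tp), !is.null(fp), !is.null(tn), !is.null(fn))
    # reconstruct unit-level data so the bootstrap can resample units
    y <- rep(c(1, 1, 0, 0), c(tp, fn, tn, fp))
    pred <- rep(c(1, 0, 0, 1), c(tp, fn, tn, fp))
  }
  res <- structure(list(
    counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
    metrics = metrics_from_counts(tp, fp, tn, fn),
    cutoff = if (from_scores) cutoff else NA_real_),
    class = "diagnostic_result")
  if (B > 0) {
    set.seed(seed)
    n <- length(y)
    bs <- replicate(B, {
      i <- sample.int(n, n, replace = TRUE)
      metrics_from_counts(sum(pred[i] == 1 & y[i] == 1),
                          sum(pred[i] == 1 & y[i] == 0),
                          sum(pred[i] == 0 & y[i] == 0),
                          sum(pred[i] == 0 & y[i] == 1))
    })
    res$ci <- t(apply(bs, 1, quantile, c(0.025, 0.975), na.rm = TRUE))
  }
  if (loocv && from_scores) {
    n <- length(y)
    lp <- integer(n)
    for (i in seq_len(n)) {
      ct <- youden_cutoff(scores[-i], y[-i])
      lp[i] <- as.integer(scores[i] >= ct)
    }
    ltp <- sum(lp == 1 & y == 1); lfp <- sum(lp == 1 & y == 0)
    ltn <- sum(lp == 0 & y == 0); lfn <- sum(lp == 0 & y == 1)
    res$loocv <- list(counts = c(tp = ltp, fp = lfp, tn = ltn, fn = lfn),
                      metrics = metrics_from_counts(ltp, lfp, ltn, lfn))
  }
  res
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat("Diagnostic 2x2 analysis\n  counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  m <- x$metrics
  cat(sprintf(
    "  sensitivity %.3f, specificity %.3f, PPV %.3f, NPV %.3f, accuracy %.3f\n",
    m["sensitivity"], m["specificity"], m["ppv"], m["npv"], m["accuracy"]))
  if (!is.null(x$loocv)) {
    l <- x$loocv$metrics
    cat(sprintf(
      "  LOOCV: sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
      l["sensitivity"], l["specificity"], l["accuracy"]))
  }
  invisible(x)
}
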