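#' Principal component ordination of aligned shapes
#'
#' Eigen-decomposition of the specimen covariance of the flattened
#' coordinates under the n-divisor convention, so the eigenvalues sum to the
#' total Procrustes variance of the sample. Axes are retained up to at least
#' 95% cumulative variance.
#'
#' @param shapes [shape_arrays()] or `n x q` matrix.
#' @return object of class `ordination_result`: `pc_scores` (n x k, axes to
#'   95%), `eigenvalues` (all non-trivial), `var_share`, `cum_share`,
#'   `k95`, `rotation` (q x k loadings).
#' @export
shape_pca <- function(shapes) {
  Y <- if (inherits(shapes, "shape_arrays")) flatten_coords(shapes$aligned)
       else as.matrix(shapes)
  n <- nrow(Y)
  if (n < 3) stop("PCA needs at least 3 specimens")
  Yc <- scale(Y, scale = FALSE)
  s <- svd(Yc)
  eig <- s$d^2 / n
  keep <- eig > max(eig) * 1e-12
  eig <- eig[keep]
  share <- eig / sum(eig)
  cum <- cumsum(share)
  k95 <- which(cum >= 0.95)[1]
  scores <- (s$u %*% diag(s$d, nrow = length(s$d)))[, keep, drop = FALSE]
  structure(list(pc_scores = scores[, seq_len(k95), drop = FALSE],
                 eigenvalues = eig, var_share = share, cum_share = cum,
                 k95 = k95,
                 rotation = s$v[, keep, drop = FALSE][, seq_len(k95),
                                                      drop = FALSE],
                 scores_all = scores),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("shape PCA: %d axes to 95%% variance; PC1 share %.3f\n",
              x$k95, x$var_share[1]))
  invisible(x)
}

#' Correlation between PC1 and the first PLS axis
#'
#' Absolute Pearson correlation between PC1 scores of the whole-shape
#' ordination and the first-axis PLS scores (axis signs are arbitrary, so
#' the absolute value is reported). Both blocks' scores are reported; the
#' NC block is the default headline value. Significance from the standard
#' correlation test.
#'
#' @param ord [shape_pca()] result.
#' @param pls [two_block_pls()] result on the same specimens in the same
#'   order.
#' @param block which block's scores lead the report, `"NC"` (x) or `"MD"`
#'   (y).
#' @return data.frame with rows per block: `block`, `r_abs`, `p_value`;
#'   attribute `headline` gives the selected block's absolute correlation.
#' @export
pc1_pls1_correlation <- function(ord, pls, block = c("NC", "MD")) {
  block <- match.arg(block)
  pc1 <- ord$pc_scores[, 1]
  if (length(pc1) != length(pls$x_scores))
    stop("PC scores (", length(pc1), ") and PLS scores (",
         length(pls$x_scores), ") have different lengths")
  row_for <- function(scores, name) {
    ct <- stats::cor.test(pc1, scores)
    data.frame(block = name, r_abs = abs(unname(ct$estimate)),
               p_value = ct$p.value)
  }
  out <- rbind(row_for(pls$x_scores, "NC"), row_for(pls$y_scores, "MD"))
  attr(out, "headline") <- out$r_abs[out$block == block]
  out
}

#' t-contrasts of eigenvalue dispersion across pairs
#'
#' Runs the cross-pair contrasts of within-module integration magnitude:
#' NC vs MD pooled over forms, NC vs MD within wild forms, within domestic
#' forms, and wild vs domestic within each module. All contrasts are paired
#' t-tests across the pairs (pair x form rows are the pairing units for the
#' pooled contrast).
#'
#' @param disp data.frame with columns `pair`, `form` (wild/domestic),
#'   `module` (NC/MD), `value`.
#' @return data.frame with columns `contrast`, `t`, `df`, `p_value`,
#'   `mean_diff`.
#' @export
dispersion_ttests <- function(disp) {
  need <- c("pair", "form", "module", "value")
  if (!all(need %in% names(disp)))
    stop("disp must have columns ", paste(need, collapse = ", "))
  if (length(unique(disp$pair)) < 2) stop("need at least 2 pairs")
  paired_t <- function(a, b, label) {
    if (length(a) != length(b) || length(a) < 2)
      stop("contrast '", label, "' needs >= 2 matched values per side")
    d <- a - b
    if (all(d == 0))
      return(data.frame(contrast = label, t = 0, df = length(d) - 1,
                        p_value = 1, mean_diff = 0))
    if (stats::sd(d) == 0)
      stop("zero variance of differences in contrast '", label, "'")
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(contrast = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               mean_diff = unname(tt$estimate))
  }
  # matched selection: sort by (pair, form) so the two sides of each
  # contrast line up unit by unit
  pick <- function(mod, form = NULL) {
    sel <- disp$module == mod
    if (!is.null(form)) sel <- sel & disp$form == form
    sub <- disp[sel, ]
    sub$value[order(sub$pair, sub$form)]
  }
  rbind(
    paired_t(pick("NC"), pick("MD"), "NC vs MD (all forms)"),
    paired_t(pick("NC", "wild"), pick("MD", "wild"), "NC vs MD (wild)"),
    paired_t(pick("NC", "domestic"), pick("MD", "domestic"),
             "NC vs MD (domestic)"),
    paired_t(pick("NC", "wild"), pick("NC", "domestic"),
             "wild vs domestic (NC)"),
    paired_t(pick("MD", "wild"), pick("MD", "domestic"),
             "wild vs domestic (MD)"))
}

#' Disparity-integration regression with form interaction
#'
#' Ordinary least squares of integration magnitude on module disparity with
#' a wild/domestic interaction (`integration ~ disparity * form`): reports
#' the slope per form, the interaction F test (is the slope different
#' between forms?), the overall model p, and the variance-ratio F test
#' between the forms' disparity values.
#'
#' @param disparity,integration numeric vectors, matched observations
#'   (pair x module x form).
#' @param form factor of `"wild"` / `"domestic"` labels.
#' @return list with `slopes` (named per form), `interaction_F`,
#'   `interaction_df` (c(num, den)), `interaction_p`, `model_p`,
#'   `var_F`, `var_df`, `var_p`, and the `lm` `fit`.
#' @export
disparity_integration_regression <- function(disparity, integration, form) {
  form <- factor(as.character(form), levels = c("wild", "domestic"))
  if (length(disparity) != length(integration) ||
      length(disparity) != length(form))
    stop("disparity, integration and form must have equal length")
  if (any(table(form) < 2))
    stop("need at least 2 observations per form")
  df <- data.frame(disparity = disparity, integration = integration,
                   form = form)
  fit <- stats::lm(integration ~ disparity * form, data = df)
  if (fit$rank < 4) stop("rank-deficient design in disparity regression")
  co <- stats::coef(fit)
  slopes <- c(wild = unname(co["disparity"]),
              domestic = unname(co["disparity"] +
                                  co["disparity:formdomestic"]))
  an <- stats::anova(fit)
  ia <- "disparity:form"
  f0 <- stats::summary.lm(fit)$fstatistic
  model_p <- stats::pf(f0[1], f0[2], f0[3], lower.tail = FALSE)
  vt <- stats::var.test(disparity[form == "domestic"],
                        disparity[form == "wild"])
  list(slopes = slopes,
       interaction_F = an[ia, "F value"],
       interaction_df = c(an[ia, "Df"], an["Residuals", "Df"]),
       interaction_p = an[ia, "Pr(>F)"],
       model_p = unname(model_p),
       var_F = unname(vt$statistic), var_df = unname(vt$parameter),
       var_p = vt$p.value, fit = fit)
}
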