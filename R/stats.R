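# Study-level statistics over morphometry tables: two-way ANOVA
# (strain x age) with Fisher LSD post hoc, Student t, Pearson correlation,
# and the min-max normalization used for the summary heat map.

#' Two-way ANOVA on a morphometry table
#'
#' Partitions the variance of `response` into the two factor main effects,
#' their interaction and the residual.  Balanced designs reproduce the
#' textbook closed-form sums of squares; unbalanced complete designs use
#' partial (Type II) sums of squares.
#'
#' @param table data.frame of per-stack records.
#' @param response name of the numeric response column.
#' @param factors names of the two factor columns (default
#'   `c("strain", "age_weeks")`).
#' @return object of class `anova_2way`: `table` (term, df, sum_sq, mean_sq,
#'   statistic, p_value), `mse`, `df_residual`, `cells` (per-cell n and
#'   mean), plus the call ingredients for [fisher_lsd()].
#' @export
two_way_anova <- function(table, response,
                          factors = c("strain", "age_weeks")) {
  stopifnot(is.data.frame(table), response %in% names(table),
            all(factors %in% names(table)), length(factors) == 2)
  df <- data.frame(y = table[[response]],
                   A = factor(table[[factors[1]]]),
                   B = factor(table[[factors[2]]]))
  df <- df[complete.cases(df), ]
  counts <- table(df$A, df$B)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factors[1], rownames(counts)[bad[1]],
                 factors[2], colnames(counts)[bad[2]]))
  }
  if (any(counts < 2))
    stop("each design cell needs at least 2 replicates")
  fit <- lm(y ~ A * B, data = df)
  # partial (Type II) SS; sequential SS coincide in the degenerate
  # zero-residual case car refuses (all SS are then determined exactly)
  a2 <- tryCatch(as.data.frame(car::Anova(fit, type = 2)),
                 error = function(e) {
                   a1 <- as.data.frame(suppressWarnings(anova(fit)))
                   a1[, c("Sum Sq", "Df", "F value", "Pr(>F)")]
                 })
  terms_map <- c("A" = factors[1], "B" = factors[2],
                 "A:B" = paste(factors, collapse = ":"),
                 "Residuals" = "residuals")
  out <- data.frame(term = unname(terms_map[rownames(a2)]),
                    df = a2$Df,
                    sum_sq = a2$`Sum Sq`,
                    statistic = a2$`F value`,
                    p_value = a2$`Pr(>F)`)
  out$mean_sq <- out$sum_sq / out$df
  res <- out$term == "residuals"
  cells <- aggregate(y ~ A + B, df, function(v) c(n = length(v), mean = mean(v)))
  cells <- data.frame(A = cells$A, B = cells$B,
                      n = cells$y[, "n"], mean = cells$y[, "mean"])
  names(cells)[1:2] <- factors
  structure(list(table = out[, c("term", "df", "sum_sq", "mean_sq",
                                 "statistic", "p_value")],
                 mse = out$mean_sq[res],
                 df_residual = out$df[res],
                 cells = cells,
                 response = response,
                 factors = factors,
                 data = df),
            class = "anova_2way")
}

#' @export
print.anova_2way <- function(x, ...) {
  cat("Two-way ANOVA (Type II) on", x$response, "\n")
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Fisher LSD post hoc comparison of two design cells
#'
#' The unadjusted pairwise test using the ANOVA pooled error:
#' `t = (m1 - m2) / sqrt(MSE * (1/n1 + 1/n2))` on the residual degrees of
#' freedom.  No family-wise correction is applied - the defining property
#' (and known liability) of the LSD procedure.
#'
#' @param anova an [two_way_anova()] result.
#' @param cell1,cell2 named lists/vectors giving a level for each factor,
#'   e.g. `list(strain = "SHR", age_weeks = 4)`.
#' @return list: `difference`, `se`, `statistic`, `df`, `p_value`, cell
#'   means and sizes.
#' @export
fisher_lsd <- function(anova, cell1, cell2) {
  stopifnot(inherits(anova, "anova_2way"))
  pick <- function(cell) {
    sel <- anova$cells[[anova$factors[1]]] == as.character(cell[[anova$factors[1]]]) &
           anova$cells[[anova$factors[2]]] == as.character(cell[[anova$factors[2]]])
    if (!any(sel))
      stop("no such design cell: ",
           paste(names(cell), unlist(cell), sep = "=", collapse = ", "))
    anova$cells[sel, , drop = FALSE]
  }
  c1 <- pick(cell1)
  c2 <- pick(cell2)
  se <- sqrt(anova$mse * (1 / c1$n + 1 / c2$n))
  diff <- c1$mean - c2$mean
  tt <- diff / se
  p <- 2 * pt(-abs(tt), anova$df_residual)
  list(difference = diff, se = se, statistic = tt, df = anova$df_residual,
       p_value = p, mean1 = c1$mean, mean2 = c2$mean, n1 = c1$n, n2 = c2$n)
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors, n >= 3, neither constant.
#' @return list: `r`, `n`, `p_value` (two-sided, via the t transform on
#'   n - 2 df).
#' @export
pearson_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = n, p_value = ct$p.value)
}

#' Two-sample Student t test (pooled variance, two-sided)
#'
#' @param x,y the two samples, n >= 2 each.
#' @return list: `statistic`, `df`, `p_value`, group means.  Zero pooled
#'   variance with equal means returns p = 1 by convention; with unequal
#'   means it is rejected.
#' @export
student_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, mean_x = mean(x), mean_y = mean(y)))
    stop("zero pooled variance with unequal means: t undefined")
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Min-max normalization of metric columns to \[0, 1\]
#'
#' Each listed metric is mapped by `(v - min) / (max - min)` over all rows,
#' the scaling used to put heterogeneous morphometries on one heat-map
#' scale.  Idempotent; constant metrics are rejected.
#'
#' @param table data.frame.
#' @param metrics character vector of numeric column names.
#' @return the table with the listed columns normalized.
#' @export
minmax_normalize <- function(table, metrics) {
  stopifnot(is.data.frame(table), all(metrics %in% names(table)))
  for (m in metrics) {
    v <- table[[m]]
    rng <- range(v, na.rm = TRUE)
    if (!(rng[2] > rng[1]))
      stop("metric `", m, "` is constant: cannot normalize")
    table[[m]] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  table
}
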