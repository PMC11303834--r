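#' Unpaired two-sample t test
#'
#' Two-sided unpaired t test; pooled-variance (equal-variance) form by
#' default, Welch as an option.
#'
#' @param x,y numeric samples, each with at least 2 finite values.
#' @param welch use the Welch (unequal-variance) form.
#' @return A list with `t`, `df`, `p`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#'   The sign convention is that of `x - y`: `t < 0` when `x` has the
#'   smaller mean.
#' @export
unpaired_t_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y),
                  n_x = length(x), n_y = length(y)))
    stop("zero variance in both samples with unequal means: t undefined",
         call. = FALSE)
  }
  ht <- t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y),
       n_x = length(x), n_y = length(y))
}

#' Step-down Holm-Sidak multiple-comparison adjustment
#'
#' Sorts the m raw p-values ascending and applies the step-down Sidak
#' adjustment `p'_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforcing
#' monotonicity by a running maximum, then maps the adjusted values back
#' to the input order. A comparison is flagged significant when its
#' adjusted p-value is below `alpha`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise significance threshold in `(0, 1)`.
#' @return A data frame with columns `p`, `p_adj`, `significant`, in the
#'   input order.
#' @export
holm_sidak_adjust <- function(p, alpha = 0.05) {
  if (length(p) == 0) {
    return(data.frame(p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- pmax(adj, ps)   # guards the adjusted >= raw invariant at the
                         # last rank, where 1 - (1 - p) can round below p
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  data.frame(p = p, p_adj = out, significant = out < alpha)
}

#' Compare sublayer thickness between groups
#'
#' Runs the specified pairwise unpaired t tests for every wall sublayer
#' across the two-level grouping variables present in the data (e.g.
#' condition: control vs diseased; side: left vs right atrium), and
#' applies the step-down Holm-Sidak correction within each sublayer's
#' family of comparisons.
#'
#' @param measurements a data frame with columns `sublayer`,
#'   `thickness_um`, and the grouping columns named in `contrasts` (a
#'   [measure_layer_thickness()] result with group columns added, or any
#'   long-format equivalent).
#' @param contrasts character vector of grouping column names; each must
#'   have exactly two levels where present. Comparisons with fewer than 2
#'   observations per group are skipped with a warning.
#' @param alpha family-wise significance threshold.
#' @param welch use Welch t tests instead of pooled-variance.
#' @return A data frame of class `comparison_result` with one row per
#'   comparison: `sublayer`, `contrast`, `group1`, `group2`, `n1`, `n2`,
#'   `mean1`, `mean2`, `t`, `df`, `p`, `p_adj`, `significant`.
#' @export
compare_thickness_groups <- function(measurements,
                                     contrasts = intersect(
                                       c("condition", "side"),
                                       names(measurements)),
                                     alpha = 0.05, welch = FALSE) {
  df <- as.data.frame(measurements)
  need <- c("sublayer", "thickness_um")
  if (!all(need %in% names(df)))
    stop("measurements need columns `sublayer` and `thickness_um`",
         call. = FALSE)
  if (length(contrasts) == 0)
    stop("no grouping columns found to compare", call. = FALSE)
  sublayers <- unique(as.character(df$sublayer))

  rows <- list()
  skipped <- character(0)
  for (sl in sublayers) {
    sub <- df[df$sublayer == sl, ]
    fam <- list()
    for (cn in contrasts) {
      lev <- sort(unique(as.character(sub[[cn]])))
      if (length(lev) != 2) {
        skipped <- c(skipped, sprintf("%s/%s (needs 2 levels, has %d)",
                                      sl, cn, length(lev)))
        next
      }
      x <- sub$thickness_um[sub[[cn]] == lev[1]]
      y <- sub$thickness_um[sub[[cn]] == lev[2]]
      if (length(x) < 2 || length(y) < 2) {
        skipped <- c(skipped, sprintf("%s/%s (n too small)", sl, cn))
        next
      }
      tt <- unpaired_t_test(x, y, welch = welch)
      fam[[length(fam) + 1L]] <- data.frame(
        sublayer = sl, contrast = cn, group1 = lev[1], group2 = lev[2],
        n1 = tt$n_x, n2 = tt$n_y, mean1 = tt$mean_x, mean2 = tt$mean_y,
        t = tt$t, df = tt$df, p = tt$p
      )
    }
    if (length(fam) == 0) next
    fam <- do.call(rbind, fam)
    adj <- holm_sidak_adjust(fam$p, alpha = alpha)  # one family per sublayer
    fam$p_adj <- adj$p_adj
    fam$significant <- adj$significant
    rows[[length(rows) + 1L]] <- fam
  }
  if (length(skipped) > 0)
    warning("skipped comparisons: ", paste(skipped, collapse = "; "))
  if (length(rows) == 0)
    stop("no comparison could be made", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_result", class(out))
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %d comparisons, Holm-Sidak within sublayer, alpha = %g\n",
    nrow(x), attr(x, "alpha")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
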