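#' qPCR relative expression (2^-dCt)
#'
#' Computes relative expression from paired cycle-threshold values:
#' `dCt = ct_target - ct_reference`, `rel_expr = 2^-dCt`, plus the log10
#' transform used for all downstream statistics. Vectorized over samples.
#'
#' @param ct_target,ct_reference numeric Ct values in `(0, 45]` (target
#'   gene and reference gene from the same sample/cell type).
#' @return Data frame with columns `rel_expr` and `log10_expr`.
#' @examples
#' relative_expression(25, 20)   # rel 0.03125, log10 -1.50515
#' @export
relative_expression <- function(ct_target, ct_reference) {
  ct_target <- as.numeric(ct_target)
  ct_reference <- as.numeric(ct_reference)
  if (length(ct_target) != length(ct_reference))
    stop("target and reference Ct vectors must have equal length",
         call. = FALSE)
  bad <- function(x) anyNA(x) | any(x <= 0 | x > 45)
  if (bad(ct_target) || bad(ct_reference))
    stop("Ct values must lie in (0, 45]", call. = FALSE)
  rel <- 2^(-(ct_target - ct_reference))
  data.frame(rel_expr = rel, log10_expr = log10(rel))
}

#' Compare expression between groups
#'
#' Two groups are compared with a t-test on the log10 scale (Welch by
#' default; the unpooled-variance form is the robust default when only
#' "t-test" is specified); three or more groups with a classic one-way
#' ANOVA F-test. Groups with fewer than 2 values are excluded with a
#' warning.
#'
#' @param values numeric vector (log10 expression values).
#' @param groups factor or character vector of group labels, same length.
#' @param var_equal use the pooled-variance Student t-test instead of Welch
#'   (ignored for >= 3 groups).
#' @return List with `method`, `statistic`, `p`, `df`, and a per-group
#'   summary data frame (`n`, `mean`, `se`).
#' @export
group_compare <- function(values, groups, var_equal = FALSE) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding group(s) with < 2 values: ",
            paste(small, collapse = ", "))
    keep2 <- !groups %in% small
    values <- values[keep2]; groups <- groups[keep2]
  }
  labs <- sort(unique(groups))
  if (length(labs) < 2L)
    stop("need at least 2 groups with >= 2 values each", call. = FALSE)
  summ <- do.call(rbind, lapply(labs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = sd(v) / sqrt(length(v)), stringsAsFactors = FALSE)
  }))
  if (length(labs) == 2L) {
    tt <- t.test(values[groups == labs[1]], values[groups == labs[2]],
                 var.equal = var_equal)
    list(method = if (var_equal) "student_t" else "welch_t",
         statistic = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), groups = summ)
  } else {
    ow <- oneway.test(values ~ factor(groups), var.equal = TRUE)
    list(method = "anova_f", statistic = unname(ow$statistic),
         p = ow$p.value, df = unname(ow$parameter), groups = summ)
  }
}

#' Simple linear regression of mRNA on miRNA expression
#'
#' Ordinary least squares of `y` on `x` with the squared Pearson
#' correlation as `r_squared` and the two-sided t-test p-value for the
#' slope — the analysis used to relate miRNA levels to target mRNA levels
#' across carriers.
#'
#' @param x predictor (e.g. log10 miRNA expression), not constant.
#' @param y response (e.g. log10 target mRNA expression).
#' @return List with `slope`, `intercept`, `r_squared`, `p_slope`, `n`.
#' @examples
#' linear_regression(1:10, 2 * (1:10) + 1)   # r_squared = 1, slope = 2
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (sd(x) == 0) stop("constant predictor: regression undefined",
                       call. = FALSE)
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_slope = s$coefficients[2, 4], n = n)
}

#' Read a qPCR Ct table and compute relative expression
#'
#' Expects the columns `sample_id`, `group`, `cell_type`, `genotype`,
#' `gene`, `ct_target`, `ct_reference`; appends `rel_expr` and
#' `log10_expr`.
#'
#' @param path CSV file.
#' @return The augmented data frame.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "cell_type", "genotype", "gene",
            "ct_target", "ct_reference")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0L)
    stop("Ct table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cbind(ct, relative_expression(ct$ct_target, ct$ct_reference))
}
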