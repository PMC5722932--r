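# Expression-side computations: descriptive 0/up/down regulation calls per
# gene (the call coding used in the published expression survey),
# pair-level co-regulation, delta-delta-Ct fold changes, and the delta-Ct
# linear regression. This is deliberately NOT a differential-expression
# method: no dispersion modelling, no multiple-testing correction.

#' Assemble an expression table
#'
#' @param values non-negative numeric matrix, genes in rows (row names =
#'   gene labels), samples in columns (column names = sample labels).
#' @param conditions character vector (one per sample) assigning each
#'   sample to `"control"` or `"treated"`.
#' @return List of class `expression_table` with `values` and `conditions`.
#' @export
expression_table <- function(values, conditions) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values))) stop("values needs gene row names")
  if (length(conditions) != ncol(values)) {
    stop("one condition per sample required (", ncol(values), " samples, ",
         length(conditions), " conditions)")
  }
  if (!all(conditions %in% c("control", "treated"))) {
    stop("conditions must be 'control' or 'treated'")
  }
  structure(list(values = values, conditions = as.character(conditions)),
            class = "expression_table")
}

#' Descriptive regulation call for one gene
#'
#' A gene is `expressed` when its mean over all samples reaches `min_expr`.
#' The fold change is `log2((mean treated + c) / (mean control + c))` with
#' pseudocount `c`. The call is `"up"`/`"down"` when the gene is expressed
#' and `|log2fc| >= min_log2fc`, else `"0"`. The thresholds are declared
#' configuration, not published values: the published survey coded calls
#' descriptively without stating cutoffs.
#'
#' @param table an [expression_table()].
#' @param gene gene label.
#' @param min_expr minimum mean expression to count as expressed
#'   (default 10; read-count scale).
#' @param min_log2fc minimum absolute log2 fold change for a non-zero call
#'   (default 1, i.e. two-fold).
#' @param pseudocount added to both means before the ratio (default 1).
#' @return List of class `regulation_call`: `gene`, `call` ("0", "up",
#'   "down"), `log2fc`, `expressed`.
#' @export
regulation_call <- function(table, gene, min_expr = 10, min_log2fc = 1,
                            pseudocount = 1) {
  stopifnot(inherits(table, "expression_table"))
  if (!gene %in% rownames(table$values)) stop("gene not in table: ", gene)
  for (cond in c("control", "treated")) {
    if (!cond %in% table$conditions) stop("no ", cond, " samples")
  }
  x <- table$values[gene, ]
  mean_all <- mean(x)
  mean_ctrl <- mean(x[table$conditions == "control"])
  mean_trt <- mean(x[table$conditions == "treated"])
  log2fc <- log2((mean_trt + pseudocount) / (mean_ctrl + pseudocount))
  expressed <- mean_all >= min_expr
  call <- if (expressed && abs(log2fc) >= min_log2fc) {
    if (log2fc > 0) "up" else "down"
  } else "0"
  structure(list(gene = gene, call = call, log2fc = log2fc,
                 expressed = expressed),
            class = "regulation_call")
}

#' Pair-level co-regulation from two gene calls
#'
#' @param call_a,call_b [regulation_call()] results.
#' @return `"coregulated_up"`, `"coregulated_down"`, `"discordant"`
#'   (both non-zero, opposite), or `"none"`.
#' @export
pair_coregulation <- function(call_a, call_b) {
  a <- call_a$call
  b <- call_b$call
  if (a == "0" || b == "0") return("none")
  if (a == b) return(paste0("coregulated_", a))
  "discordant"
}

#' Assemble qPCR records
#'
#' One record per sample; `delta_ct` is the target minus housekeeping cycle
#' threshold.
#'
#' @param sample sample labels.
#' @param ct_target,ct_housekeeping cycle-threshold values.
#' @return Data frame of class `qpcr_records` with a `delta_ct` column.
#' @export
qpcr_records <- function(sample, ct_target, ct_housekeeping) {
  stopifnot(length(sample) == length(ct_target),
            length(sample) == length(ct_housekeeping))
  out <- data.frame(sample = as.character(sample),
                    ct_target = as.numeric(ct_target),
                    ct_housekeeping = as.numeric(ct_housekeeping),
                    stringsAsFactors = FALSE)
  out$delta_ct <- out$ct_target - out$ct_housekeeping
  class(out) <- c("qpcr_records", "data.frame")
  out
}

#' Delta-delta-Ct fold change
#'
#' `ddCt = mean(dCt treated) - mean(dCt control)`; fold change =
#' `2^(-ddCt)`. Identical mean dCt gives fold 1; ddCt of -1 gives fold 2.
#'
#' @param control,treated [qpcr_records()] for the two conditions
#'   (non-empty).
#' @return Numeric fold change.
#' @export
ddct_fold_change <- function(control, treated) {
  if (nrow(control) == 0L || nrow(treated) == 0L) {
    stop("both conditions need at least one qPCR record")
  }
  ddct <- mean(treated$delta_ct) - mean(control$delta_ct)
  2^(-ddct)
}

#' Ordinary least-squares regression of paired delta-Ct values
#'
#' Fits `y ~ x` by OLS; `r_squared` is the squared Pearson correlation
#' (goodness of fit), invariant under affine transforms of either axis.
#'
#' @param x,y numeric delta-Ct vectors of equal length, n >= 2; `x` must
#'   have non-zero variance.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
delta_ct_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (stats::var(x) == 0) stop("degenerate input: x has zero variance")
  fit <- lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 1 else unname(cor(x, y)^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 n = length(x)),
            class = "regression_result")
}
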