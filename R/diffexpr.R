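#' Quantile normalization across samples
#'
#' Forces every sample (column) to share one value distribution: each column
#' is replaced by the across-sample rank means (sort each column, average
#' across columns at each rank, map the averages back by rank).  Ties within
#' a column receive the mean of the reference values at their tied ranks, so
#' tied inputs stay tied.
#'
#' @param m An [expr_matrix()] in state `"raw"` (or a plain matrix) with at
#'   least two columns.
#' @return An [expr_matrix()] in state `"quantile"`.
#' @examples
#' quantile_normalize(expr_matrix(cbind(a = c(5, 3, 1), b = c(4, 2, 6))))
#' @export
quantile_normalize <- function(m) {
  if (inherits(m, "expr_matrix") && norm_state(m) != "raw")
    stop("matrix is already normalized (state = ", norm_state(m), ")")
  x <- unclass(as.matrix(m))
  if (ncol(x) < 2L) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    v <- numeric(nrow(x))
    v[o] <- ref
    # tied input values share the mean of their reference slots
    v <- stats::ave(v, match(x[, j], x[, j]), FUN = mean)
    out[, j] <- v
  }
  expr_matrix(out, "quantile")
}

#' Regularized log2 fold change
#'
#' `log2((a + r) / (b + r))`.  The regularizer r (5 by default, 10 as the
#' common alternative) prevents low-expression genes from dominating the list
#' of genes with a large fold change: genes with expression around 5 or below
#' cannot exceed |log2FC| = 1 at r = 5 whatever their ratio.
#'
#' @param a,b Non-negative expression values (vectorised).
#' @param r Regularizer, > 0.
#' @return log2 fold change(s) of `a` over `b`.
#' @examples
#' regularized_log2fc(15, 5, r = 5)  # 1
#' @export
regularized_log2fc <- function(a, b, r = 5) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("regularizer `r` must be a single value > 0")
  if (any(a < 0) || any(b < 0)) stop("expression values must be >= 0")
  log2((a + r) / (b + r))
}

#' Paired two-sided t-test on per-pair differences
#'
#' Takes treated-minus-control differences (one vector per gene, or a genes x
#' pairs matrix) and returns the two-sided p-value from the t distribution
#' with `n_pairs - 1` degrees of freedom.  Zero-variance difference vectors
#' have no defined t statistic: they yield `NA` and are excluded from FDR
#' ranking downstream.
#'
#' @param d Numeric vector of paired differences, or a matrix with one row
#'   per gene and one column per pair.
#' @return p-value (vector for matrix input), `NA` where degenerate.
#' @examples
#' paired_test(c(1, 2, 3))  # about 0.0742
#' @export
paired_test <- function(d) {
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  k <- ncol(d)
  if (k < 2L) stop("paired test needs >= 2 pairs")
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (k - 1L))
  tt <- m / (s / sqrt(k))
  p <- 2 * stats::pt(-abs(tt), df = k - 1L)
  p[s == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1 and
#' returned in input order.  `NA` p-values (degenerate tests) are excluded
#' from the ranking and stay `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return q-values, same length and order as `p`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.5))
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv)
    qs <- pmin(1, cummin(rev(m * pv[o] / seq_len(m)))[m:1])
    tmp <- numeric(m)
    tmp[o] <- qs
    q[which(ok)] <- tmp
  }
  q
}

#' Paired differential expression with regularized fold change
#'
#' The full testing scheme: quantile-normalize (unless already normalized),
#' average each condition across pairs, form the regularized log2 fold
#' change of the means, run the paired t-test per gene, adjust with
#' Benjamini-Hochberg, and flag DEGs by the conjunction
#' |log2FC| > log2(fc_cut), p < p_cut, q < q_cut.
#'
#' @param m An [expr_matrix()] (raw matrices are quantile-normalized first).
#' @param design data.frame with columns `control` and `treated` naming the
#'   sample columns of each pair (and optionally `pair_id`).
#' @param r Regularizer for the fold change (5 or 10; recorded in the result).
#' @param fc_cut Fold-change cutoff on the natural scale (default 1.5).
#' @param p_cut,q_cut Raw p and FDR cutoffs (default 0.05 each).
#' @param log_before_test Run the t-test on log2(x + r) values instead of
#'   normalized values (default FALSE).
#' @param per_pair_fc Average per-pair regularized fold changes instead of
#'   taking the fold change of the condition means (default FALSE).
#' @param drop_undetected Exclude genes with zero expression in every sample
#'   before normalization and testing (default TRUE).  Undetected genes have
#'   no evidence to test; left in, quantile normalization gives every such
#'   row one shared tie-averaged value per sample and the t-test returns one
#'   meaningless shared p-value for all of them.  Dropped genes reappear in
#'   the result with NA p/q and `is_deg = FALSE`.
#' @return data.frame of class `differential_result`: gene_id, mean_ctrl,
#'   mean_treat, log2fc_reg, p_value, q_value, is_deg; parameters, the DEG
#'   summary and the normalized matrix (`matrix_norm`) are attached as
#'   attributes.
#' @export
diff_expression <- function(m, design, r = 5, fc_cut = 1.5, p_cut = 0.05,
                            q_cut = 0.05, log_before_test = FALSE,
                            per_pair_fc = FALSE, drop_undetected = TRUE) {
  if (!all(c("control", "treated") %in% names(design)))
    stop("`design` needs columns `control` and `treated`")
  samp <- c(design$control, design$treated)
  if (anyDuplicated(samp)) stop("a sample is reused across pairs")
  if (length(setdiff(samp, colnames(m))))
    stop("design samples missing from matrix: ",
         paste(setdiff(samp, colnames(m)), collapse = ", "))
  if (nrow(design) < 2L) stop("paired testing needs >= 2 pairs")
  if (!inherits(m, "expr_matrix")) m <- expr_matrix(m, "raw")
  undetected <- character(0)
  if (norm_state(m) == "raw") {
    if (drop_undetected) {
      zero <- rowSums(unclass(m)) == 0
      undetected <- rownames(m)[zero]
      m <- expr_matrix(unclass(m)[!zero, , drop = FALSE], "raw")
    }
    m <- quantile_normalize(m)
  }
  xc <- unclass(m)[, design$control, drop = FALSE]
  xt <- unclass(m)[, design$treated, drop = FALSE]
  mean_ctrl <- rowMeans(xc)
  mean_treat <- rowMeans(xt)
  l2 <- if (per_pair_fc)
    rowMeans(regularized_log2fc(xt, xc, r)) else
      regularized_log2fc(mean_treat, mean_ctrl, r)
  d <- if (log_before_test) log2(xt + r) - log2(xc + r) else xt - xc
  p <- paired_test(d)
  q <- fdr_adjust(p)
  res <- data.frame(gene_id = rownames(m), mean_ctrl = mean_ctrl,
                    mean_treat = mean_treat, log2fc_reg = l2,
                    p_value = p, q_value = q, stringsAsFactors = FALSE)
  if (length(undetected))
    res <- rbind(res, data.frame(gene_id = undetected, mean_ctrl = 0,
                                 mean_treat = 0, log2fc_reg = 0,
                                 p_value = NA_real_, q_value = NA_real_,
                                 stringsAsFactors = FALSE))
  rownames(res) <- NULL
  res <- call_degs(res, fc_cut = fc_cut, p_cut = p_cut, q_cut = q_cut)
  attr(res, "params") <- list(r = r, fc_cut = fc_cut, p_cut = p_cut,
                              q_cut = q_cut, fdr_method = "BH",
                              log_before_test = log_before_test,
                              per_pair_fc = per_pair_fc,
                              n_pairs = nrow(design),
                              n_undetected = length(undetected))
  attr(res, "matrix_norm") <- m
  res
}

#' Flag differentially expressed genes
#'
#' `is_deg` is the conjunction |log2fc_reg| > log2(fc_cut), p < p_cut and
#' q < q_cut (two-sided fold-change gate; down-regulated genes count).  A
#' summary (total / up / down) is attached as an attribute and printed.
#'
#' @param results data.frame with columns log2fc_reg, p_value, q_value.
#' @param fc_cut Fold-change cutoff, natural scale (default 1.5).
#' @param p_cut,q_cut p and FDR cutoffs (default 0.05).
#' @return `results` with an `is_deg` column, class `differential_result`.
#' @export
call_degs <- function(results, fc_cut = 1.5, p_cut = 0.05, q_cut = 0.05) {
  lfc <- results$log2fc_reg
  deg <- !is.na(results$p_value) & !is.na(results$q_value) &
    abs(lfc) > log2(fc_cut) & results$p_value < p_cut &
    results$q_value < q_cut
  results$is_deg <- deg
  attr(results, "deg_summary") <- c(total = sum(deg),
                                    up = sum(deg & lfc > 0),
                                    down = sum(deg & lfc < 0))
  class(results) <- unique(c("differential_result", class(results)))
  results
}

#' @export
print.differential_result <- function(x, ...) {
  s <- attr(x, "deg_summary")
  cat("differential_result:", nrow(x), "genes;",
      s["total"], "DEGs (", s["up"], "up /", s["down"], "down )\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Volcano-plot table
#'
#' Per gene: log2 fold change, -log10 p (p floored at 1e-300 so values stay
#' finite), and a neutral `highlight` flag marking which side of the
#' fold-change cutoff the gene falls on (color semantics are left to the
#' caller).
#'
#' @param results A `differential_result`.
#' @param fc_cut Fold-change cutoff, natural scale (default 1.5).
#' @return data.frame: gene_id, log2fc, neg_log10_p, highlight.
#' @export
volcano_table <- function(results, fc_cut = 1.5) {
  data.frame(
    gene_id = results$gene_id,
    log2fc = results$log2fc_reg,
    neg_log10_p = -log10(pmax(results$p_value, 1e-300)),
    highlight = abs(results$log2fc_reg) > log2(fc_cut),
    stringsAsFactors = FALSE
  )
}

#' Heatmap transform
#'
#' Elementwise `log2(value + 1)` of a non-negative expression matrix, the
#' transform conventionally applied before clustering/plotting.
#'
#' @param m Numeric matrix with values >= 0.
#' @return Transformed matrix (plain numeric matrix).
#' @export
heatmap_matrix <- function(m) {
  x <- unclass(as.matrix(m))
  if (any(x < 0)) stop("heatmap transform requires non-negative values")
  log2(x + 1)
}

#' Write a differential result as TSV
#'
#' @param results A `differential_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_result <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  pr <- attr(results, "params")
  if (!is.null(pr))
    writeLines(sprintf("#seqmed-deg r=%s fc=%s p=%s q=%s fdr=%s", pr$r,
                       pr$fc_cut, pr$p_cut, pr$q_cut, pr$fdr_method), con)
  utils::write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
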