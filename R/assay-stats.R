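#' Simulate an EdU proliferation-assay count table
#'
#' For each condition and each of `n_units` coverslips, emits nine imaged
#' fields of (DAPI+ nuclei, EdU+ nuclei): DAPI counts are Poisson around
#' `dapi_mean`, EdU counts binomial with a condition-specific proliferation
#' probability `base_p * multiplier`, modulated by a log-normal unit effect
#' shared across conditions within a pair (cultures differ; the paired design
#' exploits that).
#'
#' @param multipliers Named numeric vector of per-condition effect
#'   multipliers, e.g. `c(sham = 1, es = 2)`.
#' @param n_units Coverslips per condition (default 5, one per pair).
#' @param base_p Control proliferation probability (default 0.1).
#' @param fields Imaged fields per coverslip (default 9).
#' @param dapi_mean Mean DAPI+ nuclei per field (default 150).
#' @param unit_sd sdlog of the pair-level log-normal effect (default 0.2;
#'   0 gives independent, unblocked groups for ANOVA-style designs).
#' @param seed Integer seed.
#' @return data.frame of class `assay_counts`: coverslip_id, condition,
#'   pair_id, field_index, dapi_count, edu_count.
#' @export
simulate_assay_counts <- function(multipliers = c(sham = 1, es = 1),
                                  n_units = 5L, base_p = 0.1, fields = 9L,
                                  dapi_mean = 150, unit_sd = 0.2, seed = 1L) {
  if (is.null(names(multipliers))) stop("`multipliers` must be named by condition")
  pr <- base_p * multipliers
  if (any(pr < 0 | pr > 1))
    stop("proliferation probability outside [0, 1]: check base_p * multipliers")
  set.seed(as.integer(seed))
  pair_eff <- stats::rlnorm(n_units, 0, unit_sd)
  rows <- list()
  for (cond in names(multipliers)) {
    for (u in seq_len(n_units)) {
      p <- min(1, pr[[cond]] * pair_eff[u])
      dapi <- stats::rpois(fields, dapi_mean)
      edu <- stats::rbinom(fields, dapi, p)
      rows[[length(rows) + 1L]] <- data.frame(
        coverslip_id = sprintf("%s_u%d", cond, u), condition = cond,
        pair_id = paste0("u", u), field_index = seq_len(fields),
        dapi_count = dapi, edu_count = edu, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("assay_counts", "data.frame")
  out
}

#' Percentage of EdU+ among DAPI+ nuclei
#'
#' Pools counts over each unit's fields (sum of EdU+ divided by sum of DAPI+,
#' as a percentage), the way a fraction "among DAPI+ nuclei over the imaged
#' areas" is computed; `method = "mean_of_fields"` instead averages per-field
#' percentages.  Units with no DAPI+ nuclei give NA with a warning; units
#' with a field count other than nine are kept but reported in a message.
#'
#' @param table An `assay_counts` data.frame (or anything with columns
#'   coverslip_id, condition, pair_id (optional), dapi_count, edu_count).
#' @param per Aggregation unit: `"coverslip"` (default) or `"condition"`.
#' @param method `"pooled"` (default) or `"mean_of_fields"`.
#' @param expected_fields Expected fields per coverslip (default 9).
#' @return data.frame: unit, condition, pair_id (when present),
#'   edu_percent.
#' @export
edu_fraction <- function(table, per = c("coverslip", "condition"),
                         method = c("pooled", "mean_of_fields"),
                         expected_fields = 9L) {
  per <- match.arg(per)
  method <- match.arg(method)
  if (any(table$edu_count > table$dapi_count))
    stop("edu_count exceeds dapi_count")
  unit <- if (per == "coverslip") table$coverslip_id else table$condition
  nf <- tapply(table$dapi_count, unit, length)
  if (per == "coverslip" && any(nf != expected_fields))
    message(sum(nf != expected_fields), " coverslip(s) deviate from ",
            expected_fields, " fields")
  if (method == "pooled") {
    dapi <- tapply(table$dapi_count, unit, sum)
    edu <- tapply(table$edu_count, unit, sum)
    frac <- 100 * edu / dapi
  } else {
    pf <- 100 * table$edu_count / table$dapi_count
    frac <- tapply(pf, unit, mean, na.rm = TRUE)
  }
  if (any(!is.finite(frac))) {
    warning("unit(s) with zero DAPI+ nuclei give NA")
    frac[!is.finite(frac)] <- NA_real_
  }
  meta <- table[!duplicated(unit), , drop = FALSE]
  meta <- meta[match(names(frac), if (per == "coverslip")
    meta$coverslip_id else meta$condition), , drop = FALSE]
  out <- data.frame(unit = names(frac), condition = meta$condition,
                    edu_percent = as.numeric(frac), stringsAsFactors = FALSE)
  if (per == "coverslip" && "pair_id" %in% names(table))
    out$pair_id <- meta$pair_id
  rownames(out) <- NULL
  out
}

#' Compare assay readouts between conditions
#'
#' Runs the group comparison used for assay panels: paired or unpaired
#' two-sided t-tests of every condition against the control, or a one-way
#' ANOVA across all conditions.  Fold change versus control (ratio of group
#' means) is reported alongside each contrast.
#'
#' @param fractions Output of [edu_fraction()] (per-coverslip), or any
#'   data.frame with columns unit, condition, a value column, and pair_id for
#'   paired designs.
#' @param design `"paired"`, `"unpaired"` or `"anova"`.
#' @param control Control condition label (default `"sham"`).
#' @param value Name of the value column (default `"edu_percent"`).
#' @return data.frame: contrast, statistic, df, p_value, fold_change (NA for
#'   the ANOVA row, whose fold change has no single contrast).
#' @export
compare_conditions <- function(fractions, design = c("paired", "unpaired", "anova"),
                               control = "sham", value = "edu_percent") {
  design <- match.arg(design)
  v <- fractions[[value]]
  cond <- fractions$condition
  if (design == "anova") {
    if (length(unique(cond)) < 2L) stop("ANOVA needs >= 2 conditions")
    fit <- stats::oneway.test(v ~ factor(cond), var.equal = TRUE)
    return(data.frame(contrast = "anova",
                      statistic = unname(fit$statistic),
                      df = unname(fit$parameter[1]),
                      p_value = fit$p.value, fold_change = NA_real_,
                      stringsAsFactors = FALSE))
  }
  if (!control %in% cond) stop("control condition '", control, "' absent")
  others <- setdiff(unique(cond), control)
  res <- lapply(others, function(g) {
    xc <- fractions[cond == control, , drop = FALSE]
    xt <- fractions[cond == g, , drop = FALSE]
    if (design == "paired") {
      if (is.null(fractions$pair_id))
        stop("paired design requires a pair_id column")
      orphans <- c(setdiff(xt$pair_id, xc$pair_id),
                   setdiff(xc$pair_id, xt$pair_id))
      if (length(orphans))
        stop("unmatched pair(s): ", paste(unique(orphans), collapse = ", "))
      xt <- xt[match(xc$pair_id, xt$pair_id), , drop = FALSE]
      ht <- tryCatch(stats::t.test(xt[[value]], xc[[value]], paired = TRUE),
                     error = function(e) NULL)
      if (is.null(ht) || !is.finite(ht$p.value)) {
        # constant differences: no defined t statistic
        warning("degenerate paired contrast ", g, " vs ", control)
        ht <- list(statistic = NA_real_, parameter = NA_real_,
                   p.value = NA_real_)
      }
    } else {
      ht <- stats::t.test(xt[[value]], xc[[value]], var.equal = TRUE)
    }
    data.frame(contrast = paste(g, "vs", control),
               statistic = unname(ht$statistic),
               df = unname(ht$parameter),
               p_value = ht$p.value,
               fold_change = mean(xt[[value]]) / mean(xc[[value]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Delta-delta-Ct qPCR fold change
#'
#' Standard reference-gene normalization: per sample,
#' `dCt = mean(ct_gene) - mean(ct_reference)` (technical replicates averaged
#' first); per gene and condition, `ddCt = mean dCt(condition) - mean
#' dCt(control)`; fold change `2^-ddCt`.
#'
#' @param records data.frame with columns sample_id, gene, ct, condition
#'   (long format; replicate rows allowed).
#' @param control_condition Condition used as calibrator.
#' @param reference_gene Internal-control gene (default `"Gapdh"`).
#' @return data.frame: gene, condition, ddct, fold_change, for every
#'   non-control condition and non-reference gene.
#' @export
ddct_fold_change <- function(records, control_condition,
                             reference_gene = "Gapdh") {
  req <- c("sample_id", "gene", "ct", "condition")
  if (length(setdiff(req, names(records))))
    stop("qPCR records need columns: ", paste(req, collapse = ", "))
  if (any(records$ct <= 0)) stop("ct values must be > 0")
  if (!control_condition %in% records$condition)
    stop("control condition '", control_condition, "' absent from records")
  samples <- unique(records$sample_id)
  ref <- records[records$gene == reference_gene, , drop = FALSE]
  missing_ref <- setdiff(samples, ref$sample_id)
  if (length(missing_ref))
    stop("reference gene '", reference_gene, "' not measured in sample(s): ",
         paste(missing_ref, collapse = ", "))
  ref_ct <- tapply(ref$ct, ref$sample_id, mean)
  tgt <- records[records$gene != reference_gene, , drop = FALSE]
  key <- interaction(tgt$sample_id, tgt$gene, drop = TRUE)
  agg <- data.frame(
    sample_id = tapply(tgt$sample_id, key, `[`, 1L),
    gene = tapply(tgt$gene, key, `[`, 1L),
    ct = as.numeric(tapply(tgt$ct, key, mean)),
    stringsAsFactors = FALSE
  )
  cond_of <- tapply(records$condition, records$sample_id, `[`, 1L)
  agg$condition <- cond_of[agg$sample_id]
  agg$dct <- agg$ct - ref_ct[agg$sample_id]
  res <- list()
  for (g in unique(agg$gene)) {
    a <- agg[agg$gene == g, , drop = FALSE]
    ctrl_dct <- mean(a$dct[a$condition == control_condition])
    for (cn in setdiff(unique(a$condition), control_condition)) {
      ddct <- mean(a$dct[a$condition == cn]) - ctrl_dct
      res[[length(res) + 1L]] <- data.frame(
        gene = g, condition = cn, ddct = ddct, fold_change = 2^(-ddct),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
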