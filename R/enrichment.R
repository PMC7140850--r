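#' Gene-set collection
#'
#' Named gene sets plus the reference universe they are tested against (for
#' transcriptome-wide DEG lists the universe is conventionally all
#' protein-coding genes of the organism).  Members outside the universe are
#' dropped at construction.
#'
#' @param sets Named list of character vectors (category -> member gene ids).
#' @param universe Character vector: the reference gene list.
#' @param descriptions Optional named character vector of category
#'   descriptions.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be a named list")
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "categories, universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the conventional tab-separated gene-set format: one category per
#' line as `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @param universe Reference universe for the resulting collection.
#' @return `read_gmt()` returns a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed GMT line ", bad[1], " (need >= 3 fields)")
  nm <- vapply(parts, `[[`, character(1), 1L)
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2L), nm)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), nm)
  gene_set_collection(sets, universe, desc)
}

#' @rdname read_gmt
#' @param collection A [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  nm <- names(collection$sets)
  desc <- collection$descriptions
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(nm)), nm)
  writeLines(vapply(nm, function(n)
    paste(c(n, desc[[n]], collection$sets[[n]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric upper tail)
#'
#' For each category with at least `min_size` members (after restriction to
#' the universe), tests whether the DEG list overlaps it more than expected
#' under uniform draws: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`
#' with universe size N, category size K and DEG-list size n (exact tail via
#' [stats::phyper]).  q-values are Benjamini-Hochberg across the tested
#' (post-filter) categories only; categories are significant at `q < alpha`.
#' One-sided by design: under-representation is not scored.
#'
#' @param deg_list Character vector of DEG ids.  Duplicates are collapsed
#'   with a warning; genes outside the universe are dropped with a message.
#' @param collection A [gene_set_collection()].
#' @param min_size Minimum (universe-restricted) category size (default 5).
#' @param alpha FDR significance threshold (default 0.05).
#' @return data.frame of class `ora_result`, sorted by q then p: category_id,
#'   name, k (overlap), n (DEG-list size in universe), K (category size),
#'   N (universe size), p_value, q_value, significant.
#' @export
ora_test <- function(deg_list, collection, min_size = 5L, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(deg_list)) stop("empty DEG list")
  if (anyDuplicated(deg_list)) {
    warning("duplicated gene ids in DEG list collapsed")
    deg_list <- unique(deg_list)
  }
  universe <- collection$universe
  outside <- setdiff(deg_list, universe)
  if (length(outside)) {
    message(length(outside), " DEG(s) outside the universe dropped")
    deg_list <- intersect(deg_list, universe)
  }
  if (!length(deg_list)) stop("no DEG remains inside the universe")
  N <- length(universe)
  n <- length(deg_list)
  K <- lengths(collection$sets)
  keep <- K >= min_size
  if (!any(keep))
    return(structure(data.frame(category_id = character(0)),
                     class = c("ora_result", "data.frame")))
  sets <- collection$sets[keep]
  K <- K[keep]
  k <- vapply(sets, function(s) length(intersect(deg_list, s)), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- fdr_adjust(p)
  nm <- names(sets)
  desc <- collection$descriptions
  res <- data.frame(
    category_id = nm,
    name = if (!is.null(desc)) unname(desc[nm]) else nm,
    k = k, n = n, K = as.integer(K), N = N,
    p_value = p, q_value = q, significant = q < alpha,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$q_value, res$p_value, res$category_id), ]
  rownames(res) <- NULL
  class(res) <- c("ora_result", "data.frame")
  res
}

#' Write an ORA result as TSV
#'
#' @param res An `ora_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ora_result <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
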