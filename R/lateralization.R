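# Paired left/right transcript-lateralization filtering and qPCR helpers.

#' Paired left/right expression matrix
#'
#' Normalized intensities for probes x samples together with present/absent
#' calls and (embryo, side) metadata. Every embryo must contribute exactly
#' one left and one right sample.
#'
#' @param expr numeric matrix, rownames = probe ids, colnames = sample ids.
#' @param calls character matrix of `"P"`/`"A"` calls, same dimnames.
#' @param meta data.frame with columns `sample`, `embryo`, `side` (`"L"` or
#'   `"R"`).
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(expr, calls, meta) {
  expr <- as.matrix(expr)
  calls <- as.matrix(calls)
  meta <- as.data.frame(meta)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    phreno_stop("InvalidParams", "`expr` needs probe rownames and sample colnames")
  if (!identical(dim(expr), dim(calls)))
    phreno_stop("InvalidParams", "`expr` and `calls` dimensions differ")
  if (!all(c("sample", "embryo", "side") %in% names(meta)))
    phreno_stop("InvalidParams", "`meta` needs columns sample, embryo, side")
  if (!setequal(meta$sample, colnames(expr)))
    phreno_stop("InvalidParams", "metadata samples must match expr columns")
  meta <- meta[match(colnames(expr), meta$sample), , drop = FALSE]
  if (!all(meta$side %in% c("L", "R")))
    phreno_stop("InvalidParams", "`side` must be 'L' or 'R'")
  for (em in unique(meta$embryo)) {
    sides <- sort(meta$side[meta$embryo == em])
    if (!identical(sides, c("L", "R")))
      phreno_stop("MissingSide",
                  "embryo %s must have exactly one L and one R sample", em)
  }
  if (!all(is.finite(expr)) || any(expr < 0))
    phreno_stop("InvalidParams", "intensities must be finite and >= 0")
  if (!all(calls %in% c("P", "A")))
    phreno_stop("InvalidParams", "calls must be 'P' or 'A'")
  structure(list(expr = expr, calls = calls, meta = meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples (%d embryos)\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$meta$embryo))))
  invisible(x)
}

sample_of <- function(em, embryo, side) {
  em$meta$sample[em$meta$embryo == embryo & em$meta$side == side]
}

#' Expressed-transcript filter
#'
#' A probe is considered expressed if it is called present in at least one
#' sample of every embryo and its maximal normalized intensity over all
#' samples is at least `floor` (low-expression gate).
#'
#' @param em an [expression_matrix()].
#' @param floor intensity floor for the low-expression gate (default 200).
#' @return Character vector of expressed probe ids.
#' @export
filter_expressed <- function(em, floor = 200) {
  embryos <- unique(em$meta$embryo)
  present_all <- rep(TRUE, nrow(em$expr))
  for (emb in embryos) {
    cols <- em$meta$sample[em$meta$embryo == emb]
    present_all <- present_all &
      rowSums(em$calls[, cols, drop = FALSE] == "P") >= 1L
  }
  keep <- present_all & apply(em$expr, 1, max) >= floor
  rownames(em$expr)[keep]
}

#' Detect lateralized transcripts
#'
#' A probe is right-enriched when its per-embryo log2(R/L) ratios all share a
#' positive sign, their mean exceeds `log2(fold)`, and at least `min_embryos`
#' embryos individually exceed the fold change in that direction;
#' left-enriched is the mirror rule. All inequalities are strict, so a probe
#' sitting exactly at the fold threshold is not called. A per-embryo ratio of
#' exactly zero breaks the same-sign requirement.
#'
#' @param em an [expression_matrix()].
#' @param fold fold-change threshold (default 1.5; log2 scale 0.5849).
#' @param min_embryos embryos that must individually exceed the fold change
#'   (default 2).
#' @param probes probe ids to scan; defaults to [filter_expressed()].
#' @param expression_floor gate passed to [filter_expressed()].
#' @param intensity_floor intensities are floored at this value before log2
#'   ratios so zeros cannot produce infinities (default 1).
#' @param collapse_genes optional probe -> gene map (named character vector);
#'   when given, only the probe with the highest maximal intensity per gene
#'   is scanned.
#' @return Object of class `lateralized_gene_set`: `left_enriched`,
#'   `right_enriched`, `log2_ratios` (probes x embryos), `mean_log2_ratio`,
#'   `thresholds`.
#' @export
detect_lateralized <- function(em, fold = 1.5, min_embryos = 2L,
                               probes = NULL, expression_floor = 200,
                               intensity_floor = 1,
                               collapse_genes = NULL) {
  stopifnot_scalar_number(fold, "fold", positive = TRUE)
  if (fold <= 1) phreno_stop("InvalidParams", "`fold` must be > 1")
  if (is.null(probes)) probes <- filter_expressed(em, expression_floor)
  if (!is.null(collapse_genes)) {
    genes <- collapse_genes[probes]
    mx <- apply(em$expr[probes, , drop = FALSE], 1, max)
    probes <- unlist(lapply(split(probes, genes),
                            function(p) p[which.max(mx[p])]),
                     use.names = FALSE)
  }
  embryos <- unique(em$meta$embryo)
  lr <- sapply(embryos, function(emb) {
    l <- pmax(em$expr[probes, sample_of(em, emb, "L")], intensity_floor)
    r <- pmax(em$expr[probes, sample_of(em, emb, "R")], intensity_floor)
    log2(r / l)
  })
  lr <- matrix(lr, nrow = length(probes),
               dimnames = list(probes, embryos))
  thr <- log2(fold)
  # strict inequality with a 1e-9 guard on the log2 scale, so a probe
  # sitting exactly at the fold threshold is never called regardless of
  # floating-point rounding in the ratio
  eps <- 1e-9
  mean_lr <- rowMeans(lr)
  right <- rowSums(lr > 0) == ncol(lr) & mean_lr > thr + eps &
    rowSums(lr > thr + eps) >= min_embryos
  left <- rowSums(lr < 0) == ncol(lr) & mean_lr < -thr - eps &
    rowSums(lr < -thr - eps) >= min_embryos
  structure(list(left_enriched = probes[left],
                 right_enriched = probes[right],
                 log2_ratios = lr, mean_log2_ratio = mean_lr,
                 thresholds = list(fold = fold, log2_fold = thr,
                                   expression_floor = expression_floor,
                                   min_embryos = min_embryos)),
            class = "lateralized_gene_set")
}

#' @export
print.lateralized_gene_set <- function(x, ...) {
  cat(sprintf(
    "<lateralized_gene_set> %d left-enriched, %d right-enriched (fold > %g, >= %d embryos)\n",
    length(x$left_enriched), length(x$right_enriched),
    x$thresholds$fold, x$thresholds$min_embryos))
  invisible(x)
}

#' Annotation-category proportions of lateralized genes
#'
#' Percentage of left- and right-enriched probes per annotation category
#' (e.g. Gene Ontology cellular-component terms); probes missing from the
#' annotation are pooled under `"unannotated"`. Percentages sum to 100 within
#' each side.
#'
#' @param gene_set a `lateralized_gene_set` from [detect_lateralized()].
#' @param annotation data.frame with columns `probe` and `category`.
#' @return data.frame with columns `side`, `category`, `n`, `percent`.
#' @export
category_proportions <- function(gene_set, annotation) {
  annotation <- as.data.frame(annotation)
  lookup <- stats::setNames(as.character(annotation$category),
                            annotation$probe)
  one_side <- function(probes, side) {
    if (length(probes) == 0L) return(NULL)
    cat_ <- lookup[probes]
    cat_[is.na(cat_)] <- "unannotated"
    tab <- table(cat_)
    data.frame(side = side, category = names(tab), n = as.integer(tab),
               percent = 100 * as.numeric(tab) / length(probes),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(gene_set$left_enriched, "left"),
               one_side(gene_set$right_enriched, "right"))
  rownames(out) <- NULL
  out
}

#' Reference-normalized qPCR expression
#'
#' Relative expression per sample is `2^-(Ct_target - Ct_reference)`
#' (normalization to a housekeeping reference such as GAPDH), and the
#' right/left ratio is formed per embryo.
#'
#' @param ct_table data.frame with columns `embryo`, `side` (`"L"`/`"R"`),
#'   `ct_target`, `ct_reference`.
#' @return List with `samples` (input plus `relative_expression`) and
#'   `ratios` (data.frame embryo/ratio of right over left).
#' @export
qpcr_relative <- function(ct_table) {
  ct <- as.data.frame(ct_table)
  need <- c("embryo", "side", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    phreno_stop("InvalidParams", "`ct_table` needs columns %s",
                paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct_reference)))
    phreno_stop("MissingReference", "reference Ct missing for some samples")
  if (any(!is.finite(ct$ct_target)))
    phreno_stop("InvalidParams", "target Ct must be finite")
  ct$relative_expression <- 2^(-(ct$ct_target - ct$ct_reference))
  ratios <- do.call(rbind, lapply(split(ct, ct$embryo), function(g) {
    l <- g$relative_expression[g$side == "L"]
    r <- g$relative_expression[g$side == "R"]
    if (length(l) != 1L || length(r) != 1L)
      phreno_stop("MissingSide", "embryo %s lacks a paired L/R sample",
                  g$embryo[1])
    data.frame(embryo = g$embryo[1], ratio = r / l)
  }))
  rownames(ratios) <- NULL
  list(samples = ct, ratios = ratios)
}

#' Read a paired expression dataset from CSV files
#'
#' @param expr_path CSV of intensities, first column probe ids, remaining
#'   columns samples.
#' @param calls_path CSV of `"P"`/`"A"` calls with the same layout.
#' @param meta_path CSV with columns `sample`, `embryo`, `side`.
#' @return An [expression_matrix()].
#' @export
read_expression_csv <- function(expr_path, calls_path, meta_path) {
  ex <- utils::read.csv(expr_path, row.names = 1, check.names = FALSE)
  ca <- utils::read.csv(calls_path, row.names = 1, check.names = FALSE)
  me <- utils::read.csv(meta_path)
  expression_matrix(as.matrix(ex), as.matrix(ca), me)
}

#' Write lateralized gene lists to CSV
#'
#' One row per enriched probe with its per-embryo log2(R/L) ratios and their
#' mean, mirroring the source-data layout of published gene lists.
#'
#' @param gene_set a `lateralized_gene_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gene_set_csv <- function(gene_set, path) {
  probes <- c(gene_set$left_enriched, gene_set$right_enriched)
  side <- rep(c("left", "right"), c(length(gene_set$left_enriched),
                                    length(gene_set$right_enriched)))
  lr <- gene_set$log2_ratios[probes, , drop = FALSE]
  colnames(lr) <- paste0("log2_ratio_", colnames(lr))
  out <- data.frame(probe = probes, side = side, lr,
                    mean_log2_ratio = gene_set$mean_log2_ratio[probes],
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
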