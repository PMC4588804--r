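#' Normalize a feature table
#'
#' * `none` — identity.
#' * `log2_plus_one` — elementwise `log2(area + 1)` (exactly invertible
#'   via `2^x - 1`).
#' * `total_area` — each file's column divided by its total area, so
#'   non-zero columns sum to 1; all-zero columns stay zero.
#'
#' Below-detection flags are preserved untouched.
#'
#' @param ft a [build_feature_table()] result.
#' @param method one of `"none"`, `"log2_plus_one"`, `"total_area"`.
#' @return A `feature_table` with transformed areas.
#' @export
normalize_table <- function(ft, method = c("none", "log2_plus_one",
                                           "total_area")) {
  stopifnot(inherits(ft, "feature_table"))
  method <- match.arg(method)
  a <- ft$areas
  if (any(a < 0)) stop("normalize_table requires non-negative areas")
  a <- switch(method,
    none = a,
    log2_plus_one = log2(a + 1),
    total_area = {
      tot <- colSums(a)
      sweep(a, 2, ifelse(tot > 0, tot, 1), "/")
    })
  ft$areas <- a
  ft$provenance$normalization <- method
  ft
}

#' Hierarchically cluster a feature table
#'
#' Agglomerative clustering of compounds or files on the feature-table
#' areas, the standard first look at a targeted-metabolomics result.
#' Distances are Euclidean or correlation (`1 - Pearson r`); linkage is
#' average, complete or Ward. Deterministic; for tie-free dissimilarities
#' the result is independent of input row order (up to relabeling).
#'
#' @param ft a [build_feature_table()] result (normalize first if
#'   desired).
#' @param axis cluster `"compounds"` (rows) or `"files"` (columns).
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward on squared
#'   Euclidean distances, `stats::hclust`'s `"ward.D2"`).
#' @param metric `"euclidean"` or `"correlation"`. Constant items have no
#'   defined correlation and are reported by name as an error.
#' @return An [stats::hclust] object (leaf labels are compound or file
#'   ids).
#' @export
cluster_features <- function(ft, axis = c("compounds", "files"),
                             linkage = c("average", "complete", "ward"),
                             metric = c("euclidean", "correlation")) {
  stopifnot(inherits(ft, "feature_table"))
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  m <- if (axis == "compounds") ft$areas else t(ft$areas)
  if (axis == "files") rownames(m) <- as.character(ft$file_ids)
  if (nrow(m) < 2) stop("need at least 2 items on the '", axis, "' axis")
  if (any(!is.finite(m))) stop("non-finite values: normalize or clean first")
  if (metric == "euclidean") {
    d <- stats::dist(m, method = "euclidean")
  } else {
    const <- apply(m, 1, function(r) stats::sd(r) == 0)
    if (any(const))
      stop("constant row(s) under correlation metric: ",
           paste(rownames(m)[const], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(t(m)))
  }
  method <- c(average = "average", complete = "complete",
              ward = "ward.D2")[[linkage]]
  stats::hclust(d, method = method)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc an [stats::hclust] object (e.g. from [cluster_features()]).
#' @param path optional file to write to.
#' @return The Newick string, invisibly if written to `path`.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Per-compound two-group testing with FDR control
#'
#' Welch's two-sample t-test per compound on the (optionally normalized)
#' areas, with Benjamini-Hochberg adjustment across compounds. Exactly two
#' groups with at least two files each are required.
#'
#' Degenerate variance convention: when both groups are constant, `p = 1`
#' if the group means are equal and `p = 0` otherwise (perfect
#' separation); the statistic is `NA` in either case.
#'
#' @param ft a [build_feature_table()] result.
#' @param groups named character vector mapping file id (name) to group
#'   label; every file in the table must be labeled.
#' @return A data.frame with one row per compound: `compound_id`, the two
#'   group means, `statistic`, `p_value`, `q_value` (BH-adjusted), ordered
#'   as in the feature table.
#' @export
group_test <- function(ft, groups) {
  stopifnot(inherits(ft, "feature_table"))
  fids <- as.character(ft$file_ids)
  if (!all(fids %in% names(groups)))
    stop("design error: every file in the feature table needs a group label")
  g <- factor(groups[fids])
  if (nlevels(g) != 2)
    stop("design error: exactly 2 groups required, got ", nlevels(g))
  if (any(table(g) < 2))
    stop("design error: each group needs >= 2 files")
  lv <- levels(g)
  res <- lapply(ft$compound_ids, function(cid) {
    y <- ft$areas[cid, ]
    y1 <- y[g == lv[1]]
    y2 <- y[g == lv[2]]
    if (stats::sd(y1) == 0 && stats::sd(y2) == 0) {
      p <- if (mean(y1) == mean(y2)) 1 else 0
      stat <- NA_real_
    } else {
      tt <- stats::t.test(y1, y2, var.equal = FALSE)
      p <- tt$p.value
      stat <- unname(tt$statistic)
    }
    data.frame(compound_id = cid, mean_1 = mean(y1), mean_2 = mean(y2),
               statistic = stat, p_value = p)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", lv)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
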