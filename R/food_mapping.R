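#' Spearman rank correlation with average-tie ranks
#'
#' Pearson correlation of average-tie ranks. When either vector is constant
#' the coefficient is undefined and `NA` is returned (never coerced to 0):
#' a food with an all-zero content vector, or a category with a flat
#' strength vector, carries no rank information.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation in \[-1, 1\], or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) fa_stop("length mismatch")
  if (length(x) < 3L) fa_stop("need vectors of length >= 3")
  if (is_constant(x) || is_constant(y)) return(NA_real_)
  cor(rank(x), rank(y))
}

#' Score every food against every ATC category
#'
#' Computes the Spearman correlation between each food's flavonoid content
#' vector (mg/100 g over the flavonoid panel) and each category's
#' association-strength vector. One row is emitted per food x category
#' pair. Pairs with an undefined correlation (constant vector) are flagged
#' `defined = FALSE`. Ranks run over the defined correlations, descending,
#' with ties broken by (food_id, atc_code) lexicographic order.
#' `predicted` is `TRUE` where the correlation is positive.
#'
#' @param foods numeric matrix of compositions, foods in rows and
#'   flavonoids in columns (as from [read_food_composition()]).
#' @param strengths numeric matrix of association strengths, flavonoids in
#'   rows and ATC categories in columns (as from
#'   [coef.flav_enrichment()], usually restricted to the significant
#'   categories). Flavonoid sets must match.
#' @return data.frame of class `food_atc_scores` with columns `food_id`,
#'   `atc_code`, `rho`, `defined`, `rank`, `predicted`, `high_confidence`
#'   (all `FALSE` until [call_high_confidence()] is applied).
#' @export
score_all_foods <- function(foods, strengths) {
  if (is.null(colnames(foods)) || is.null(rownames(strengths))) {
    fa_stop("foods columns and strengths rows must be named by flavonoid")
  }
  if (!setequal(colnames(foods), rownames(strengths))) {
    fa_stop("flavonoid universe mismatch between foods and strengths")
  }
  strengths <- strengths[colnames(foods), , drop = FALSE]
  if (ncol(foods) < 3L) fa_stop("need at least 3 flavonoids")

  rank_rows <- t(apply(foods, 1L, rank))
  rank_cols <- apply(strengths, 2L, rank)
  if (!is.matrix(rank_cols)) rank_cols <- matrix(rank_cols, ncol = 1L,
    dimnames = list(NULL, colnames(strengths)))
  rho <- suppressWarnings(cor(t(rank_rows), rank_cols))
  const_food <- apply(foods, 1L, is_constant)
  const_cat <- apply(strengths, 2L, is_constant)
  rho[const_food, ] <- NA_real_
  rho[, const_cat] <- NA_real_

  out <- data.frame(
    food_id = rep(rownames(foods), times = ncol(rho)),
    atc_code = rep(colnames(strengths), each = nrow(rho)),
    rho = as.vector(rho),
    stringsAsFactors = FALSE
  )
  out$defined <- !is.na(out$rho)
  out$rank <- NA_integer_
  idx <- which(out$defined)
  ord <- idx[order(-out$rho[idx], out$food_id[idx], out$atc_code[idx])]
  out$rank[ord] <- seq_along(ord)
  out$predicted <- out$defined & out$rho > 0
  out$high_confidence <- FALSE
  class(out) <- c("food_atc_scores", "data.frame")
  out
}

#' Flag top-quantile food-ATC correlations as high confidence
#'
#' Flags the top `quantile` fraction of all defined correlations: the
#' threshold is the k-th largest defined rho with `k = ceiling(quantile *
#' n_defined)`, all boundary ties are included, and a flagged pair must
#' also have `rho > 0`. Undefined correlations never participate in the
#' quantile computation. The realized threshold is attached as attribute
#' `"threshold"`.
#'
#' @param scores a `food_atc_scores` data.frame.
#' @param quantile tail fraction in (0, 1); 0.05 flags the top 5%.
#' @return `scores` with the `high_confidence` column set and attributes
#'   `threshold` (the rho cutoff) and `quantile`.
#' @export
call_high_confidence <- function(scores, quantile = 0.05) {
  if (!(quantile > 0 && quantile < 1)) fa_stop("quantile must be in (0, 1)")
  r <- scores$rho[scores$defined]
  if (length(r) == 0L) fa_stop("no defined correlations")
  k <- ceiling(quantile * length(r))
  thr <- sort(r, decreasing = TRUE)[k]
  scores$high_confidence <- scores$defined & scores$rho >= thr &
    scores$rho > 0
  attr(scores, "threshold") <- thr
  attr(scores, "quantile") <- quantile
  scores
}

#' Sensitivity sweep over the high-confidence quantile
#'
#' Recomputes the high-confidence set over a ladder of quantiles and
#' reports, for each, the realized rho threshold, the number of flagged
#' pairs, and the Jaccard similarity of the flag set with the set at the
#' reference quantile (default 0.05). Stricter quantiles produce nested
#' subsets of looser ones.
#'
#' @param scores a `food_atc_scores` data.frame.
#' @param quantiles numeric vector of tail fractions (sorted ascending
#'   internally).
#' @param reference the reference quantile for the Jaccard column
#'   (default 0.05).
#' @return data.frame with columns `quantile`, `threshold`, `n_flagged`,
#'   `jaccard_vs_reference`.
#' @export
threshold_sweep <- function(scores, quantiles, reference = 0.05) {
  if (nrow(scores) == 0L) fa_stop("empty score list")
  quantiles <- sort(quantiles)
  key <- function(s) paste(s$food_id, s$atc_code)[s$high_confidence]
  ref_set <- key(call_high_confidence(scores, reference))
  rows <- lapply(quantiles, function(q) {
    s <- call_high_confidence(scores, q)
    set <- key(s)
    data.frame(quantile = q,
               threshold = attr(s, "threshold"),
               n_flagged = length(set),
               jaccard_vs_reference =
                 length(intersect(set, ref_set)) /
                 length(union(set, ref_set)))
  })
  do.call(rbind, rows)
}

#' Hierarchical clustering of food or category correlation profiles
#'
#' Agglomerative clustering (UPGMA / average linkage) of the rows or
#' columns of the food x category correlation matrix under correlation
#' distance `d = 1 - Pearson(profile_i, profile_j)`. Items whose profile
#' contains undefined entries are excluded with a warning; items with a
#' constant profile (undefined correlation distance) are likewise
#' excluded.
#'
#' @param mat numeric matrix of correlations, foods in rows and categories
#'   in columns (see [score_matrix()]).
#' @param axis cluster `"foods"` (rows) or `"categories"` (columns).
#' @return an object of class `hclust` (n - 1 merges with non-decreasing
#'   heights under average linkage on a metric-free dissimilarity).
#' @export
cluster_profiles <- function(mat, axis = c("foods", "categories")) {
  axis <- match.arg(axis)
  m <- if (axis == "foods") mat else t(mat)
  # a feature that is NA for every item (e.g. an all-zero food when
  # clustering categories) carries no profile information: drop it first
  # rather than losing every item that touches it
  all_na_feat <- apply(m, 2L, function(col) all(is.na(col)))
  if (any(all_na_feat)) {
    warning(sum(all_na_feat), " all-undefined profile feature(s) dropped",
            call. = FALSE)
    m <- m[, !all_na_feat, drop = FALSE]
  }
  bad <- apply(m, 1L, function(r) any(is.na(r)) || is_constant(r))
  if (any(bad)) {
    warning(sum(bad), " item(s) with undefined or constant profiles ",
            "excluded from clustering", call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 2L) fa_stop("need at least 2 items with defined profiles")
  d <- 1 - cor(t(m))
  hclust(as.dist(d), method = "average")
}

#' Reshape food-ATC scores to a correlation matrix
#'
#' @param scores a `food_atc_scores` data.frame.
#' @return numeric matrix of rho values, foods in rows, categories in
#'   columns (`NA` where undefined).
#' @export
score_matrix <- function(scores) {
  foods <- sort(unique(scores$food_id))
  cats <- sort(unique(scores$atc_code))
  m <- matrix(NA_real_, length(foods), length(cats),
              dimnames = list(foods, cats))
  m[cbind(match(scores$food_id, foods), match(scores$atc_code, cats))] <-
    scores$rho
  m
}

#' Write a cluster tree in Newick format
#'
#' @param hc an `hclust` object, e.g. from [cluster_profiles()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_cluster_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Predict food-ATC therapeutic associations from a fitted enrichment
#'
#' The prediction step of the model: each food's flavonoid content vector
#' is rank-correlated against the association-strength vector of every
#' selected ATC category (by default, the Level-2 categories with raw
#' p < alpha for at least one flavonoid), positive correlations are
#' predictions, and the top-`quantile` correlations are flagged high
#' confidence.
#'
#' @param object a `flav_enrichment` fit.
#' @param foods composition matrix, foods in rows and flavonoids in columns.
#' @param quantile high-confidence tail fraction (default 0.05).
#' @param level ATC level of the selected categories (default 2).
#' @param categories explicit category codes; overrides the default
#'   selection when non-`NULL`.
#' @param use selection rule for the default categories, `"raw"` or
#'   `"fdr"` (see [significant_categories()]).
#' @param ... unused.
#' @return a `food_atc_scores` data.frame (see [score_all_foods()]) with
#'   `high_confidence` set and the threshold attributes of
#'   [call_high_confidence()].
#' @export
predict.flav_enrichment <- function(object, foods, quantile = 0.05,
                                    level = 2L, categories = NULL,
                                    use = c("raw", "fdr"), ...) {
  use <- match.arg(use)
  if (is.null(categories)) {
    categories <- significant_categories(object, level = level, use = use)
  }
  if (length(categories) == 0L) {
    fa_stop("no significant categories to predict against")
  }
  strengths <- coef(object)[, categories, drop = FALSE]
  scores <- score_all_foods(foods, strengths)
  call_high_confidence(scores, quantile)
}
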