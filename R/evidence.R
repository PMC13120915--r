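#' Epidemiological support rates for predicted food-ATC associations
#'
#' Joins the predicted food-ATC pairs (rows of a `food_atc_scores` table
#' with `predicted = TRUE`) against an evidence table and summarizes, per
#' group and overall: the number of predictions, the number with supporting
#' evidence, the support rate, and the total evidence count. Groups can be
#' the ATC code, the Level-1 ATC domain (letter prefix), or a user-supplied
#' food category mapping. Evidence rows referencing pairs that were not
#' predicted are excluded with a warning.
#'
#' @param predictions a `food_atc_scores` data.frame (or any data.frame
#'   with `food_id`, `atc_code`, `predicted`).
#' @param evidence data.frame as from [read_evidence_table()].
#' @param group_by `"atc_code"`, `"atc_domain"` or `"food_group"`.
#' @param food_groups named character vector mapping `food_id` to a
#'   category (required for `group_by = "food_group"`); unmapped foods form
#'   their own singleton category.
#' @return data.frame with one row per group plus an `"overall"` row:
#'   `group_id`, `n_predictions`, `n_supported`, `support_rate`,
#'   `total_evidence`.
#' @export
support_rates <- function(predictions, evidence,
                          group_by = c("atc_code", "atc_domain",
                                       "food_group"),
                          food_groups = NULL) {
  group_by <- match.arg(group_by)
  pred <- predictions[predictions$predicted, , drop = FALSE]
  pkey <- paste(pred$food_id, pred$atc_code, sep = "\r")
  ekey <- paste(evidence$food_id, evidence$atc_code, sep = "\r")
  orphan <- !(ekey %in% pkey)
  if (any(orphan)) {
    warning(sum(orphan), " evidence row(s) referencing non-predicted ",
            "pairs excluded", call. = FALSE)
    evidence <- evidence[!orphan, , drop = FALSE]
    ekey <- ekey[!orphan]
  }
  grp <- switch(group_by,
    atc_code = pred$atc_code,
    atc_domain = substr(pred$atc_code, 1L, 1L),
    food_group = {
      if (is.null(food_groups)) {
        fa_stop("food_groups mapping required for group_by = 'food_group'")
      }
      g <- unname(food_groups[pred$food_id])
      ifelse(is.na(g), pred$food_id, g)
    }
  )
  supported_keys <- unique(ekey[evidence$supported])
  is_supported <- pkey %in% supported_keys
  ev_by_key <- tapply(evidence$evidence_count, ekey, sum)
  ev_total <- unname(ev_by_key[match(pkey, names(ev_by_key))])
  ev_total[is.na(ev_total)] <- 0

  one <- function(ids, label) {
    np <- length(ids)
    ns <- sum(is_supported[ids])
    data.frame(group_id = label,
               n_predictions = np,
               n_supported = ns,
               support_rate = if (np > 0L) ns / np else 0,
               total_evidence = sum(ev_total[ids]),
               stringsAsFactors = FALSE)
  }
  groups <- sort(unique(grp))
  rows <- lapply(groups, function(g) one(which(grp == g), g))
  rows <- c(rows, list(one(seq_along(pkey), "overall")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative evidence totals by food category
#'
#' Sums evidence counts within food categories (e.g. all tomato product
#' forms) and ranks categories by total, descending, ties broken
#' lexicographically. Foods absent from the mapping form their own
#' singleton category.
#'
#' @param evidence data.frame as from [read_evidence_table()].
#' @param food_groups named character vector mapping `food_id` to category.
#' @return data.frame `category`, `total_evidence`, sorted descending.
#' @export
food_category_totals <- function(evidence, food_groups) {
  g <- unname(food_groups[evidence$food_id])
  g <- ifelse(is.na(g), evidence$food_id, g)
  tot <- tapply(evidence$evidence_count, g, sum)
  out <- data.frame(category = names(tot),
                    total_evidence = as.numeric(tot),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_evidence, out$category), ]
  rownames(out) <- NULL
  out
}

#' Average evidence pieces per supported prediction
#'
#' @param total_evidence total evidence count.
#' @param n_supported number of supported predictions (> 0).
#' @return `total_evidence / n_supported`.
#' @export
evidence_per_supported <- function(total_evidence, n_supported) {
  if (n_supported <= 0) fa_stop("n_supported must be positive")
  total_evidence / n_supported
}

#' Concordance of association strength with bioassay potency
#'
#' Pearson correlation between per-flavonoid network association strengths
#' (for one ATC category) and experimental potency derived from LC50
#' values, with the two-sided p-value from the t distribution on
#' `n - 2` degrees of freedom. Potency is `-log10(LC50)` by default (so
#' more potent compounds score higher) or `1/LC50` as the alternate
#' transform. Right-censored LC50 records ("> bound") enter at their bound
#' value and are counted; set `include_censored = FALSE` to drop them.
#'
#' @param strengths named numeric vector, flavonoid id -> association
#'   strength (-log10 p) for the category of interest.
#' @param assays data.frame as from [read_bioassay_table()].
#' @param transform `"neg_log10_lc50"` (default) or `"reciprocal_lc50"`.
#' @param include_censored include censored records at their bound
#'   (default `TRUE`).
#' @return object of class `concordance_result`: list with `pairs`
#'   (data.frame `flavonoid_id`, `strength`, `potency`, `censored`),
#'   `pearson_r`, `r_squared` (= r^2), `p_value`, `transform`,
#'   `n_censored`.
#' @export
prediction_potency_concordance <- function(strengths, assays,
                                           transform = c("neg_log10_lc50",
                                                         "reciprocal_lc50"),
                                           include_censored = TRUE) {
  transform <- match.arg(transform)
  if (!include_censored) {
    assays <- assays[!assays$censored, , drop = FALSE]
  }
  common <- intersect(names(strengths), assays$flavonoid_id)
  if (length(common) < 3L) {
    fa_stop("need at least 3 flavonoids with both a strength and an assay")
  }
  a <- assays[match(common, assays$flavonoid_id), , drop = FALSE]
  potency <- switch(transform,
                    neg_log10_lc50 = -log10(a$lc50),
                    reciprocal_lc50 = 1 / a$lc50)
  s <- unname(strengths[common])
  if (is_constant(potency)) fa_stop("all potencies are equal")
  if (is_constant(s)) fa_stop("all strengths are equal")
  ct <- cor.test(s, potency, method = "pearson")
  out <- list(
    pairs = data.frame(flavonoid_id = common, strength = s,
                       potency = potency, censored = a$censored,
                       stringsAsFactors = FALSE),
    pearson_r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    transform = transform,
    n_censored = sum(a$censored)
  )
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance over %d flavonoids (%d censored, transform %s):\n",
    nrow(x$pairs), x$n_censored, x$transform))
  cat(sprintf("  Pearson r = %.3f, R^2 = %.3f, p = %.4g\n",
              x$pearson_r, x$r_squared, x$p_value))
  invisible(x)
}
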