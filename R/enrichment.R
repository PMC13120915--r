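#' Upper-tail hypergeometric probability
#'
#' The probability of observing at least `x` category drugs when `n` drugs
#' are drawn without replacement from a universe of `N` drugs of which `M`
#' belong to the category:
#' \deqn{P = \sum_{i=x}^{\min(n, M)} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}}
#' This is the one-sided Fisher's exact enrichment p-value. The sum is
#' computed stably in log space. The upper limit is `min(n, M)` (terms with
#' `i > M` vanish since `choose(M, i) = 0`).
#'
#' @param N universe size (total drugs).
#' @param M category size (drugs in the category), `0 <= M <= N`.
#' @param n draw size (drugs sharing targets with the flavonoid),
#'   `0 <= n <= N`.
#' @param x observed overlap, `0 <= x <= min(n, M)`.
#' @return the tail probability in (0, 1\]; exactly 1 when `x = 0`.
#' @export
hypergeom_tail <- function(N, M, n, x) {
  if (any(c(N, M, n, x) < 0) || M > N || n > N) {
    fa_stop("require 0 <= M <= N and 0 <= n <= N")
  }
  if (x > min(n, M)) {
    fa_stop("x = ", x, " exceeds min(n, M) = ", min(n, M))
  }
  if (x == 0) return(1)
  i <- x:min(n, M)
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

# internal vectorized form (inputs recycled to common length)
fa_hyper_tail <- function(N, M, n, x) {
  len <- max(length(N), length(M), length(n), length(x))
  N <- rep_len(N, len); M <- rep_len(M, len)
  n <- rep_len(n, len); x <- rep_len(x, len)
  vapply(seq_len(len),
         function(j) hypergeom_tail(N[j], M[j], n[j], x[j]), 0)
}

#' Association strength from a p-value
#'
#' \eqn{-\log_{10}(p)}, the linear-scale association strength. p is floored
#' at 1e-300 before the logarithm so strengths stay finite.
#'
#' @param p p-value(s) in (0, 1\].
#' @return numeric vector of strengths (>= 0).
#' @export
association_strength <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    fa_stop("p must lie in (0, 1]")
  }
  -log10(pmax(p, 1e-300))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted q-values \eqn{q_{(i)} = \min_{j \ge i} (m p_{(j)} / j)},
#' clipped at 1 and returned in input order (a thin validated wrapper
#' around `stats::p.adjust(method = "BH")`).
#'
#' @param p_values non-empty vector of p-values in (0, 1\].
#' @return q-values, same length and order as the input; never below the
#'   input, never above 1.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) fa_stop("empty p-value list")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    fa_stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Drugs sharing at least one protein target with a flavonoid
#'
#' @param net a `master_network`.
#' @param flavonoid a flavonoid identifier present in the network.
#' @return sorted character vector of drug identifiers whose target set
#'   intersects the flavonoid's target set. Never contains compounds other
#'   than drugs.
#' @export
shared_target_drugs <- function(net, flavonoid) {
  i <- match(flavonoid, net$nodes$node)
  if (is.na(i) || net$nodes$kind[i] != "flavonoid") {
    fa_stop("unknown flavonoid: ", flavonoid)
  }
  ft <- target_set(net, flavonoid)
  dsets <- fa_target_sets(net, "drug")
  sort(names(dsets)[vapply(dsets, function(t) any(t %in% ft), TRUE)])
}

# internal: expand a level-2-only ATC table to both levels
fa_expand_atc <- function(atc) {
  if (!"atc_level" %in% names(atc)) {
    atc <- rbind(
      data.frame(drug_id = atc$drug_id, atc_code = atc$atc_code,
                 atc_level = 2L, stringsAsFactors = FALSE),
      data.frame(drug_id = atc$drug_id,
                 atc_code = substr(atc$atc_code, 1L, 1L),
                 atc_level = 1L, stringsAsFactors = FALSE)
    )
  }
  unique(atc[, c("drug_id", "atc_code", "atc_level")])
}

#' Flavonoid-ATC enrichment analysis
#'
#' Fits the flavonoid-to-drug-category association model: for every
#' flavonoid in the network and every ATC category at Levels 1 and 2, the
#' drugs sharing at least one protein target with the flavonoid are tested
#' for over-representation in the category with the exact hypergeometric
#' tail test. The universe `N` for each level is the set of network drugs
#' carrying at least one ATC code at that level; `M` is the category size,
#' `n` the flavonoid's shared-target drug count within the universe and `x`
#' the overlap. Association strength is `-log10(p)`. One joint
#' Benjamini-Hochberg FDR correction is applied across all tests at both
#' levels (the tests form a single inferential family). Drugs with several
#' Level-2 codes count in each of their categories.
#'
#' @param net a `master_network`.
#' @param atc ATC annotation data.frame (`drug_id`, `atc_code`, and
#'   optionally `atc_level`; a two-level expansion is derived when absent).
#'   Annotated drugs not present in the network are ignored with a warning.
#' @param alpha significance level for both the raw-p and FDR flags
#'   (default 0.05).
#' @return an object of class `flav_enrichment` with components
#'   \describe{
#'     \item{tests}{data.frame, one row per (flavonoid, category):
#'       `flavonoid`, `atc_code`, `level`, `N`, `M`, `n`, `x`, `p`, `q`,
#'       `strength`, `sig_raw` (p < alpha), `sig_fdr` (q < alpha).}
#'     \item{strength, p, q}{flavonoid x category matrices (Level-1
#'       categories first).}
#'     \item{alpha}{the significance level used.}
#'     \item{category_level}{named integer vector, category -> ATC level.}
#'   }
#' @seealso [predict.flav_enrichment()] for food-level prediction,
#'   [coef.flav_enrichment()] for the strength matrix.
#' @export
enrich_all <- function(net, atc, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) fa_stop("alpha must be in (0, 1)")
  atc <- fa_expand_atc(atc)
  drug_ids <- net$nodes$node[net$nodes$kind == "drug"]
  missing_drugs <- setdiff(unique(atc$drug_id), drug_ids)
  if (length(missing_drugs) > 0L) {
    warning(length(missing_drugs),
            " annotated drug(s) absent from the network were ignored",
            call. = FALSE)
    atc <- atc[atc$drug_id %in% drug_ids, , drop = FALSE]
  }
  if (nrow(atc) == 0L) fa_stop("no annotated drugs present in the network")

  flavs <- sort(net$nodes$node[net$nodes$kind == "flavonoid"])
  if (length(flavs) == 0L) fa_stop("no flavonoids in the network")

  fsets <- fa_target_sets(net, "flavonoid")
  dsets <- fa_target_sets(net, "drug")
  dp_drug <- rep(names(dsets), lengths(dsets))
  dp_prot <- unlist(dsets, use.names = FALSE)
  shared <- lapply(fsets[flavs], function(ft) {
    unique(dp_drug[dp_prot %in% ft])
  })

  rows <- vector("list", 2L)
  for (lev in 1:2) {
    al <- atc[atc$atc_level == lev, , drop = FALSE]
    if (nrow(al) == 0L) next
    universe <- unique(al$drug_id)
    N <- length(universe)
    cats <- sort(unique(al$atc_code))
    members <- split(al$drug_id, al$atc_code)
    M <- vapply(members[cats], function(d) length(unique(d)), 0L)
    lev_rows <- lapply(flavs, function(f) {
      sh <- intersect(shared[[f]], universe)
      n <- length(sh)
      x <- vapply(members[cats],
                  function(d) length(intersect(d, sh)), 0L)
      data.frame(flavonoid = f, atc_code = cats, level = lev,
                 N = N, M = as.integer(M), n = n, x = as.integer(x),
                 stringsAsFactors = FALSE)
    })
    rows[[lev]] <- do.call(rbind, lev_rows)
  }
  tests <- do.call(rbind, rows)
  if (is.null(tests) || nrow(tests) == 0L) {
    fa_stop("no testable (flavonoid, category) pairs")
  }
  tests$p <- fa_hyper_tail(tests$N, tests$M, tests$n, tests$x)
  tests$q <- bh_fdr(tests$p)
  tests$strength <- association_strength(tests$p)
  tests$sig_raw <- tests$p < alpha
  tests$sig_fdr <- tests$q < alpha
  tests <- tests[order(tests$level, tests$atc_code, tests$flavonoid), ]
  rownames(tests) <- NULL

  cats_all <- unique(tests[, c("atc_code", "level")])
  cats_all <- cats_all[order(cats_all$level, cats_all$atc_code), ]
  to_matrix <- function(col) {
    m <- matrix(NA_real_, nrow = length(flavs), ncol = nrow(cats_all),
                dimnames = list(flavs, cats_all$atc_code))
    m[cbind(match(tests$flavonoid, flavs),
            match(tests$atc_code, cats_all$atc_code))] <- tests[[col]]
    m
  }
  out <- list(tests = tests,
              strength = to_matrix("strength"),
              p = to_matrix("p"),
              q = to_matrix("q"),
              alpha = alpha,
              category_level = setNames(cats_all$level, cats_all$atc_code))
  class(out) <- "flav_enrichment"
  out
}

#' @export
print.flav_enrichment <- function(x, ...) {
  cat("flav_enrichment:", nrow(x$strength), "flavonoids x",
      ncol(x$strength), "ATC categories (",
      sum(x$category_level == 1L), "Level-1,",
      sum(x$category_level == 2L), "Level-2 ) =",
      nrow(x$tests), "tests\n")
  cat("  significant at raw p <", x$alpha, ":", sum(x$tests$sig_raw),
      "; at FDR q <", x$alpha, ":", sum(x$tests$sig_fdr), "\n")
  invisible(x)
}

#' @export
summary.flav_enrichment <- function(object, ...) {
  t <- object$tests
  top <- t[order(t$p), c("flavonoid", "atc_code", "level", "N", "M",
                         "n", "x", "p", "q", "strength")]
  cat("Top associations by p-value:\n")
  print(utils::head(top, 10L), row.names = FALSE, digits = 4)
  cat("\nSignificant categories (raw p) by level:\n")
  for (lev in 1:2) {
    sig <- unique(t$atc_code[t$level == lev & t$sig_raw])
    cat("  Level", lev, ":", length(sig), "of",
        sum(object$category_level == lev), "\n")
  }
  invisible(top)
}

#' Association-strength matrix of a fitted enrichment object
#'
#' @param object a `flav_enrichment`.
#' @param ... unused.
#' @return the flavonoid x category matrix of `-log10(p)` strengths.
#' @export
coef.flav_enrichment <- function(object, ...) {
  object$strength
}

#' Heatmap of association strengths
#'
#' @param x a `flav_enrichment`.
#' @param level restrict to one ATC level (1, 2, or `NULL` for both).
#' @param ... passed to [graphics::image()].
#' @export
plot.flav_enrichment <- function(x, level = NULL, ...) {
  m <- x$strength
  if (!is.null(level)) {
    m <- m[, x$category_level == level, drop = FALSE]
  }
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  xlab = "ATC category", ylab = "flavonoid", axes = FALSE,
                  main = "association strength (-log10 p)", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 1, cex.axis = 0.7)
  invisible(m)
}

#' Categories significantly associated with at least one flavonoid
#'
#' Selects the ATC categories carried forward to food-level prediction:
#' by default the Level-2 categories with raw `p < alpha` for at least one
#' flavonoid.
#'
#' @param fit a `flav_enrichment`.
#' @param level ATC level (default 2).
#' @param use `"raw"` (p < alpha, the selection rule for downstream food
#'   mapping) or `"fdr"` (q < alpha).
#' @return character vector of category codes.
#' @export
significant_categories <- function(fit, level = 2L, use = c("raw", "fdr")) {
  use <- match.arg(use)
  t <- fit$tests
  flag <- if (use == "raw") t$sig_raw else t$sig_fdr
  sort(unique(t$atc_code[t$level == level & flag]))
}
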