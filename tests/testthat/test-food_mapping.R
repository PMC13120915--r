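test_that("spearman_rho handles ties, monotone maps and degenerate input", {
  expect_equal(spearman_rho(1:5, c(2, 4, 8, 16, 32)), 1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_true(is.na(spearman_rho(c(2, 2, 2), 1:3)))
  expect_error(spearman_rho(1:3, 1:4), "length mismatch")
  expect_error(spearman_rho(1:2, 1:2), "length >= 3")
  # agrees with stats::cor(method = "spearman") including average-tie ranks
  set.seed(2)
  for (i in 1:10) {
    x <- sample(0:5, 12, replace = TRUE)
    y <- rnorm(12)
    expect_equal(spearman_rho(x, y),
                 suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("score_all_foods emits one row per pair with consistent ranks", {
  set.seed(9)
  foods <- matrix(rexp(20 * 6), nrow = 20,
                  dimnames = list(sprintf("food%02d", 1:20),
                                  sprintf("fl%d", 1:6)))
  foods[3, ] <- 0  # an all-zero content vector
  strengths <- matrix(rexp(6 * 4), nrow = 6,
                      dimnames = list(sprintf("fl%d", 1:6),
                                      c("C01", "C02", "L01", "L02")))
  sc <- score_all_foods(foods, strengths)
  expect_equal(nrow(sc), 20 * 4)
  expect_true(all(is.na(sc$rho[sc$food_id == "food03"])))
  expect_false(any(sc$predicted[sc$food_id == "food03"]))
  # ranks: descending rho over defined pairs, lexicographic tie-break
  def <- sc[sc$defined, ]
  def <- def[order(def$rank), ]
  expect_true(all(diff(def$rho) <= 1e-15))
  # each defined rho equals the direct pairwise computation
  for (k in sample(which(sc$defined), 10)) {
    expect_equal(sc$rho[k],
                 spearman_rho(foods[sc$food_id[k], ],
                              strengths[, sc$atc_code[k]]),
                 tolerance = 1e-12)
  }
  expect_error(score_all_foods(foods[, 1:5, drop = FALSE], strengths),
               "universe mismatch")
})

test_that("food order and positive content scaling do not change scores", {
  set.seed(10)
  foods <- matrix(rexp(12 * 5), nrow = 12,
                  dimnames = list(sprintf("f%02d", 1:12),
                                  sprintf("fl%d", 1:5)))
  strengths <- matrix(rexp(5 * 3), nrow = 5,
                      dimnames = list(sprintf("fl%d", 1:5),
                                      c("A01", "B01", "C01")))
  sc1 <- score_all_foods(foods, strengths)
  sc2 <- score_all_foods(foods[sample(12), ], strengths)
  key <- function(s) s[order(s$food_id, s$atc_code),
                       c("food_id", "atc_code", "rho", "rank")]
  expect_equal(key(sc1), key(sc2), ignore_attr = TRUE)
  # scaling one food's contents by a positive constant is rank-invariant
  foods3 <- foods; foods3[4, ] <- foods3[4, ] * 17.3
  sc3 <- score_all_foods(foods3, strengths)
  expect_equal(sc3$rho, sc1$rho, tolerance = 1e-12)
})

test_that("high-confidence calls flag the top quantile with ties included", {
  mk_scores <- function(rho) {
    s <- data.frame(food_id = sprintf("f%04d", seq_along(rho)),
                    atc_code = "C01", rho = rho,
                    defined = !is.na(rho), rank = NA_integer_,
                    predicted = !is.na(rho) & rho > 0,
                    high_confidence = FALSE)
    class(s) <- c("food_atc_scores", "data.frame")
    s
  }
  # 100 distinct values at quantile 0.05: exactly the 5 largest
  set.seed(12)
  rho <- sample(seq(-0.9, 0.9, length.out = 100))
  sc <- call_high_confidence(mk_scores(rho), 0.05)
  expect_equal(sum(sc$high_confidence), 5L)
  expect_equal(sort(sc$rho[sc$high_confidence]),
               sort(rho, decreasing = TRUE)[5:1])

  # boundary ties are all included
  sc2 <- call_high_confidence(mk_scores(c(rep(0.8, 3), 0.9, 0.7,
                                          seq(0.1, 0.6, length.out = 95))),
                              0.02)
  expect_equal(sum(sc2$high_confidence), 4L)  # 0.9 plus all three 0.8 ties

  # vanishing quantile flags only the maximum
  sc3 <- call_high_confidence(mk_scores(rho), 1e-9)
  expect_equal(sum(sc3$high_confidence), 1L)
  expect_equal(sc3$rho[sc3$high_confidence], max(rho))

  # undefined rho never flagged, and a flagged pair must be positive
  sc4 <- call_high_confidence(mk_scores(c(NA, -0.5, -0.2, -0.9, 0.4)), 0.5)
  expect_equal(sum(sc4$high_confidence), 1L)

  # flagged fraction calibrated on uniform scores (order-statistics check)
  set.seed(13)
  u <- runif(2000, -1, 1)
  sc5 <- call_high_confidence(mk_scores(u), 0.05)
  frac <- mean(sc5$high_confidence)
  half <- 2.576 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)

  expect_error(call_high_confidence(mk_scores(NA_real_), 0.05),
               "no defined")
  expect_error(call_high_confidence(mk_scores(0.5), 0), "quantile")
})

test_that("threshold sweep produces nested sets matching a full sort", {
  set.seed(14)
  rho <- runif(400, -1, 1)
  s <- data.frame(food_id = sprintf("f%04d", 1:400), atc_code = "C01",
                  rho = rho, defined = TRUE, rank = NA_integer_,
                  predicted = rho > 0, high_confidence = FALSE)
  class(s) <- c("food_atc_scores", "data.frame")
  sw <- threshold_sweep(s, c(0.10, 0.01, 0.05))
  expect_equal(sw$quantile, c(0.01, 0.05, 0.10))
  expect_true(all(diff(sw$n_flagged) >= 0))
  expect_equal(sw$jaccard_vs_reference[sw$quantile == 0.05], 1.0)
  # flag sets equal brute-force sort-and-slice
  for (q in c(0.01, 0.05, 0.10)) {
    k <- ceiling(q * 400)
    brute <- sort(rho, decreasing = TRUE)[k]
    sc <- call_high_confidence(s, q)
    expect_equal(sum(sc$high_confidence), sum(rho >= brute & rho > 0))
  }
  # nesting: stricter sets are subsets of looser ones
  f01 <- call_high_confidence(s, 0.01)$high_confidence
  f10 <- call_high_confidence(s, 0.10)$high_confidence
  expect_true(all(!f01 | f10))
  expect_error(threshold_sweep(s[0, ], 0.05), "empty")
})

test_that("profile clustering reproduces naive UPGMA agglomeration", {
  # two identical profiles merge at height zero, before an anticorrelated one
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  m[2, ] <- m[1, ]  # identical profiles
  hc <- cluster_profiles(m, "foods")
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(hclust_merge_sets(hc)[[1]]), c(1, 2))

  # 6-item random matrix against the O(n^3) oracle
  set.seed(15)
  m6 <- matrix(rnorm(6 * 8), nrow = 6,
               dimnames = list(letters[1:6], NULL))
  hc6 <- cluster_profiles(m6, "foods")
  d <- 1 - cor(t(m6))
  or <- oracle_upgma(d)
  expect_equal(hc6$height, or$heights, tolerance = 1e-10)
  expect_equal(hclust_merge_sets(hc6), or$merges)
  expect_true(all(diff(hc6$height) >= -1e-12))

  # rows with undefined profiles are excluded with a warning
  m_na <- rbind(m6, bad = NA_real_)
  expect_warning(cluster_profiles(m_na, "foods"), "excluded")
  expect_error(cluster_profiles(m6[1, , drop = FALSE], "foods"),
               "at least 2")
})

test_that("predict() scores foods against the significant categories", {
  cfg <- synthetic_config(seed = 31L)
  gen <- generate_interactome(cfg)
  net <- build_master_network(filter_by_score(gen$pp, 700),
                              filter_by_score(gen$cp, 700),
                              gen$truth$flavonoids, gen$truth$drugs)
  fit <- enrich_all(net, gen$atc)
  foods <- generate_foods(cfg, gen$truth)
  sc <- predict(fit, foods, quantile = 0.05)
  cats <- significant_categories(fit)
  expect_equal(nrow(sc), nrow(foods) * length(cats))
  expect_setequal(unique(sc$atc_code), cats)
  expect_true(all(sc$rho[sc$high_confidence] >= attr(sc, "threshold")))
  # a planted food-category pair scores in the top decile of defined rho
  pf <- gen$truth$planted_food_links[1, ]
  rho_planted <- sc$rho[sc$food_id == pf$food & sc$atc_code == pf$category]
  expect_gte(rho_planted, quantile(sc$rho[sc$defined], 0.9))
})
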