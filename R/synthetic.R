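#' Configuration for the synthetic study generator
#'
#' Defines the sizes, noise levels and planted ground truth of a synthetic
#' network-pharmacology study. The defaults describe a small but complete
#' study: 500 proteins, 120 drugs, 10 flavonoids, 8 ATC Level-2 categories
#' in 3 Level-1 domains, and 60 foods, with a set of planted
#' flavonoid-category links of graded intensity (the fraction of a
#' flavonoid's targets drawn from the category's protein pool) and planted
#' food-category links (foods whose content loads on the flavonoids
#' carrying a category's signal). Anti-planted foods load exclusively on
#' flavonoids without the category's signal and serve as negative controls.
#'
#' @param n_proteins,n_drugs,n_flavonoids,n_foods entity counts.
#' @param n_categories_l2 number of ATC Level-2 categories.
#' @param n_domains number of Level-1 domains the Level-2 categories are
#'   spread over (round-robin).
#' @param pool_size proteins per category-specific target pool; pools are
#'   disjoint, remaining proteins form the background pool.
#' @param drug_targets_mean,flavonoid_targets_mean mean per-compound target
#'   counts (Poisson + 1).
#' @param category_fidelity fraction of a drug's targets drawn from its
#'   primary category pool (0 makes category labels independent of targets,
#'   the null model).
#' @param multi_code_prob probability a drug carries a second Level-2 code.
#' @param subthreshold_ratio decoy (sub-threshold score) edges generated
#'   per true edge; 19 puts ~5% of scores at or above 700.
#' @param pp_edges number of true protein-protein edges.
#' @param planted_links data.frame `flavonoid`, `category`, `intensity`
#'   (in \[0,1\]; per-flavonoid intensities must sum to <= 1).
#' @param planted_food_links data.frame `food`, `category`, `intensity`.
#' @param anti_planted_food_links data.frame `food`, `category`.
#' @param content_scale mg/100 g scale of planted signal content.
#' @param content_noise_sigma log-normal sigma of content noise.
#' @param background_sparsity probability a background food-flavonoid entry
#'   is exactly zero (USDA-style sparsity).
#' @param planted_food_sparsity zero-probability for the non-signal entries
#'   of planted and anti-planted foods (sparser than background).
#' @param support_base_rate,support_logit_slope parameters of the logistic
#'   evidence model: support probability
#'   `plogis(qlogis(base_rate) + slope * rho)`.
#' @param seed default random seed used by the generators.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 500L,
                             n_drugs = 120L,
                             n_flavonoids = 10L,
                             n_categories_l2 = 8L,
                             n_domains = 3L,
                             n_foods = 60L,
                             pool_size = 40L,
                             drug_targets_mean = 17,
                             flavonoid_targets_mean = 45,
                             category_fidelity = 0.8,
                             multi_code_prob = 0.15,
                             subthreshold_ratio = 19,
                             pp_edges = 2000L,
                             planted_links = default_planted_links(),
                             planted_food_links = default_planted_food_links(),
                             anti_planted_food_links =
                               default_anti_planted_food_links(),
                             content_scale = 50,
                             content_noise_sigma = 0.3,
                             background_sparsity = 0.6,
                             planted_food_sparsity = 0.9,
                             support_base_rate = 0.14,
                             support_logit_slope = 3,
                             seed = 1L) {
  cfg <- list(n_proteins = n_proteins, n_drugs = n_drugs,
              n_flavonoids = n_flavonoids,
              n_categories_l2 = n_categories_l2, n_domains = n_domains,
              n_foods = n_foods, pool_size = pool_size,
              drug_targets_mean = drug_targets_mean,
              flavonoid_targets_mean = flavonoid_targets_mean,
              category_fidelity = category_fidelity,
              multi_code_prob = multi_code_prob,
              subthreshold_ratio = subthreshold_ratio,
              pp_edges = pp_edges,
              planted_links = planted_links,
              planted_food_links = planted_food_links,
              anti_planted_food_links = anti_planted_food_links,
              content_scale = content_scale,
              content_noise_sigma = content_noise_sigma,
              background_sparsity = background_sparsity,
              planted_food_sparsity = planted_food_sparsity,
              support_base_rate = support_base_rate,
              support_logit_slope = support_logit_slope,
              seed = as.integer(seed))
  if (n_categories_l2 < 2L) fa_stop("need >= 2 categories")
  if (n_flavonoids < 3L) fa_stop("need >= 3 flavonoids")
  if (n_foods < 5L) fa_stop("need >= 5 foods")
  if (pool_size * n_categories_l2 > n_proteins) {
    fa_stop("category pools exceed the protein universe")
  }
  if (nrow(planted_links) > 0L) {
    tot <- tapply(planted_links$intensity, planted_links$flavonoid, sum)
    if (any(tot > 1)) {
      fa_stop("per-flavonoid planted intensities must sum to <= 1")
    }
    if (any(planted_links$intensity < 0 | planted_links$intensity > 1)) {
      fa_stop("intensities must lie in [0, 1]")
    }
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Default planted flavonoid -> category links. Each planted category
# carries a graded 4-flavonoid signature (intensities 0.5/0.35/0.25/0.2)
# so its strength vector is informative for rank correlation (with 10
# flavonoids, a 4-rank aligned signature supports Spearman rho near 0.9,
# well separated from the null). The assignment keeps each planted
# flavonoid's intensity total between 0.5 and 0.95: targets not claimed by
# a planted pool are drawn from the background, and a flavonoid with many
# background targets shares drugs indiscriminately, inflating its
# shared-drug count n and diluting every one of its enrichment signals.
# F10 is an unplanted null flavonoid.
default_planted_links <- function() {
  data.frame(
    flavonoid = c("F01", "F02", "F03", "F04",
                  "F05", "F06", "F01", "F02",
                  "F07", "F08", "F04", "F03",
                  "F09", "F03", "F06", "F05",
                  "F04", "F09", "F08", "F06"),
    category = c("C01", "C01", "C01", "C01",
                 "C02", "C02", "C02", "C02",
                 "L01", "L01", "L01", "L01",
                 "L02", "L02", "L02", "L02",
                 "N01", "N01", "N01", "N01"),
    intensity = c(0.5, 0.35, 0.25, 0.2,
                  0.5, 0.35, 0.25, 0.2,
                  0.5, 0.35, 0.25, 0.2,
                  0.5, 0.35, 0.25, 0.2,
                  0.5, 0.35, 0.25, 0.2),
    stringsAsFactors = FALSE
  )
}

default_planted_food_links <- function() {
  data.frame(
    food = c("FOOD01", "FOOD02", "FOOD03", "FOOD04", "FOOD05"),
    category = c("C01", "C02", "L01", "L02", "N01"),
    intensity = c(0.9, 0.9, 0.9, 0.9, 0.9),
    stringsAsFactors = FALSE
  )
}

default_anti_planted_food_links <- function() {
  data.frame(
    food = c("FOOD06", "FOOD07"),
    category = c("C01", "L01"),
    stringsAsFactors = FALSE
  )
}

#' Null-model configuration for type-I error calibration
#'
#' A configuration with no planted links and `category_fidelity = 0`, so
#' ATC categories are assigned to drugs uniformly at random and
#' independently of target sets. The universe is deliberately large
#' (9,600 drugs, 4 Level-2 categories in 2 domains) so that the null
#' hypergeometric overlap distribution has a large standard deviation and
#' the exact test's achievable significance levels are dense near 0.05;
#' with small category sizes the discrete test is visibly conservative and
#' a calibration experiment would measure the discreteness of the support,
#' not the error rate. Few flavonoids are generated per dataset because
#' tests sharing one dataset are correlated through its drug-category
#' randomness; a calibration experiment should average over many
#' replicate datasets instead.
#'
#' @param seed random seed.
#' @return a `synthetic_config`.
#' @export
null_calibration_config <- function(seed = 1L) {
  empty_links <- data.frame(flavonoid = character(), category = character(),
                            intensity = numeric(), stringsAsFactors = FALSE)
  synthetic_config(
    n_proteins = 1100L, n_drugs = 9600L, n_flavonoids = 4L,
    n_categories_l2 = 4L, n_domains = 2L, n_foods = 20L,
    pool_size = 50L, drug_targets_mean = 17, flavonoid_targets_mean = 45,
    category_fidelity = 0, multi_code_prob = 0, subthreshold_ratio = 0.2,
    pp_edges = 500L,
    planted_links = empty_links,
    planted_food_links = empty_links[, c("flavonoid", "category",
                                         "intensity")] |>
      setNames(c("food", "category", "intensity")),
    anti_planted_food_links = data.frame(food = character(),
                                         category = character(),
                                         stringsAsFactors = FALSE),
    seed = seed
  )
}

# internal: category codes and domain letters
fa_make_categories <- function(cfg) {
  letters14 <- c("C", "L", "N", "A", "B", "D", "G", "H", "J", "M",
                 "P", "R", "S", "V")
  if (cfg$n_domains > length(letters14)) fa_stop("at most 14 domains")
  dom <- letters14[seq_len(cfg$n_domains)]
  dom_of <- dom[((seq_len(cfg$n_categories_l2) - 1L) %% cfg$n_domains) + 1L]
  idx <- stats::ave(seq_along(dom_of), dom_of, FUN = seq_along)
  data.frame(code = paste0(dom_of, sprintf("%02d", idx)),
             domain = dom_of, stringsAsFactors = FALSE)
}

#' Generate a synthetic interactome with planted category structure
#'
#' Produces STRING/STITCH-dialect record tables and the planted truth:
#' proteins are partitioned into per-category pools plus a background pool;
#' each drug draws a `category_fidelity` fraction of its targets from its
#' primary category's pool; each planted flavonoid draws its stated
#' intensity fraction of targets from the linked category's pool. True
#' edges carry scores in \[700, 999\]; `subthreshold_ratio` decoy edges per
#' true edge carry scores in \[150, 699\] to exercise score filtering.
#' Output is a pure function of `(config, seed)`.
#'
#' @param config a `synthetic_config`.
#' @param seed random seed (defaults to `config$seed`).
#' @return list with `pp` and `cp` interaction record data.frames (columns
#'   `node_a`, `node_b`, `combined_score`), `atc` (drug_id, atc_code Level-2
#'   rows), and `truth` (planted links, entity ids, category pools).
#' @export
generate_interactome <- function(config, seed = config$seed) {
  cfg <- config
  set.seed(seed)
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  drugs <- sprintf("D%04d", seq_len(cfg$n_drugs))
  flavs <- sprintf("F%02d", seq_len(cfg$n_flavonoids))
  cats <- fa_make_categories(cfg)

  pools <- split(
    seq_len(cfg$pool_size * cfg$n_categories_l2),
    rep(cats$code, each = cfg$pool_size)
  )
  background <- setdiff(seq_len(cfg$n_proteins),
                        unlist(pools, use.names = FALSE))

  # drug ATC assignment: balanced allocation (shuffled round-robin) keeps
  # category sizes near n_drugs / n_categories rather than multinomially
  # uneven; secondary codes are uniform over the other categories
  primary <- sample(rep_len(cats$code, cfg$n_drugs))
  extra <- runif(cfg$n_drugs) < cfg$multi_code_prob
  second <- vapply(primary, function(p) sample(setdiff(cats$code, p), 1L),
                   "")
  atc <- rbind(
    data.frame(drug_id = drugs, atc_code = primary,
               stringsAsFactors = FALSE),
    data.frame(drug_id = drugs[extra], atc_code = second[extra],
               stringsAsFactors = FALSE)
  )
  atc <- unique(atc[order(atc$drug_id, atc$atc_code), ])
  rownames(atc) <- NULL

  # drug targets
  sample_targets <- function(size, from_pool, pool_idx) {
    size <- max(1L, size)
    k <- min(round(from_pool * size), length(pool_idx))
    rest <- size - k
    pool_part <- if (k > 0L) sample(pool_idx, k) else integer()
    univ <- if (cfg$category_fidelity > 0 || k > 0L) background
            else seq_len(cfg$n_proteins)
    bg_part <- if (rest > 0L) sample(univ, min(rest, length(univ)))
               else integer()
    unique(c(pool_part, bg_part))
  }
  drug_targets <- lapply(seq_len(cfg$n_drugs), function(i) {
    size <- rpois(1L, cfg$drug_targets_mean - 1) + 1L
    if (cfg$category_fidelity > 0) {
      sample_targets(size, cfg$category_fidelity, pools[[primary[i]]])
    } else {
      sample(seq_len(cfg$n_proteins), min(size, cfg$n_proteins))
    }
  })
  names(drug_targets) <- drugs

  # flavonoid targets
  pl <- cfg$planted_links
  flav_targets <- lapply(flavs, function(f) {
    size <- max(1L, rpois(1L, cfg$flavonoid_targets_mean - 1) + 1L)
    links <- pl[pl$flavonoid == f, , drop = FALSE]
    picked <- integer()
    for (j in seq_len(nrow(links))) {
      pool_idx <- pools[[links$category[j]]]
      if (round(links$intensity[j] * cfg$flavonoid_targets_mean) >
          length(pool_idx)) {
        fa_stop("infeasible config: pool smaller than the expected ",
                "planted target count for ", f, " -> ", links$category[j])
      }
      # cap stochastic overshoot of the Poisson draw at the pool size
      k <- min(round(links$intensity[j] * size), length(pool_idx))
      picked <- c(picked, sample(pool_idx, k))
    }
    rest <- size - length(picked)
    univ <- if (nrow(links) > 0L) background else seq_len(cfg$n_proteins)
    if (rest > 0L) picked <- c(picked, sample(univ, min(rest, length(univ))))
    unique(picked)
  })
  names(flav_targets) <- flavs

  # compound-protein records (true edges, score >= 700)
  cp_cmp <- c(rep(drugs, lengths(drug_targets)),
              rep(flavs, lengths(flav_targets)))
  cp_prot <- proteins[c(unlist(drug_targets, use.names = FALSE),
                        unlist(flav_targets, use.names = FALSE))]
  cp <- data.frame(node_a = cp_cmp, node_b = cp_prot,
                   combined_score = sample(700:999, length(cp_cmp),
                                           replace = TRUE),
                   stringsAsFactors = FALSE)

  # protein-protein records (true edges)
  n_pp <- cfg$pp_edges
  ia <- sample(cfg$n_proteins, n_pp, replace = TRUE)
  ib <- sample(cfg$n_proteins - 1L, n_pp, replace = TRUE)
  ib <- ifelse(ib >= ia, ib + 1L, ib)  # avoid self-loops
  pp <- data.frame(node_a = proteins[ia], node_b = proteins[ib],
                   combined_score = sample(700:999, n_pp, replace = TRUE),
                   stringsAsFactors = FALSE)

  # decoy (sub-threshold) edges
  add_decoys <- function(df, left_ids) {
    n_d <- round(cfg$subthreshold_ratio * nrow(df))
    if (n_d <= 0L) return(df)
    rbind(df, data.frame(
      node_a = sample(left_ids, n_d, replace = TRUE),
      node_b = sample(proteins, n_d, replace = TRUE),
      combined_score = sample(150:699, n_d, replace = TRUE),
      stringsAsFactors = FALSE
    ))
  }
  pp <- add_decoys(pp, proteins)
  cp <- add_decoys(cp, c(drugs, flavs))

  truth <- list(
    planted_links = pl,
    planted_food_links = cfg$planted_food_links,
    anti_planted_food_links = cfg$anti_planted_food_links,
    flavonoids = flavs, drugs = drugs, proteins = proteins,
    categories = cats,
    category_pools = lapply(pools, function(i) proteins[i]),
    flavonoid_targets = lapply(flav_targets, function(i) proteins[i]),
    config = cfg, seed = seed
  )
  list(pp = pp, cp = cp, atc = atc, truth = truth)
}

#' Generate a synthetic food composition matrix
#'
#' Planted foods have high, log-normally noised content of the flavonoids
#' carrying their linked category's signal, with content proportional to
#' the planted intensity; anti-planted foods load exclusively on flavonoids
#' without the category's signal; background foods draw sparse content
#' (many exact zeros, emulating USDA sparsity).
#'
#' @param config a `synthetic_config`.
#' @param truth the `truth` component of [generate_interactome()].
#' @param seed random seed (defaults to `config$seed + 1`).
#' @return numeric matrix, foods x flavonoids (mg/100 g).
#' @export
generate_foods <- function(config, truth, seed = config$seed + 1L) {
  cfg <- config
  set.seed(seed)
  flavs <- truth$flavonoids
  foods <- sprintf("FOOD%02d", seq_len(cfg$n_foods))
  pl <- truth$planted_links
  signal <- function(category) {
    s <- setNames(numeric(length(flavs)), flavs)
    rows <- pl[pl$category == category, , drop = FALSE]
    s[rows$flavonoid] <- rows$intensity
    s
  }
  bg_draw <- function(k) {
    ifelse(runif(k) < cfg$background_sparsity, 0,
           rlnorm(k, meanlog = log(2), sdlog = 1))
  }
  m <- matrix(0, nrow = cfg$n_foods, ncol = length(flavs),
              dimnames = list(foods, flavs))
  for (i in seq_len(cfg$n_foods)) m[i, ] <- bg_draw(length(flavs))

  # planted foods: content proportional to the category's signal
  # intensities; non-signal entries are sparser than background so the
  # aligned signature ranks dominate the rank correlation
  cold_draw <- function(k) {
    ifelse(runif(k) < cfg$planted_food_sparsity, 0,
           rlnorm(k, meanlog = log(2), sdlog = 1))
  }
  pf <- cfg$planted_food_links
  for (j in seq_len(nrow(pf))) {
    s <- signal(pf$category[j])
    hot <- s > 0
    row <- cold_draw(length(flavs))
    row[hot] <- cfg$content_scale * s[hot] * pf$intensity[j] *
      rlnorm(sum(hot), meanlog = 0, sdlog = cfg$content_noise_sigma)
    m[pf$food[j], ] <- row
  }
  af <- cfg$anti_planted_food_links
  for (j in seq_len(nrow(af))) {
    s <- signal(af$category[j])
    row <- numeric(length(flavs))
    cold <- s == 0
    row[cold] <- cfg$content_scale *
      rlnorm(sum(cold), meanlog = 0, sdlog = cfg$content_noise_sigma)
    m[af$food[j], ] <- row
  }
  m
}

#' Generate a synthetic epidemiological evidence table
#'
#' For each predicted food-ATC pair, support is drawn from a Bernoulli
#' whose probability is a logistic function of the pair's correlation:
#' `plogis(qlogis(base_rate) + slope * rho)`. Supported rows carry an
#' evidence count drawn uniformly from 1-9; unsupported rows carry 0.
#'
#' @param scores a `food_atc_scores` data.frame.
#' @param config a `synthetic_config` (uses `support_base_rate`,
#'   `support_logit_slope`).
#' @param seed random seed (defaults to `config$seed + 2`).
#' @return data.frame `food_id`, `atc_code`, `evidence_count`, `supported`
#'   with one row per predicted pair (empty for an empty score list).
#' @export
generate_evidence <- function(scores, config, seed = config$seed + 2L) {
  set.seed(seed)
  pred <- scores[scores$predicted, , drop = FALSE]
  if (nrow(pred) == 0L) {
    return(data.frame(food_id = character(), atc_code = character(),
                      evidence_count = integer(), supported = logical(),
                      stringsAsFactors = FALSE))
  }
  prob <- plogis(stats::qlogis(config$support_base_rate) +
                   config$support_logit_slope * pred$rho)
  supported <- runif(nrow(pred)) < prob
  count <- ifelse(supported, sample(1:9, nrow(pred), replace = TRUE), 0L)
  data.frame(food_id = pred$food_id, atc_code = pred$atc_code,
             evidence_count = as.integer(count), supported = supported,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic bioassay (LC50) table from a strength vector
#'
#' Emulates the concordance between association strength and cytotoxic
#' potency: `log10(LC50)` decreases linearly in strength plus Gaussian
#' noise, and LC50 values above the censoring bound are right-censored at
#' the bound.
#'
#' @param strengths named numeric vector, flavonoid -> strength.
#' @param slope decrease in log10(LC50) per strength unit (default 0.15).
#' @param intercept log10(LC50) at zero strength (default log10(250)).
#' @param sigma Gaussian noise sd on log10(LC50) (default 0.1).
#' @param bound censoring bound in uM (default 200).
#' @param seed random seed.
#' @return data.frame `flavonoid_id`, `lc50`, `censored`.
#' @export
generate_bioassay <- function(strengths, slope = 0.15,
                              intercept = log10(250), sigma = 0.1,
                              bound = 200, seed = 1L) {
  set.seed(seed)
  log_lc50 <- intercept - slope * strengths +
    rnorm(length(strengths), 0, sigma)
  lc50 <- 10^log_lc50
  censored <- lc50 > bound
  lc50[censored] <- bound
  data.frame(flavonoid_id = names(strengths), lc50 = lc50,
             censored = censored, stringsAsFactors = FALSE)
}

#' Convert a composition matrix to the long-format table dialect
#'
#' Inverse of [read_food_composition()] (explicit zeros are written so the
#' round trip is lossless).
#'
#' @param m foods x flavonoids matrix.
#' @return data.frame `food_id`, `flavonoid_id`, `mg_per_100g`.
#' @export
composition_table <- function(m) {
  data.frame(food_id = rep(rownames(m), times = ncol(m)),
             flavonoid_id = rep(colnames(m), each = nrow(m)),
             mg_per_100g = as.vector(m),
             stringsAsFactors = FALSE)
}
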