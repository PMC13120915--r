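# fixture builders and independent oracles shared across test files

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# a small hand-drawable master network: proteins p1..p6, flavonoids fA/fB,
# drugs dX/dY/dZ (all edges already above any score threshold)
toy_network <- function() {
  pp <- data.frame(
    node_a = c("p1", "p1", "p2", "p3", "p4", "p5"),
    node_b = c("p2", "p3", "p3", "p4", "p5", "p6"),
    combined_score = c(800L, 810L, 820L, 830L, 840L, 850L),
    stringsAsFactors = FALSE
  )
  cp <- data.frame(
    node_a = c("fA", "fA", "fB", "dX", "dY", "dZ"),
    node_b = c("p1", "p2", "p4", "p2", "p4", "p6"),
    combined_score = c(900L, 901L, 902L, 903L, 904L, 905L),
    stringsAsFactors = FALSE
  )
  build_master_network(pp, cp, flavonoids = c("fA", "fB"),
                       drugs = c("dX", "dY", "dZ"))
}

# independent oracle: exact hypergeometric upper tail by direct rational
# enumeration with choose() (exact in doubles for N <= 30)
oracle_hyper_tail <- function(N, M, n, x) {
  i <- x:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# independent oracle: BH step-up by the textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# independent oracle: naive O(n^3) UPGMA agglomeration returning merge
# heights and the leaf composition of each merged cluster
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dd <- d
  heights <- numeric(0)
  merges <- list()
  for (step in seq_len(n - 1L)) {
    best <- Inf; bi <- bj <- NA
    idx <- which(active)
    for (a in idx) for (b in idx) {
      if (a < b && dd[a, b] < best) { best <- dd[a, b]; bi <- a; bj <- b }
    }
    heights <- c(heights, best)
    new <- c(clusters[[bi]], clusters[[bj]])
    merges[[step]] <- sort(new)
    # average linkage: mean of all leaf-pair distances
    for (a in idx) {
      if (a != bi && a != bj) {
        dd[bi, a] <- dd[a, bi] <- mean(d[clusters[[a]], new])
      }
    }
    clusters[[bi]] <- new
    active[bj] <- FALSE
  }
  list(heights = heights, merges = merges)
}

# leaf sets of each internal merge of an hclust object
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (k in seq_len(nrow(hc$merge))) {
    take <- function(v) {
      if (v < 0) -v else sets[[v]]
    }
    sets[[k]] <- sort(c(take(hc$merge[k, 1]), take(hc$merge[k, 2])))
  }
  sets
}

# independent oracle: exact two-sided rank-sum p by full enumeration of
# group assignments (small samples only)
oracle_ranksum_exact_p <- function(x, y) {
  n1 <- length(x)
  all_vals <- c(x, y)
  r <- rank(all_vals)
  W_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(all_vals) + 1) / 2
  combs <- utils::combn(length(all_vals), n1)
  W_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(W_all - mu) >= abs(W_obs - mu))
}

# build a master_network with prescribed per-compound target counts
# (compounds attached to disjoint protein sets, plus a pp backbone)
network_with_target_counts <- function(flav_counts, drug_counts) {
  n_prot <- sum(flav_counts) + sum(drug_counts) + 2L
  prot <- sprintf("p%05d", seq_len(n_prot))
  flavs <- sprintf("fl%02d", seq_along(flav_counts))
  drugs <- sprintf("dr%02d", seq_along(drug_counts))
  cmp <- rep(c(flavs, drugs), c(flav_counts, drug_counts))
  tgt <- prot[seq_along(cmp)]
  cp <- data.frame(node_a = cmp, node_b = tgt,
                   combined_score = 900L, stringsAsFactors = FALSE)
  pp <- data.frame(node_a = prot[n_prot - 1L], node_b = prot[n_prot],
                   combined_score = 900L, stringsAsFactors = FALSE)
  build_master_network(pp, cp, flavonoids = flavs, drugs = drugs)
}
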