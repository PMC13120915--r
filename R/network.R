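#' Filter interaction records by combined confidence score
#'
#' Keeps records with `combined_score >= min_score` (inclusive, matching the
#' conventional ">= 700" high-confidence STRING/STITCH cutoff). Input order
#' is preserved.
#'
#' @param records data.frame as returned by [read_interaction_table()].
#' @param min_score integer threshold in \[0, 1000\].
#' @return the filtered data.frame (possibly zero rows).
#' @export
filter_by_score <- function(records, min_score) {
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      min_score < 0 || min_score > 1000) {
    fa_stop("min_score must be a single value in [0, 1000]")
  }
  out <- records[records$combined_score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the master protein/compound interaction network
#'
#' Merges a filtered protein-protein layer and a filtered compound-protein
#' layer into one undirected typed graph:
#' \itemize{
#'   \item compound nodes are restricted to the `flavonoids` and `drugs`
#'     whitelists; compound-protein records for other compounds are dropped;
#'   \item self-loops are removed;
#'   \item symmetric duplicate edges are collapsed, keeping the maximum
#'     combined score;
#'   \item nodes left with degree 0 are removed (so drugs or flavonoids
#'     without surviving targets disappear from the network and from every
#'     downstream universe).
#' }
#' Node kinds (`protein`, `flavonoid`, `drug`) are assigned from the
#' whitelists, never inferred from identifier syntax. A whitelisted
#' compound appearing in the protein-protein layer, or on both whitelists,
#' is an error.
#'
#' @param pp data.frame of protein-protein records (already score-filtered),
#'   columns `node_a`, `node_b`, `combined_score`.
#' @param cp data.frame of compound-protein records (already score-filtered),
#'   first column the compound, second the protein.
#' @param flavonoids character vector of flavonoid identifiers.
#' @param drugs character vector of drug identifiers.
#' @return an object of class `master_network`: a list with data.frames
#'   `nodes` (`node`, `kind`) and `edges` (`node_a`, `node_b`,
#'   `combined_score`, `layer` in `{protein_protein, compound_protein}`).
#' @export
build_master_network <- function(pp, cp, flavonoids, drugs) {
  flavonoids <- unique(as.character(flavonoids))
  drugs <- unique(as.character(drugs))
  if (length(intersect(flavonoids, drugs)) > 0L) {
    fa_stop("identifiers on both whitelists: ",
            paste(utils::head(intersect(flavonoids, drugs), 5L),
                  collapse = ", "))
  }
  compounds <- c(flavonoids, drugs)

  pp_nodes <- unique(c(pp$node_a, pp$node_b))
  if (any(pp_nodes %in% compounds)) {
    fa_stop("whitelisted compound(s) appear in the protein-protein layer: ",
            paste(utils::head(intersect(pp_nodes, compounds), 5L),
                  collapse = ", "))
  }
  if (any(cp$node_b %in% compounds)) {
    fa_stop("compound-compound edge(s) in the compound-protein layer")
  }

  # keep only whitelisted compounds, drop self-loops
  cp <- cp[cp$node_a %in% compounds & cp$node_a != cp$node_b, , drop = FALSE]
  pp <- pp[pp$node_a != pp$node_b, , drop = FALSE]

  dedupe <- function(df) {
    if (nrow(df) == 0L) {
      return(data.frame(node_a = character(), node_b = character(),
                        combined_score = integer(), stringsAsFactors = FALSE))
    }
    a <- pmin(df$node_a, df$node_b)
    b <- pmax(df$node_a, df$node_b)
    key <- paste(a, b, sep = "\r")
    # keep the max score per unordered pair: order by key then score
    # descending, the first row of each key block wins
    o <- order(key, -df$combined_score)
    keep <- o[!duplicated(key[o])]
    out <- data.frame(node_a = a[keep], node_b = b[keep],
                      combined_score = as.integer(df$combined_score[keep]),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
  pp <- dedupe(pp)
  cp <- dedupe(cp)
  edges <- rbind(
    if (nrow(pp)) cbind(pp, layer = "protein_protein") else NULL,
    if (nrow(cp)) cbind(cp, layer = "compound_protein") else NULL
  )
  if (is.null(edges)) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        combined_score = integer(), layer = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL

  ids <- sort(unique(c(edges$node_a, edges$node_b)))
  kind <- ifelse(ids %in% flavonoids, "flavonoid",
                 ifelse(ids %in% drugs, "drug", "protein"))
  nodes <- data.frame(node = ids, kind = kind, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "master_network")
}

#' @export
print.master_network <- function(x, ...) {
  k <- table(factor(x$nodes$kind, c("protein", "flavonoid", "drug")))
  l <- table(factor(x$edges$layer, c("protein_protein", "compound_protein")))
  cat("master_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", k[["protein"]], "proteins,", k[["flavonoid"]],
      "flavonoids,", k[["drug"]], "drugs\n")
  cat("  edges:", l[["protein_protein"]], "protein-protein,",
      l[["compound_protein"]], "compound-protein\n")
  invisible(x)
}

#' @export
summary.master_network <- function(object, ...) {
  topology_summary(object)
}

#' Density and mean degree from node/edge totals
#'
#' The closed-form topology metrics of an undirected simple graph:
#' density \eqn{2E / (N(N-1))} and mean degree \eqn{2E / N}. Useful for
#' checking reported totals without the graph itself.
#'
#' @param n_nodes node count (>= 2).
#' @param n_edges edge count.
#' @return list with `density` and `mean_degree`.
#' @export
topology_metrics <- function(n_nodes, n_edges) {
  if (n_nodes < 2) fa_stop("need at least 2 nodes")
  list(density = 2 * n_edges / (n_nodes * (n_nodes - 1)),
       mean_degree = 2 * n_edges / n_nodes)
}

#' Topology summary of a master network
#'
#' Counts nodes and edges by kind and layer and computes density, mean
#' degree and the population standard deviation of node degrees.
#'
#' @param net a `master_network`.
#' @return object of class `topology_summary` (a list) with fields
#'   `n_nodes`, `n_edges`, `n_protein_nodes`, `n_compound_nodes`,
#'   `n_pp_edges`, `n_cp_edges`, `density`, `mean_degree`, `degree_sd`.
#' @export
topology_summary <- function(net) {
  if (nrow(net$nodes) < 2L) fa_stop("need at least 2 nodes")
  deg <- table(factor(c(net$edges$node_a, net$edges$node_b),
                      levels = net$nodes$node))
  deg <- as.numeric(deg)
  m <- topology_metrics(nrow(net$nodes), nrow(net$edges))
  out <- list(
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_protein_nodes = sum(net$nodes$kind == "protein"),
    n_compound_nodes = sum(net$nodes$kind != "protein"),
    n_pp_edges = sum(net$edges$layer == "protein_protein"),
    n_cp_edges = sum(net$edges$layer == "compound_protein"),
    density = m$density,
    mean_degree = m$mean_degree,
    degree_sd = sqrt(mean((deg - mean(deg))^2))
  )
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("nodes:", x$n_nodes, "(", x$n_protein_nodes, "proteins,",
      x$n_compound_nodes, "compounds )\n")
  cat("edges:", x$n_edges, "(", x$n_pp_edges, "pp,", x$n_cp_edges, "cp )\n")
  cat(sprintf("density: %.4g   mean degree: %.3f (population SD %.3f)\n",
              x$density, x$mean_degree, x$degree_sd))
  invisible(x)
}

#' Protein targets of a compound in the master network
#'
#' The protein neighbours of a flavonoid or drug via compound-protein
#' edges. Compounds never appear in the result.
#'
#' @param net a `master_network`.
#' @param compound a flavonoid or drug identifier present in the network.
#' @return character vector of protein identifiers (sorted).
#' @export
target_set <- function(net, compound) {
  i <- match(compound, net$nodes$node)
  if (is.na(i)) fa_stop("unknown compound: ", compound)
  if (net$nodes$kind[i] == "protein") {
    fa_stop(compound, " is a protein, not a compound")
  }
  e <- net$edges[net$edges$layer == "compound_protein", , drop = FALSE]
  nb <- c(e$node_b[e$node_a == compound], e$node_a[e$node_b == compound])
  sort(unique(nb))
}

# internal: named list of target sets for all compounds of a kind
fa_target_sets <- function(net, kind) {
  ids <- net$nodes$node[net$nodes$kind == kind]
  e <- net$edges[net$edges$layer == "compound_protein", , drop = FALSE]
  is_cmp_a <- e$node_a %in% net$nodes$node[net$nodes$kind != "protein"]
  cmp <- ifelse(is_cmp_a, e$node_a, e$node_b)
  prot <- ifelse(is_cmp_a, e$node_b, e$node_a)
  sets <- split(prot, cmp)
  out <- sets[ids]
  names(out) <- ids
  out[vapply(out, is.null, TRUE)] <- list(character())
  out
}

#' Two-sample Wilcoxon rank-sum test (normal approximation)
#'
#' Rank-sum test with average ranks for ties, the tie-corrected variance,
#' and a continuity correction, reporting the standardized Z statistic and
#' the two-sided p-value. When all observations are identical (zero
#' variance) Z = 0 and p = 1.
#'
#' @param x,y numeric vectors (each length >= 1).
#' @return list with `z`, `p_value` and the rank-sum statistic `W` of `x`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) fa_stop("both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(z = 0, p_value = 1, W = W))
  }
  cc <- sign(W - mu) * 0.5
  z <- (W - mu - cc) / sqrt(sigma2)
  list(z = z, p_value = min(1, 2 * pnorm(-abs(z))), W = W)
}

#' Compare target-set sizes of flavonoids and drugs
#'
#' Mean per-compound protein target counts by compound kind, their fold
#' ratio (flavonoid mean / drug mean), and a two-sided Wilcoxon rank-sum
#' test of the two count distributions.
#'
#' @param net a `master_network` with at least 2 flavonoids and 2 drugs.
#' @return list with `flavonoid_mean`, `drug_mean`, `fold_ratio`,
#'   `wilcoxon_z`, `wilcoxon_p`, and the per-compound count vectors
#'   `flavonoid_counts`, `drug_counts`.
#' @export
target_count_comparison <- function(net) {
  fl <- lengths(fa_target_sets(net, "flavonoid"))
  dr <- lengths(fa_target_sets(net, "drug"))
  if (length(fl) < 2L || length(dr) < 2L) {
    fa_stop("need at least 2 flavonoids and 2 drugs in the network")
  }
  w <- wilcoxon_ranksum(fl, dr)
  list(flavonoid_mean = mean(fl), drug_mean = mean(dr),
       fold_ratio = mean(fl) / mean(dr),
       wilcoxon_z = w$z, wilcoxon_p = w$p_value,
       flavonoid_counts = fl, drug_counts = dr)
}

#' Serialize / deserialize a master network
#'
#' The network is written as two TSV files: an edge list
#' (`node_a`, `node_b`, `combined_score`, `layer`) and a node table
#' (`node`, `kind`). `read_network()` restores the `master_network` object.
#'
#' @param net a `master_network`.
#' @param edge_path,node_path output (or input) file paths.
#' @return `write_network()` invisibly returns the paths; `read_network()`
#'   returns a `master_network`.
#' @export
write_network <- function(net, edge_path, node_path) {
  write_results_table(net$edges, edge_path)
  write_results_table(net$nodes, node_path)
  invisible(c(edge_path, node_path))
}

#' @rdname write_network
#' @export
read_network <- function(edge_path, node_path) {
  edges <- read_results_table(edge_path)
  nodes <- read_results_table(node_path)
  if (nrow(edges) == 0L) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        combined_score = integer(), layer = character())
  }
  if (!all(nodes$kind %in% c("protein", "flavonoid", "drug"))) {
    fa_stop("node table contains unknown kinds")
  }
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  nodes$node <- as.character(nodes$node)
  structure(list(nodes = nodes, edges = edges), class = "master_network")
}

#' Convert a master network to an igraph object
#'
#' Convenience converter for users of the igraph ecosystem; requires the
#' igraph package. Node kind and edge score/layer become vertex and edge
#' attributes.
#'
#' @param net a `master_network`.
#' @return an igraph undirected graph.
#' @export
as_igraph <- function(net) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    fa_stop("the igraph package is required for as_igraph()")
  }
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}
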