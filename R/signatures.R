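# Downstream interpretation: features differential in the worst-survival
# subtype, rank aggregation of signatures across datasets, and consensus
# co-expression networks with random-walk community detection.

#' Features differential in the worst-survival subtype
#'
#' Two-sided Wilcoxon rank-sum test of every feature, worst-survival group
#' (label 0) versus all other samples; features with p below the threshold are
#' retained, with direction ("over"/"under") from the median difference. Each
#' retained feature also gets a univariate Cox p-value (on the full cohort)
#' and a per-dataset normalized rank in \[0, 1\] where 1 marks the smallest
#' Cox p — the inputs to [pan_dataset_rank()].
#'
#' @param layer an [omics_matrix()] (aligned to `survival`).
#' @param labeling a `subtype_labeling` for the same samples.
#' @param survival the cohort [survival_table()].
#' @param p_threshold Wilcoxon retention threshold (default 0.001).
#' @return A `differential_feature_set`: data.frame `features` (feature,
#'   direction, wilcoxon_p, cox_p, norm_rank) plus `omic_tag`, `threshold`.
#' @export
differential_features <- function(layer, labeling, survival,
                                  p_threshold = 0.001) {
  worst <- labeling$ordered_labels == 0
  if (sum(worst) < 3 || sum(!worst) < 3)
    abort_omicsurv("each side of the worst-vs-rest split needs >= 3 samples",
                   "argument")
  idx <- match(labeling$sample_ids, layer$sample_ids)
  if (anyNA(idx))
    abort_omicsurv("labeling samples missing from the omics layer", "argument")
  vals <- layer$values[, idx, drop = FALSE]
  wt <- wilcoxon_matrix(vals, worst)
  keep <- which(wt$p_value < p_threshold)
  if (length(keep) > 0) {
    scr <- cox_screen(t(vals[keep, , drop = FALSE]),
                      subset_survival(survival, labeling$sample_ids))
    nr <- if (length(keep) == 1) 1 else rescale01(-log10(pmax(scr$p_value,
                                                              1e-300)))
    feats <- data.frame(
      feature = layer$feature_ids[keep],
      direction = ifelse(wt$delta_median[keep] > 0, "over", "under"),
      wilcoxon_p = wt$p_value[keep],
      cox_p = scr$p_value,
      norm_rank = nr,
      stringsAsFactors = FALSE)
    feats <- feats[order(feats$wilcoxon_p, feats$feature), ]
    rownames(feats) <- NULL
  } else {
    feats <- data.frame(feature = character(0), direction = character(0),
                        wilcoxon_p = numeric(0), cox_p = numeric(0),
                        norm_rank = numeric(0))
  }
  structure(list(features = feats, omic_tag = layer$omic_tag,
                 threshold = p_threshold),
            class = "differential_feature_set")
}

#' @export
print.differential_feature_set <- function(x, ...) {
  cat(sprintf("<differential_feature_set '%s'> %d feature(s) at p < %g\n",
              x$omic_tag, nrow(x$features), x$threshold))
  invisible(x)
}

#' Aggregate signature ranks across datasets
#'
#' Within each dataset the retained features carry a normalized rank in
#' \[0, 1\] (1 = smallest Cox p, 0 = largest; a dataset with a single retained
#' feature contributes rank 1). The final score of a feature is the sum of its
#' normalized ranks across datasets (absent features contribute 0), so scores
#' lie in \[0, number of datasets\].
#'
#' @param per_dataset named list of `differential_feature_set`s.
#' @return data.frame `feature`, `score`, `n_datasets`, sorted by decreasing
#'   score.
#' @export
pan_dataset_rank <- function(per_dataset) {
  if (length(per_dataset) < 1)
    abort_omicsurv("need >= 1 dataset", "argument")
  all <- do.call(rbind, lapply(per_dataset, function(d)
    d$features[, c("feature", "norm_rank")]))
  if (nrow(all) == 0)
    return(data.frame(feature = character(0), score = numeric(0),
                      n_datasets = integer(0)))
  agg <- stats::aggregate(norm_rank ~ feature, data = all, FUN = sum)
  cnt <- stats::aggregate(norm_rank ~ feature, data = all, FUN = length)
  out <- data.frame(feature = agg$feature, score = agg$norm_rank,
                    n_datasets = cnt$norm_rank)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Build a co-expression network over worst-subtype signature genes
#'
#' Nodes are (at most) the `top_n` retained features by Wilcoxon p; the edge
#' weight between two genes is their absolute Spearman correlation across
#' samples (`method = "pearson"` behind the flag), normalized by the network
#' maximum; a node's score is the sum of its incident normalized weights.
#' Constant genes (undefined correlations) are dropped with a warning.
#'
#' @param layer an [omics_matrix()].
#' @param de a `differential_feature_set` for that layer.
#' @param top_n maximum number of nodes (default 1000).
#' @param method correlation type: `"spearman"` (default) or `"pearson"`.
#' @return A `coexpression_graph`: `nodes` (data.frame feature, score),
#'   `edges` (data.frame from, to, weight in \[0, 1\]), `communities` (NULL
#'   until [consensus_network()]).
#' @export
build_coexpression_network <- function(layer, de, top_n = 1000,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  genes <- utils::head(de$features$feature, top_n)
  genes <- intersect(genes, layer$feature_ids)
  if (length(genes) < 2)
    abort_omicsurv("need >= 2 retained genes to build a network", "argument")
  vals <- layer$values[match(genes, layer$feature_ids), , drop = FALSE]
  const <- apply(vals, 1, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("dropping %d constant gene(s) with undefined correlations",
                    sum(const)))
    vals <- vals[!const, , drop = FALSE]
    genes <- genes[!const]
    if (length(genes) < 2)
      abort_omicsurv("fewer than 2 non-constant genes remain", "argument")
  }
  r <- abs(stats::cor(t(vals), method = method))
  diag(r) <- 0
  if (max(r) == 0)
    abort_omicsurv("all pairwise correlations are zero; no network", "degenerate")
  r <- r / max(r)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(from = genes[ut[, 1]], to = genes[ut[, 2]],
                      weight = r[ut], stringsAsFactors = FALSE)
  nodes <- data.frame(feature = genes, score = rowSums(r),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, communities = NULL),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("<coexpression_graph> %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (!is.null(x$communities))
                sprintf(", %d communities", length(unique(x$communities)))
              else ""))
  invisible(x)
}

#' Consensus co-expression network with communities
#'
#' Sums node and edge weights across the input graphs, keeps the `top_nodes`
#' heaviest nodes, prunes each node to its `max_edges_per_node` heaviest
#' incident edges (an edge survives if it is in the top list of at least one
#' endpoint), and detects communities with the walktrap (random-walk)
#' algorithm.
#'
#' @param graphs list of `coexpression_graph`s.
#' @param top_nodes nodes kept in the consensus (default 200).
#' @param max_edges_per_node incident edges kept per node (default 10).
#' @return A `coexpression_graph` with `communities` (named membership
#'   vector).
#' @export
consensus_network <- function(graphs, top_nodes = 200,
                              max_edges_per_node = 10) {
  if (length(graphs) < 1)
    abort_omicsurv("need >= 1 input graph", "argument")
  nodes <- do.call(rbind, lapply(graphs, function(g) g$nodes))
  nodes <- stats::aggregate(score ~ feature, data = nodes, FUN = sum)
  edges <- do.call(rbind, lapply(graphs, function(g) {
    e <- g$edges
    swap <- e$from > e$to                     # canonical undirected key
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
    e
  }))
  edges <- stats::aggregate(weight ~ from + to, data = edges, FUN = sum)
  keep_nodes <- nodes$feature[order(-nodes$score,
                                    nodes$feature)][seq_len(min(top_nodes,
                                                                nrow(nodes)))]
  nodes <- nodes[nodes$feature %in% keep_nodes, ]
  edges <- edges[edges$from %in% keep_nodes & edges$to %in% keep_nodes, ,
                 drop = FALSE]
  if (nrow(nodes) == 0)
    abort_omicsurv("empty consensus network", "degenerate")
  # per-node top-k incident edges; an edge survives if kept by either endpoint
  if (nrow(edges) > 0) {
    ekey <- paste(edges$from, edges$to, sep = "\r")
    kept <- character(0)
    for (v in nodes$feature) {
      inc <- which(edges$from == v | edges$to == v)
      if (length(inc) == 0) next
      inc <- inc[order(-edges$weight[inc], ekey[inc])]
      kept <- c(kept, ekey[inc[seq_len(min(max_edges_per_node,
                                           length(inc)))]])
    }
    edges <- edges[ekey %in% unique(kept), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes$feature)
  comm <- igraph::cluster_walktrap(g, weights = edges$weight)
  membership <- stats::setNames(as.integer(igraph::membership(comm)),
                                names(igraph::membership(comm)))
  structure(list(nodes = nodes[order(-nodes$score, nodes$feature), ],
                 edges = edges, communities = membership),
            class = "coexpression_graph")
}

#' Write a co-expression graph as TSV edge list (+ communities)
#'
#' @param graph a `coexpression_graph`.
#' @param path edge-list TSV path; community membership (if present) goes to
#'   `<path>.communities.tsv`.
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graph$communities))
    utils::write.table(
      data.frame(feature = names(graph$communities),
                 community = graph$communities),
      paste0(path, ".communities.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(path)
}
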