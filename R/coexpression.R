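# Robustness check of the NMF protein clusters: Louvain community detection
# on the weighted protein coexpression network (Pearson correlations over AD
# samples, negative edges truncated, zero diagonal) and quantification of the
# overlap between the two protein partitions.

#' Build a weighted protein coexpression network
#'
#' Pairwise Pearson correlations between proteins, computed across the AD
#' samples by default (the clustered population). Negative correlations are
#' truncated to zero (with `edge_mode = "absolute"`, absolute values are
#' kept instead); the diagonal is excluded.
#'
#' @param norm a `normalized_matrix` or plain matrix (proteins x samples).
#' @param proteins optional protein subset.
#' @param samples optional sample subset (e.g. AD sample ids); default all
#'   columns.
#' @param edge_mode `"truncate"` (default) or `"absolute"`.
#' @return An object of class `coexpression_network`: list with `adjacency`
#'   (symmetric, non-negative, zero diagonal), `proteins`, `edge_mode`.
#' @export
build_coexpression_network <- function(norm, proteins = NULL, samples = NULL,
                                       edge_mode = c("truncate", "absolute")) {
  edge_mode <- match.arg(edge_mode)
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (!is.null(proteins)) values <- values[proteins, , drop = FALSE]
  if (!is.null(samples)) values <- values[, samples, drop = FALSE]
  if (nrow(values) < 3 || ncol(values) < 3) {
    stop("need at least 3 proteins and 3 samples", call. = FALSE)
  }
  constant <- apply(values, 1, function(x) stats::sd(x, na.rm = TRUE) == 0)
  A <- suppressWarnings(stats::cor(t(values), use = "pairwise.complete.obs"))
  if (any(constant)) {
    warning(sprintf("%d constant protein(s): correlations set to 0",
                    sum(constant)), call. = FALSE)
  }
  A[is.na(A)] <- 0
  A <- if (edge_mode == "truncate") pmax(A, 0) else abs(A)
  diag(A) <- 0
  structure(list(adjacency = A, proteins = rownames(values),
                 edge_mode = edge_mode),
            class = "coexpression_network")
}

#' Louvain community detection on a coexpression network
#'
#' Greedy weighted-modularity optimization with resolution parameter
#' `gamma` in the quality function
#' `Q = sum_c (e_c / m - gamma * (d_c / 2m)^2)`; the default resolution of
#' 1.15 matches the discovery analysis. The sweep order is seeded.
#'
#' @param net a `coexpression_network`.
#' @param resolution resolution parameter gamma.
#' @param seed integer seed.
#' @return A list with `membership` (named community labels), `modularity`
#'   and `n_communities`.
#' @export
louvain_communities <- function(net, resolution = 1.15, seed = 1L) {
  stopifnot(inherits(net, "coexpression_network"))
  A <- net$adjacency
  if (all(A == 0)) stop("network has no edges", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  membership <- igraph::membership(cl)
  q <- igraph::modularity(g, membership, weights = igraph::E(g)$weight,
                          resolution = resolution)
  list(membership = stats::setNames(as.integer(membership), net$proteins),
       modularity = q, n_communities = length(unique(membership)))
}

#' Percent overlap between two protein partitions
#'
#' Clusters of the two partitions are matched one-to-one by maximum-weight
#' assignment over their contingency table (solved exactly); the overlap is
#' the fraction of proteins falling in matched cluster pairs, in percent.
#' Invariant under relabeling of either partition.
#'
#' @param labels_a,labels_b label vectors over the same protein universe;
#'   if named, they are aligned by name.
#' @return Percent overlap in \[0, 100\].
#' @export
cluster_overlap <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b))) {
      stop("partitions cover different protein universes", call. = FALSE)
    }
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b)) {
    stop("partitions cover different protein universes", call. = FALSE)
  }
  ct <- table(labels_a, labels_b)
  wide <- ncol(ct) >= nrow(ct)
  W <- if (wide) unclass(ct) else t(unclass(ct))
  match <- assignment_max(W)
  matched <- sum(W[cbind(seq_len(nrow(W)), match)[match > 0, , drop = FALSE]])
  100 * matched / sum(ct)
}

#' Louvain vs NMF protein-cluster robustness check
#'
#' Builds the coexpression network over the model's panel proteins and AD
#' samples, runs Louvain at the given resolution, and reports the percent
#' overlap with the NMF protein clusters.
#'
#' @param norm a `normalized_matrix`.
#' @param model a fitted `subtype_model`.
#' @param meta a `sample_metadata` (used to restrict to AD samples).
#' @param resolution,seed passed to [louvain_communities()].
#' @return A list with `overlap_percent`, `louvain`, `network`.
#' @export
coexpression_robustness <- function(norm, model, meta, resolution = 1.15,
                                    seed = 1L) {
  stopifnot(inherits(model, "subtype_model"))
  meta <- read_metadata(meta)
  panel <- names(model$protein_labels)
  ad_ids <- intersect(colnames(norm$values),
                      meta$sample_id[meta$group == "AD"])
  net <- build_coexpression_network(norm, proteins = panel, samples = ad_ids)
  lv <- louvain_communities(net, resolution = resolution, seed = seed)
  list(overlap_percent = cluster_overlap(model$protein_labels, lv$membership),
       louvain = lv, network = net)
}
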