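# Survey2Vector network inference: cosine similarities between respondents'
# [0,1] feature vectors, threshold calibration against a target average
# degree, and construction of the inferred undirected colleague network.

#' Cosine similarity matrix over respondents
#'
#' S[i, j] = <X_i, X_j> / (||X_i|| ||X_j||) for the rows of the feature
#' matrix. Feature entries are nonnegative, so every similarity lies in
#' [0, 1]; the diagonal is exactly 1.
#'
#' @param features a `feature_matrix` (see [encode_features()]).
#' @return object of class `similarity_matrix`: list with `values` (N x N
#'   symmetric matrix) and `ids`.
#' @export
#' @examples
#' F <- structure(list(values = rbind(c(1, 0, 1), c(1, 1, 0)),
#'                     row_ids = c("a", "b")), class = "feature_matrix")
#' cosine_similarity_matrix(F)$values["a", "b"]  # 0.5
cosine_similarity_matrix <- function(features) {
  V <- features$values
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0))
    stop("zero-norm feature vector for respondent: ",
         features$row_ids[which(nrm == 0)[1]])
  S <- tcrossprod(V / nrm)
  S[S > 1] <- 1
  S[S < 0] <- 0
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(features$row_ids, features$row_ids)
  structure(list(values = S, ids = features$row_ids),
            class = "similarity_matrix")
}

new_network <- function(ids, status, edges, n, threshold_used = NA_real_) {
  structure(
    list(ids = ids, status = status,
         edges = matrix(as.integer(edges), ncol = 2,
                        dimnames = list(NULL, c("i", "j"))),
         n = as.integer(n), threshold_used = threshold_used),
    class = "burnout_network"
  )
}

#' @export
print.burnout_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "burnout_network: %d nodes, %d edges (avg degree %.2f, density %.4g)%s\n",
    s$n_nodes, s$n_edges, s$avg_degree, s$density,
    if (is.na(x$threshold_used)) "" else sprintf(", t = %.4f", x$threshold_used)))
  if (!is.null(x$status))
    cat("  burnout status:",
        paste(sprintf("%s = %d", names(s$status_counts), s$status_counts),
              collapse = ", "), "\n")
  invisible(x)
}

#' Build the inferred network by thresholding similarities
#'
#' Links respondents i and j whenever S[i, j] >= t (ties at the threshold
#' are included). The result is an undirected simple graph on all N nodes;
#' isolated nodes are retained.
#'
#' @param similarity a `similarity_matrix`.
#' @param t threshold in [0, 1].
#' @param status optional per-node burnout status (`"low"`/`"high"`).
#' @return object of class `burnout_network` with fields `ids`, `status`,
#'   `edges` (m x 2 index matrix, i < j), `n`, `threshold_used`.
#' @export
threshold_network <- function(similarity, t, status = NULL) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1)
    stop("threshold t must lie in [0, 1]")
  S <- similarity$values
  n <- nrow(S)
  if (!is.null(status) && length(status) != n)
    stop("status must have one entry per node")
  idx <- which(upper.tri(S) & S >= t, arr.ind = TRUE)
  new_network(similarity$ids, status, idx, n, threshold_used = t)
}

#' Calibrate the similarity threshold to a target average degree
#'
#' The published construction sets the threshold from an externally
#' estimated average number of colleagues per respondent. This calibration
#' returns the largest threshold t at which the thresholded network's
#' average degree reaches the target: the empirical quantile of the
#' off-diagonal similarities at rank 1 - target/(N-1). With all-distinct
#' similarities the achieved average degree is within one edge-quantum
#' (2/N) of the target; ties at t can only add edges (the >= rule).
#'
#' @param similarity a `similarity_matrix`.
#' @param target_avg_degree desired average degree in (0, N-1].
#' @return threshold value t.
#' @export
calibrate_threshold <- function(similarity, target_avg_degree) {
  S <- similarity$values
  n <- nrow(S)
  if (!is.numeric(target_avg_degree) || length(target_avg_degree) != 1 ||
      target_avg_degree <= 0 || target_avg_degree > n - 1)
    stop("target_avg_degree must lie in (0, N-1]")
  s <- sort(S[upper.tri(S)], decreasing = TRUE)
  n_edges <- min(length(s), ceiling(n * target_avg_degree / 2))
  s[n_edges]
}

#' Summarise an inferred network
#'
#' @param g a `burnout_network`.
#' @return list with `n_nodes`, `n_edges`, `avg_degree`, `density`
#'   (2E / (N(N-1))) and `status_counts`.
#' @export
network_summary <- function(g) {
  n <- g$n
  m <- nrow(g$edges)
  list(
    n_nodes = n, n_edges = m,
    avg_degree = if (n > 0) 2 * m / n else 0,
    density = if (n > 1) 2 * m / (n * (n - 1)) else 0,
    status_counts = if (is.null(g$status)) NULL
      else base::table(factor(g$status, levels = c("low", "high")))
  )
}

#' Write a network as edge-list and node-attribute TSV files
#'
#' @param g a `burnout_network`.
#' @param edges_path path for the edge list (columns `id_i`, `id_j`).
#' @param nodes_path path for node attributes (columns `id`, `burnout`).
#' @export
write_network <- function(g, edges_path, nodes_path) {
  el <- data.frame(id_i = g$ids[g$edges[, 1]], id_j = g$ids[g$edges[, 2]],
                   stringsAsFactors = FALSE)
  utils::write.table(el, edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  nd <- data.frame(id = g$ids,
                   burnout = if (is.null(g$status)) NA else g$status,
                   stringsAsFactors = FALSE)
  utils::write.table(nd, nodes_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(edges_path, nodes_path))
}

#' Read a network from edge-list and node-attribute TSV files
#'
#' @param edges_path edge-list TSV (columns `id_i`, `id_j`).
#' @param nodes_path node-attribute TSV (columns `id`, `burnout`).
#' @return a `burnout_network`.
#' @export
read_network <- function(edges_path, nodes_path) {
  nd <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
  el <- utils::read.delim(edges_path, stringsAsFactors = FALSE)
  if (anyDuplicated(nd$id)) stop("duplicate node ids")
  i <- match(el$id_i, nd$id); j <- match(el$id_j, nd$id)
  if (any(is.na(i)) || any(is.na(j)))
    stop("edge references unknown node id")
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  new_network(nd$id, nd$burnout, cbind(i, j), nrow(nd))
}
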