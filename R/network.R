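#' Pairwise Pearson correlations of dF/F0 traces
#'
#' The classic sample correlation
#' `rho(A,B) = 1/(N-1) * sum_i ((A_i - mu_A)/sigma_A) ((B_i - mu_B)/sigma_B)`
#' over a stated frame window. Zero-variance traces have undefined entries
#' (`NA`); the diagonal is 1 where defined.
#'
#' @param dff_window cells x frames matrix of dF/F0 (rownames = cell ids).
#' @param min_samples minimum number of frames required (default 30); a
#'   shorter window returns `NULL` so the caller can withhold the matrix.
#' @return a `correlation_matrix` (list with `rho`, `cell_ids`, `window`)
#'   or `NULL`.
#' @export
pairwise_correlations <- function(dff_window, min_samples = 30) {
  if (ncol(dff_window) < min_samples) return(NULL)
  rho <- suppressWarnings(stats::cor(t(dff_window),
                                     use = "pairwise.complete.obs"))
  sds <- apply(dff_window, 1, stats::sd, na.rm = TRUE)
  und <- !is.finite(sds) | sds == 0
  rho[und, ] <- NA_real_
  rho[, und] <- NA_real_
  diag(rho)[!und] <- 1
  rn <- rownames(dff_window)
  ids <- if (is.null(rn)) seq_len(nrow(dff_window)) - 1L else as.integer(rn)
  structure(list(rho = rho, cell_ids = ids,
                 window = c(1L, ncol(dff_window))),
            class = "correlation_matrix")
}

new_functional_graph <- function(cell_ids, edges, method) {
  degree <- stats::setNames(integer(length(cell_ids)), cell_ids)
  if (nrow(edges)) {
    tab <- table(factor(c(edges$cell_i, edges$cell_j), levels = cell_ids))
    degree[] <- as.integer(tab)
  }
  structure(list(cell_ids = cell_ids, edges = edges, method = method,
                 degree = degree),
            class = "functional_graph")
}

edge_table <- function(corr) {
  n <- length(corr$cell_ids)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  rho <- corr$rho[ij]
  w <- 1 - abs(rho)
  w[!is.finite(w)] <- 1  # undefined correlations connect last
  data.frame(i = ij[, 1], j = ij[, 2],
             cell_i = corr$cell_ids[ij[, 1]], cell_j = corr$cell_ids[ij[, 2]],
             rho = rho, weight = w)
}

#' Minimum-spanning-tree functional network
#'
#' Builds the complete graph with edge weight `1 - |rho|` and prunes it to
#' the spanning tree of minimal total weight, so the N-1 retained edges link
#' the most correlated neurons while keeping every neuron connected.
#' Kruskal's algorithm with edges pre-sorted by (weight, min id, max id)
#' gives a deterministic result under ties. Undefined correlations enter
#' with weight 1 (connected last).
#'
#' @param corr a [pairwise_correlations()] result.
#' @return a `functional_graph` with `method = "mst"` (empty if < 2 nodes).
#' @export
mst_network <- function(corr) {
  ids <- corr$cell_ids
  n <- length(ids)
  empty <- data.frame(cell_i = integer(), cell_j = integer(),
                      rho = numeric(), weight = numeric())
  if (n < 2) return(new_functional_graph(ids, empty, "mst"))
  ed <- edge_table(corr)
  ed <- ed[order(ed$weight, pmin(ed$cell_i, ed$cell_j),
                 pmax(ed$cell_i, ed$cell_j)), ]
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  keep <- logical(nrow(ed))
  taken <- 0L
  for (e in seq_len(nrow(ed))) {
    ra <- find(ed$i[e]); rb <- find(ed$j[e])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  ed <- ed[keep, c("cell_i", "cell_j", "rho", "weight")]
  rownames(ed) <- NULL
  new_functional_graph(ids, ed, "mst")
}

#' Thresholded functional network
#'
#' Keeps every pair with `|rho| >= theta`; isolated nodes are retained with
#' degree 0. Undefined correlations never form edges. With
#' `signed = TRUE` the threshold applies to the signed correlation instead.
#'
#' @param corr a [pairwise_correlations()] result.
#' @param theta correlation threshold in \[0, 1\].
#' @param signed threshold signed `rho` rather than `|rho|`.
#' @return a `functional_graph` with `method = "threshold"`.
#' @export
threshold_network <- function(corr, theta, signed = FALSE) {
  stopifnot(theta >= 0, theta <= 1)
  ed <- edge_table(corr)
  val <- if (signed) ed$rho else abs(ed$rho)
  ed <- ed[is.finite(val) & val >= theta, c("cell_i", "cell_j", "rho", "weight")]
  rownames(ed) <- NULL
  new_functional_graph(corr$cell_ids, ed, "threshold")
}

#' Rank neurons by network degree
#'
#' Higher degree (more functional connections) means higher rank; ties break
#' toward the lower cell id. The top five ranked neurons are the automatic
#' display / photostimulation candidates.
#'
#' @param graph a `functional_graph`.
#' @return data frame `cell_id`, `degree`, `rank` (ordered), with the top-5
#'   ids in `attr(, "top5")`.
#' @export
rank_by_degree <- function(graph) {
  ord <- order(-graph$degree, graph$cell_ids)
  out <- data.frame(cell_id = graph$cell_ids[ord],
                    degree = as.integer(graph$degree[ord]),
                    rank = seq_along(ord))
  attr(out, "top5") <- utils::head(out$cell_id, 5L)
  out
}

#' Stability of the top-k ranking over successive network updates
#'
#' For each pair of adjacent rankings the percent change is
#' `100 * |top-k set difference| / k` (set turnover); the mean over all
#' adjacent pairs is returned. `method = "positional"` instead counts the
#' fraction of top-k positions whose occupant changed.
#'
#' @param ranking_series list of cell-id vectors in rank order.
#' @param k number of top ranks compared (default 10).
#' @param method `"set"` (turnover, default) or `"positional"`.
#' @return mean percent change across adjacent updates.
#' @export
ranking_stability <- function(ranking_series, k = 10, method = c("set", "positional")) {
  method <- match.arg(method)
  stopifnot(length(ranking_series) >= 2)
  tops <- lapply(ranking_series, utils::head, k)
  pc <- vapply(seq_len(length(tops) - 1L), function(i) {
    a <- tops[[i]]; b <- tops[[i + 1L]]
    if (method == "set") 100 * length(setdiff(a, b)) / k
    else 100 * mean(a != b[seq_along(a)])
  }, numeric(1))
  mean(pc)
}

#' @export
print.functional_graph <- function(x, ...) {
  cat("<functional_graph> ", x$method, ": ", length(x$cell_ids), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}
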