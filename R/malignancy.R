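#' Pool a patient's paired samples with the healthy reference
#'
#' Concatenates healthy, pre- and post-therapy matrices over their gene
#' intersection and records each cell's sample origin, the anchor set on
#' which co-clustering malignancy calling operates.
#'
#' @param healthy,pre,post \code{CellMatrix} objects
#' @return list with \code{cells} (combined \code{CellMatrix}; the metadata
#'   gains an \code{origin} column in \{healthy, pre, post\}) and
#'   \code{n_common_genes}
#' @export
compose_anchor_set <- function(healthy, pre, post) {
  for (m in list(healthy, pre, post))
    stopifnot(inherits(m, "CellMatrix"))
  combined <- bind_cells(healthy, pre, post)
  origin <- rep(c("healthy", "pre", "post"),
                c(nrow(healthy$counts), nrow(pre$counts), nrow(post$counts)))
  combined$cell_meta$origin <- origin
  list(cells = combined, n_common_genes = ncol(combined$counts))
}

#' Call leukemic clusters by pre-therapy composition
#'
#' A cluster is leukemic iff strictly more than \code{threshold} of its cells
#' originate from the pre-therapy sample. All cells of a leukemic cluster
#' inherit the call, including post-therapy cells (residual disease).
#' Clusters smaller than \code{min_cluster_size} are never called leukemic.
#'
#' @param clusters integer cluster labels covering all cells
#' @param origins character vector in \{healthy, pre, post\}, same length
#' @param threshold strict pre-therapy fraction cutoff (default 0.8)
#' @param min_cluster_size clusters below this size stay normal (default 10)
#' @return list of class \code{MalignancyCall}: \code{cluster_summary}
#'   (data.frame: cluster, n_cells, fraction_pre, call) and \code{cell_call}
#'   (character, "leukemic"/"normal" per cell)
#' @export
call_leukemic_clusters <- function(clusters, origins, threshold = 0.8,
                                   min_cluster_size = 10L) {
  if (length(clusters) != length(origins))
    stop("clusters and origins must align")
  if (!all(origins %in% c("healthy", "pre", "post")))
    stop("unknown origin label")
  cl <- sort(unique(clusters))
  summ <- do.call(rbind, lapply(cl, function(k) {
    sel <- clusters == k
    data.frame(cluster = k, n_cells = sum(sel),
               fraction_pre = mean(origins[sel] == "pre"))
  }))
  summ$call <- ifelse(summ$fraction_pre > threshold &
                        summ$n_cells >= min_cluster_size,
                      "leukemic", "normal")
  cell_call <- summ$call[match(clusters, summ$cluster)]
  structure(list(cluster_summary = summ, cell_call = cell_call,
                 clusters = clusters),
            class = "MalignancyCall")
}

#' Revise leukemic clusters resembling mature lymphoid cells
#'
#' Leukemic clusters whose majority projected cell type is a mature lymphoid
#' type are re-labelled normal; the operation never converts normal to
#' leukemic and is idempotent.
#'
#' @param call a \code{MalignancyCall}
#' @param cluster_types named character vector: cluster id -> majority
#'   projected type (must cover every leukemic cluster)
#' @param lymphoid_types types triggering revision
#' @return revised \code{MalignancyCall}
#' @export
revise_lymphoid <- function(call, cluster_types,
                            lymphoid_types = c("B", "CTL", "NK", "T")) {
  stopifnot(inherits(call, "MalignancyCall"))
  summ <- call$cluster_summary
  leuk <- summ$cluster[summ$call == "leukemic"]
  missing <- setdiff(as.character(leuk), names(cluster_types))
  if (length(missing))
    stop("missing projection for leukemic cluster(s): ",
         paste(missing, collapse = ", "))
  summ$projected_majority_type <- unname(
    cluster_types[as.character(summ$cluster)])
  revise <- summ$call == "leukemic" &
    summ$projected_majority_type %in% lymphoid_types
  summ$call[revise] <- "normal"
  call$cluster_summary <- summ
  call$cell_call <- summ$call[match(call$clusters, summ$cluster)]
  call
}

#' Per-origin residual-disease summary
#'
#' @param call a \code{MalignancyCall}
#' @param origins origin labels aligned with the call
#' @return data.frame per origin: \code{origin}, \code{n_leukemic},
#'   \code{n_total}, \code{fraction}
#' @export
summarize_residual <- function(call, origins) {
  stopifnot(inherits(call, "MalignancyCall"),
            length(origins) == length(call$cell_call))
  do.call(rbind, lapply(c("healthy", "pre", "post"), function(o) {
    sel <- origins == o
    data.frame(origin = o,
               n_leukemic = sum(call$cell_call[sel] == "leukemic"),
               n_total = sum(sel),
               fraction = if (any(sel))
                 mean(call$cell_call[sel] == "leukemic") else NA_real_)
  }))
}

#' Majority projected type per cluster
#'
#' Helper linking the projection result to [revise_lymphoid()]: the modal
#' assigned type among each cluster's cells (ties broken by type-name order).
#'
#' @param clusters cluster labels
#' @param assigned_types per-cell projected types
#' @return named character vector cluster -> majority type
#' @export
cluster_majority_type <- function(clusters, assigned_types) {
  stopifnot(length(clusters) == length(assigned_types))
  out <- vapply(sort(unique(clusters)), function(k) {
    tab <- sort(table(assigned_types[clusters == k]), decreasing = TRUE)
    names(tab)[order(-tab, names(tab))][1]
  }, "")
  names(out) <- sort(unique(clusters))
  out
}
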