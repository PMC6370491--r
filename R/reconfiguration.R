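# Node flexibility and promiscuity from multilayer partitions.

#' Node flexibility
#'
#' Fraction of possible between-window transitions at which a node changes
#' community: `f_i = m / (T - 1)` where `m` counts the layers `l` with
#' `g_il != g_i,l+1`.
#'
#' @param labels n x T community assignment matrix (T >= 2).
#' @return length-n numeric vector in `[0, 1]`.
#' @export
node_flexibility <- function(labels) {
  labels <- as.matrix(labels)
  t_l <- ncol(labels)
  if (t_l < 2L) stop_validation("flexibility needs at least 2 layers")
  changes <- labels[, -1L, drop = FALSE] != labels[, -t_l, drop = FALSE]
  rowSums(changes) / (t_l - 1L)
}

#' Node promiscuity
#'
#' Fraction of all communities a node ever joins: `psi_i = k_i / K`, where
#' `k_i` is the number of distinct communities node `i` participates in
#' and `K` is the total number of distinct communities anywhere in the
#' partition (all nodes, all layers).
#'
#' @param labels n x T community assignment matrix.
#' @return length-n numeric vector in `(0, 1]`.
#' @export
node_promiscuity <- function(labels) {
  labels <- as.matrix(labels)
  k_total <- length(unique(as.vector(labels)))
  k_i <- apply(labels, 1L, function(r) length(unique(r)))
  k_i / k_total
}

#' Average reconfiguration profile over optimization iterations
#'
#' Elementwise mean of per-iteration flexibility and promiscuity vectors
#' across the partitions of a [maximize_modularity()] run; the global
#' summaries F and Psi are node means of the averaged vectors.
#'
#' @param partitions a `dfc_partition_set` or list of partitions (each
#'   with an n x T `labels` matrix).
#' @return object of class `dfc_reconfiguration`: list with
#'   `flexibility`, `promiscuity` (length-n vectors), `global_F`,
#'   `global_Psi`, `n_iterations_averaged`.
#' @export
average_profiles <- function(partitions) {
  if (inherits(partitions, "dfc_partition_set")) {
    partitions <- partitions$partitions
  }
  stopifnot(length(partitions) >= 1L)
  shapes <- vapply(partitions, function(p) dim(as.matrix(p$labels)), integer(2))
  if (any(shapes[1L, ] != shapes[1L, 1L]) ||
      any(shapes[2L, ] != shapes[2L, 1L])) {
    stop_validation("partitions have inconsistent label shapes")
  }
  f <- rowMeans(vapply(partitions, function(p) node_flexibility(p$labels),
                       numeric(shapes[1L, 1L])))
  psi <- rowMeans(vapply(partitions, function(p) node_promiscuity(p$labels),
                         numeric(shapes[1L, 1L])))
  structure(list(
    flexibility = f,
    promiscuity = psi,
    global_F = mean(f),
    global_Psi = mean(psi),
    n_iterations_averaged = length(partitions)
  ), class = "dfc_reconfiguration")
}
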