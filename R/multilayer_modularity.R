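# Multilayer modularity: quality function, Newman-Girvan intralayer null,
# generalized Louvain maximization, and an exhaustive oracle for small
# instances.

#' Construct a multilayer network from an ordered set of layers
#'
#' Layers are symmetric nonnegative intralayer weight matrices (zero
#' diagonal), coupled by identity edges of weight `omega` that connect a
#' node in one layer to itself in the adjacent (neighboring) layers only.
#'
#' @param layers a `dfc_stack`, a list of n x n matrices, or a T x n x n
#'   array.
#' @param omega interlayer identity-edge weight (>= 0, default 1).
#' @return object of class `dfc_multilayer`: list with `layers` (list of
#'   matrices), `n`, `n_layers`, `omega`.
#' @export
multilayer_network <- function(layers, omega = 1) {
  if (inherits(layers, "dfc_stack")) {
    if (layers$negative_policy != "zero") {
      stop_validation(
        "multilayer modularity needs nonnegative layers; build the stack %s",
        "with negative_policy = 'zero'")
    }
    layers <- lapply(seq_len(dim(layers$z)[1L]),
                     function(w) layers$z[w, , ])
  }
  if (is.array(layers) && length(dim(layers)) == 3L) {
    layers <- lapply(seq_len(dim(layers)[1L]), function(w) layers[w, , ])
  }
  stopifnot(is.list(layers), length(layers) >= 1L)
  if (omega < 0) stop_validation("omega must be >= 0")
  n <- nrow(layers[[1L]])
  for (l in seq_along(layers)) {
    a <- layers[[l]]
    if (!is_square_sym(a) || nrow(a) != n) {
      stop_validation("layer %d is not a symmetric %d x %d matrix", l, n, n)
    }
    if (any(a < 0)) stop_validation("layer %d has negative weights", l)
    if (any(diag(a) != 0)) stop_validation("layer %d has nonzero diagonal", l)
  }
  structure(list(layers = layers, n = n, n_layers = length(layers),
                 omega = omega), class = "dfc_multilayer")
}

#' Newman-Girvan null model of one layer
#'
#' Expected edge weight under the configuration-style null:
#' `P_ij = k_i * k_j / (2m)` from the intralayer strengths. A layer with
#' zero total weight yields a zero null matrix with a warning.
#'
#' @param layer symmetric nonnegative n x n matrix.
#' @return n x n null-model matrix.
#' @export
newman_girvan_null <- function(layer) {
  stopifnot(is_square_sym(layer))
  k <- rowSums(layer)
  two_m <- sum(k)
  if (two_m <= 0) {
    warning("layer has zero total weight; null model is zero")
    return(matrix(0, nrow(layer), ncol(layer)))
  }
  outer(k, k) / two_m
}

# Total multilayer edge weight mu = sum of intralayer weights plus
# omega * n * (T - 1) from the ordinal identity coupling.
multilayer_mu <- function(network) {
  mu_intra <- sum(vapply(network$layers, sum, 0)) / 2
  mu_intra + network$omega * network$n * (network$n_layers - 1L)
}

# Dense supra-modularity matrix: block diagonal (A_l - gamma * P_l) plus
# omega on the identity coupling between adjacent layers. Slots are
# flattened layer-major: slot = (l - 1) * n + i.
supra_modularity_matrix <- function(network, gamma = 1) {
  n <- network$n
  t_l <- network$n_layers
  b <- matrix(0, n * t_l, n * t_l)
  for (l in seq_len(t_l)) {
    idx <- (l - 1L) * n + seq_len(n)
    p <- suppressWarnings(newman_girvan_null(network$layers[[l]]))
    gl <- if (length(gamma) > 1L) gamma[l] else gamma
    b[idx, idx] <- network$layers[[l]] - gl * p
    if (l < t_l) {
      nxt <- l * n + seq_len(n)
      b[cbind(idx, nxt)] <- network$omega
      b[cbind(nxt, idx)] <- network$omega
    }
  }
  b
}

canonicalize_labels <- function(labels) {
  u <- unique(as.vector(labels))
  out <- match(as.vector(labels), u)
  if (is.matrix(labels)) out <- matrix(out, nrow(labels), ncol(labels))
  out
}

#' Multilayer modularity quality Q of a partition
#'
#' Evaluates
#' `Q = (1 / 2mu) * sum_{ijlr} [(A_ijl - gamma_l P_ijl) delta_lr +
#' delta_ij omega_jlr] delta(g_il, g_jr)` with the Newman-Girvan
#' intralayer null and ordinal (adjacent-layer) identity coupling, where
#' `mu` is the total multilayer edge weight.
#'
#' @param network a `dfc_multilayer`.
#' @param labels n x T community assignment matrix.
#' @param gamma structural resolution parameter, scalar or per-layer
#'   vector (default 1).
#' @return the quality value Q.
#' @export
modularity_quality <- function(network, labels, gamma = 1) {
  stopifnot(inherits(network, "dfc_multilayer"))
  labels <- as.matrix(labels)
  if (nrow(labels) != network$n || ncol(labels) != network$n_layers) {
    stop_validation("labels must be %d x %d", network$n, network$n_layers)
  }
  if (any(gamma <= 0)) stop_validation("gamma must be positive")
  mu <- multilayer_mu(network)
  if (mu <= 0) stop_validation("total multilayer weight mu must be positive")
  q_raw <- 0
  for (l in seq_len(network$n_layers)) {
    p <- suppressWarnings(newman_girvan_null(network$layers[[l]]))
    gl <- if (length(gamma) > 1L) gamma[l] else gamma
    b <- network$layers[[l]] - gl * p
    same <- outer(labels[, l], labels[, l], "==")
    q_raw <- q_raw + sum(b[same])
    if (l < network$n_layers) {
      q_raw <- q_raw +
        2 * network$omega * sum(labels[, l] == labels[, l + 1L])
    }
  }
  q_raw / (2 * mu)
}

#' Maximize multilayer modularity by generalized Louvain
#'
#' Runs the nondeterministic generalized Louvain heuristic
#' `n_iterations` times with derived seeds (randomized node sweep order;
#' greedy single-slot moves on the modularity gain, aggregation, repeat
#' until no gain exceeds `tol`), and reports every partition together with
#' its quality and the mean Q across iterations.
#'
#' @param network a `dfc_multilayer`.
#' @param gamma structural resolution (default 1).
#' @param n_iterations number of restarts (default 100).
#' @param seed integer seed; iteration `i` uses a seed derived from it.
#' @param tol minimum quality gain for a move (default 1e-10).
#' @return object of class `dfc_partition_set`: list with `partitions`
#'   (each: `labels` n x T, `Q`, `iteration`), `Q_values`, `mean_Q`,
#'   `best` (index of the best iteration).
#' @export
maximize_modularity <- function(network, gamma = 1, n_iterations = 100L,
                                seed = 1L, tol = 1e-10) {
  stopifnot(inherits(network, "dfc_multilayer"))
  n_iterations <- assert_count(n_iterations, "n_iterations")
  b <- supra_modularity_matrix(network, gamma)
  n <- network$n
  t_l <- network$n_layers
  partitions <- vector("list", n_iterations)
  q_values <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(derive_seed(seed, it))
    lab <- .louvain_dense(b, tol)
    labels <- canonicalize_labels(matrix(lab, n, t_l))
    q <- modularity_quality(network, labels, gamma)
    partitions[[it]] <- list(labels = labels, Q = q, iteration = it)
    q_values[it] <- q
  }
  structure(list(
    partitions = partitions,
    Q_values = q_values,
    mean_Q = mean(q_values),
    best = which.max(q_values)
  ), class = "dfc_partition_set")
}

#' Exhaustive multilayer modularity maximum (small-instance oracle)
#'
#' Enumerates every set partition of the `n * T` node-layer slots
#' (restricted growth strings) and returns the partition with the highest
#' quality. Limited to `n * T <= 12` slots.
#'
#' @param network a `dfc_multilayer`.
#' @param gamma structural resolution (default 1).
#' @return list with `Q` (the optimum) and `labels` (n x T, canonical).
#' @export
brute_force_max <- function(network, gamma = 1) {
  stopifnot(inherits(network, "dfc_multilayer"))
  n_slots <- network$n * network$n_layers
  if (n_slots > 12L) {
    stop_validation("exhaustive search limited to n * T <= 12 (got %d)",
                    n_slots)
  }
  b <- supra_modularity_matrix(network, gamma)
  res <- .brute_force_partition(b)
  labels <- canonicalize_labels(matrix(res$labels, network$n,
                                       network$n_layers))
  list(Q = modularity_quality(network, labels, gamma), labels = labels)
}
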