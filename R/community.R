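# Weighted Newman-Girvan modularity and a from-scratch Louvain
# implementation; a brute-force exact oracle over all set partitions backs
# both in the tests.
#
# Conventions: W is a symmetric non-negative weight matrix whose diagonal
# holds self-loop weight (full contribution, so strength s_i = sum_j W_ij
# and total weight 2m = sum_ij W_ij). With these conventions aggregation is
# exact: summing W over community blocks preserves modularity identically.

.as_weight_matrix <- function(x) {
  if (inherits(x, "disease_network")) return(net_weight_matrix(x))
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("weight matrix must be square")
    if (nrow(x) > 0 && max(abs(x - t(x))) > 1e-12) {
      stop("weight matrix must be symmetric")
    }
    if (is.null(rownames(x))) {
      dimnames(x) <- list(as.character(seq_len(nrow(x))),
                          as.character(seq_len(nrow(x))))
    }
    return(x)
  }
  stop("expected a disease_network or a symmetric weight matrix")
}

.modularity_W <- function(W, comm, resolution = 1) {
  tw <- sum(W)                       # 2m
  if (tw <= 0) return(0)
  s <- rowSums(W)
  same <- outer(comm, comm, "==")
  sum((W - resolution * outer(s, s) / tw) * same) / tw
}

.canon_comm <- function(comm) {
  # contiguous ids from 0, numbered by first appearance
  match(comm, unique(comm)) - 1L
}

#' Weighted modularity of a partition
#'
#' Newman-Girvan modularity at resolution \eqn{\gamma}:
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(w_{ij} - \gamma \frac{s_i s_j}{2m}\right) [c_i = c_j],}
#' with \eqn{s_i} the weighted degree and \eqn{2m} the total weight. It
#' compares the density of edges inside communities to the expectation under
#' a degree-preserving null, so a single all-inclusive community always
#' scores 0 and \eqn{Q \in [-1/2, 1)}. An edgeless graph scores 0 by
#' convention.
#'
#' @param x A `disease_network` or a symmetric non-negative weight matrix.
#' @param partition A [partition] object, or a vector of community ids in
#'   node order (or named by node).
#' @param resolution Resolution \eqn{\gamma}, default 1 (classic
#'   modularity).
#' @return The modularity score.
#' @export
modularity_q <- function(x, partition, resolution = 1) {
  W <- .as_weight_matrix(x)
  comm <- if (inherits(partition, "partition")) partition$assignment else partition
  if (!is.null(names(comm))) {
    miss <- setdiff(rownames(W), names(comm))
    if (length(miss)) stop("partition is missing node(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    comm <- comm[rownames(W)]
  } else if (length(comm) != nrow(W)) {
    stop("partition is missing nodes: expected ", nrow(W), " assignments")
  }
  .modularity_W(W, as.integer(comm), resolution)
}

.new_partition <- function(assignment, q) {
  structure(list(assignment = assignment, q = q), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(x$assignment))
  cat(sprintf("Partition: %d nodes in %d communities, Q = %.4f\n",
              length(x$assignment), k, x$q))
  invisible(x)
}

# One Louvain level: local moves on Wl until no single-node move improves
# modularity. Returns the community vector. `next_order` supplies the node
# visit order for each sweep.
.louvain_local <- function(Wl, resolution, next_order) {
  nl <- nrow(Wl)
  comm <- seq_len(nl)
  tw <- sum(Wl)
  m <- tw / 2
  s <- rowSums(Wl)
  Stot <- s
  q_prev <- .modularity_W(Wl, comm, resolution)
  repeat {
    moved <- FALSE
    ord <- next_order(nl)
    for (i in ord) {
      ci <- comm[i]
      ki <- Wl[i, ]
      # candidates: own community, neighboring communities, and (when the
      # node is not already alone) a fresh empty community so a node can
      # detach if every attachment has negative gain
      nbr <- which(ki > 0 & seq_len(nl) != i)
      cand <- unique(c(ci, comm[nbr]))
      empty <- setdiff(seq_len(nl), comm)
      if (length(empty) && sum(comm == ci) > 1L) {
        cand <- c(cand, min(empty))
      }
      kc <- vapply(cand, function(cc) sum(ki[comm == cc & seq_len(nl) != i]),
                   numeric(1))
      sc <- Stot[cand] - ifelse(cand == ci, s[i], 0)
      gain <- kc / m - resolution * s[i] * sc / (2 * m^2)
      cur <- gain[cand == ci]
      better <- which(gain > cur + 1e-13)
      if (length(better)) {
        best <- better[gain[better] >= max(gain[better]) - 1e-13]
        target <- min(cand[best])   # lowest community id among tied best
        Stot[ci] <- Stot[ci] - s[i]
        Stot[target] <- Stot[target] + s[i]
        comm[i] <- target
        moved <- TRUE
      }
    }
    # monotone improvement across sweeps is a structural guarantee of the
    # move rule; verify it rather than assume it
    q_now <- .modularity_W(Wl, comm, resolution)
    if (q_now < q_prev - 1e-9) {
      stop("internal error: modularity decreased during a Louvain sweep")
    }
    q_prev <- q_now
    if (!moved) break
  }
  comm
}

.louvain_W <- function(W, resolution = 1, gain_tol = 1e-10, orders = NULL) {
  n0 <- nrow(W)
  membership <- seq_len(n0)
  if (sum(W) <= 0) {
    return(.new_partition(
      stats::setNames(.canon_comm(membership), rownames(W)), 0))
  }
  order_idx <- 0L
  next_order <- function(nl) {
    if (is.null(orders)) return(sample.int(nl))
    order_idx <<- order_idx + 1L
    o <- orders[[min(order_idx, length(orders))]]
    o[o <= nl]
  }
  Wl <- W
  q_best <- .modularity_W(W, membership, resolution)
  repeat {
    comm <- .louvain_local(Wl, resolution, next_order)
    comm <- match(comm, sort(unique(comm)))
    membership_new <- comm[membership]
    q_new <- .modularity_W(W, membership_new, resolution)
    if (q_new <= q_best + gain_tol) break
    membership <- membership_new
    q_best <- q_new
    # phase 2: aggregate communities into super-nodes
    Wagg <- rowsum(t(rowsum(Wl, comm)), comm)
    # aggregation must preserve modularity exactly
    q_agg <- .modularity_W(Wagg, seq_len(nrow(Wagg)), resolution)
    q_lvl <- .modularity_W(Wl, comm, resolution)
    if (abs(q_agg - q_lvl) > 1e-9) {
      stop("internal error: aggregation changed modularity")
    }
    if (nrow(Wagg) == nrow(Wl)) break
    Wl <- Wagg
  }
  .new_partition(stats::setNames(.canon_comm(membership), rownames(W)), q_best)
}

#' Louvain community detection
#'
#' Extracts disease patterns by modularity optimization: phase 1 repeatedly
#' moves single nodes to the neighboring community with the largest positive
#' modularity gain (keeping the current community on ties, otherwise taking
#' the lowest community id); phase 2 aggregates communities into super-nodes
#' and repeats, until a full pass improves modularity by less than
#' `gain_tol`. The node visit order is shuffled under `seed`, and the same
#' seed always yields the same partition. Nodes are processed in
#' name-canonical order internally, so relabelling or reordering the nodes
#' changes nothing but the labels of the result. The returned modularity is
#' always at least that of the all-singletons start.
#'
#' Edge weights must be non-negative (the network builder's default of
#' positive-correlation edges guarantees this); negative weights are
#' rejected because modularity on signed graphs is a different method.
#'
#' @param x A `disease_network` or symmetric non-negative weight matrix.
#' @param seed Integer seed for the node visit order; `NULL` uses the
#'   current RNG state.
#' @param resolution Modularity resolution, default 1.
#' @param gain_tol Minimum absolute modularity improvement to continue.
#' @param n_restarts Number of independent seeded runs; the best-modularity
#'   partition is returned (seeds `seed, seed+1, ...`).
#' @param orders Internal: explicit list of visit orders, overriding the
#'   seeded shuffle (used for equivariance testing).
#' @return A `partition`: named assignment (community ids contiguous from 0)
#'   plus its modularity `q`.
#' @export
louvain <- function(x, seed = NULL, resolution = 1, gain_tol = 1e-10,
                    n_restarts = 1L, orders = NULL) {
  W <- .as_weight_matrix(x)
  if (nrow(W) == 0) stop("graph must contain at least one node")
  if (min(W) < 0) stop("negative edge weights are not supported by modularity optimization")
  # canonicalize on node names so the result is equivariant under node
  # relabelling: the seeded visit order and all index-based tie-breaks then
  # depend only on names, never on input order
  ord <- order(rownames(W))
  W <- W[ord, ord, drop = FALSE]
  run1 <- function(sd) {
    if (!is.null(orders)) return(.louvain_W(W, resolution, gain_tol, orders))
    if (is.null(sd)) return(.louvain_W(W, resolution, gain_tol))
    withr::with_seed(as.integer(sd), .louvain_W(W, resolution, gain_tol))
  }
  if (n_restarts <= 1L || !is.null(orders)) return(run1(seed))
  base <- if (is.null(seed)) 0L else as.integer(seed)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    p <- run1(base + k - 1L)
    if (is.null(best) || p$q > best$q) best <- p
  }
  best
}

# Enumerate all set partitions of n items as restricted growth strings and
# return the best modularity partition. Bell(10) = 115975, the practical
# ceiling for this oracle.
.enumerate_partitions <- function(n, fun) {
  labels <- integer(n)
  rec <- function(i, maxlab) {
    if (i > n) {
      fun(labels)
      return(invisible(NULL))
    }
    for (lab in seq_len(maxlab + 1L)) {
      labels[i] <<- lab
      rec(i + 1L, max(maxlab, lab))
    }
  }
  rec(1L, 0L)
}

#' Exact maximum-modularity partition by exhaustive enumeration
#'
#' Enumerates every set partition of the nodes (Bell-number loop over
#' restricted growth strings) and returns one achieving the maximum
#' modularity. Exponential: refused above `max_nodes` nodes. This is the
#' test oracle against which the Louvain heuristic is validated.
#'
#' @param x A `disease_network` or symmetric non-negative weight matrix.
#' @param max_nodes Hard cap on node count (Bell(10) = 115,975 partitions).
#' @param resolution Modularity resolution.
#' @return A `partition` attaining the exact optimum.
#' @export
brute_force_best_partition <- function(x, max_nodes = 10L, resolution = 1) {
  W <- .as_weight_matrix(x)
  n <- nrow(W)
  if (n == 0) stop("graph must contain at least one node")
  if (n > max_nodes) {
    stop("brute-force enumeration refused for ", n, " nodes (max ", max_nodes, ")")
  }
  tw <- sum(W)
  if (tw <= 0) {
    return(.new_partition(stats::setNames(seq_len(n) - 1L, rownames(W)), 0))
  }
  s <- rowSums(W)
  B <- W - resolution * outer(s, s) / tw   # modularity kernel
  best_q <- -Inf
  best <- NULL
  .enumerate_partitions(n, function(labels) {
    q <- sum(B[outer(labels, labels, "==")]) / tw
    if (q > best_q) {
      best_q <<- q
      best <<- labels
    }
  })
  .new_partition(stats::setNames(.canon_comm(best), rownames(W)), best_q)
}

#' Write a partition as TSV
#'
#' @param part A [partition] (e.g. from [louvain()]).
#' @param path Output file; columns `disease`, `community`.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(part, path) {
  stopifnot(inherits(part, "partition"))
  utils::write.table(
    data.frame(disease = names(part$assignment),
               community = unname(part$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
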