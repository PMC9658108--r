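# Per-stratum disease networks: nodes are prevalent diseases, edges are
# statistically significant tetrachoric correlations.

#' Drop diseases at or below a prevalence floor
#'
#' Keeps only diseases whose stratum prevalence is strictly greater than
#' `min_prev` (the study convention "prevalence > 1%" with the default).
#' Removing every disease yields an empty matrix with a warning, not an
#' error, so multi-stratum runs continue.
#'
#' @param dm A [disease_matrix()].
#' @param min_prev Prevalence floor, default 0.01.
#' @return The restricted [disease_matrix()].
#' @export
prevalence_filter <- function(dm, min_prev = 0.01) {
  stopifnot(inherits(dm, "disease_matrix"))
  keep <- prevalence(dm) > min_prev
  if (!any(keep)) {
    warning(sprintf("stratum %s %s: no disease exceeds prevalence %g; network will be empty",
                    dm$sex, dm$age_band, min_prev))
  }
  disease_matrix(dm$indicators[, keep, drop = FALSE],
                 sex = dm$sex, age_band = dm$age_band)
}

#' Build the comorbidity network of one stratum
#'
#' For every unordered disease pair, tabulates joint presence/absence,
#' estimates the tetrachoric correlation, and adds an edge when the
#' zero-correlation test rejects at `alpha`. By default only positive
#' correlations become edges (comorbidity is co-occurrence); set
#' `include_negative = TRUE` to admit negative edges, which then carry
#' \eqn{|\hat\rho|} as their weight. Isolated diseases remain as edge-less
#' nodes. Pairs whose estimation fails (e.g. a degenerate margin) are
#' skipped and recorded in the `skipped` field, never fatal.
#'
#' @param dm A prevalence-filtered [disease_matrix()].
#' @param alpha Significance level for edge inclusion, default 0.01.
#' @param include_negative Admit negative significant correlations as edges.
#' @return A `disease_network`: list with `sex`, `age_band`, `n_patients`,
#'   `nodes` (data frame `disease`, `prevalence`), `edges` (data frame
#'   `from`, `to`, `rho`, `p_value`, `weight`), `alpha`, `skipped`.
#' @export
build_network <- function(dm, alpha = 0.01, include_negative = FALSE) {
  stopifnot(inherits(dm, "disease_matrix"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  ind <- dm$indicators
  prev <- prevalence(dm)
  diseases <- colnames(ind)
  D <- length(diseases)

  edges <- data.frame(from = character(), to = character(), rho = numeric(),
                      p_value = numeric(), weight = numeric(),
                      stringsAsFactors = FALSE)
  skipped <- data.frame(from = character(), to = character(),
                        reason = character(), stringsAsFactors = FALSE)
  if (D >= 2) {
    cross <- crossprod(ind)          # n11 for every pair
    npos <- diag(cross)
    n <- nrow(ind)
    for (i in seq_len(D - 1)) {
      for (j in (i + 1):D) {
        n11 <- cross[i, j]
        tab <- try(contingency_table(n11, npos[i] - n11, npos[j] - n11,
                                     n - npos[i] - npos[j] + n11),
                   silent = TRUE)
        fit <- if (inherits(tab, "try-error")) tab else {
          try(estimate_tetrachoric(tab), silent = TRUE)
        }
        if (inherits(fit, "try-error")) {
          skipped <- rbind(skipped,
                           data.frame(from = diseases[i], to = diseases[j],
                                      reason = trimws(conditionMessage(attr(fit, "condition"))),
                                      stringsAsFactors = FALSE))
          next
        }
        if (fit$p_value < alpha && (fit$rho > 0 || include_negative)) {
          edges <- rbind(edges,
                         data.frame(from = diseases[i], to = diseases[j],
                                    rho = fit$rho, p_value = fit$p_value,
                                    weight = abs(fit$rho),
                                    stringsAsFactors = FALSE))
        }
      }
    }
  }
  structure(list(sex = dm$sex, age_band = dm$age_band,
                 n_patients = nrow(ind),
                 nodes = data.frame(disease = diseases,
                                    prevalence = unname(prev),
                                    stringsAsFactors = FALSE),
                 edges = edges, alpha = alpha, skipped = skipped),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("Disease network, stratum %s %s: %d nodes, %d edges (n = %d, alpha = %g)\n",
              x$sex, x$age_band, nrow(x$nodes), nrow(x$edges),
              x$n_patients, x$alpha))
  invisible(x)
}

#' Convert a disease network to an igraph graph
#'
#' Nodes carry `prevalence`; edges carry `rho`, `p_value` and `weight`;
#' stratum metadata becomes graph attributes.
#'
#' @param net A [build_network()] result.
#' @return An undirected [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g <- igraph::set_graph_attr(g, "sex", net$sex)
  g <- igraph::set_graph_attr(g, "age_band", net$age_band)
  g <- igraph::set_graph_attr(g, "n_patients", net$n_patients)
  g
}

# Symmetric non-negative weight matrix of a network, nodes in node-table
# order. Edge weight is the (absolute) tetrachoric correlation.
net_weight_matrix <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  d <- net$nodes$disease
  W <- matrix(0, length(d), length(d), dimnames = list(d, d))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, d)
    j <- match(net$edges$to, d)
    W[cbind(i, j)] <- net$edges$weight
    W[cbind(j, i)] <- net$edges$weight
  }
  W
}
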