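# Shared fixtures, generated in code.

# Two disjoint unit-weight triangles on nodes a..f.
two_triangles <- function() {
  W <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    W[p[1], p[2]] <- 1
    W[p[2], p[1]] <- 1
  }
  W
}

# Random Erdos-Renyi weighted graph with continuous (tie-free) weights.
random_weighted_graph <- function(n, p_edge = 0.45) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w <- stats::runif(1)
        A[i, j] <- w
        A[j, i] <- w
      }
    }
  }
  dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  A
}

# A small planted three-block cohort spec; prevalences spread over
# (0.05, 0.25) so every disease clears the 1% node filter.
planted_spec <- function(n_per_stratum, seed, n_blocks = 3, per_block = 8,
                         sexes = c("M", "F"), bands = age_bands(),
                         rho_within = 0.5) {
  D <- n_blocks * per_block
  diseases <- do.call(rbind, lapply(seq_len(D), function(i) {
    disease_spec(sprintf("D%02d", i),
                 prevalence = 0.05 + 0.2 * ((i - 1) %% per_block) / (per_block - 1),
                 block_id = (i - 1) %/% per_block + 1)
  }))
  strata <- expand.grid(sex = sexes, age_band = bands,
                        stringsAsFactors = FALSE)
  strata$n_patients <- n_per_stratum
  cohort_spec(strata, diseases, rho_within = rho_within, rho_between = 0,
              seed = seed)
}

# Toy code lookup: 6 codes, 4 categories, codes C5/C6 not chronic.
toy_lookup <- function() {
  code_lookup(
    chronic = data.frame(
      code = paste0("C", 1:6),
      chronic_flag = c("chronic", "chronic", "chronic", "chronic",
                       "not_chronic", "not_chronic")),
    category = data.frame(
      code = paste0("C", 1:6),
      category_id = c(1L, 2L, 3L, 4L, 1L, 2L),
      category_label = c("asthma", "rhinitis", "anxiety", "obesity",
                         "asthma", "rhinitis")))
}

write_records_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
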