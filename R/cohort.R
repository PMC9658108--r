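# Synthetic stratified cohorts from a latent-Gaussian threshold model.
#
# Each patient carries a latent multivariate normal vector with a planted
# block-correlation structure; disease j is recorded present when the latent
# value exceeds the (1 - prevalence_j) standard-normal quantile. The
# tetrachoric estimator is exactly the inverse of this generator, so
# parameter recovery is a valid end-to-end test of the whole pipeline.

#' Canonical age bands
#'
#' The five age intervals used for stratification: 0-2, 3-10, 11-17, 18-65,
#' and >65 years (inclusive integer bounds; 65 falls in 18-65).
#'
#' @return Character vector of the five band labels.
#' @export
age_bands <- function() c("0-2", "3-10", "11-17", "18-65", ">65")

#' Assign an age in years to its band
#'
#' @param age Numeric ages in years (fractional ages are floored).
#' @return Factor of band labels with levels [age_bands()].
#' @export
assign_age_band <- function(age) {
  if (any(!is.finite(age)) || any(age < 0)) stop("ages must be finite and non-negative")
  a <- floor(age)
  band <- ifelse(a <= 2, "0-2",
          ifelse(a <= 10, "3-10",
          ifelse(a <= 17, "11-17",
          ifelse(a <= 65, "18-65", ">65"))))
  factor(band, levels = age_bands())
}

.norm_band <- function(x) {
  # tolerate en-dashes from copy-pasted tables
  gsub("–|—", "-", trimws(x))
}

#' Specification of one synthetic disease
#'
#' @param disease_id Short unique label.
#' @param prevalence Target marginal prevalence, strictly in (0, 1).
#' @param block_id Integer community label; diseases sharing a block are
#'   latently correlated at `rho_within`, cross-block pairs at `rho_between`.
#' @return A one-row data frame; rows from several calls can be combined
#'   with `rbind()` and passed to [cohort_spec()].
#' @export
disease_spec <- function(disease_id, prevalence, block_id) {
  data.frame(disease_id = as.character(disease_id),
             prevalence = as.numeric(prevalence),
             block_id = as.integer(block_id),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic stratified cohort
#'
#' Defines the study conditions for the generator: the sex-by-age strata and
#' their sizes, the disease list with target prevalences and planted blocks,
#' and the two latent correlation levels. The implied latent correlation
#' matrix must be positive definite; the spec is rejected otherwise.
#'
#' @param strata Data frame with columns `sex` (`"M"`/`"F"`), `age_band`
#'   (one of [age_bands()]) and `n_patients` (positive integer).
#' @param diseases Data frame with columns `disease_id`, `prevalence`,
#'   `block_id` (see [disease_spec()]).
#' @param rho_within Latent correlation for same-block pairs, in `[0, 1)`.
#' @param rho_between Latent correlation for cross-block pairs (default 0).
#' @param seed Master integer seed; every stratum draws from its own
#'   substream derived deterministically from this seed and the stratum
#'   label.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(strata, diseases, rho_within = 0.5, rho_between = 0,
                        seed = 1L) {
  stopifnot(is.data.frame(strata), is.data.frame(diseases))
  req <- setdiff(c("sex", "age_band", "n_patients"), names(strata))
  if (length(req)) stop("strata is missing column(s): ", paste(req, collapse = ", "))
  req <- setdiff(c("disease_id", "prevalence", "block_id"), names(diseases))
  if (length(req)) stop("diseases is missing column(s): ", paste(req, collapse = ", "))
  if (nrow(strata) == 0) stop("strata must contain at least one stratum")
  if (nrow(diseases) == 0) stop("diseases must contain at least one disease")
  strata$age_band <- .norm_band(strata$age_band)
  if (!all(strata$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (!all(strata$age_band %in% age_bands())) {
    stop("age_band must be one of: ", paste(age_bands(), collapse = ", "))
  }
  if (any(strata$n_patients < 1 | strata$n_patients != round(strata$n_patients))) {
    stop("n_patients must be positive integers")
  }
  if (anyDuplicated(strata[c("sex", "age_band")])) stop("duplicate strata")
  if (anyDuplicated(diseases$disease_id)) stop("disease_ids must be unique")
  if (any(diseases$prevalence <= 0 | diseases$prevalence >= 1)) {
    stop("prevalences must lie strictly in (0, 1)")
  }
  spec <- structure(list(strata = strata, diseases = diseases,
                         rho_within = rho_within, rho_between = rho_between,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  build_latent_sigma(spec)  # rejects non-positive-definite specs
  spec
}

#' Latent correlation matrix implied by a cohort spec
#'
#' Builds the diseases-by-diseases correlation matrix of the latent Gaussian:
#' unit diagonal, `rho_within` for same-block pairs, `rho_between` otherwise.
#' Positive definiteness is verified; a spec whose parameters imply a
#' non-positive-definite matrix (e.g. a strongly negative `rho_within` in a
#' block of 3 or more diseases) is rejected.
#'
#' @param spec A [cohort_spec()].
#' @return The correlation matrix with disease ids as dimnames.
#' @export
build_latent_sigma <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  blocks <- spec$diseases$block_id
  same <- outer(blocks, blocks, "==")
  sigma <- ifelse(same, spec$rho_within, spec$rho_between)
  diag(sigma) <- 1
  dimnames(sigma) <- list(spec$diseases$disease_id, spec$diseases$disease_id)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop(sprintf(paste0("latent correlation matrix is not positive definite ",
                        "(min eigenvalue %.3g) for rho_within = %g, ",
                        "rho_between = %g with block sizes %s"),
                 min(ev), spec$rho_within, spec$rho_between,
                 paste(table(blocks), collapse = "/")))
  }
  sigma
}

.band_code <- c("0-2" = "00to02", "3-10" = "03to10", "11-17" = "11to17",
                "18-65" = "18to65", ">65" = "gt65")

# Deterministic per-stratum substream seed: a small polynomial hash of the
# stratum label folded into the master seed, kept below 2^31.
stratum_seed <- function(seed, sex, age_band) {
  lab <- paste0(sex, ":", age_band)
  h <- sum(utf8ToInt(lab) * (31L^(seq_along(utf8ToInt(lab)) %% 5L))) %% 1000003L
  as.integer((as.numeric(seed) * 69911 + h) %% 2147483647)
}

#' Generate a synthetic stratified cohort
#'
#' For each stratum, draws `n_patients` i.i.d. latent normal vectors with
#' covariance [build_latent_sigma()] (via the upper Cholesky factor applied
#' to a column-major matrix of standard normals -- this fixes the generator
#' stream order) and thresholds disease j at the `(1 - prevalence_j)`
#' standard-normal quantile: indicator 1 means latent value above threshold.
#' Strata are generated independently from per-stratum substreams, so the
#' same spec and seed always reproduce the same cohort, even if strata are
#' subset or reordered.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `matrices` (one [disease_matrix]
#'   per stratum, named `"<sex>:<age_band>"`) and `truth` (the ground-truth
#'   record: `sigma`, `blocks`, `thresholds`, `seed`, per-stratum seeds).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sigma <- build_latent_sigma(spec)
  L <- chol(sigma)
  thresholds <- stats::qnorm(1 - spec$diseases$prevalence)
  names(thresholds) <- spec$diseases$disease_id
  D <- nrow(spec$diseases)

  matrices <- list()
  seeds <- integer(0)
  for (r in seq_len(nrow(spec$strata))) {
    sex <- spec$strata$sex[r]
    band <- spec$strata$age_band[r]
    n <- spec$strata$n_patients[r]
    sseed <- stratum_seed(spec$seed, sex, band)
    X <- withr::with_seed(sseed, matrix(stats::rnorm(n * D), n, D) %*% L)
    ind <- (X > matrix(thresholds, n, D, byrow = TRUE)) + 0L
    colnames(ind) <- spec$diseases$disease_id
    rownames(ind) <- sprintf("%s_%s_p%05d", sex, .band_code[[band]], seq_len(n))
    key <- paste0(sex, ":", band)
    matrices[[key]] <- disease_matrix(ind, sex = sex, age_band = band)
    seeds[key] <- sseed
  }
  blocks <- spec$diseases$block_id
  names(blocks) <- spec$diseases$disease_id
  structure(list(matrices = matrices,
                 truth = list(sigma = sigma, blocks = blocks,
                              thresholds = thresholds, seed = spec$seed,
                              stratum_seeds = seeds,
                              rho_within = spec$rho_within,
                              rho_between = spec$rho_between)),
            class = "synthetic_cohort")
}

#' Simulate one median-split disease pair
#'
#' Draws `n` latent bivariate normal pairs with correlation `rho`, thresholds
#' both at 0 (prevalence 1/2), and tabulates the four joint outcomes. Under
#' this design the expected joint-presence fraction has the closed form
#' \eqn{1/4 + \arcsin(\rho)/(2\pi)}, which makes the pair a convenient
#' calibration harness for the tetrachoric estimator.
#'
#' @param rho Latent correlation, `|rho| < 1`.
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return A [contingency_table()].
#' @export
median_split_pair <- function(rho, n, seed = 1L) {
  if (!is.finite(rho) || abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1")
  withr::with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    a <- z1 > 0
    b <- z2 > 0
    contingency_table(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
  })
}

#' Write a synthetic cohort as delimited text plus a ground-truth sidecar
#'
#' Writes `records.tsv` (dense long format: `patient_id`, `sex`, `age_band`,
#' `disease_id`, `indicator`, one row per patient-disease combination) and
#' `truth.json` (latent sigma parameters, block labels, thresholds, seeds)
#' into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$matrices, function(dm) {
    ind <- dm$indicators
    data.frame(patient_id = rep(rownames(ind), times = ncol(ind)),
               sex = dm$sex, age_band = dm$age_band,
               disease_id = rep(colnames(ind), each = nrow(ind)),
               indicator = as.integer(ind),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(long, file.path(dir, "records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$sigma <- as.data.frame(truth$sigma)
  # named vectors must become JSON objects, not bare arrays
  truth$blocks <- as.list(truth$blocks)
  truth$thresholds <- as.list(truth$thresholds)
  truth$stratum_seeds <- as.list(truth$stratum_seeds)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `records.tsv` and `truth.json`.
#' @return A `synthetic_cohort` equal to the one written.
#' @export
read_cohort <- function(dir) {
  long <- utils::read.delim(file.path(dir, "records.tsv"),
                            colClasses = c(patient_id = "character",
                                           sex = "character",
                                           age_band = "character",
                                           disease_id = "character",
                                           indicator = "integer"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth$sigma <- as.matrix(truth$sigma)
  rownames(truth$sigma) <- colnames(truth$sigma)
  truth$blocks <- unlist(truth$blocks)
  truth$thresholds <- unlist(truth$thresholds)
  truth$stratum_seeds <- unlist(truth$stratum_seeds)
  key <- paste0(long$sex, ":", long$age_band)
  matrices <- lapply(split(long, key), function(d) {
    ind <- stats::xtabs(indicator ~ patient_id + disease_id, data = d)
    m <- matrix(as.integer(ind), nrow(ind), ncol(ind),
                dimnames = dimnames(ind))
    names(dimnames(m)) <- NULL
    disease_matrix(m, sex = d$sex[1], age_band = d$age_band[1])
  })
  structure(list(matrices = matrices[order(names(matrices))], truth = truth),
            class = "synthetic_cohort")
}

#' Flatten a synthetic cohort to diagnosis records
#'
#' Emits one diagnosis record per positive indicator, using the disease id as
#' the code (coding system `ICD9CM`), so the cohort can be fed through the
#' record-based front end of the pipeline. Patients with no diseases produce
#' no records.
#'
#' @param cohort A [generate_cohort()] result.
#' @return Data frame with columns `patient_id`, `sex`, `age_band`, `code`,
#'   `coding_system`.
#' @export
as_diagnosis_records <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(cohort$matrices, function(dm) {
    w <- which(dm$indicators == 1L, arr.ind = TRUE)
    data.frame(patient_id = rownames(dm$indicators)[w[, 1]],
               sex = dm$sex, age_band = dm$age_band,
               code = colnames(dm$indicators)[w[, 2]],
               coding_system = "ICD9CM", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$patient_id, out$code), , drop = FALSE]
}

#' Toy lookup tables matching a synthetic cohort
#'
#' Every synthetic disease id is marked chronic and mapped to its own
#' category, so the record-based pipeline reproduces the cohort's disease
#' matrix exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A [code_lookup()].
#' @export
synthetic_lookup <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- spec$diseases$disease_id
  code_lookup(
    chronic = data.frame(code = ids, chronic_flag = "chronic",
                         stringsAsFactors = FALSE),
    category = data.frame(code = ids, category_id = seq_along(ids),
                          category_label = ids, stringsAsFactors = FALSE))
}
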