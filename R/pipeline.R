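# End-to-end orchestration: records (or a synthetic spec) -> chronic filter
# -> per-stratum matrices -> prevalence-filtered networks -> Louvain
# patterns -> reports and exports. With both sexes and all five age bands
# present this yields ten networks.

#' Configuration of a pipeline run
#'
#' Exactly one input source must be given: either file paths (`records_path`
#' plus the two lookup paths) or a synthetic [cohort_spec()].
#'
#' @param records_path Delimited diagnosis-records file (see
#'   [read_records()]).
#' @param chronic_path,category_path Lookup TSVs (see [read_code_lookup()]).
#' @param cohort A [cohort_spec()] for a synthetic run.
#' @param alpha Edge significance level, default 0.01.
#' @param min_prevalence Node prevalence floor, default 0.01.
#' @param include_negative Admit negative-correlation edges.
#' @param exclude_categories Category labels dropped from every matrix
#'   (e.g. the cohort-defining index condition).
#' @param seed Integer seed; drives the synthetic generator and the Louvain
#'   visit orders.
#' @param louvain_restarts Best-of restarts per stratum for [louvain()].
#' @param out_dir Output directory for artifacts; `NULL` disables writing.
#' @param formats Network export formats, subset of `c("graphml", "gexf")`.
#' @return A `run_config` object.
#' @export
run_config <- function(records_path = NULL, chronic_path = NULL,
                       category_path = NULL, cohort = NULL,
                       alpha = 0.01, min_prevalence = 0.01,
                       include_negative = FALSE, exclude_categories = NULL,
                       seed = 1L, louvain_restarts = 5L,
                       out_dir = NULL, formats = c("graphml", "gexf")) {
  from_files <- !is.null(records_path)
  from_spec <- !is.null(cohort)
  if (from_files == from_spec) {
    stop("exactly one input source required: records_path (files) XOR cohort (synthetic spec)")
  }
  if (from_files && (is.null(chronic_path) || is.null(category_path))) {
    stop("file input requires chronic_path and category_path lookups")
  }
  if (from_spec && !inherits(cohort, "cohort_spec")) {
    stop("`cohort` must be a cohort_spec")
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (min_prevalence < 0 || min_prevalence >= 1) {
    stop("`min_prevalence` must lie in [0, 1)")
  }
  formats <- match.arg(formats, several.ok = TRUE)
  structure(list(records_path = records_path, chronic_path = chronic_path,
                 category_path = category_path, cohort = cohort,
                 alpha = alpha, min_prevalence = min_prevalence,
                 include_negative = include_negative,
                 exclude_categories = exclude_categories,
                 seed = as.integer(seed),
                 louvain_restarts = as.integer(louvain_restarts),
                 out_dir = out_dir, formats = formats),
            class = "run_config")
}

.config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$out_dir <- NULL   # where artifacts land, not what they contain
  if (!is.null(snap$cohort)) {
    snap$cohort <- list(strata = snap$cohort$strata,
                        diseases = snap$cohort$diseases,
                        rho_within = snap$cohort$rho_within,
                        rho_between = snap$cohort$rho_between,
                        seed = snap$cohort$seed)
  }
  snap
}

#' Run the full comorbidity-pattern pipeline
#'
#' Builds one disease network and one Louvain partition per observed
#' (sex, age band) stratum, writes all artifacts to `out_dir` when set
#' (networks in the configured formats, partition TSVs, demographics CSV,
#' a Markdown pattern report, a log, and a resolved-config snapshot that
#' suffices to reproduce the run), and returns everything invisibly. A
#' stratum emptied by the prevalence filter is reported as empty and the
#' run continues. Reruns with the same config and seed are bit-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `matrices`, `networks`, `partitions`,
#'   `demographics`, `report` (data frame), and `log` (character).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$cohort)) {
    say("input: synthetic cohort spec (seed %d)", config$cohort$seed)
    cohort <- generate_cohort(config$cohort)
    matrices <- cohort$matrices
  } else {
    say("input: records file %s", config$records_path)
    lookup <- read_code_lookup(config$chronic_path, config$category_path)
    rr <- read_records(config$records_path)
    say("records read: %d valid, %d rejected", nrow(rr$records), nrow(rr$rejects))
    fc <- filter_chronic(rr$records, lookup)
    say("chronic filter: %d records retained, %d unmapped codes",
        nrow(fc$records), nrow(fc$unmapped))
    matrices <- build_matrix(fc$records, lookup,
                             exclude_categories = config$exclude_categories)
  }
  say("strata: %s", paste(names(matrices), collapse = ", "))

  networks <- list()
  partitions <- list()
  for (key in names(matrices)) {
    dm <- prevalence_filter(matrices[[key]], config$min_prevalence)
    if (ncol(dm$indicators) == 0) {
      say("stratum %s: empty after prevalence filter", key)
      networks[key] <- list(NULL)
      partitions[key] <- list(NULL)
      next
    }
    net <- build_network(dm, alpha = config$alpha,
                         include_negative = config$include_negative)
    part <- louvain(net, seed = stratum_seed(config$seed, net$sex, net$age_band),
                    n_restarts = config$louvain_restarts)
    say("stratum %s: %d nodes, %d edges, %d patterns, Q = %.4f",
        key, nrow(net$nodes), nrow(net$edges),
        length(unique(part$assignment)), part$q)
    networks[[key]] <- net
    partitions[[key]] <- part
  }

  demographics <- summarize_demographics(patients = .patients_table(matrices))
  report <- pattern_report(networks, partitions)

  if (!is.null(config$out_dir)) {
    .write_artifacts(config, networks, partitions, demographics, report, log)
  }
  invisible(list(matrices = matrices, networks = networks,
                 partitions = partitions, demographics = demographics,
                 report = report, log = log))
}

.patients_table <- function(matrices) {
  rows <- lapply(matrices, function(dm) {
    data.frame(patient_id = rownames(dm$indicators), sex = dm$sex,
               age_band = dm$age_band, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.write_artifacts <- function(config, networks, partitions, demographics,
                             report, log) {
  out <- config$out_dir
  dir.create(file.path(out, "networks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "partitions"), recursive = TRUE, showWarnings = FALSE)
  for (key in names(networks)) {
    if (is.null(networks[[key]])) next
    stem <- gsub("[^0-9A-Za-z]", "_", key)
    if ("graphml" %in% config$formats) {
      write_network_graphml(networks[[key]],
                            file.path(out, "networks", paste0(stem, ".graphml")))
    }
    if ("gexf" %in% config$formats) {
      write_network_gexf(networks[[key]],
                         file.path(out, "networks", paste0(stem, ".gexf")))
    }
    write_partition_tsv(partitions[[key]],
                        file.path(out, "partitions", paste0(stem, ".tsv")))
  }
  utils::write.csv(demographics, file.path(out, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(report, file.path(out, "pattern_report.csv"),
                   row.names = FALSE)
  writeLines(.report_markdown(networks, partitions, report),
             file.path(out, "pattern_report.md"))
  yaml::write_yaml(.config_snapshot(config), file.path(out, "config.yaml"))
  writeLines(log, file.path(out, "run.log"))
  invisible(out)
}

#' Per-pattern descriptive report
#'
#' One row per community ("pattern") per stratum: its member diseases sorted
#' by decreasing prevalence, the strongest intra-community correlations, and
#' the stratum modularity. This is the tabular stand-in for the human step
#' of naming patterns, which stays with the clinicians.
#'
#' @param networks,partitions Parallel named lists from [run_pipeline()]
#'   (entries may be `NULL` for empty strata).
#' @param top_edges How many of the strongest within-pattern edges to list.
#' @return Data frame with columns `sex`, `age_band`, `n_patients`,
#'   `pattern`, `n_diseases`, `members` (semicolon-separated, by decreasing
#'   prevalence), `top_edges`, `modularity`.
#' @export
pattern_report <- function(networks, partitions, top_edges = 3L) {
  rows <- list()
  for (key in names(networks)) {
    net <- networks[[key]]
    part <- partitions[[key]]
    if (is.null(net)) next
    prev <- stats::setNames(net$nodes$prevalence, net$nodes$disease)
    for (cid in sort(unique(part$assignment))) {
      members <- names(part$assignment)[part$assignment == cid]
      members <- members[order(-prev[members], members)]
      ed <- net$edges[net$edges$from %in% members & net$edges$to %in% members, ,
                      drop = FALSE]
      ed <- ed[order(-abs(ed$rho)), , drop = FALSE]
      ed <- utils::head(ed, top_edges)
      rows[[length(rows) + 1]] <- data.frame(
        sex = net$sex, age_band = net$age_band, n_patients = net$n_patients,
        pattern = cid, n_diseases = length(members),
        members = paste(members, collapse = ";"),
        top_edges = paste(sprintf("%s-%s (%.2f)", ed$from, ed$to, ed$rho),
                          collapse = "; "),
        modularity = part$q, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sex = character(), age_band = character(),
                      n_patients = integer(), pattern = integer(),
                      n_diseases = integer(), members = character(),
                      top_edges = character(), modularity = numeric()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.report_markdown <- function(networks, partitions, report) {
  lines <- c("# Comorbidity pattern report", "")
  for (key in names(networks)) {
    net <- networks[[key]]
    lines <- c(lines, sprintf("## Stratum %s", key), "")
    if (is.null(net)) {
      lines <- c(lines, "Empty after prevalence filtering.", "")
      next
    }
    part <- partitions[[key]]
    lines <- c(lines,
               sprintf("%d patients, %d diseases, %d significant edges, %d patterns, Q = %.4f",
                       net$n_patients, nrow(net$nodes), nrow(net$edges),
                       length(unique(part$assignment)), part$q), "")
    sub <- report[report$sex == net$sex & report$age_band == net$age_band, ,
                  drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      lines <- c(lines,
                 sprintf("- pattern %d (%d diseases): %s", sub$pattern[r],
                         sub$n_diseases[r], sub$members[r]))
      if (nzchar(sub$top_edges[r])) {
        lines <- c(lines, sprintf("  strongest correlations: %s", sub$top_edges[r]))
      }
    }
    lines <- c(lines, "")
  }
  lines
}

#' Demographic summary table
#'
#' Counts and percentages by sex and by each categorical characteristic,
#' with percentages computed within column (total / men / women) and
#' rounded to one decimal place, the convention of demographic tables in
#' epidemiological studies.
#'
#' Input is either patient-level data (`patients`: one row per patient with
#' `sex` plus categorical columns such as `age_band`) or pre-aggregated
#' counts (`counts`: columns `characteristic`, `level`, `sex`, `n`) -- the
#' latter reproduces a printed table directly from its counts.
#'
#' @param patients Patient-level data frame, or `NULL`.
#' @param counts Aggregated counts data frame, or `NULL`.
#' @return Data frame with columns `characteristic`, `level`, `n_total`,
#'   `pct_total`, `n_men`, `pct_men`, `n_women`, `pct_women`. The first
#'   rows summarize sex itself (as percentages of the overall total).
#' @export
summarize_demographics <- function(patients = NULL, counts = NULL) {
  if (is.null(patients) == is.null(counts)) {
    stop("give exactly one of `patients` or `counts`")
  }
  if (!is.null(patients)) {
    if (!all(c("patient_id", "sex") %in% names(patients))) {
      stop("`patients` needs columns patient_id and sex")
    }
    patients <- unique(patients)
    if (anyDuplicated(patients$patient_id)) {
      stop("a patient appears with conflicting characteristics")
    }
    chars <- setdiff(names(patients), c("patient_id", "sex"))
    if (!length(chars)) stop("`patients` needs at least one characteristic column")
    counts <- do.call(rbind, lapply(chars, function(ch) {
      tab <- as.data.frame(table(level = patients[[ch]], sex = patients$sex),
                           stringsAsFactors = FALSE)
      data.frame(characteristic = ch, level = tab$level, sex = tab$sex,
                 n = tab$Freq, stringsAsFactors = FALSE)
    }))
  }
  req <- setdiff(c("characteristic", "level", "sex", "n"), names(counts))
  if (length(req)) stop("`counts` is missing column(s): ", paste(req, collapse = ", "))
  if (!all(counts$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")

  totals_by <- function(d) c(M = sum(d$n[d$sex == "M"]),
                             F = sum(d$n[d$sex == "F"]))
  per_char <- lapply(split(counts, counts$characteristic), totals_by)
  tot <- per_char[[1]]
  for (t in per_char) {
    if (!isTRUE(all.equal(t, tot))) {
      stop("characteristics disagree on the sex totals; counts are inconsistent")
    }
  }
  N <- sum(tot)
  pct <- function(n, d) round(100 * n / d, 1)

  out <- data.frame(characteristic = "sex", level = c("Men", "Women"),
                    n_total = c(tot[["M"]], tot[["F"]]),
                    pct_total = pct(c(tot[["M"]], tot[["F"]]), N),
                    n_men = c(tot[["M"]], 0L), pct_men = pct(c(tot[["M"]], 0), tot[["M"]]),
                    n_women = c(0L, tot[["F"]]), pct_women = pct(c(0, tot[["F"]]), tot[["F"]]),
                    stringsAsFactors = FALSE)
  for (ch in unique(counts$characteristic)) {
    d <- counts[counts$characteristic == ch, , drop = FALSE]
    lv <- unique(d$level)
    nm <- vapply(lv, function(l) sum(d$n[d$level == l & d$sex == "M"]), numeric(1))
    nf <- vapply(lv, function(l) sum(d$n[d$level == l & d$sex == "F"]), numeric(1))
    out <- rbind(out, data.frame(
      characteristic = ch, level = lv,
      n_total = nm + nf, pct_total = pct(nm + nf, N),
      n_men = nm, pct_men = pct(nm, tot[["M"]]),
      n_women = nf, pct_women = pct(nf, tot[["F"]]),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
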