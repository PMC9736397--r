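#' Default pipeline configuration
#'
#' @param ... overrides of the defaults shown below.
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  config <- list(
    mode = "synthetic",          # "synthetic" or "files"
    synthetic_spec = "paperlike",# or a generator_spec object
    input = NULL,                # records CSV (mode = "files")
    control_input = NULL,        # optional pre-matched control CSV
    level = "patient",           # or "record"
    chronic_list = NULL,         # path or character vector; NULL = all codes
    prevalence_floor = 0.01,
    excluded_chapters = c("XIX", "XX", "XXI", "XXII"),
    caliper_years = 2L,
    edge_rule = list(min_cooccurrence = 2L, sci_cutoff = NULL,
                     alpha_edge = 0.05),
    role_percentile = 0.10,
    arm = list(consequent = "I50", min_support = 0.01, min_confidence = 0.5),
    seed = 20220101L
  )
  overrides <- list(...)
  for (key in names(overrides)) config[[key]] <- overrides[[key]]
  config
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config(sprintf("config not found: %s", config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML path")
  config
}

.group_outputs <- function(records, group, config, chronic, out_dir) {
  all_matrix <- identify_comorbidities(
    records, chronic_list = chronic,
    prevalence_floor = config$prevalence_floor,
    excluded_chapters = config$excluded_chapters,
    level = config$level, group = group, stratum = "all")
  strata_matrices <- stratify_by_age(
    records, group = group, chronic_list = chronic,
    prevalence_floor = config$prevalence_floor,
    excluded_chapters = config$excluded_chapters, level = config$level)
  matrices <- c(list(all = all_matrix), strata_matrices)
  matrices <- matrices[!vapply(matrices, is.null, TRUE)]

  er <- config$edge_rule
  nets <- lapply(matrices, function(m) {
    if (ncol(m$incidence) < 2L) return(NULL)
    build_network(m, min_cooccurrence = er$min_cooccurrence,
                  sci_cutoff = er$sci_cutoff, alpha_edge = er$alpha_edge)
  })
  nets <- nets[!vapply(nets, is.null, TRUE)]
  roles <- lapply(nets, node_roles, percentile = config$role_percentile)

  topo <- do.call(rbind, lapply(names(nets), function(lab) {
    t <- topology(nets[[lab]])
    data.frame(group = group, stratum = lab, sample_size = nets[[lab]]$n_patients,
               as.data.frame(t[setdiff(names(t), "singleton")]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(topo, file.path(out_dir, sprintf("topology_%s.csv", group)),
                   row.names = FALSE)

  for (lab in names(nets)) {
    stub <- file.path(out_dir, sprintf("network_%s_%s", group, lab))
    write_network(nets[[lab]], graphml = paste0(stub, ".graphml"),
                  edges_tsv = paste0(stub, "_edges.tsv"),
                  nodes_csv = paste0(stub, "_nodes.csv"),
                  roles = roles[[lab]])
  }
  utils::write.csv(role_appearance(roles),
                   file.path(out_dir, sprintf("roles_%s.csv", group)),
                   row.names = FALSE)
  utils::write.csv(cumulative_role_sci(nets, roles),
                   file.path(out_dir, sprintf("role_sci_%s.csv", group)),
                   row.names = FALSE)

  burden <- comorbid_burden(all_matrix)
  list(matrices = matrices, nets = nets, roles = roles, burden = burden)
}

#' Run the full multimorbidity pipeline
#'
#' Chains every stage — synthetic generation or file input, control
#' matching, comorbidity identification per group and age stratum,
#' enrichment, network construction with topology and node roles, and
#' targeted association-rule mining — and writes all artifacts plus a run
#' manifest (config, package version, seed) into `out_dir`. A rerun with
#' the same config and seed reproduces the outputs exactly.
#'
#' @param config list from [pipeline_config()] or a YAML file path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  config <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  chronic <- config$chronic_list
  if (is.character(chronic) && length(chronic) == 1L && file.exists(chronic))
    chronic <- read_chronic_list(chronic)

  if (identical(config$mode, "synthetic")) {
    spec <- config$synthetic_spec
    if (identical(spec, "paperlike")) spec <- paperlike_spec()
    sim <- generate(spec, seed = config$seed)
    cases <- sim$cases
    pool <- sim$pool
    if (is.null(chronic)) chronic <- sim$truth$chronic_codes
    matching <- match_controls(cases, pool,
                               caliper_years = config$caliper_years)
    controls <- matching$controls
    write_records(cases, file.path(out_dir, "cases.csv"))
    write_records(controls, file.path(out_dir, "controls.csv"))
  } else {
    if (is.null(config$input)) stop_config("mode 'files' needs config$input")
    cases <- read_records(config$input)
    if (!is.null(config$control_input)) {
      controls <- read_records(config$control_input)
      matching <- NULL
    } else {
      stop_config("mode 'files' needs config$control_input (pre-matched controls)")
    }
  }

  case_out <- .group_outputs(cases, "case", config, chronic, out_dir)
  ctrl_out <- .group_outputs(controls, "control", config, chronic, out_dir)

  enrich <- enrich_table(case_out$matrices$all, ctrl_out$matrices$all)
  utils::write.csv(enrich, file.path(out_dir, "enrichment.csv"),
                   row.names = FALSE)

  burden <- data.frame(
    group = c("case", "control"),
    mean_burden = c(case_out$burden$mean_burden, ctrl_out$burden$mean_burden),
    share_multimorbid = c(case_out$burden$share_multimorbid,
                          ctrl_out$burden$share_multimorbid),
    n = c(length(case_out$burden$counts), length(ctrl_out$burden$counts))
  )
  utils::write.csv(burden, file.path(out_dir, "burden.csv"), row.names = FALSE)

  rules <- mine_rules(case_out$matrices$all,
                      consequent = config$arm$consequent,
                      min_support = config$arm$min_support,
                      min_confidence = config$arm$min_confidence)
  write_rules(rules, file.path(out_dir, "rules.csv"))
  message(sprintf("%d association rules survive the thresholds", nrow(rules)))

  manifest <- list(
    package = "pdnet",
    version = as.character(utils::packageVersion("pdnet")),
    seed = config$seed,
    config = config[!vapply(config, is.function, TRUE)]
  )
  manifest$config$synthetic_spec <-
    if (is.character(config$synthetic_spec)) config$synthetic_spec
    else "custom generator_spec"
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(cases = cases, controls = controls,
                 case = case_out, control = ctrl_out,
                 enrichment = enrich, burden = burden, rules = rules))
}
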