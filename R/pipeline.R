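# End-to-end orchestration: filter -> test -> classify -> phospho ->
# bi-level -> orthology -> interolog transfer -> decorate -> export.

#' Assemble a run configuration
#'
#' @param inputs Named list of input paths: `abundance`,
#'   `phosphopeptides`, `proteome_query`, `proteome_template`,
#'   `template_edges`, and optionally `pathway_annotation`, `domains`.
#' @param out_dir Output directory.
#' @param thr A [thresholds()] object.
#' @param stringency Phosphopeptide stringency tier, `"HIGH"` (default) or
#'   `"LOW"`.
#' @param orthology Alignment/clustering parameters: list with `matrix`,
#'   `gap_open`, `gap_extend`, `inflation`.
#' @param seed Seed for the (deterministic) network layout.
#' @param stages Character vector of stages to run, any of `"quantify"`,
#'   `"phospho"`, `"bilevel"`, `"orthology"`, `"network"` (later stages
#'   require the earlier ones).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(inputs, out_dir, thr = thresholds(),
                       stringency = "HIGH",
                       orthology = list(matrix = "BLOSUM62", gap_open = 11,
                                        gap_extend = 1, inflation = 1.5),
                       seed = 1L,
                       stages = c("quantify", "phospho", "bilevel",
                                  "orthology", "network")) {
  structure(list(inputs = inputs, out_dir = out_dir, thr = thr,
                 stringency = stringency, orthology = orthology,
                 seed = as.integer(seed), stages = stages),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `thresholds` is
#' a mapping passed to [thresholds()].
#'
#' @param path YAML file.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(inputs = y$inputs,
             out_dir = y$out_dir %||% ".",
             thr = do.call(thresholds, y$thresholds %||% list()),
             stringency = y$stringency %||% "HIGH",
             orthology = utils::modifyList(
               list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                    inflation = 1.5), y$orthology %||% list()),
             seed = y$seed %||% 1L,
             stages = y$stages %||% c("quantify", "phospho", "bilevel",
                                      "orthology", "network"))
}

stage_error <- function(stage, e) {
  stop_(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes the configured stages in order - signal filtering,
#' differential testing against the optimum for both stress conditions,
#' regulation classification and profile clustering; phosphopeptide
#' parsing, stringency filtering and site aggregation; bi-level
#' intersection and report; reciprocal-best-hit orthology with Markov
#' clustering of the similarity graph; interolog network transfer,
#' node decoration, edge classification and export (SVG, GraphML, SIF) -
#' writing each stage's outputs under `config$out_dir` together with a
#' run manifest (package version, parameters, input checksums, per-stage
#' record counts). Outputs are pure functions of (inputs, config, seed).
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  need <- c("quantify", "phospho", "bilevel", "orthology", "network")
  stages <- intersect(need, config$stages)
  required <- c(abundance = "quantify", phosphopeptides = "phospho",
                proteome_query = "orthology", proteome_template = "orthology",
                template_edges = "network")
  for (nm in names(required)) {
    if (!required[[nm]] %in% stages) next
    p <- config$inputs[[nm]]
    if (is.null(p) || !file.exists(p))
      stop_("input '", nm, "' missing or not found: ", p %||% "<unset>")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  thr <- config$thr
  out <- function(f) file.path(config$out_dir, f)

  expression <- NULL; inventories <- NULL; records <- NULL; report <- NULL
  classes <- NULL; quant_pres <- NULL

  if ("quantify" %in% stages) {
    tryCatch({
      ab <- read_abundance(config$inputs$abundance)
      counts$proteins_loaded <- nrow(ab$intensity)
      ab <- apply_signal_threshold(ab, thr)
      counts$signal_filtered_values <- attr(ab, "filter_log")$n_removed
      lo <- test_differential(ab, "LOW", thr)
      hi <- test_differential(ab, "HIGH", thr)
      expression <- rbind(lo, hi)
      write_expression_results(expression, out("expression.tsv"))
      counts$de_low <- sum(lo$call %in% c("UP", "DOWN"))
      counts$de_high <- sum(hi$call %in% c("UP", "DOWN"))
      classes <- classify_regulation_table(lo, hi)
      write_tsv(classes, out("regulation_classes.tsv"))
      counts$regulated_both <- sum(classes$class %in%
                                     c("UP_UP", "DOWN_DOWN", "UP22_DOWN40",
                                       "DOWN22_UP40"))
      if (nrow(ab$intensity) >= 2L) {
        hc <- suppressWarnings(cluster_expression_profiles(ab))
        write_dendrogram_newick(hc, out("expression_dendrogram.nwk"))
      }
      quant_pres <- presence_by_condition(ab)
    }, error = function(e) stage_error("quantify", e))
  }

  if ("phospho" %in% stages) {
    tryCatch({
      pep <- read_phosphopeptides(config$inputs$phosphopeptides)
      counts$phosphopeptides_loaded <- nrow(pep)
      pep <- filter_stringency(pep, config$stringency)
      counts$phosphopeptides_kept <- nrow(pep)
      inventories <- aggregate_all_sites(pep)
      counts$phosphoproteins <- length(inventories)
      counts$phosphosites <- sum(vapply(inventories,
                                        function(i) i$counts[["total"]], 0L))
      st <- sites_table(inventories)
      if (!is.null(st)) write_tsv(st, out("phosphosites.tsv"))
    }, error = function(e) stage_error("phospho", e))
  }

  if ("bilevel" %in% stages) {
    tryCatch({
      if (is.null(expression) || is.null(inventories))
        stop_("bilevel requires the quantify and phospho stages")
      lo <- expression[expression$contrast == "LOW_vs_OPT", ]
      hi <- expression[expression$contrast == "HIGH_vs_OPT", ]
      records <- identify_bilevel(lo, hi, inventories, thr)
      report <- build_bilevel_report(records)
      write_bilevel_report(report, out("bilevel_report.tsv"),
                           out("bilevel_totals.json"))
      counts$bilevel_candidates <- sum(records$candidate)
      counts$bilevel_reported <- nrow(report$rows)
    }, error = function(e) stage_error("bilevel", e))
  }

  rbh <- NULL
  if ("orthology" %in% stages) {
    tryCatch({
      oo <- config$orthology
      rbh <- reciprocal_best_hits(config$inputs$proteome_query,
                                  config$inputs$proteome_template, thr,
                                  matrix = oo$matrix, gap_open = oo$gap_open,
                                  gap_extend = oo$gap_extend)
      write_tsv(rbh, out("rbh_pairs.tsv"))
      counts$rbh_pairs <- nrow(rbh)
      if (nrow(rbh)) {
        part <- markov_cluster(similarity_graph(rbh),
                               inflation = oo$inflation)
        species <- function(a) if (a %in% rbh$query_a) "query" else "template"
        write_tsv(ortholog_groups(part, species), out("ortholog_groups.tsv"))
        counts$ortholog_groups <- length(part$groups)
      }
    }, error = function(e) stage_error("orthology", e))
  }

  if ("network" %in% stages) {
    tryCatch({
      if (is.null(rbh)) stop_("network requires the orthology stage")
      te <- read_template_edges(config$inputs$template_edges)
      net <- transfer_network(te, rbh)
      counts$template_edges <- nrow(te)
      counts$inferred_edges <- nrow(net$edges)
      counts$skipped_template_edges <- nrow(net$skipped)
      phos_pres <- if (!is.null(inventories)) phospho_presence(inventories)
      dec <- decorate_nodes(net, expression %||%
                              data.frame(accession = character(),
                                         call = character()),
                            records %||%
                              data.frame(accession = character(),
                                         candidate = logical(),
                                         reported = logical()),
                            quant_pres, phos_pres)
      ec <- classify_edges(net, dec)
      counts$green_edges <- sum(ec$class == "GREEN")
      counts$purple_edges <- sum(ec$class == "PURPLE")
      export_network(net, dec, ec, out("network.sif"), "SIF")
      export_network(net, dec, ec, out("network.graphml"), "GraphML")
      export_network(net, dec, ec, out("network.svg"), "SVG",
                     seed = config$seed)
      if (!is.null(config$inputs$pathway_annotation) && !is.null(classes)) {
        ann <- read_pathway_annotation(config$inputs$pathway_annotation)
        write_tsv(summarize_pathways(classes, ann), out("pathways_by_class.tsv"))
      }
    }, error = function(e) stage_error("network", e))
  }

  inputs_present <- Filter(function(p) is.character(p) && file.exists(p),
                           config$inputs)
  manifest <- list(
    package = "bilevelppi",
    version = as.character(utils::packageVersion("bilevelppi")),
    seed = config$seed,
    stages = stages,
    thresholds = unclass(thr),
    orthology = config$orthology,
    stringency = config$stringency,
    input_md5 = as.list(vapply(inputs_present,
                               function(p) unname(tools::md5sum(p)), "")),
    counts = counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
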