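#' Demo pipeline configuration over the bundled fixtures
#'
#' Runs the crosslink-network stage over the packaged 12-row dipeptide table
#' with the subunit registry.
#'
#' @param out_dir Output directory.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("pepmap_demo")) {
  list(stages = list(xlms = TRUE),
       inputs = list(crosslinks = system.file("extdata",
                                              "table1_crosslinks.tsv",
                                              package = "pepmap",
                                              mustWork = TRUE)),
       params = list(), seed = 1L, out_dir = out_dir)
}

default_params <- function() {
  list(window_size = 11L, min_run = 3L, min_score = 30, max_distance = 30,
       exposure_threshold = 0.25, len_range = c(6L, 30L), alpha_id = "rpoA")
}

validate_config <- function(config) {
  params <- utils::modifyList(default_params(), config$params %||% list())
  stopifnot(params$window_size %% 2L == 1L, params$window_size >= 1L,
            params$min_run >= 1L, params$min_score >= 0,
            params$max_distance > 0,
            params$exposure_threshold >= 0, params$exposure_threshold <= 1,
            length(params$len_range) == 2L)
  stages <- config$stages %||% list()
  inputs <- config$inputs %||% list()
  need_input <- function(stage, keys) {
    if (!isTRUE(stages[[stage]])) return(invisible(NULL))
    for (k in keys) {
      if (is.null(inputs[[k]]))
        stop("stage '", stage, "' enabled but input '", k, "' missing")
      if (!file.exists(inputs[[k]]))
        stop("input path does not exist: ", inputs[[k]])
    }
  }
  need_input("xlms", "crosslinks")
  need_input("conserve", "alignment")
  need_input("ibaq", c("intensities", "sequences"))
  need_input("mapdiverge", c("alignment", "structure"))
  config$params <- params
  config$out_dir <- config$out_dir %||% tempfile("pepmap_run")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order over the configured
#' inputs, logging record counts at every filter, and writes a JSON report
#' plus a parameter manifest (and a minimal HTML index) into the output
#' directory. Two runs with identical config and seed produce identical
#' report payloads.
#'
#' @param config List: `stages` (named logical toggles among `xlms`,
#'   `conserve`, `ibaq`, `mapdiverge`), `inputs` (named paths:
#'   `crosslinks`, `alignment`, `clade_map` (2-column TSV taxon/clade),
#'   `structure`, `intensities`, `sequences` (FASTA)), `params` (overrides of
#'   window_size, min_run, min_score, max_distance, exposure_threshold,
#'   len_range, alpha_id), `seed`, `out_dir`. A path to a JSON config file is
#'   also accepted.
#' @return The report list, invisibly. Stage failures are reported per stage
#'   in `report$errors` and make the function error after all stages ran.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_config(config)
  params <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed %||% 1L)
  registry <- load_registry()
  report <- list(seed = config$seed %||% 1L, params = params, stages = list())
  errors <- list()
  run_stage <- function(name, fn) {
    if (!isTRUE(config$stages[[name]])) return(NULL)
    message("[pepmap] stage ", name)
    tryCatch(fn(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  report$stages$xlms <- run_stage("xlms", function() {
    rec <- parse_crosslink_table(config$inputs$crosslinks)
    kept <- filter_records(rec, min_score = params$min_score)
    message("[pepmap]   records in: ", nrow(rec), ", after filter: ", nrow(kept))
    g <- build_graph(kept, registry, restrict_to_members = TRUE)
    write_graph_json(g, file.path(config$out_dir, "graph.json"))
    write.table(as.data.frame(kept),
                file.path(config$out_dir, "links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_records = nrow(rec), n_filtered = nrow(kept),
         n_clusters = length(g$clusters), clusters = g$clusters)
  })
  report$stages$conserve <- run_stage("conserve", function() {
    clade_map_df <- read.delim(config$inputs$clade_map, header = TRUE,
                               stringsAsFactors = FALSE)
    clade_map <- setNames(clade_map_df[[2]], clade_map_df[[1]])
    msa <- read_alignment(config$inputs$alignment, clade_map = clade_map)
    profiles <- clade_profiles(msa, window_size = params$window_size)
    ref <- config$inputs$reference_taxon %||% rownames(msa$mat)[1]
    tab <- profile_table(profiles, map_columns_to_reference(msa, ref))
    write.table(tab, file.path(config$out_dir, "conservation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_columns = msa$n_columns, subsets = names(profiles),
         mean_identity_all = mean(profiles$all$column_identity))
  })
  report$stages$ibaq <- run_stage("ibaq", function() {
    intens <- read.delim(config$inputs$intensities, stringsAsFactors = FALSE)
    seqs <- Biostrings::readAAStringSet(config$inputs$sequences)
    sequences <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
    ib <- compute_ibaq(intens, sequences, alpha_id = params$alpha_id,
                       len_range = params$len_range)
    write.table(ib$table, file.path(config$out_dir, "ibaq.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_proteins = nrow(ib$table), alpha_found = ib$alpha_found)
  })
  report$errors <- errors
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "pepmap",
                   version = as.character(utils::packageVersion("pepmap")),
                   seed = config$seed %||% 1L, params = params,
                   inputs = config$inputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  html <- c("<html><body><h1>pepmap report</h1><pre>",
            jsonlite::toJSON(report, auto_unbox = TRUE, pretty = TRUE),
            "</pre></body></html>")
  writeLines(html, file.path(config$out_dir, "report.html"))
  if (length(errors) > 0L)
    stop("pipeline stage(s) failed: ",
         paste(sprintf("%s (%s)", names(errors), unlist(errors)),
               collapse = "; "))
  invisible(report)
}
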