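#' Export a network as GraphML and edge-list TSV
#'
#' @param net A `cgbn_network`.
#' @param graphml,edges_tsv Output paths (either may be `NULL` to skip).
#' @return The network, invisibly.
#' @export
write_network <- function(net, graphml = NULL, edges_tsv = NULL) {
  stopifnot(inherits(net, "cgbn_network"))
  if (!is.null(edges_tsv)) {
    readr::write_tsv(net$edges %>% rename(source = "from", target = "to"),
                     edges_tsv)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to", "log_bf")],
                                       vertices = net$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(net)
}

#' Export a variable list with annotations (published-table schema)
#'
#' Writes a TSV with columns `Metabolite`, `SuperPathway`, `SubPathway`,
#' `HMDB` and, when present in `x`, `Loading` — the schema of the
#' influential-loading and network-membership tables of metabolomics
#' reports.
#'
#' @param x A tibble with a `metabolite` (or `node`) column and optionally
#'   `loading`.
#' @param annotations The cohort annotations tibble.
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_annotated_table <- function(x, annotations, path) {
  key <- if ("metabolite" %in% names(x)) x$metabolite else x$node
  ann <- annotations[match(key, annotations$metabolite), ]
  out <- tibble(Metabolite = key,
                SuperPathway = ann$super_pathway,
                SubPathway = ann$sub_pathway,
                HMDB = ann$hmdb_id)
  if ("loading" %in% names(x)) out$Loading <- x$loading
  if ("role" %in% names(x)) out$Role <- x$role
  readr::write_tsv(out, path, na = "")
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' Writes the flat numeric summary of [report_metrics()] plus the seed and
#' configuration hash; identical configuration and seed give a
#' byte-identical file.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return The metrics list, invisibly.
#' @export
write_report <- function(report, path) {
  metrics <- report_metrics(report)
  metrics$config_hash <- report$config_hash
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(metrics)
}

#' Write a QC report as TSV plus JSON summary
#'
#' @param report The filter report from [qc_filter()].
#' @param tsv,json Output paths (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_qc_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    flat <- report %>%
      mutate(batch_missing_frac = vapply(.data$batch_missing_frac, function(v) {
        paste(sprintf("%s=%.4f", names(v), v), collapse = ";")
      }, ""))
    readr::write_tsv(flat, tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(
      n_before = attr(report, "n_before"),
      n_after = attr(report, "n_after"),
      dropped = as.list(table(report$status[report$status != "kept"]))
    ), json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}
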