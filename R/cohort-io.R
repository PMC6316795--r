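#' Read and write cohorts as plain-text tables
#'
#' A cohort is stored as three files in a directory: `intensities.tsv`
#' (samples in rows, metabolites in columns, empty cell = missing),
#' `annotations.tsv` (columns `Metabolite`, `SuperPathway`, `SubPathway`,
#' `HMDB`, `Xenobiotic`), and `samples.csv` (phenotype label, batch and any
#' covariates). [write_cohort()] additionally writes the ground truth, when
#' given, as `truth.json`.
#'
#' @param cohort A `metab_cohort`.
#' @param dir Directory to write into / read from (created if needed).
#' @param truth Optional `ground_truth` to serialise alongside.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `metab_cohort`.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "metab_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ints <- as.data.frame(cohort$intensities)
  ints <- cbind(SampleID = rownames(cohort$intensities), ints)
  readr::write_tsv(ints, file.path(dir, "intensities.tsv"), na = "")
  ann <- tibble(
    Metabolite = cohort$annotations$metabolite,
    SuperPathway = cohort$annotations$super_pathway,
    SubPathway = cohort$annotations$sub_pathway,
    HMDB = cohort$annotations$hmdb_id,
    Xenobiotic = cohort$annotations$xenobiotic
  )
  readr::write_tsv(ann, file.path(dir, "annotations.tsv"), na = "")
  readr::write_csv(cohort$samples, file.path(dir, "samples.csv"), na = "")
  if (!is.null(truth)) {
    tr <- unclass(truth)
    tr$batch_factors <- list(
      metabolite = rownames(truth$batch_factors),
      batch = colnames(truth$batch_factors),
      values = unname(as.data.frame(truth$batch_factors))
    )
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ints <- readr::read_tsv(file.path(dir, "intensities.tsv"),
                          show_col_types = FALSE, na = c("", "NA"))
  m <- as.matrix(ints[, -1, drop = FALSE])
  rownames(m) <- ints[[1]]
  ann <- readr::read_tsv(file.path(dir, "annotations.tsv"),
                         show_col_types = FALSE, na = character())
  annotations <- tibble(
    metabolite = ann$Metabolite, super_pathway = ann$SuperPathway,
    sub_pathway = ann$SubPathway, hmdb_id = ann$HMDB,
    xenobiotic = as.logical(ann$Xenobiotic)
  )
  samples <- readr::read_csv(file.path(dir, "samples.csv"),
                             show_col_types = FALSE)
  new_cohort(samples, m, annotations)
}
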