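#' @importFrom stats median sd qt density kmeans dnorm phyper setNames
#' @importFrom utils read.delim write.table
NULL

.cohorts <- c("bone_comparison", "maturation", "enrichment", "tissue_panel")
.conditions <- c("osteocyte_enriched", "whole_bone", "other")

#' Read and validate a sample metadata table
#'
#' Tab-separated table with columns `sample_id`, `cohort`, `tissue`,
#' `condition`, `animal_id`, `age_weeks`, `sex`, `replicate`. Sample ids
#' must be unique; within the enrichment cohort every animal must
#' contribute exactly one osteocyte-enriched and one whole-bone sample
#' (left/right limbs of the same mouse).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_table(df)
}

#' Validate a sample table held in memory
#'
#' @param df A data.frame with the columns listed in [read_sample_table()].
#' @return The validated data.frame with typed columns.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "cohort", "tissue", "condition", "animal_id",
            "age_weeks", "sex", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  bad <- setdiff(unique(df$cohort), .cohorts)
  if (length(bad)) stop("unknown cohort: ", bad[1L])
  bad <- setdiff(unique(df$condition), .conditions)
  if (length(bad)) stop("unknown condition: ", bad[1L])
  df$age_weeks <- as.integer(df$age_weeks)
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$age_weeks)) || any(df$age_weeks <= 0L))
    stop("age_weeks must be a positive integer")
  if (any(is.na(df$replicate)) || any(df$replicate <= 0L))
    stop("replicate must be a positive integer")
  enr <- df[df$cohort == "enrichment", ]
  if (nrow(enr)) {
    tab <- table(enr$animal_id, enr$condition)
    ok <- all(colnames(tab) %in% c("osteocyte_enriched", "whole_bone")) &&
      all(tab[, "osteocyte_enriched"] == 1L) && all(tab[, "whole_bone"] == 1L)
    if (!ok)
      stop("enrichment cohort: each animal_id needs exactly one ",
           "osteocyte_enriched and one whole_bone sample")
  }
  df
}

#' Write a sample table to TSV
#' @param df Sample table data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, `set_name TAB description TAB gene1 TAB
#' gene2 ...`. Members are trimmed and de-duplicated within a line (with
#' a warning naming the set); lines with fewer than three fields are
#' rejected with their line number.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors, with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no sets found in ", path)
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(f) < 3L)
      stop(sprintf("line %d: expected >= 3 tab-separated fields", i))
    nm <- f[1L]
    if (nm %in% names(sets)) stop("duplicate set name: ", nm)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': %d duplicate member(s) collapsed",
                      nm, sum(duplicated(members))))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("line %d: set '%s' is empty", i, nm))
    sets[[nm]] <- members
    desc[nm] <- f[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the `descriptions` attribute or the set name.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression exclusion table
#'
#' Tab-separated table with columns `gene`, `contrast_tissue`, `lfc`,
#' `p_value` listing genes tested for higher expression in contaminant
#' tissues (blood, bone marrow, muscle) relative to osteocyte-enriched
#' bone. Positive `lfc` means higher in the contrast tissue.
#'
#' @param path Path to the TSV file.
#' @param tissues Allow-list of contrast tissues.
#' @return A data.frame with typed columns.
#' @export
read_exclusion_table <- function(path,
                                 tissues = c("blood", "bone_marrow", "muscle")) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "contrast_tissue", "lfc", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("exclusion table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    bad <- setdiff(unique(df$contrast_tissue), tissues)
    if (length(bad)) stop("unknown contrast tissue: ", bad[1L])
    df$lfc <- as.numeric(df$lfc)
    df$p_value <- as.numeric(df$p_value)
    if (anyNA(df$p_value) || any(df$p_value < 0) || any(df$p_value > 1))
      stop("p_value must lie in [0, 1]")
  }
  df
}

#' Read a two-column mouse-to-human ortholog map
#'
#' Tab-separated, columns `mouse_gene_id` and `human_gene_id`; may be
#' many-to-many but duplicate pairs are rejected.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `mouse_gene_id`, `human_gene_id`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("mouse_gene_id", "human_gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ortholog map missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df[need]))
    stop("duplicate ortholog pair")
  df[need]
}

#' Read / write a plain-text gene list (one id per line)
#' @param path File path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes Character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters and the seed of a pipeline stage so that a
#' run can be reproduced exactly.
#'
#' @param path Output path (`.json`).
#' @param stage Name of the pipeline stage.
#' @param inputs Named list of input file paths or descriptions.
#' @param params Named list of parameters.
#' @param seed Integer seed used for the stage (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, stage, inputs = list(),
                               params = list(), seed = NULL) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifact_version = as.character(utils::packageVersion("osteosig")),
    seed = seed,
    inputs = inputs,
    params = params
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
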