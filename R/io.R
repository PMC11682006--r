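#' Validate a beta-value matrix
#'
#' A beta matrix is a numeric matrix of methylation fractions (CpG probes in
#' rows, samples in columns) with unique row and column names and every
#' non-missing value in \[0, 1\].
#'
#' @param beta Numeric matrix with probe ids as rownames and sample ids as
#'   colnames. Missing values (`NA`) are allowed.
#' @return The matrix, invisibly, if valid; otherwise an error naming the
#'   offending probe/sample cell.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta matrix must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(beta)[duplicated(rownames(beta))]), collapse = ", "))
  if (anyDuplicated(colnames(beta)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(beta)[duplicated(colnames(beta))]), collapse = ", "))
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "beta value outside [0, 1]: probe %s, sample %s, value %g",
      rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
      beta[bad[1, 1], bad[1, 2]]))
  }
  invisible(beta)
}

#' Read a beta-value matrix from a delimited file
#'
#' Expects probe ids in the first column and sample ids in the header row.
#' "NA", "NaN" and empty cells are read as missing.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; `"auto"` (default) lets the reader sniff it.
#' @return A validated beta matrix (see [validate_beta_matrix()]).
#' @export
read_beta_matrix <- function(path, sep = "auto") {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("NA", "NaN", ""),
                          colClasses = list(character = 1))
  probe_ids <- dt[[1]]
  m <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in beta matrix: ", path)
  rownames(m) <- probe_ids
  validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix to a TSV file
#'
#' @param beta Beta matrix.
#' @param path Output path. Missing values are written as "NA".
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  dt <- data.table::data.table(probe_id = rownames(beta), beta)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.group_levels <- c("tumor", "adjacent", "cirrhotic", "healthy", "blood", "disease")

#' Validate a sample sheet
#'
#' @param sheet data.frame with columns `sample_id`, `cohort`, `group`,
#'   `tissue`; `group` must be one of tumor, adjacent, cirrhotic, healthy,
#'   blood, disease.
#' @param beta Optional beta matrix the sheet accompanies; every column of
#'   the matrix must then appear exactly once in the sheet.
#' @return The sheet, invisibly.
#' @export
validate_sample_sheet <- function(sheet, beta = NULL) {
  need <- c("sample_id", "cohort", "group", "tissue")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sheet")
  bad <- setdiff(unique(sheet$group), .group_levels)
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (!is.null(beta)) {
    absent <- setdiff(colnames(beta), sheet$sample_id)
    if (length(absent))
      stop("samples absent from sheet: ", paste(absent, collapse = ", "))
  }
  invisible(sheet)
}

#' Read a sample sheet CSV
#'
#' @param path CSV with header `sample_id,cohort,group,tissue`.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- data.table::fread(path, colClasses = "character", data.table = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Read a CpG manifest CSV
#'
#' Columns: `probe_id,chrom,pos,strand,in_cgi,gene,tss_pos,gene_start,gene_end`.
#' Coordinates are 1-based, as in array manifests. Probes without an assigned
#' gene carry empty `gene` and coordinate fields.
#'
#' @param path CSV path.
#' @return data.frame with typed columns (`pos` etc. integer, `in_cgi` logical).
#' @export
read_manifest <- function(path) {
  man <- data.table::fread(path, data.table = FALSE, na.strings = c("NA", ""))
  validate_manifest(man)
}

#' Validate a CpG manifest
#' @param man Manifest data.frame.
#' @return The manifest (gene NAs normalised to ""), invisibly returned visibly.
#' @export
validate_manifest <- function(man) {
  need <- c("probe_id", "chrom", "pos", "strand", "in_cgi",
            "gene", "tss_pos", "gene_start", "gene_end")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$probe_id)) stop("duplicate probe ids in manifest")
  man$gene[is.na(man$gene)] <- ""
  man$in_cgi <- as.logical(man$in_cgi)
  no_gene <- man$gene == ""
  if (any(no_gene & !is.na(man$tss_pos)))
    stop("manifest rows with tss_pos but no gene")
  span <- !is.na(man$gene_start) & !is.na(man$gene_end)
  if (any(span & man$gene_start > man$gene_end))
    stop("manifest rows with gene_start > gene_end")
  man
}

#' Read an epigenetic-clock probe list
#'
#' @param path Plain-text file, one probe id per line.
#' @return Character vector of probe ids.
#' @export
read_clock_list <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0) stop("clock list is empty: ", path)
  if (!all(grepl("^[A-Za-z][A-Za-z0-9_.-]*$", ids)))
    stop("clock list contains ids that do not look like probe ids")
  unique(ids)
}

#' Merge cohorts on their common probe universe
#'
#' Probes enter the merged universe only if observed (non-missing) in all
#' samples of every cohort, up to `max_missing_frac` missing samples per
#' cohort. Probe order follows the first cohort; sample ids are prefixed
#' with `"<cohort>:"` to guarantee global uniqueness.
#'
#' Sample ids are prefixed with their own cohort (`"<cohort>:"`) unless
#' already carrying that prefix, which makes the merge idempotent on its own
#' output.
#'
#' @param matrices List of beta matrices, one per cohort.
#' @param sheets List of matching sample sheets (same length/order).
#' @param max_missing_frac Maximum tolerated fraction of missing samples per
#'   probe within each cohort (default 0: probe must be complete everywhere).
#' @return List with elements `beta` (merged matrix) and `sheet` (merged
#'   sample sheet recording the cohort of origin).
#' @export
merge_cohorts <- function(matrices, sheets, max_missing_frac = 0) {
  stopifnot(length(matrices) >= 1, length(matrices) == length(sheets))
  keep_per_cohort <- lapply(matrices, function(m) {
    ok <- rowMeans(is.na(m)) <= max_missing_frac
    rownames(m)[ok]
  })
  universe <- Reduce(intersect, keep_per_cohort)
  # preserve first-cohort order
  universe <- keep_per_cohort[[1]][keep_per_cohort[[1]] %in% universe]
  if (length(universe) == 0) stop("no probes shared by all cohorts")
  prefix <- function(ids, cohorts) {
    ifelse(startsWith(ids, paste0(cohorts, ":")), ids,
           paste0(cohorts, ":", ids))
  }
  pieces <- vector("list", length(matrices))
  sheet_pieces <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    s <- sheets[[i]]
    m <- matrices[[i]][universe, , drop = FALSE]
    col_cohort <- s$cohort[match(colnames(m), s$sample_id)]
    colnames(m) <- prefix(colnames(m), col_cohort)
    pieces[[i]] <- m
    s$sample_id <- prefix(s$sample_id, s$cohort)
    sheet_pieces[[i]] <- s
  }
  beta <- do.call(cbind, pieces)
  sheet <- do.call(rbind, sheet_pieces)
  validate_beta_matrix(beta)
  validate_sample_sheet(sheet, beta)
  list(beta = beta, sheet = sheet)
}

#' Export a CpG panel as BED6
#'
#' Single-base intervals in 0-based half-open convention
#' (`start = pos - 1`, `end = pos`), sorted by chromosome then start.
#'
#' @param panel Character vector of probe ids.
#' @param manifest CpG manifest containing every panel probe.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, manifest, path) {
  missing <- setdiff(panel, manifest$probe_id)
  if (length(missing))
    stop("panel probes without manifest coordinates: ",
         paste(missing, collapse = ", "))
  if (length(panel) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- manifest[match(panel, manifest$probe_id), ]
  bed <- data.frame(chrom = rows$chrom,
                    start = rows$pos - 1L,
                    end = rows$pos,
                    name = rows$probe_id,
                    score = ".",
                    strand = ifelse(is.na(rows$strand) | rows$strand == "",
                                    ".", rows$strand),
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$name), ]
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pipeline table with a JSON run summary
#'
#' Writes `records` as TSV at `path` and, alongside it, a
#' `<path>.summary.json` recording thresholds, per-stage counts and the
#' seed, so any run can be audited and reproduced.
#'
#' @param records data.frame to write (columns kept in order given).
#' @param path Output TSV path.
#' @param summary Named list appended to the JSON summary (e.g. thresholds,
#'   stage counts, seed). A `timestamp` field is added automatically.
#' @return Invisible list with `table` and `summary` paths.
#' @export
write_report <- function(records, path, summary = list()) {
  if (is.null(records)) stop("records must be non-null")
  data.table::fwrite(as.data.frame(records), path, sep = "\t",
                     na = "NA", quote = FALSE)
  summary_path <- paste0(path, ".summary.json")
  payload <- c(summary, list(timestamp = format(Sys.time(), tz = "UTC")))
  jsonlite::write_json(payload, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(table = path, summary = summary_path))
}
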