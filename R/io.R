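# Readers/writers for the package's data carriers. Intensities are kept
# on the linear (MAS5-like) scale at parse time; the log2(x + 1)
# transform is applied downstream (evidence mapping, calibration), never
# here, so there is a single documented transform site. Missing values
# stay missing and become "no observation" evidence.

#' Validate an expression tibble
#'
#' An expression matrix is a tibble with a character `probeset_id` first
#' column (unique IDs) and one numeric column per sample (unique sample
#' IDs); `NA` marks a missing measurement.
#'
#' @param data Candidate expression tibble.
#' @return `data`, invisibly, or an error.
#' @keywords internal
check_expression <- function(data) {
  if (!is.data.frame(data) || names(data)[1] != "probeset_id") {
    abort_pathact("expression data must be a data frame with first column `probeset_id`")
  }
  if (ncol(data) < 2) {
    abort_pathact("expression data must contain at least one sample column")
  }
  if (anyDuplicated(data$probeset_id)) {
    abort_pathact("duplicate probeset IDs in expression data")
  }
  if (anyDuplicated(names(data))) {
    abort_pathact("duplicate sample IDs in expression data")
  }
  invisible(data)
}

split_tsv_lines <- function(lines, path) {
  lines <- sub("\r$", "", lines)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops a trailing empty field (missing value in the last column)
  ends <- endsWith(lines, "\t")
  parts[ends] <- lapply(parts[ends], function(x) c(x, ""))
  parts
}

parse_expression_table <- function(lines, path, first_line_number = 1,
                                   strip_quotes = FALSE) {
  cells <- split_tsv_lines(lines, path)
  if (strip_quotes) {
    cells <- lapply(cells, function(x) gsub('^"|"$', "", x))
  }
  header <- cells[[1]]
  n_col <- length(header)
  if (n_col < 2) {
    abort_pathact(paste0(path, ": header must name an ID column and at least one sample"))
  }
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids) || any(sample_ids == "")) {
    abort_pathact(paste0(path, ": sample IDs must be unique and non-empty"))
  }
  body <- cells[-1]
  widths <- lengths(body)
  bad <- which(widths != n_col)
  if (length(bad) > 0) {
    abort_pathact(paste0(
      path, ": line ", first_line_number + bad[1],
      " has ", widths[bad[1]], " fields, expected ", n_col
    ))
  }
  ids <- vapply(body, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort_pathact(paste0(
      path, ": duplicate probeset ID(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1,
                 dimnames = list(NULL, sample_ids))
  for (j in seq_len(n_col - 1)) {
    raw <- vapply(body, `[[`, character(1), j + 1)
    empty <- raw == "" | toupper(raw) %in% c("NA", "NULL")
    num <- suppressWarnings(as.numeric(raw))
    bad_num <- which(!empty & is.na(num))
    if (length(bad_num) > 0) {
      abort_pathact(paste0(
        path, ": line ", first_line_number + bad_num[1],
        ": non-numeric value \"", raw[bad_num[1]], "\" in column ",
        sample_ids[j]
      ))
    }
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  dplyr::bind_cols(tibble::tibble(probeset_id = ids),
                   tibble::as_tibble(vals))
}

#' Read a tab-separated expression matrix
#'
#' First header cell names the ID column (renamed to `probeset_id`),
#' remaining header cells are sample IDs. Empty cells (or `NA`) become
#' missing values. Ragged rows and duplicate probeset IDs are rejected
#' with the offending line.
#'
#' @param path Path to a TSV file.
#' @return Expression tibble (`probeset_id` + one column per sample).
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) abort_pathact(paste0(path, ": empty file"))
  out <- parse_expression_table(lines, path)
  check_expression(out)
  out
}

#' Write a tab-separated expression matrix
#'
#' Values are written with 17 significant digits so that
#' `read_expression_tsv(write_expression_tsv(x))` round-trips doubles
#' exactly; missing values are written as empty cells.
#'
#' @param data Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(data, path) {
  check_expression(data)
  sample_ids <- setdiff(names(data), "probeset_id")
  header <- paste(c("probeset_id", sample_ids), collapse = "\t")
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  body <- vapply(seq_len(nrow(data)), function(i) {
    paste(c(data$probeset_id[i],
            vapply(sample_ids, function(s) fmt(data[[s]][i]), character(1))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GEO series-matrix text file
#'
#' Parses the expression table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers and
#' captures `!Sample_*` metadata lines (e.g. title, GEO accession) as
#' per-sample annotations. Quoted and unquoted identifiers and Windows
#' line endings are both tolerated.
#'
#' @param path Path to an uncompressed series-matrix file.
#' @return A list with `expression` (tibble as in
#'   [read_expression_tsv()]) and `annotations` (tibble: `sample_id`
#'   plus one column per captured metadata key).
#' @export
read_series_matrix <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin) {
    abort_pathact(paste0(
      path, ": series-matrix table markers missing or malformed ",
      "(!series_matrix_table_begin / !series_matrix_table_end)"
    ))
  }
  tbl_lines <- lines[(begin + 1):(end - 1)]
  if (length(tbl_lines) < 1) {
    abort_pathact(paste0(path, ": empty series-matrix table"))
  }
  expression <- parse_expression_table(tbl_lines, path,
                                       first_line_number = begin + 1,
                                       strip_quotes = TRUE)
  check_expression(expression)

  meta_lines <- grep("^!Sample_", lines[seq_len(begin - 1)], value = TRUE)
  sample_ids <- setdiff(names(expression), "probeset_id")
  ann <- tibble::tibble(sample_id = sample_ids)
  for (ml in meta_lines) {
    parts <- gsub('^"|"$', "", strsplit(ml, "\t", fixed = TRUE)[[1]])
    key <- sub("^!Sample_", "", parts[1])
    vals <- parts[-1]
    if (length(vals) == length(sample_ids) && !(key %in% names(ann))) {
      ann[[key]] <- vals
    }
  }
  list(expression = expression, annotations = ann)
}

# ---- model spec JSON ----

MODEL_SPEC_SCHEMA_VERSION <- "1.0"

#' Read and write pathway model specification files
#'
#' The model spec is a JSON document:
#' `{"schema_version": "1.0", "pathway": ..., "prior_active": ...,
#' "frozen": ..., "thresholds": {...}, "target_genes": [{"gene": ...,
#' "direction": ..., "p_up_given_active": ..., "p_up_given_inactive":
#' ..., "probesets": [{"id": ..., "p_high_given_up": ...,
#' "p_high_given_down": ..., "log2_threshold": ..., "soft_scale":
#' ...}]}]}`. Probabilities are serialised with 17 significant digits so
#' that write/read round-trips are bit-exact. Schema violations and
#' degenerate probabilities are rejected.
#'
#' @param path Path to the JSON file.
#' @return [read_model_spec()] returns a `pathway_model`;
#'   [write_model_spec()] returns `path` invisibly.
#' @export
read_model_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("schema_version", "pathway", "prior_active", "target_genes")) {
    if (is.null(doc[[field]])) {
      abort_pathact(paste0(path, ": model spec is missing field `", field, "`"))
    }
  }
  if (!identical(as.character(doc$schema_version), MODEL_SPEC_SCHEMA_VERSION)) {
    abort_pathact(paste0(
      path, ": unsupported schema_version \"", doc$schema_version,
      "\" (expected \"", MODEL_SPEC_SCHEMA_VERSION, "\")"
    ))
  }
  rows <- purrr::map_dfr(doc$target_genes, function(tg) {
    for (field in c("gene", "direction", "p_up_given_active",
                    "p_up_given_inactive", "probesets")) {
      if (is.null(tg[[field]])) {
        abort_pathact(paste0(path, ": target gene entry is missing `", field, "`"))
      }
    }
    purrr::map_dfr(tg$probesets, function(psn) {
      for (field in c("id", "p_high_given_up", "p_high_given_down",
                      "log2_threshold", "soft_scale")) {
        if (is.null(psn[[field]])) {
          abort_pathact(paste0(
            path, ": probeset entry of gene ", tg$gene,
            " is missing `", field, "`"
          ))
        }
      }
      tibble::tibble(
        gene = tg$gene, direction = tg$direction,
        p_up_given_active = as.numeric(tg$p_up_given_active),
        p_up_given_inactive = as.numeric(tg$p_up_given_inactive),
        probeset_id = psn$id,
        p_high_given_up = as.numeric(psn$p_high_given_up),
        p_high_given_down = as.numeric(psn$p_high_given_down),
        log2_threshold = as.numeric(psn$log2_threshold),
        soft_scale = as.numeric(psn$soft_scale)
      )
    })
  })
  thresholds <- c(default = 0)
  if (!is.null(doc$thresholds) && length(doc$thresholds) > 0) {
    thresholds <- unlist(doc$thresholds)
    if (is.null(names(thresholds))) {
      abort_pathact(paste0(path, ": `thresholds` must be a named object"))
    }
  }
  model <- pathway_model(rows, pathway = doc$pathway,
                         prior_active = as.numeric(doc$prior_active),
                         thresholds = thresholds)
  if (isTRUE(doc$frozen)) model <- freeze(model)
  model
}

#' @rdname read_model_spec
#' @param model A `pathway_model`.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "pathway_model"))
  ps <- model$probesets
  target_genes <- lapply(unique(ps$gene), function(g) {
    rows <- ps[ps$gene == g, ]
    list(
      gene = g,
      direction = rows$direction[1],
      p_up_given_active = rows$p_up_given_active[1],
      p_up_given_inactive = rows$p_up_given_inactive[1],
      probesets = lapply(seq_len(nrow(rows)), function(i) {
        list(
          id = rows$probeset_id[i],
          p_high_given_up = rows$p_high_given_up[i],
          p_high_given_down = rows$p_high_given_down[i],
          log2_threshold = rows$log2_threshold[i],
          soft_scale = rows$soft_scale[i]
        )
      })
    )
  })
  doc <- list(
    schema_version = MODEL_SPEC_SCHEMA_VERSION,
    pathway = model$pathway,
    prior_active = model$prior_active,
    frozen = model$frozen,
    thresholds = as.list(model$thresholds),
    target_genes = target_genes
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read and write calibration label files
#'
#' Two-column TSV (`sample_id`, `label`) with labels `active` or
#' `inactive`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id` and `label`.
#' @export
read_labels_tsv <- function(path) {
  lines <- sub("\r$", "", readLines(path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (length(cells) < 2) abort_pathact(paste0(path, ": no label rows"))
  header <- cells[[1]]
  if (length(header) != 2 || header[1] != "sample_id" || header[2] != "label") {
    abort_pathact(paste0(path, ": header must be `sample_id<TAB>label`"))
  }
  body <- cells[-1]
  bad <- which(lengths(body) != 2)
  if (length(bad) > 0) {
    abort_pathact(paste0(path, ": line ", 1 + bad[1], " does not have 2 fields"))
  }
  out <- tibble::tibble(
    sample_id = vapply(body, `[[`, character(1), 1),
    label = vapply(body, `[[`, character(1), 2)
  )
  if (!all(out$label %in% c("active", "inactive"))) {
    abort_pathact(paste0(path, ": labels must be `active` or `inactive`"))
  }
  if (anyDuplicated(out$sample_id)) {
    abort_pathact(paste0(path, ": duplicate sample IDs"))
  }
  out
}

#' @rdname read_labels_tsv
#' @param labels Tibble with columns `sample_id`, `label`.
#' @export
write_labels_tsv <- function(labels, path) {
  stopifnot(all(c("sample_id", "label") %in% names(labels)))
  writeLines(c("sample_id\tlabel",
               paste(labels$sample_id, labels$label, sep = "\t")), path)
  invisible(path)
}
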