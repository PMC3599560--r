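# Readers and writers for the three plain-text formats the package
# consumes: CSV expression tables, GEO SOFT (GDS) dataset files with
# subset cohort tags, and GMT gene-set collections. All readers accept
# plain or gzip-compressed files (gzfile() transparently handles both).

read_text_lines <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_numeric_cells <- function(cells, line_no) {
  vals <- suppressWarnings(as.numeric(cells))
  bad <- is.na(vals) | cells == ""
  if (any(bad)) {
    abort_parse(sprintf("line %d: non-numeric expression value '%s'",
                        line_no, cells[which(bad)[1L]]))
  }
  vals
}

#' Read a CSV expression table
#'
#' Fixed dialect: genes in rows, samples in columns; the first column
#' holds the gene identifier; a mandatory header row
#' `gene_id,<sample1>,<sample2>,...`; period decimal separator. All
#' samples start out unassigned — use [assign_classes()] or
#' [assign_classes_by_cohort()] before training. Plain or gzipped files
#' are accepted.
#'
#' @param path path to the CSV file.
#' @return an `expression_dataset` with row/column order as in the file.
#' @seealso [write_expression_csv()]
#' @export
read_expression_csv <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!(seq_along(lines) > 1L & lines == "")]
  if (length(lines) < 2L) abort_parse("CSV must contain a header and at least one gene row")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 2L) abort_parse("line 1: header must name at least one sample")
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    abort_parse(sprintf("line 1: duplicate sample id '%s'",
                        samples[duplicated(samples)][1L]))
  }
  n_fields <- length(header)
  rows <- strsplit(lines[-1L], ",", fixed = TRUE)
  genes <- character(length(rows))
  values <- matrix(NA_real_, length(rows), length(samples))
  for (i in seq_along(rows)) {
    line_no <- i + 1L
    row <- rows[[i]]
    if (length(row) != n_fields) {
      abort_parse(sprintf("line %d: expected %d fields, found %d",
                          line_no, n_fields, length(row)))
    }
    genes[i] <- row[1L]
    values[i, ] <- parse_numeric_cells(row[-1L], line_no)
  }
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    abort_parse(sprintf("line %d: duplicate gene id '%s'",
                        which(genes == dup)[2L] + 1L, dup))
  }
  expression_dataset(values, gene_ids = genes, sample_ids = samples)
}

#' Write a CSV expression table
#'
#' Inverse of [read_expression_csv()]; values are printed with 17
#' significant digits so the written file reads back bit-exactly.
#' Class labels are not stored in the CSV.
#'
#' @param dataset an `expression_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(dataset, path) {
  header <- paste(c("gene_id", sample_ids(dataset)), collapse = ",")
  body <- vapply(seq_len(n_genes(dataset)), function(i) {
    paste(c(gene_ids(dataset)[i], format_value(dataset$values[i, ])),
          collapse = ",")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GEO SOFT (GDS) dataset file
#'
#' Parses the GDS layout: `^SUBSET` blocks carrying
#' `!subset_description` and `!subset_sample_id` lines, and a dataset
#' table delimited by `!dataset_table_begin` / `!dataset_table_end`. The
#' table's first column is taken as the gene/probe identifier (an
#' optional second `IDENTIFIER` column is skipped); the remaining
#' columns are samples. Blank or `null` expression cells are rejected as
#' parse errors. Plain or gzipped files are accepted.
#'
#' @param path path to the SOFT file.
#' @return a list with elements `dataset` (an `expression_dataset`, all
#'   classes unassigned) and `cohorts` (named list: subset description
#'   -> character vector of sample ids). A sample may appear in several
#'   cohorts.
#' @export
read_soft <- function(path) {
  lines <- read_text_lines(path)
  begin <- which(lines == "!dataset_table_begin")
  end <- which(lines == "!dataset_table_end")
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    abort_parse("SOFT file must contain one !dataset_table_begin/!dataset_table_end block")
  }

  # subset blocks (anywhere above the table)
  cohorts <- list()
  current_desc <- NULL
  for (i in seq_len(begin - 1L)) {
    line <- lines[i]
    if (startsWith(line, "^SUBSET")) {
      current_desc <- NULL
    } else if (startsWith(line, "!subset_description")) {
      current_desc <- sub("^!subset_description\\s*=\\s*", "", line)
    } else if (startsWith(line, "!subset_sample_id")) {
      ids <- sub("^!subset_sample_id\\s*=\\s*", "", line)
      ids <- trimws(strsplit(ids, ",", fixed = TRUE)[[1L]])
      if (is.null(current_desc)) {
        abort_parse(sprintf("line %d: subset sample list without a description", i))
      }
      cohorts[[current_desc]] <- unique(c(cohorts[[current_desc]], ids))
    }
  }

  header <- strsplit(lines[begin + 1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) abort_parse("SOFT table header must name sample columns")
  skip <- if (length(header) >= 2L && header[2L] == "IDENTIFIER") 2L else 1L
  samples <- header[-seq_len(skip)]
  if (length(samples) < 1L) abort_parse("SOFT table has no sample columns")
  if (anyDuplicated(samples)) {
    abort_parse(sprintf("duplicate sample column '%s' in SOFT table",
                        samples[duplicated(samples)][1L]))
  }

  body_idx <- seq.int(begin + 2L, end - 1L)
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  genes <- character(length(rows))
  values <- matrix(NA_real_, length(rows), length(samples))
  for (i in seq_along(rows)) {
    line_no <- body_idx[i]
    row <- rows[[i]]
    if (length(row) != length(header)) {
      abort_parse(sprintf("line %d: expected %d fields, found %d",
                          line_no, length(header), length(row)))
    }
    genes[i] <- row[1L]
    cells <- row[-seq_len(skip)]
    if (any(tolower(cells) %in% c("null", "na", ""))) {
      abort_parse(sprintf("line %d: blank/null expression cell", line_no))
    }
    values[i, ] <- parse_numeric_cells(cells, line_no)
  }
  if (anyDuplicated(genes)) {
    abort_parse(sprintf("duplicate probe id '%s' in SOFT table",
                        genes[duplicated(genes)][1L]))
  }
  dataset <- expression_dataset(values, gene_ids = genes, sample_ids = samples)

  for (tag in names(cohorts)) {
    unknown <- setdiff(cohorts[[tag]], samples)
    if (length(unknown)) {
      abort_parse(sprintf("subset '%s' lists sample '%s' absent from the dataset table",
                          tag, unknown[1L]))
    }
  }
  list(dataset = dataset, cohorts = cohorts)
}

#' Assign classes from cohort tags
#'
#' Mirrors batch class definition from GEO subset metadata: every sample
#' carrying one of `class1_tags` goes to class 1, every sample carrying
#' one of `class2_tags` to class 2; all other samples become unassigned
#' and are excluded from training.
#'
#' @param dataset an `expression_dataset`.
#' @param cohorts named list mapping cohort tag -> sample ids, as
#'   returned by [read_soft()].
#' @param class1_tags,class2_tags character vectors of cohort tags
#'   (both non-empty).
#' @return the relabelled dataset.
#' @export
assign_classes_by_cohort <- function(dataset, cohorts, class1_tags, class2_tags) {
  if (length(class1_tags) == 0L || length(class2_tags) == 0L) {
    abort_precondition("both classes need at least one cohort tag")
  }
  unknown <- setdiff(c(class1_tags, class2_tags), names(cohorts))
  if (length(unknown)) {
    abort_lookup(sprintf("unknown cohort tag: %s", unknown[1L]))
  }
  ids1 <- unique(unlist(cohorts[class1_tags], use.names = FALSE))
  ids2 <- unique(unlist(cohorts[class2_tags], use.names = FALSE))
  both <- intersect(ids1, ids2)
  if (length(both)) {
    abort_conflict(sprintf("samples claimed by both classes: %s",
                           paste(both, collapse = ", ")))
  }
  assign_classes(dataset, ids1, ids2)
}

#' Gene-set collection
#'
#' An ordered collection of named gene sets ("networks"), as read from a
#' GMT file. Used by the DIRAC classifier.
#'
#' @param sets list of lists, each with elements `name`, `description`
#'   and `genes` (character vector).
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  nm <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) {
    abort_argument(sprintf("duplicate gene-set name: %s", nm[duplicated(nm)][1L]))
  }
  for (s in sets) {
    if (length(s$genes) == 0L) {
      abort_argument(sprintf("gene set '%s' is empty", s$name))
    }
  }
  structure(list(sets = sets), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$genes), integer(1L))
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n",
              length(x$sets), paste(range(sizes), collapse = "-")))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

set_names <- function(collection) {
  vapply(collection$sets, `[[`, character(1L), "name")
}

#' Read a GMT gene-set file
#'
#' One set per line: tab-separated name, description, then one or more
#' gene symbols. Duplicate symbols within a line are dropped, keeping
#' the first occurrence. Plain or gzipped files are accepted.
#'
#' @param path path to the GMT file.
#' @return a `gene_set_collection` in file order.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[lines != ""]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort_parse(sprintf("line %d: GMT line needs name, description and >=1 gene", i))
    }
    sets[[i]] <- list(name = fields[1L], description = fields[2L],
                      genes = unique(fields[-c(1L, 2L)]))
  }
  gene_set_collection(sets)
}

#' Write a GMT gene-set file
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Merge datasets by gene-identifier intersection
#'
#' Combines two or more datasets measured on (possibly) different gene
#' panels: the merged gene set is the exact intersection of all inputs'
#' gene identifiers, in the first dataset's order, and samples are
#' concatenated. Class labels are carried through. Probe identifiers are
#' never collapsed or translated — matching is by exact identifier.
#'
#' @param datasets list of two or more `expression_dataset` objects with
#'   globally unique sample ids.
#' @return the merged `expression_dataset`.
#' @export
merge_datasets <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    abort_argument("merge needs at least two datasets")
  }
  all_samples <- unlist(lapply(datasets, sample_ids), use.names = FALSE)
  if (anyDuplicated(all_samples)) {
    abort_conflict(sprintf("duplicate sample id across datasets: %s",
                           all_samples[duplicated(all_samples)][1L]))
  }
  common <- Reduce(intersect, lapply(datasets, gene_ids))
  common <- gene_ids(datasets[[1L]])[gene_ids(datasets[[1L]]) %in% common]
  if (length(common) == 0L) {
    abort_merge("gene-identifier intersection of the datasets is empty")
  }
  values <- do.call(cbind, lapply(datasets, function(d) {
    d$values[common, , drop = FALSE]
  }))
  classes <- unlist(lapply(datasets, sample_classes))
  expression_dataset(values, classes = classes)
}
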