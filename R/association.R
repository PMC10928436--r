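# Reading, filtering and summarizing miRNA-disease association records in the
# HMDD v3 dialect, plus the disease -> MeSH-class mapping.

EVIDENCE_UP <- "tissue_expression_up"
EVIDENCE_DOWN <- "tissue_expression_down"

#' HMDD column dialect
#'
#' Column-name configuration for [parse_hmdd_tsv()]. Defaults match the
#' HMDD v3.0 download (`category`, `mir`, `disease`, `pmid`, `description`);
#' other versions of the database can be parsed by overriding the names here,
#' without code changes.
#'
#' @param category name of the evidence-code column.
#' @param mirna name of the miRNA identifier column (pre-miRNA level).
#' @param disease name of the disease name column.
#' @param reference name of the literature reference (PMID) column.
#' @param description name of the free-text description column (optional in
#'   the input file).
#' @return a named list of class `hmdd_dialect`.
#' @export
hmdd_dialect <- function(category = "category", mirna = "mir",
                         disease = "disease", reference = "pmid",
                         description = "description") {
  structure(list(category = category, mirna = mirna, disease = disease,
                 reference = reference, description = description),
            class = "hmdd_dialect")
}

#' Parse an HMDD-style association TSV
#'
#' Reads a tab-separated miRNA-disease association table and maps each row to
#' an association record. Records whose evidence code is
#' `tissue_expression_up` get direction `+1`, `tissue_expression_down` gets
#' `-1`; rows with any other evidence code (Circulation, Genetics, Target, ...)
#' are returned with `curatable = FALSE` and `direction = NA` rather than
#' silently dropped, so filtering is auditable.
#'
#' @param path path to a UTF-8 TSV file with a header row.
#' @param dialect an [hmdd_dialect()] naming the columns.
#' @return a data frame with one row per input row and columns `mirna_id`,
#'   `disease_name`, `evidence_code`, `direction` (`+1`, `-1` or `NA`),
#'   `reference_id` and `curatable`.
#' @export
parse_hmdd_tsv <- function(path, dialect = hmdd_dialect()) {
  if (!file.exists(path)) {
    stop("input file not found: ", path)
  }
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "", check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("malformed association file '", path, "': ",
                             conditionMessage(e))
  )
  mandatory <- c("category", "mirna", "disease", "reference")
  for (field in mandatory) {
    col <- dialect[[field]]
    if (!col %in% names(raw)) {
      stop("missing mandatory column '", col, "' in ", path)
    }
  }
  if (nrow(raw) == 0L) {
    stop("association file '", path, "' contains a header but no records")
  }
  evidence <- tolower(trimws(raw[[dialect$category]]))
  direction <- ifelse(evidence == EVIDENCE_UP, 1L,
                      ifelse(evidence == EVIDENCE_DOWN, -1L, NA_integer_))
  data.frame(
    mirna_id = raw[[dialect$mirna]],
    disease_name = raw[[dialect$disease]],
    evidence_code = evidence,
    direction = direction,
    reference_id = raw[[dialect$reference]],
    curatable = !is.na(direction),
    stringsAsFactors = FALSE
  )
}

# Accept either the parser's column names or the curated internal ones.
canonical_records <- function(records) {
  stopifnot(is.data.frame(records))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(records)) return(records[[nm]])
    stop("records are missing a '", ..1, "' column")
  }
  mirna <- pick("mirna_id", "mirna")
  disease <- pick("disease_name", "disease")
  direction <- if ("direction" %in% names(records)) {
    records$direction
  } else {
    ev <- tolower(trimws(pick("evidence_code")))
    ifelse(ev == EVIDENCE_UP, 1L, ifelse(ev == EVIDENCE_DOWN, -1L, NA_integer_))
  }
  reference <- if ("reference_id" %in% names(records)) {
    records$reference_id
  } else if ("reference" %in% names(records)) {
    records$reference
  } else {
    rep(NA_character_, nrow(records))
  }
  data.frame(mirna = as.character(mirna), disease = as.character(disease),
             direction = as.integer(direction),
             reference_id = as.character(reference), stringsAsFactors = FALSE)
}

#' Curate association records into an analysis-ready dataset
#'
#' Keeps only records with an up/down tissue-expression direction, normalizes
#' names (miRNA ids lowercased and trimmed; disease names trimmed, compared
#' case-insensitively with the first-seen spelling kept for display), and
#' computes the marginals the similarity model needs: the disease count `N`,
#' the miRNA count `M`, per-pair signed record counts (record multiplicity is
#' preserved because the weight model sums over records, not pairs), and each
#' miRNA's disease spectrum width `n_j` (the number of distinct diseases it is
#' recorded in).
#'
#' Curation is idempotent: curating the `records` component of a curated
#' dataset reproduces the dataset.
#'
#' @param records a data frame of association records, e.g. from
#'   [parse_hmdd_tsv()] or the `records` of a previous curation.
#' @return an object of class `curated_dataset`: a list with `records`,
#'   `diseases` (sorted, `N` of them), `mirnas` (sorted, `M` of them),
#'   `pair_counts` (per (disease, miRNA) pair: `up`, `down`, `records`),
#'   `n_j` (named integer vector), `N`, `M`, and `n_dropped` (records removed
#'   by the evidence filter).
#' @export
curate <- function(records) {
  rec <- canonical_records(records)
  keep <- !is.na(rec$direction) & rec$direction %in% c(-1L, 1L)
  n_dropped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    stop("no curatable records: every record lacks an up/down ",
         "tissue-expression evidence code")
  }
  rec$mirna <- norm_mirna(rec$mirna)
  disease_raw <- trimws(rec$disease)
  key <- tolower(disease_raw)
  display <- disease_raw[!duplicated(key)]
  names(display) <- key[!duplicated(key)]
  rec$disease <- unname(display[key])
  rec$evidence_code <- ifelse(rec$direction == 1L, EVIDENCE_UP, EVIDENCE_DOWN)
  rownames(rec) <- NULL
  rec <- rec[, c("mirna", "disease", "direction", "evidence_code",
                 "reference_id")]

  diseases <- sort(unique(rec$disease), method = "radix")
  mirnas <- sort(unique(rec$mirna), method = "radix")

  pair_key <- paste(rec$disease, rec$mirna, sep = "\r")
  up <- rowsum(as.integer(rec$direction == 1L), pair_key)
  down <- rowsum(as.integer(rec$direction == -1L), pair_key)
  parts <- strsplit(rownames(up), "\r", fixed = TRUE)
  pair_counts <- data.frame(
    disease = vapply(parts, `[`, character(1), 1L),
    mirna = vapply(parts, `[`, character(1), 2L),
    up = as.integer(up[, 1]),
    down = as.integer(down[, 1]),
    stringsAsFactors = FALSE
  )
  pair_counts$records <- pair_counts$up + pair_counts$down
  ord <- order(pair_counts$disease, pair_counts$mirna, method = "radix")
  pair_counts <- pair_counts[ord, , drop = FALSE]
  rownames(pair_counts) <- NULL

  n_j <- vapply(split(pair_counts$disease, pair_counts$mirna),
                function(d) length(unique(d)), integer(1))
  n_j <- n_j[mirnas]

  structure(list(records = rec, diseases = diseases, mirnas = mirnas,
                 pair_counts = pair_counts, n_j = n_j,
                 N = length(diseases), M = length(mirnas),
                 n_dropped = n_dropped),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("Curated miRNA-disease association dataset\n")
  cat(sprintf("  %d records over %d diseases and %d miRNAs\n",
              nrow(x$records), x$N, x$M))
  up <- unique_pair_counts(x)
  cat(sprintf("  %d unique (disease, miRNA, direction) pairs: %d up, %d down\n",
              up["total"], up["up"], up["down"]))
  invisible(x)
}

#' Count unique association pairs by direction
#'
#' Deduplicates the curated records to distinct (disease, miRNA, direction)
#' triples and counts them by direction. This is the pair-level summary of the
#' dataset; record multiplicity is intentionally collapsed here and only here.
#'
#' @param dataset a `curated_dataset`.
#' @return named integer vector `c(up, down, total)`.
#' @export
unique_pair_counts <- function(dataset) {
  stopifnot(inherits(dataset, "curated_dataset"))
  pc <- dataset$pair_counts
  n_up <- sum(pc$up > 0L)
  n_down <- sum(pc$down > 0L)
  c(up = n_up, down = n_down, total = n_up + n_down)
}

#' Construct a disease-to-class map
#'
#' @param disease character vector of disease names.
#' @param class character vector of class labels (e.g. MeSH top-level
#'   categories), same length.
#' @return an object of class `class_map`.
#' @export
class_map <- function(disease, class) {
  stopifnot(length(disease) == length(class), length(disease) >= 1L)
  key <- norm_disease_key(disease)
  if (anyDuplicated(key)) {
    dup <- disease[duplicated(key)][1L]
    stop("duplicate disease in class map: ", dup)
  }
  map <- as.character(class)
  names(map) <- key
  structure(list(map = map, display = trimws(as.character(disease))),
            class = "class_map")
}

#' Read a disease-to-class mapping TSV
#'
#' Expects a header row with columns `disease` and `class`.
#'
#' @param path TSV file path.
#' @return a `class_map`.
#' @export
read_class_map <- function(path) {
  if (!file.exists(path)) stop("class map file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE, colClasses = "character")
  for (col in c("disease", "class")) {
    if (!col %in% names(df)) stop("class map is missing column '", col, "'")
  }
  class_map(df$disease, df$class)
}

#' Write a class map to TSV
#'
#' @param classes a `class_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(classes, path) {
  stopifnot(inherits(classes, "class_map"))
  df <- data.frame(disease = classes$display,
                   class = unname(classes$map), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up the class of each disease
#'
#' The class map must be total on the queried diseases: an unmapped disease is
#' an error naming the disease, never a silent default.
#'
#' @param classes a `class_map`.
#' @param diseases character vector of disease names.
#' @return character vector of class labels, named by `diseases`.
#' @export
disease_classes <- function(classes, diseases) {
  stopifnot(inherits(classes, "class_map"))
  out <- unname(classes$map[norm_disease_key(diseases)])
  if (anyNA(out)) {
    stop("disease not present in class map: ",
         paste(diseases[is.na(out)], collapse = ", "))
  }
  names(out) <- diseases
  out
}

#' Summarize a curated dataset
#'
#' Reports per-class disease counts, the top `k` diseases ranked by number of
#' distinct associated miRNAs, and the top `k` miRNAs ranked by number of
#' distinct associated diseases (the disease spectrum width). Ties are broken
#' lexicographically by name; if `k` exceeds the number of entities the full
#' ranking is returned without padding.
#'
#' @param dataset a `curated_dataset`.
#' @param classes a `class_map`, total on the dataset's diseases.
#' @param k number of top entries to report (default 10).
#' @return a list with data frames `class_counts`, `top_diseases`,
#'   `top_mirnas`.
#' @export
dataset_summary <- function(dataset, classes, k = 10L) {
  stopifnot(inherits(dataset, "curated_dataset"), k >= 1L)
  cls <- disease_classes(classes, dataset$diseases)
  tab <- table(cls)
  class_counts <- data.frame(class = names(tab),
                             n_diseases = as.integer(tab),
                             stringsAsFactors = FALSE)
  class_counts <- class_counts[order(-class_counts$n_diseases,
                                     class_counts$class, method = "radix"), ]
  rownames(class_counts) <- NULL

  pc <- dataset$pair_counts
  d_counts <- vapply(split(pc$mirna, pc$disease),
                     function(m) length(unique(m)), integer(1))
  top_diseases <- data.frame(disease = names(d_counts),
                             n_mirnas = as.integer(d_counts),
                             stringsAsFactors = FALSE)
  top_diseases <- top_diseases[order(-top_diseases$n_mirnas,
                                     tolower(top_diseases$disease),
                                     method = "radix"), ]
  top_diseases <- utils::head(top_diseases, k)
  rownames(top_diseases) <- NULL

  top_mirnas <- data.frame(mirna = names(dataset$n_j),
                           n_diseases = as.integer(dataset$n_j),
                           stringsAsFactors = FALSE)
  top_mirnas <- top_mirnas[order(-top_mirnas$n_diseases, top_mirnas$mirna,
                                 method = "radix"), ]
  top_mirnas <- utils::head(top_mirnas, k)
  rownames(top_mirnas) <- NULL

  list(class_counts = class_counts, top_diseases = top_diseases,
       top_mirnas = top_mirnas)
}
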