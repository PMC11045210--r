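# Data containers and plain-text readers/writers: expression matrices with
# tumor/normal labels, GMT annotation maps, minimal OBO is_a edges, and
# survival tables.

#' Construct an expression dataset
#'
#' Bundles a genes x samples matrix of normalized expression values with a
#' binary tumor/normal label per sample. Values may be on the linear scale
#' (FPKM/RPKM-like, non-negative) or already log2-transformed; the scale is
#' declared by the caller and never inferred, because a silent misdetection
#' would corrupt every downstream fold change.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param labels Character vector of class labels, one per sample, each
#'   `"tumor"` or `"normal"` (case-insensitive). May be named by sample id;
#'   unnamed vectors are matched positionally.
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `labels` (named character), and `scale`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
#' ds <- expression_dataset(m, c("tumor", "tumor", "normal"))
#' dim(ds$values)
#' @export
expression_dataset <- function(values, labels, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  if (scale == "linear" && any(values < 0))
    stop("negative expression value under scale = \"linear\"")
  labels <- normalize_labels(labels, colnames(values))
  structure(list(values = values, labels = labels, scale = scale),
            class = "expression_dataset")
}

normalize_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("missing class label for sample(s): ", paste(missing, collapse = ", "))
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("`labels` must cover every sample (", length(sample_ids), " needed)")
  }
  lab <- tolower(trimws(as.character(labels)))
  bad <- !lab %in% c("tumor", "normal")
  if (any(bad))
    stop("labels must be tumor/normal; offending value(s): ",
         paste(unique(labels[bad]), collapse = ", "))
  stats::setNames(lab, sample_ids)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s scale); %d tumor / %d normal\n",
              nrow(x$values), ncol(x$values), x$scale,
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  invisible(x)
}

infer_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix with class labels
#'
#' Reads a delimited text matrix (TSV by default, CSV by extension) with ids
#' in the header row and first column. Labels come either from a separate
#' two-column file (`sample_id<TAB>class`) or from a row (or column, under
#' `samples_in_rows`) of the matrix itself named `class` or `label`.
#'
#' Duplicate gene rows are collapsed by keeping the row with the highest mean
#' expression (the common probe-collapse rule); the number collapsed is
#' reported via [message()].
#'
#' @param path Path to the matrix file.
#' @param labels_file Optional path to a two-column label file. When `NULL`,
#'   an embedded `class`/`label` row is looked for.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param scale Declared value scale, `"linear"` or `"log2"`.
#' @param sep Field separator; inferred from the file extension when `NULL`.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, labels_file = NULL,
                            orientation = c("genes_in_rows", "samples_in_rows"),
                            scale = c("linear", "log2"), sep = NULL) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- sep %||% infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]  # duplicates allowed here; collapsed below
  if (orientation == "samples_in_rows") m <- t(m)
  labels <- NULL
  label_row <- which(tolower(rownames(m)) %in% c("class", "label"))
  if (length(label_row)) {
    labels <- stats::setNames(m[label_row[1], ], colnames(m))
    m <- m[-label_row, , drop = FALSE]
  }
  if (!is.null(labels_file)) {
    if (!file.exists(labels_file)) stop("labels file not found: ", labels_file)
    labels <- read_labels(labels_file)
  }
  if (is.null(labels))
    stop("no class labels: supply `labels_file` or embed a 'class' row")
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (scale == "linear" && any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s' under scale = \"linear\"",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  num <- collapse_duplicate_genes(num)
  expression_dataset(num, labels, scale)
}

collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  means <- rowMeans(m)
  ord <- order(rownames(m), -means)  # within a gene id, highest mean first
  m2 <- m[ord, , drop = FALSE]
  keep <- !duplicated(rownames(m2))
  message(sum(!keep), " duplicate gene row(s) collapsed to the max-mean row")
  # restore first-appearance order of the surviving ids
  m2 <- m2[keep, , drop = FALSE]
  m2[unique(rownames(m)), , drop = FALSE]
}

#' Read a two-column sample label file
#'
#' @param path TSV/CSV file with columns sample id and class (tumor/normal).
#' @return Named character vector of lower-cased labels.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = infer_sep(path),
                           colClasses = "character", comment.char = "")
  if (ncol(tab) < 2) stop("label file needs two columns: sample_id, class")
  if (tolower(tab[1, 2]) %in% c("class", "label")) tab <- tab[-1, , drop = FALSE]
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write an expression dataset (matrix + labels) to disk
#'
#' Values are serialized with 17 significant digits so a read round-trips to
#' the identical double-precision matrix.
#'
#' @param ds An [expression_dataset()].
#' @param path Output matrix TSV (genes in rows).
#' @param labels_file Output two-column label TSV.
#' @return Invisibly, `c(path, labels_file)`.
#' @export
write_expression <- function(ds, path, labels_file) {
  chr <- matrix(sprintf("%.17g", ds$values), nrow(ds$values),
                dimnames = dimnames(ds$values))
  out <- cbind(gene_id = rownames(chr), chr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(ds$labels), class = ds$labels),
                     labels_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(path, labels_file))
}

#' Construct an annotation map
#'
#' A disease term to gene-set mapping, optionally carrying `is_a` edges of
#' the ontology for ancestor propagation.
#'
#' @param term_to_genes Named list; each element a character vector of gene
#'   ids annotated to that term (de-duplicated; must be non-empty).
#' @param term_names Optional named character vector of human-readable term
#'   labels.
#' @param dag_edges Optional two-column data.frame/matrix of `(child, parent)`
#'   is_a pairs; must be acyclic.
#' @return An object of class `annotation_map`.
#' @export
annotation_map <- function(term_to_genes, term_names = NULL, dag_edges = NULL) {
  if (!length(term_to_genes) || is.null(names(term_to_genes)))
    stop("`term_to_genes` must be a non-empty named list")
  term_to_genes <- lapply(term_to_genes, function(g) unique(as.character(g)))
  if (any(lengths(term_to_genes) == 0))
    stop("every term must annotate at least one gene")
  if (is.null(term_names))
    term_names <- stats::setNames(names(term_to_genes), names(term_to_genes))
  if (!is.null(dag_edges)) {
    dag_edges <- as.data.frame(dag_edges, stringsAsFactors = FALSE)
    names(dag_edges) <- c("child", "parent")
    check_acyclic(dag_edges)
  }
  structure(list(term_to_genes = term_to_genes,
                 term_names = term_names,
                 dag_edges = dag_edges),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms, %d distinct genes%s\n",
              length(x$term_to_genes),
              length(unique(unlist(x$term_to_genes, use.names = FALSE))),
              if (is.null(x$dag_edges)) "" else sprintf(", %d is_a edges", nrow(x$dag_edges))))
  invisible(x)
}

# Depth-first cycle check; reports one offending cycle on failure.
check_acyclic <- function(edges) {
  if (!nrow(edges)) return(invisible(TRUE))
  children <- split(edges$parent, edges$child)  # child -> parents (edge direction)
  state <- new.env(parent = emptyenv())
  visit <- function(node, path) {
    st <- state[[node]] %||% 0L
    if (st == 1L) {
      cyc <- c(path[which(path == node)[1]:length(path)], node)
      stop("cycle in is_a edges: ", paste(cyc, collapse = " -> "))
    }
    if (st == 2L) return()
    state[[node]] <- 1L
    for (p in children[[node]] %||% character()) visit(p, c(path, node))
    state[[node]] <- 2L
  }
  for (n in unique(edges$child)) visit(n, character())
  invisible(TRUE)
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one term per line, `term_id TAB description TAB gene...`.
#' Genes listed twice under one term are de-duplicated.
#'
#' @param path GMT file path.
#' @return An [annotation_map()] without DAG edges.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); nm <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need term, description, >=1 gene",
                   i, length(f)))
    sets[[f[1]]] <- unique(c(sets[[f[1]]], f[-(1:2)]))
    nm[f[1]] <- f[2]
  }
  annotation_map(sets, nm)
}

#' Write an annotation map to GMT
#'
#' @param map An [annotation_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(map, path) {
  lines <- vapply(names(map$term_to_genes), function(t) {
    paste(c(t, unname(map$term_names[t]), map$term_to_genes[[t]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read is_a edges from a minimal OBO flat file
#'
#' Parses only `[Term]` stanzas and their `id:`, `name:`, `is_a:` and
#' `is_obsolete:` tags; obsolete terms are skipped, every other tag is
#' ignored. The resulting edge set must be acyclic.
#'
#' @param path OBO 1.2/1.4 flat file.
#' @return data.frame with columns `child`, `parent` (zero rows when the file
#'   has no `is_a` lines), with a `term_names` attribute.
#' @export
read_obo_isa <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  edges <- list(); nms <- character()
  cur <- NULL; cur_parents <- character(); obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete && length(cur_parents))
      edges[[length(edges) + 1L]] <<- data.frame(child = cur, parent = cur_parents,
                                                 stringsAsFactors = FALSE)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; cur_parents <- character(); obsolete <- FALSE; in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:") && !is.null(cur)) nms[cur] <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur_parents <- c(cur_parents, tgt)
    } else if (startsWith(ln, "is_obsolete:") && grepl("true", ln)) obsolete <- TRUE
  }
  flush()
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(child = character(), parent = character(), stringsAsFactors = FALSE)
  check_acyclic(out)
  attr(out, "term_names") <- nms
  out
}

#' Read a survival table
#'
#' Expects columns sample id, time, event (header optional; recognized names
#' are matched case-insensitively, otherwise the first three columns are
#' used). Rows with missing time or event are dropped with a reported count.
#'
#' @param path TSV/CSV file.
#' @return data.frame of class `survival_table` with columns `sample`,
#'   `time` (positive), `event` (0 censored / 1 event).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                           stringsAsFactors = FALSE, comment.char = "")
  nm <- tolower(names(tab))
  pick <- function(cands, fallback) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1] else fallback
  }
  df <- data.frame(sample = as.character(tab[[pick(c("sample", "sample_id", "id"), 1)]]),
                   time = suppressWarnings(as.numeric(tab[[pick("time", 2)]])),
                   event = suppressWarnings(as.numeric(tab[[pick(c("event", "status"), 3)]])),
                   stringsAsFactors = FALSE)
  survival_table(df)
}

#' Validate a survival table
#'
#' @param df data.frame with columns `sample`, `time`, `event`.
#' @return The validated data.frame, classed `survival_table`.
#' @export
survival_table <- function(df) {
  stopifnot(all(c("sample", "time", "event") %in% names(df)))
  drop <- is.na(df$time) | is.na(df$event)
  if (any(drop)) {
    message(sum(drop), " survival row(s) dropped for missing time/event")
    df <- df[!drop, , drop = FALSE]
  }
  if (any(df$time <= 0)) stop("survival times must be > 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in survival table")
  rownames(df) <- NULL
  class(df) <- c("survival_table", "data.frame")
  df
}
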