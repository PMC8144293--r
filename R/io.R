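#' Read a sample-by-ASV count table from TSV
#'
#' Parses a tab-separated count table with one header row and one id column
#' into a validated sample-by-taxon integer matrix. Leading lines beginning
#' with `#` are treated as comments and skipped, with one exception that
#' accommodates the BIOM TSV export dialect: a leading `#` line that itself
#' contains tab-separated fields (e.g. `#OTU ID<tab>sample1...`) is taken as
#' the header, with the `#` stripped.
#'
#' Cells must parse as non-negative integers; non-integer or negative values
#' are rejected with their row/column coordinates rather than silently
#' rounded, because downstream metrics (Morisita in particular, whose
#' formula uses x(x-1)) are undefined on non-integer counts.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"samples-as-rows"` (default) or
#'   `"taxa-as-rows"`; the returned matrix always has samples as rows.
#' @return A numeric matrix of counts, samples as rows, taxa as columns,
#'   with unique dimnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tasv1\tasv2", "s1\t3\t0", "s2\t1\t2"), tf)
#' read_feature_table(tf)
#' @export
read_feature_table <- function(path, orientation = c("samples-as-rows", "taxa-as-rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("feature table file is empty: ", path)
  # skip leading comment lines; a '#' line with tab-separated fields is the
  # BIOM-dialect header
  first <- 1L
  while (first <= length(lines) && startsWith(lines[first], "#") &&
         !grepl("\t", lines[first], fixed = TRUE)) {
    first <- first + 1L
  }
  if (first > length(lines)) stop("no header row found in ", path)
  lines <- lines[first:length(lines)]
  lines[1] <- sub("^#", "", lines[1])

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2L) stop("header row must contain an id column and at least one data column")
  col_ids <- header[-1]
  body <- fields[-1]
  body <- body[vapply(body, function(f) length(f) > 0L && any(nzchar(f)), logical(1))]
  if (length(body) == 0L) stop("feature table has no data rows: ", path)
  bad_len <- which(vapply(body, length, integer(1)) != length(header))
  if (length(bad_len) > 0L) {
    stop("row ", bad_len[1] + 1L, " has ", length(body[[bad_len[1]]]),
         " fields, expected ", length(header))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)

  check_unique(row_ids, "row id")
  check_unique(col_ids, "column id")

  x <- matrix(NA_real_, nrow = length(body), ncol = length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop("non-numeric cell at row '", row_ids[i], "', column '",
           col_ids[bad[1]], "'")
    }
    x[i, ] <- v
  }
  validate_counts(x)
  if (orientation == "taxa-as-rows") x <- t(x)
  x
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate ", what, "(s): ", paste(dup, collapse = ", "))
  }
  invisible(ids)
}

#' Validate a count matrix
#'
#' Checks that a matrix holds non-negative integer counts with unique
#' sample and taxon identifiers. Called at every package entry point that
#' accepts a feature table.
#'
#' @param x Numeric matrix, samples as rows.
#' @return `x`, invisibly.
#' @export
validate_counts <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("counts must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count matrix must have sample (row) and taxon (column) names")
  }
  check_unique(rownames(x), "sample id")
  check_unique(colnames(x), "taxon id")
  bad <- which(is.na(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid count (negative, missing or non-integer) at row '",
         rownames(x)[bad[1, 1]], "', column '", colnames(x)[bad[1, 2]], "'")
  }
  invisible(x)
}

#' Read a rooted Newick phylogeny
#'
#' Wraps [ape::read.tree()] with the validation the pipeline relies on:
#' exactly one tree, unique non-empty leaf labels, branch lengths present
#' and non-negative on every edge. A missing root edge length defaults to
#' zero. Internal node labels are kept but never interpreted as lengths.
#'
#' @param path Path to a Newick file (or a literal Newick string via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return An [ape::read.tree()] `"phylo"` object with `root.edge` set.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    withCallingHandlers(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
      warning = function(w) stop("Newick parse error: ", conditionMessage(w))
    ),
    error = function(e) stop("Newick parse error: ", conditionMessage(e))
  )
  if (is.null(tr)) stop("Newick parse error: no tree found")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, found ", length(tr))
  validate_phylogeny(tr)
}

#' Validate a phylogeny for use with the diversity kernel
#'
#' @param tree A `"phylo"` object.
#' @return The tree with `root.edge` defaulted to 0, invisibly usable.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    stop("tree has unlabeled leaves")
  }
  check_unique(tree$tip.label, "leaf label")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) ||
      any(!is.finite(tree$edge.length))) {
    stop("tree has missing branch lengths; missing lengths are an error, not 0")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$root.edge)) tree$root.edge <- 0
  if (!is.finite(tree$root.edge) || tree$root.edge < 0) {
    stop("invalid root edge length")
  }
  tree
}

#' Total branch length of a phylogeny (including the root edge)
#' @param tree A validated `"phylo"` object.
#' @return Sum of all edge lengths plus the root edge.
#' @export
total_branch_length <- function(tree) {
  sum(tree$edge.length) + if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Reconcile a feature table with a phylogeny
#'
#' The phylogenetic metrics require every table taxon to be a tree leaf.
#' Three policies are offered: `"error"` refuses any mismatch, naming the
#' offending identifiers; `"prune-tree"` prunes tree leaves absent from the
#' table (degree-2 internal nodes are removed by summing their adjacent
#' branch lengths, so all pairwise leaf-to-leaf path lengths among retained
#' leaves are preserved); `"drop-taxa"` drops table taxa absent from the
#' tree.
#'
#' @param table Count matrix, samples as rows.
#' @param tree A `"phylo"` object.
#' @param policy One of `"error"`, `"prune-tree"`, `"drop-taxa"`.
#' @return `list(table =, tree =)` with leaf set covering the taxon set.
#' @export
align_table_and_tree <- function(table, tree,
                                 policy = c("error", "prune-tree", "drop-taxa")) {
  policy <- match.arg(policy)
  tree <- validate_phylogeny(tree)
  taxa <- colnames(table)
  leaves <- tree$tip.label
  missing_from_tree <- setdiff(taxa, leaves)
  extra_leaves <- setdiff(leaves, taxa)

  if (policy == "drop-taxa") {
    if (length(missing_from_tree) > 0L) {
      table <- table[, setdiff(taxa, missing_from_tree), drop = FALSE]
    }
    return(list(table = table, tree = tree))
  }
  if (length(missing_from_tree) > 0L) {
    stop("table taxa absent from tree: ",
         paste(utils::head(missing_from_tree, 10), collapse = ", "),
         if (length(missing_from_tree) > 10) " ...")
  }
  if (policy == "prune-tree" && length(extra_leaves) > 0L) {
    if (length(taxa) < 1L) stop("cannot prune tree to an empty taxon set")
    tree <- validate_phylogeny(ape::keep.tip(tree, taxa))
  }
  list(table = table, tree = tree)
}

#' Write a result table as deterministic tidy TSV
#'
#' Writes a rectangular set of named columns as a TSV with header, rows
#' sorted by all columns left to right, and doubles serialized with 10
#' significant digits so that a write/read round trip reproduces values at
#' that precision.
#'
#' @param records A data frame (or coercible).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 0L) {
    key <- lapply(records, function(col) if (is.numeric(col)) col else as.character(col))
    records <- records[do.call(order, unname(key)), , drop = FALSE]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.10g", out[[j]])
  }
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tidy TSV written by [write_tidy()]
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_tidy <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read sample metadata (sample_id, dataset_label)
#' @param path TSV with columns `sample_id` and `dataset_label`.
#' @return Data frame with those two columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "dataset_label")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  check_unique(md$sample_id, "metadata sample_id")
  md[, need]
}
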