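#' @useDynLib essnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rnorm runif sd var
#' @importFrom utils head read.delim write.table
NULL

# Canonical node order used everywhere: lexicographic on the C locale so that
# matrices, label vectors and tie-breaks are reproducible across platforms.
sort_ids <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(unique(x))
}

canonical_pair <- function(u, v) {
  swap <- u > v
  list(u = ifelse(swap, v, u), v = ifelse(swap, u, v))
}

#' Construct a static PPI network
#'
#' An undirected simple graph of protein identifiers: no self-loops, no
#' duplicate edges, each edge stored with its endpoints in lexicographic
#' order. Self-loops and duplicates in the input are dropped silently (they
#' are expected in raw interaction exports).
#'
#' @param u,v Character vectors of equal length: the interacting protein pairs.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   node identifiers to include in the node set.
#' @return An object of class `ppi_network`: a list with `nodes` (sorted
#'   character vector) and `edges` (data.frame with columns `u`, `v`,
#'   `u < v`, sorted by (`u`,`v`)).
#' @export
ppi_network <- function(u, v, nodes = character()) {
  stopifnot(length(u) == length(v))
  u <- as.character(u); v <- as.character(v)
  ok <- u != v
  p <- canonical_pair(u[ok], v[ok])
  key <- paste(p$u, p$v, sep = "\t")
  keep <- !duplicated(key)
  edges <- data.frame(u = p$u[keep], v = p$v[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = sort_ids(c(edges$u, edges$v, as.character(nodes))),
         edges = edges),
    class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(net) paste(net$edges$u, net$edges$v, sep = "\t")

#' Read a PPI network from a tab-separated edge list
#'
#' Accepts BioGRID-style exports: the first two tab-separated columns are the
#' interactor identifiers and any further columns are ignored. Self-loops and
#' duplicate records (in either endpoint order) are removed.
#'
#' @param source Path to a file or a connection.
#' @param comment_prefix Lines starting with this prefix are skipped.
#' @return A [ppi_network()].
#' @export
read_ppi_edge_list <- function(source, comment_prefix = "#") {
  lines <- readLines(source)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, comment_prefix)
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate whitespace-separated fixtures as well as strict TSV
  nf <- lengths(parts)
  if (any(nf < 2)) {
    resplit <- strsplit(lines[nf < 2], "[[:space:]]+")
    parts[nf < 2] <- resplit
    nf <- lengths(parts)
  }
  if (any(nf < 2)) {
    bad <- lineno[which(nf < 2)[1]]
    stop(sprintf("edge list line %d has fewer than 2 fields", bad))
  }
  u <- vapply(parts, `[[`, "", 1L)
  v <- vapply(parts, `[[`, "", 2L)
  net <- ppi_network(u, v)
  if (nrow(net$edges) == 0L)
    stop("edge list contains no edges after removing self-loops")
  net
}

#' Write a PPI network as a two-column edge list
#' @param net A [ppi_network()].
#' @param path Output file path.
#' @export
write_ppi_edge_list <- function(net, path) {
  writeLines(paste(net$edges$u, net$edges$v, sep = "\t"), path)
  invisible(path)
}

#' Read a temporal gene-expression matrix
#'
#' Expects a single header row of timepoint labels, then one row per protein:
#' the protein identifier followed by one numeric expression value per
#' timepoint. Rows must be rectangular and protein identifiers unique.
#'
#' @param source Path or connection.
#' @return Numeric matrix, rows named by protein, columns by timepoint.
#' @export
read_expression_matrix <- function(source) {
  lines <- readLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("expression matrix needs a header and >=1 row")
  split1 <- function(x) strsplit(x, "[\t ]+")[[1]]
  header <- split1(lines[1])
  rows <- lapply(lines[-1], split1)
  nt <- length(header)
  widths <- lengths(rows)
  if (any(widths != nt + 1L)) {
    bad <- which(widths != nt + 1L)[1]
    stop(sprintf("expression row %d has %d fields, expected %d",
                 bad, widths[bad], nt + 1L))
  }
  ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate expression row for protein '%s'",
                 ids[duplicated(ids)][1]))
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(nt)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stop(sprintf("non-numeric expression value in row for protein '%s'",
                 ids[bad]))
  }
  m <- t(matrix(vals, nrow = nt))
  dimnames(m) <- list(ids, header)
  m
}

#' Read a protein-to-subcellular-term table
#'
#' Two tab-separated columns per line: protein identifier and localization
#' term. Duplicate pairs are collapsed.
#'
#' @param source Path or connection.
#' @return data.frame with columns `protein`, `term` (unique pairs).
#' @export
read_localization_table <- function(source) {
  lines <- readLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("localization table is empty")
    return(data.frame(protein = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop(sprintf("localization line %d is missing the term column",
                 which(nf < 2L)[1]))
  tab <- data.frame(protein = vapply(parts, `[[`, "", 1L),
                    term = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(tab$term))) stop("empty localization term")
  tab <- tab[!duplicated(paste(tab$protein, tab$term, sep = "\t")), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read an essential-protein list (one identifier per line)
#' @param source Path or connection.
#' @return Character vector of unique identifiers.
#' @export
read_label_list <- function(source) {
  lines <- trimws(readLines(source))
  ids <- unique(lines[nzchar(lines)])
  if (length(ids) == 0L) warning("label list is empty")
  ids
}

#' Align the four inputs on the PPI node universe
#'
#' The sample universe is the network's node set in canonical (lexicographic)
#' order. Expression rows, localization records and labels that name proteins
#' outside the network are dropped (counts reported via message); network
#' nodes without an expression row are retained and treated as always active
#' downstream.
#'
#' @param network A [ppi_network()].
#' @param expression Expression matrix from [read_expression_matrix()], or
#'   `NULL`.
#' @param localization Localization data.frame, or `NULL` (treated as empty).
#' @param labels Character vector of essential-protein identifiers.
#' @return Object of class `aligned_dataset`: list with `network`,
#'   `expression`, `localization`, `labels` (named 0/1 integer vector over
#'   nodes), and `dropped` (counts of discarded records).
#' @export
align_dataset <- function(network, expression, localization, labels) {
  nodes <- network$nodes
  dropped <- c(expression = 0L, localization = 0L, labels = 0L)
  if (!is.null(expression)) {
    keep <- rownames(expression) %in% nodes
    dropped["expression"] <- sum(!keep)
    expression <- expression[keep, , drop = FALSE]
  }
  if (is.null(localization))
    localization <- data.frame(protein = character(), term = character(),
                               stringsAsFactors = FALSE)
  keep <- localization$protein %in% nodes
  dropped["localization"] <- sum(!keep)
  localization <- localization[keep, , drop = FALSE]
  rownames(localization) <- NULL
  labels <- as.character(labels)
  keep <- labels %in% nodes
  dropped["labels"] <- sum(!keep)
  y <- as.integer(nodes %in% labels[keep])
  names(y) <- nodes
  if (sum(y) == 0L)
    stop("no essential protein maps onto the network; labels are all zero")
  if (any(dropped > 0))
    message(sprintf(
      "align_dataset: dropped %d expression row(s), %d localization record(s), %d label(s) outside the network",
      dropped["expression"], dropped["localization"], dropped["labels"]))
  structure(list(network = network, expression = expression,
                 localization = localization, labels = y, dropped = dropped),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat(sprintf(
    "aligned_dataset: %d proteins, %d edges, %d essential (%.1f%%), %d expression rows, %d localization records\n",
    length(x$labels), nrow(x$network$edges), sum(x$labels),
    100 * mean(x$labels),
    if (is.null(x$expression)) 0L else nrow(x$expression),
    nrow(x$localization)))
  invisible(x)
}

#' Write a feature matrix as TSV (header row, proteins in canonical order)
#' @param m Matrix with protein rownames.
#' @param path Output path.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(protein = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-protein prediction scores and labels as TSV
#' @param proteins Character vector of identifiers.
#' @param score Numeric scores in `[0, 1]`.
#' @param label Predicted 0/1 labels.
#' @param path Output path.
#' @export
write_predictions <- function(proteins, score, label, path) {
  write.table(
    data.frame(protein = proteins, score = score, label = label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
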