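#' Read a numeric matrix from TSV
#'
#' First column holds row identifiers (probes or genes), the header row holds
#' sample identifiers; missing values are encoded as `NA`.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_femnet("matrix file needs an id column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a numeric matrix to TSV
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the identifier column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "id") {
  check_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 450k-style probe annotation table
#'
#' Expects columns `probe_id`, `gene`, `region`, where `region` is one of
#' `TSS200`, `FirstExon`, `TSS1500`, `Body`.
#'
#' @param path Path to a tab-separated annotation file.
#' @return A validated data.frame.
#' @export
read_probe_annotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  validate_probe_annotation(ann)
}

valid_regions <- c("TSS200", "FirstExon", "TSS1500", "Body")

validate_probe_annotation <- function(ann) {
  need <- c("probe_id", "gene", "region")
  if (!is.data.frame(ann) || !all(need %in% names(ann)))
    stop_femnet("annotation needs columns probe_id, gene, region")
  if (!all(ann$region %in% valid_regions))
    stop_femnet("annotation region must be one of ",
                paste(valid_regions, collapse = ", "))
  if (anyDuplicated(ann[, need]))
    stop_femnet("duplicated (probe_id, gene, region) rows in annotation")
  ann[, need]
}

#' Read a sample phenotype table
#'
#' Expects columns `sample_id`, `group` (`normal`/`tumour`) and optionally
#' `subtype` (`lumA`/`lumB`/`none`).
#'
#' @param path Path to a tab-separated phenotype file.
#' @return A validated data.frame.
#' @export
read_phenotype <- function(path) {
  check_phenotype(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a protein-protein interaction edge list
#'
#' Two-column TSV of gene symbols describing undirected edges. Duplicate
#' edges and self-loops are dropped on read.
#'
#' @param path Path to the edge list (header optional, see `header`).
#' @param header Logical; does the file carry a header row?
#' @return An undirected simple [igraph::graph] object.
#' @export
read_ppi <- function(path, header = TRUE) {
  el <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(el) < 2L) stop_femnet("PPI edge list needs two columns")
  g <- igraph::graph_from_edgelist(as.matrix(el[, 1:2]), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated member genes.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_femnet("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a module report table
#'
#' One row per module: seed, size, modularity, permutation p, and, when
#' available, validation modularity and validation p.
#'
#' @param modules A list of [fem_module] objects or a data.frame from
#'   [as.data.frame.fem_module_list()].
#' @param path Output path.
#' @export
write_module_table <- function(modules, path) {
  df <- if (is.data.frame(modules)) modules else module_table(modules)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
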